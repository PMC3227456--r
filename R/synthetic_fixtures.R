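# Synthetic labeled protein surfaces: spherical-shell residue clouds with
# controllable composition and local residue co-occurrence structure, plus
# toy PDB / MSMS-vertex writers so the whole pipeline is testable offline.

# Background amino-acid frequencies (approximate natural abundances),
# normalized at use; shared by default across families so that family
# identity is carried by co-occurrence structure, not composition.
AA_BACKGROUND <- c(
  A = 0.078, C = 0.019, D = 0.053, E = 0.063, F = 0.039,
  G = 0.072, H = 0.023, I = 0.053, K = 0.059, L = 0.091,
  M = 0.022, N = 0.043, P = 0.052, Q = 0.042, R = 0.051,
  S = 0.068, T = 0.059, V = 0.066, W = 0.014, Y = 0.032
)

#' Specify a synthetic surface family
#'
#' A family is a recipe for labeled residue clouds on a spherical shell:
#' residue composition, pairwise co-occurrence boosts (type pairs whose
#' members are preferentially found within `boost_radius` of each other),
#' chain size range, shell radius and positional jitter.
#'
#' @param name Family label.
#' @param composition Named length-20 probability vector over residue
#'   types; defaults to approximate natural frequencies. Normalized to
#'   sum 1.
#' @param cooccurrence_boost data.frame with columns `center`, `partner`,
#'   `strength` (>= 1): for each residue of type `center`, with probability
#'   `1 - 1/strength` a residue within `boost_radius` is relabeled to
#'   `partner`. `strength = 1` is no boost.
#' @param size_range Integer min/max residue count, drawn uniformly.
#' @param radius Shell radius in Angstrom.
#' @param jitter Gaussian positional noise (sd, Angstrom); must be below
#'   `radius`.
#' @param boost_radius Locality of the co-occurrence boost in Angstrom
#'   (default 10, the default patch radius).
#' @return A `family_spec` object.
#' @export
family_spec <- function(name, composition = NULL, cooccurrence_boost = NULL,
                        size_range = c(40L, 80L), radius = 12, jitter = 1,
                        boost_radius = 10) {
  composition <- composition %||% AA_BACKGROUND
  stopifnot(setequal(names(composition), AA_ALPHABET),
            all(composition >= 0), sum(composition) > 0)
  composition <- composition[AA_ALPHABET] / sum(composition)
  stopifnot(length(size_range) == 2L, size_range[1L] >= 1L,
            size_range[1L] <= size_range[2L],
            radius > jitter, jitter >= 0, boost_radius > 0)
  if (!is.null(cooccurrence_boost)) {
    stopifnot(is.data.frame(cooccurrence_boost),
              all(c("center", "partner", "strength") %in%
                    names(cooccurrence_boost)),
              all(cooccurrence_boost$center %in% AA_ALPHABET),
              all(cooccurrence_boost$partner %in% AA_ALPHABET),
              all(cooccurrence_boost$strength >= 1))
  }
  structure(
    list(name = name, composition = composition,
         cooccurrence_boost = cooccurrence_boost,
         size_range = as.integer(size_range), radius = radius,
         jitter = jitter, boost_radius = boost_radius),
    class = "family_spec"
  )
}

#' @export
print.family_spec <- function(x, ...) {
  nb <- if (is.null(x$cooccurrence_boost)) 0L else nrow(x$cooccurrence_boost)
  cat(sprintf("<family_spec %s: %d-%d residues, shell %g A (jitter %g A), %d boost pair(s)>\n",
              x$name, x$size_range[1L], x$size_range[2L], x$radius,
              x$jitter, nb))
  invisible(x)
}

#' Three demonstration families
#'
#' Identical composition and geometry across families; only the boosted
#' co-occurrence pairs differ, so residue co-occurrence (RC/DRC) carries
#' the family signal while pooled distance distributions (DD1) carry
#' almost none. Sizes (80-150 surface residues on a 15 Angstrom shell) and
#' boost strength (10, i.e. 90% of center-type residues acquire a partner)
#' emulate families whose surfaces share conserved local residue pairings.
#'
#' @param strength Boost strength shared by all pairs (default 10).
#' @param size_range Residue count range per chain (default 80-150).
#' @return List of three `family_spec` objects.
#' @export
demo_family_specs <- function(strength = 10, size_range = c(80L, 150L)) {
  boost <- function(...) {
    p <- list(...)
    data.frame(center = vapply(p, `[`, "", 1L),
               partner = vapply(p, `[`, "", 2L),
               strength = strength, stringsAsFactors = FALSE)
  }
  mk <- function(name, pairs) {
    family_spec(name, cooccurrence_boost = pairs, size_range = size_range,
                radius = 15)
  }
  list(
    mk("famA", boost(c("K", "E"), c("L", "F"), c("A", "G"), c("D", "S"))),
    mk("famB", boost(c("G", "W"), c("S", "H"), c("V", "Y"), c("E", "K"))),
    mk("famC", boost(c("R", "D"), c("T", "C"), c("I", "N"), c("F", "P")))
  )
}

#' Sample one synthetic surface chain
#'
#' Residue count is uniform over the spec's size range; C-alpha positions
#' are uniform on the shell with isotropic Gaussian jitter; types are drawn
#' from the composition; then each boost pair relabels, with probability
#' `1 - 1/strength` per center-type residue, one uniformly chosen residue
#' within `boost_radius` to the partner type. Fully reproducible given
#' `seed`.
#'
#' @param spec A [family_spec()].
#' @param seed Integer RNG seed.
#' @param structure_id,chain_id Identifiers stored in the result.
#' @return A [surface_chain()].
#' @export
sample_chain <- function(spec, seed, structure_id = spec$name,
                         chain_id = "A") {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(seed)
  n <- if (spec$size_range[1L] == spec$size_range[2L]) spec$size_range[1L] else
    sample(seq(spec$size_range[1L], spec$size_range[2L]), 1L)
  # uniform direction on the sphere via normalized Gaussian triples
  dir <- matrix(stats::rnorm(3L * n), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  xyz <- dir * spec$radius + matrix(stats::rnorm(3L * n, sd = spec$jitter),
                                    ncol = 3L)
  types <- sample(AA_ALPHABET, n, replace = TRUE, prob = spec$composition)
  if (!is.null(spec$cooccurrence_boost)) {
    d2 <- as.matrix(stats::dist(xyz))^2
    r2 <- spec$boost_radius^2
    for (k in seq_len(nrow(spec$cooccurrence_boost))) {
      a <- spec$cooccurrence_boost$center[k]
      bb <- spec$cooccurrence_boost$partner[k]
      p <- 1 - 1 / spec$cooccurrence_boost$strength[k]
      for (i in which(types == a)) {
        if (stats::runif(1L) >= p) next
        nbr <- setdiff(which(d2[i, ] <= r2), i)
        if (length(nbr) == 0L) next
        j <- if (length(nbr) == 1L) nbr else nbr[sample.int(length(nbr), 1L)]
        types[j] <- bb
      }
    }
  }
  surface_chain(structure_id, chain_id,
                data.frame(residue_seq = seq_len(n), residue_type = types,
                           x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                           stringsAsFactors = FALSE))
}

#' Generate a labeled multi-family dataset
#'
#' @param specs List of at least two [family_spec()] objects.
#' @param chains_per_family Chains sampled per family.
#' @param seed Integer base seed; chain `i` of family `f` uses a seed
#'   derived deterministically from it.
#' @return List: `chains` (list of `surface_chain` with unique structure
#'   ids), `labels` (character, family per chain).
#' @export
generate_family_dataset <- function(specs, chains_per_family = 50L, seed = 1L) {
  stopifnot(length(specs) >= 2L)
  chains <- list()
  labels <- character(0)
  for (f in seq_along(specs)) {
    spec <- specs[[f]]
    for (i in seq_len(chains_per_family)) {
      sid <- sprintf("%s_%03d", spec$name, i)
      sub_seed <- as.integer((as.numeric(seed) * 1009 + f * 131 + i) %%
                               2147483647)
      chains[[sid]] <- sample_chain(spec, seed = sub_seed, structure_id = sid)
      labels <- c(labels, spec$name)
    }
  }
  list(chains = unname(chains), labels = labels)
}

#' Write a toy PDB file for a surface chain
#'
#' One fixed-column CA ATOM record per residue (occupancy 1.00, B-factor
#' 0.00, element C), terminated by TER and END, so the file round-trips
#' through [read_pdb_chains()].
#'
#' @param chain A `surface_chain`.
#' @param path Output path.
#' @export
write_toy_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "surface_chain"))
  res <- chain$residues
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(res)), AA_1TO3[res$residue_type],
    substr(chain$chain_id, 1L, 1L), res$residue_seq,
    res$x, res$y, res$z, 1, 0
  )
  ok <- tryCatch({
    writeLines(c(lines, "TER", "END"), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_sp("cannot write PDB to %s", path)
  invisible(path)
}

#' Write a matching toy MSMS-style vertex file
#'
#' One vertex per residue, placed by inflating the C-alpha position
#' radially from the chain centroid by `probe_radius`; the nearest-atom
#' index of vertex i is i (the writer emits one CA atom per residue in the
#' same order), so [select_surface_residues()] marks every residue surface.
#'
#' @param chain A `surface_chain`.
#' @param path Output path.
#' @param probe_radius Inflation distance in Angstrom (default 1.4).
#' @export
write_toy_vert <- function(chain, path, probe_radius = 1.4) {
  stopifnot(inherits(chain, "surface_chain"))
  res <- chain$residues
  xyz <- as.matrix(res[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2L, ctr)
  nrm <- sqrt(rowSums(rel^2))
  nrm[nrm == 0] <- 1
  normals <- rel / nrm
  verts <- xyz + normals * probe_radius
  n <- nrow(res)
  body <- sprintf("%9.3f %9.3f %9.3f %9.3f %9.3f %9.3f %7d %7d %2d",
                  verts[, 1L], verts[, 2L], verts[, 3L],
                  normals[, 1L], normals[, 2L], normals[, 3L],
                  seq_len(n), seq_len(n), 1L)
  hdr <- c("# toy MSMS-style vertex file",
           "#faces  #sphere density probe_r",
           sprintf("%8d %8d %8.2f %8.2f", n, n, 1.0, probe_radius))
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_sp("cannot write vertex file to %s", path)
  invisible(path)
}
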