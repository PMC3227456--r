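# Structure input: PDB chains, MSMS vertex files, surface-residue selection.

#' Read the protein chains of a PDB file
#'
#' Parses the ATOM records of a PDB file (first model only) into one entry
#' per chain. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by the lexicographically first altloc code).
#' HETATM records are ignored except for MSE, SEC and PYL, which are kept
#' and remapped to M, C and K; any other residue type outside the 20-letter
#' canonical alphabet is discarded. Residues whose C-alpha atom is missing
#' are dropped with a warning.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param model_policy Multi-model handling; only `"first"` is supported.
#' @return A named list with one `pdb_chain` object per chain id. Each holds
#'   `$atoms` (all kept atoms: residue_seq, residue_type, atom_name,
#'   x, y, z, occupancy, altloc) and `$residues` (one row per residue with a
#'   C-alpha: residue_seq, residue_type, x, y, z).
#' @seealso [select_surface_residues()], [sasa_surface_fallback()]
#' @export
read_pdb_chains <- function(path, model_policy = "first") {
  if (!file.exists(path)) stop_sp("PDB file not found: %s", path)
  model_policy <- match.arg(model_policy, "first")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop_sp("not a parsable PDB file: %s (%s)",
                                path, conditionMessage(e))
  )
  at <- pdb$atom
  # first model only: bio3d with multi = FALSE already truncates coordinates
  # to model 1, but the atom table can repeat across MODEL records
  n_xyz <- length(pdb$xyz[1, ]) / 3
  if (nrow(at) > n_xyz) at <- at[seq_len(n_xyz), , drop = FALSE]

  keep <- at$type == "ATOM" | (at$type == "HETATM" &
                                 at$resid %in% c("MSE", "SEC", "PYL"))
  at <- at[keep & at$resid %in% names(AA_3TO1), , drop = FALSE]
  if (nrow(at) == 0L) stop_sp("no parsable ATOM records in %s", path)

  at$residue_type <- unname(AA_3TO1[at$resid])
  at$altloc <- ifelse(is.na(at$alt) | at$alt == "", " ", at$alt)
  at$occupancy <- ifelse(is.na(at$o), 1, at$o)
  at$chain[is.na(at$chain)] <- " "

  out <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    ca <- resolve_altloc(ca)
    atoms <- data.frame(
      residue_seq = ca$resno, residue_type = ca$residue_type,
      atom_name = ca$elety, x = ca$x, y = ca$y, z = ca$z,
      occupancy = ca$occupancy, altloc = ca$altloc,
      stringsAsFactors = FALSE
    )
    if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
      stop_sp("non-finite coordinates in %s chain %s", path, ch)
    }
    is_ca <- atoms$atom_name == "CA"
    res_seq <- sort(unique(atoms$residue_seq))
    no_ca <- setdiff(res_seq, atoms$residue_seq[is_ca])
    if (length(no_ca) > 0L) {
      warning(sprintf("chain %s: dropping %d residue(s) without a CA atom (%s)",
                      ch, length(no_ca), paste(no_ca, collapse = ", ")),
              call. = FALSE)
    }
    cas <- atoms[is_ca, , drop = FALSE]
    cas <- cas[order(cas$residue_seq), , drop = FALSE]
    residues <- data.frame(
      residue_seq = cas$residue_seq, residue_type = cas$residue_type,
      x = cas$x, y = cas$y, z = cas$z, stringsAsFactors = FALSE
    )
    out[[ch]] <- structure(
      list(chain_id = ch, atoms = atoms, residues = residues),
      class = "pdb_chain"
    )
  }
  out
}

# Keep, per (residue, atom name), the highest-occupancy altloc; ties go to
# the lexicographically first altloc code.
resolve_altloc <- function(at) {
  ord <- order(at$resno, at$elety, -at$occupancy, at$altloc)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(paste(at$resno, at$elety, sep = "\r")), , drop = FALSE]
}

#' @export
print.pdb_chain <- function(x, ...) {
  cat(sprintf("<pdb_chain %s: %d atoms, %d residues with CA>\n",
              x$chain_id, nrow(x$atoms), nrow(x$residues)))
  invisible(x)
}

#' Read an MSMS dot-surface vertex file
#'
#' Reads the `.vert` file written by the MSMS program: three header lines
#' (two comments, then a counts line whose first field is the number of
#' vertices), followed by one line per vertex with the coordinates, the
#' outward normal, and integer annotation fields of which the second is the
#' index of the closest atom/sphere.
#'
#' @param path Path to the `.vert` file.
#' @return A `surface_vertices` object: `$vertices` (n x 3 matrix, Angstrom),
#'   `$normals` (n x 3 or NULL), `$nearest_atom` (1-based integer vector or
#'   NULL), `$probe_radius` (parsed from the header when present, else NA).
#' @export
read_msms_vertices <- function(path) {
  if (!file.exists(path)) stop_sp("vertex file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop_sp("vertex file %s: fewer than 3 header lines", path)
  hdr <- strsplit(trimws(lines[3L]), "\\s+")[[1]]
  n_decl <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(n_decl)) stop_sp("vertex file %s: bad count header '%s'", path, lines[3L])
  if (n_decl <= 0L) stop_sp("vertex file %s declares an empty surface", path)
  probe <- if (length(hdr) >= 4L) suppressWarnings(as.numeric(hdr[4L])) else NA_real_

  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_decl) {
    stop_sp("vertex file %s: header declares %d vertices but body has %d lines",
            path, n_decl, length(body))
  }
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  verts <- matrix(NA_real_, n_decl, 3L)
  normals <- matrix(NA_real_, n_decl, 3L)
  nearest <- rep(NA_integer_, n_decl)
  for (i in seq_len(n_decl)) {
    f <- suppressWarnings(as.numeric(fields[[i]]))
    if (any(is.na(f[seq_len(min(3L, nf[i]))])) || nf[i] < 3L) {
      stop_sp("vertex file %s: non-numeric coordinate on body line %d", path, i)
    }
    verts[i, ] <- f[1:3]
    if (nf[i] >= 6L && !any(is.na(f[4:6]))) normals[i, ] <- f[4:6]
    if (nf[i] >= 8L && !is.na(f[8L])) nearest[i] <- as.integer(f[8L])
  }
  if (any(is.na(normals))) normals <- NULL
  if (any(is.na(nearest))) nearest <- NULL
  if (!is.null(normals)) {
    nrm <- sqrt(rowSums(normals^2))
    if (any(abs(nrm - 1) > 1e-3)) {
      warning("vertex normals are not unit length; ignoring them", call. = FALSE)
      normals <- NULL
    }
  }
  structure(
    list(vertices = verts, normals = normals, nearest_atom = nearest,
         probe_radius = probe),
    class = "surface_vertices"
  )
}

#' @export
print.surface_vertices <- function(x, ...) {
  cat(sprintf("<surface_vertices: %d vertices%s%s>\n", nrow(x$vertices),
              if (is.null(x$normals)) "" else ", normals",
              if (is.null(x$nearest_atom)) "" else ", nearest-atom indices"))
  invisible(x)
}

#' Construct a surface chain
#'
#' A `surface_chain` is one protein chain reduced to its surface residues:
#' residue type (1-letter) and C-alpha coordinate each, ordered by residue
#' number. This is the input unit of [surface_descriptor()].
#'
#' @param structure_id Structure identifier (e.g. a PDB id).
#' @param chain_id Chain identifier.
#' @param residues data.frame with columns residue_seq, residue_type
#'   (1-letter), x, y, z.
#' @return A `surface_chain` object.
#' @export
surface_chain <- function(structure_id, chain_id, residues) {
  stopifnot(is.data.frame(residues),
            all(c("residue_seq", "residue_type", "x", "y", "z") %in%
                  names(residues)))
  bad <- !residues$residue_type %in% AA_ALPHABET
  if (any(bad)) {
    stop_sp("residue types outside the canonical alphabet: %s",
            paste(unique(residues$residue_type[bad]), collapse = ", "))
  }
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z")])))) {
    stop_sp("non-finite C-alpha coordinates")
  }
  residues <- residues[order(residues$residue_seq), , drop = FALSE]
  rownames(residues) <- NULL
  structure(
    list(structure_id = as.character(structure_id),
         chain_id = as.character(chain_id),
         residues = residues[, c("residue_seq", "residue_type", "x", "y", "z")]),
    class = "surface_chain"
  )
}

#' @export
print.surface_chain <- function(x, ...) {
  cat(sprintf("<surface_chain %s chain %s: %d surface residues>\n",
              x$structure_id, x$chain_id, nrow(x$residues)))
  invisible(x)
}

#' @export
as.data.frame.surface_chain <- function(x, ...) {
  cbind(structure_id = x$structure_id, chain_id = x$chain_id, x$residues,
        stringsAsFactors = FALSE)
}

#' Select surface residues by dot-surface vertex ownership
#'
#' Each surface vertex is owned by the atom nearest to it (the vertex file's
#' nearest-atom index when present, else a nearest-neighbor search over the
#' chain's atoms). A residue is a surface residue iff it owns at least one
#' vertex. Interior residues are discarded; surface residues are reduced to
#' residue type plus C-alpha coordinate.
#'
#' @param chain A `pdb_chain` from [read_pdb_chains()].
#' @param vertices A `surface_vertices` from [read_msms_vertices()]. A
#'   nearest-atom index, when present, is interpreted as 1-based into
#'   `chain$atoms` row order.
#' @param structure_id Structure identifier stored in the result.
#' @return A [surface_chain()].
#' @export
select_surface_residues <- function(chain, vertices, structure_id = "struct") {
  stopifnot(inherits(chain, "pdb_chain"), inherits(vertices, "surface_vertices"))
  if (nrow(chain$atoms) == 0L) stop_sp("chain has no atoms")
  if (nrow(vertices$vertices) == 0L) stop_sp("empty vertex set")

  owner <- vertices$nearest_atom
  if (is.null(owner)) {
    owner <- nearest_atom_index(vertices$vertices,
                                as.matrix(chain$atoms[, c("x", "y", "z")]))
  } else if (any(owner < 1L | owner > nrow(chain$atoms))) {
    stop_sp("nearest-atom index out of range for this chain")
  }
  surf_seq <- unique(chain$atoms$residue_seq[owner])
  res <- chain$residues[chain$residues$residue_seq %in% surf_seq, , drop = FALSE]
  if (nrow(res) == 0L) stop_sp("no surface residues (surface/structure mismatch?)")
  surface_chain(structure_id, chain$chain_id, res)
}

# For each query point the index of the nearest atom; ties resolved to the
# lowest atom index (deterministic under input-order permutation only via
# exact coordinates, which is what the tests exercise).
nearest_atom_index <- function(points, atoms) {
  n <- nrow(points)
  out <- integer(n)
  a2 <- rowSums(atoms^2)
  step <- max(1L, floor(1e6 / nrow(atoms)))
  for (start in seq(1L, n, by = step)) {
    idx <- start:min(n, start + step - 1L)
    p <- points[idx, , drop = FALSE]
    # squared distances via expansion; rows = points, cols = atoms
    d2 <- outer(rowSums(p^2), a2, "+") - 2 * p %*% t(atoms)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Surface residues by solvent accessibility (fallback)
#'
#' When no dot-surface vertex file is available, marks a residue as surface
#' iff its relative solvent-accessible surface area (Shrake-Rupley, fixed
#' deterministic 960-point sphere lattice, normalized by a per-residue-type
#' maximum) is at least `rel_threshold`.
#'
#' @param chain A `pdb_chain`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param rel_threshold Relative SASA cutoff in `[0, 1]` (default 0.05).
#' @param structure_id Structure identifier stored in the result.
#' @return A [surface_chain()].
#' @export
sasa_surface_fallback <- function(chain, probe_radius = 1.4,
                                  rel_threshold = 0.05,
                                  structure_id = "struct") {
  stopifnot(inherits(chain, "pdb_chain"), probe_radius > 0)
  if (nrow(chain$atoms) == 0L) stop_sp("chain has no atoms")
  sasa <- residue_sasa(chain$atoms, probe_radius)
  res <- chain$residues
  rel <- rep(NA_real_, nrow(res))
  for (i in seq_len(nrow(res))) {
    s <- sasa$area[match(res$residue_seq[i], sasa$residue_seq)]
    mx <- AA_MAX_SASA[[res$residue_type[i]]]
    rel[i] <- s / mx
  }
  keep <- !is.na(rel) & rel >= rel_threshold
  if (!any(keep)) stop_sp("no surface residues (all below relative SASA %.3g)",
                          rel_threshold)
  surface_chain(structure_id, chain$chain_id, res[keep, , drop = FALSE])
}

# Van der Waals radius from the first letter of the atom name (PDB
# convention: digits stripped, element is the leading letter for standard
# protein atoms).
atom_vdw_radius <- function(atom_name) {
  el <- substr(gsub("[0-9]", "", trimws(atom_name)), 1L, 1L)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)[el]
  ifelse(is.na(r), 1.70, unname(r))
}

# Deterministic golden-spiral lattice of n points on the unit sphere.
sphere_lattice <- function(n = 960L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley accessible surface area per residue, summed over its atoms.
residue_sasa <- function(atoms, probe_radius, n_points = 960L) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atom_vdw_radius(atoms$atom_name) + probe_radius
  pts <- sphere_lattice(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    test <- sweep(pts * rad[i], 2L, xyz[i, ], "+")
    nbr <- which(rowSums(sweep(xyz, 2L, xyz[i, ], "-")^2) <
                   (rad + rad[i])^2)
    nbr <- setdiff(nbr, i)
    free <- rep(TRUE, n_points)
    for (j in nbr) {
      d2 <- rowSums(sweep(test, 2L, xyz[j, ], "-")^2)
      free <- free & d2 >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  stats::aggregate(list(area = area),
                   by = list(residue_seq = atoms$residue_seq), FUN = sum)
}

#' Write / read a surface chain as TSV
#'
#' Columns: structure_id, chain_id, residue_seq, residue_type, x, y, z.
#'
#' @param chain A `surface_chain`.
#' @param path Output (input) path.
#' @return `write_chain_tsv` returns `path` invisibly; `read_chain_tsv`
#'   returns a `surface_chain`.
#' @export
write_chain_tsv <- function(chain, path) {
  stopifnot(inherits(chain, "surface_chain"))
  utils::write.table(as.data.frame(chain), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_tsv
#' @export
read_chain_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  surface_chain(df$structure_id[1L], df$chain_id[1L],
                df[, c("residue_seq", "residue_type", "x", "y", "z")])
}
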