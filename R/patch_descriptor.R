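# Circular surface patches and the local/global invariant descriptors.
#
# A patch is the set of surface residues whose C-alpha lies within tau_p of
# a central surface residue's C-alpha. Its local descriptor is a
# (20+1) x (b+1) matrix: 20 residue-type rows x b distance-bin columns of
# member counts, bordered by the distance-distribution marginal row (sum C)
# and the residue co-occurrence marginal column (sum R). Global descriptors
# average the per-patch marginals over patches sharing a central type.

#' Build one circular patch per surface residue
#'
#' Membership is by Euclidean C-alpha distance `d <= tau_p`; the center is
#' not a member of its own patch. Centers with no member within `tau_p`
#' yield empty patches, which are kept but contribute nothing to the global
#' averages.
#'
#' @param chain A [surface_chain()].
#' @param tau_p Patch radius in Angstrom (default 10).
#' @return A `patch_set`: list of patches, each with `center_index`,
#'   `center_type`, `tau_p` and a `members` data.frame (index, residue_type,
#'   distance) sorted by (distance, index).
#' @export
build_patches <- function(chain, tau_p = 10) {
  stopifnot(inherits(chain, "surface_chain"), tau_p > 0)
  res <- chain$residues
  n <- nrow(res)
  if (n == 0L) stop_sp("empty surface chain")
  dmat <- as.matrix(stats::dist(res[, c("x", "y", "z")]))
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dmat[i, ]
    j <- setdiff(which(d <= tau_p), i)
    ord <- order(d[j], j)
    j <- j[ord]
    patches[[i]] <- list(
      center_index = i,
      center_type = res$residue_type[i],
      tau_p = tau_p,
      members = data.frame(index = j, residue_type = res$residue_type[j],
                           distance = unname(d[j]), stringsAsFactors = FALSE)
    )
  }
  structure(patches, class = "patch_set", tau_p = tau_p,
            structure_id = chain$structure_id, chain_id = chain$chain_id)
}

#' @export
print.patch_set <- function(x, ...) {
  sizes <- vapply(x, function(p) nrow(p$members), integer(1))
  cat(sprintf("<patch_set: %d patches (tau_p = %g A), %d empty, mean size %.1f>\n",
              length(x), attr(x, "tau_p"), sum(sizes == 0L), mean(sizes)))
  invisible(x)
}

#' Local patch descriptor
#'
#' Counts patch members into a 20 x b matrix (rows: residue types in
#' alphabetical 1-letter order; columns: uniform distance bins over
#' `(0, tau_p]`, the last bin closed at `tau_p`), with the marginal
#' distance-distribution row `sum_c` and co-occurrence column `sum_r`.
#'
#' @param patch One element of a [build_patches()] result.
#' @param b Number of distance bins (default 5).
#' @return A `local_descriptor`: `center_type`, `counts` (20 x b),
#'   `sum_c` (length b), `sum_r` (length 20, named), `b`, `tau_p`.
#' @export
local_descriptor <- function(patch, b = 5L) {
  stopifnot(b >= 1L)
  tau_p <- patch$tau_p
  counts <- matrix(0L, nrow = 20L, ncol = b,
                   dimnames = list(AA_ALPHABET, NULL))
  m <- patch$members
  if (nrow(m) > 0L) {
    if (any(m$distance > tau_p | m$distance <= 0)) {
      stop_sp("patch member distance outside (0, tau_p]: invariant broken")
    }
    bin <- pmin(b, floor(m$distance / (tau_p / b)) + 1L)
    for (k in seq_len(nrow(m))) {
      counts[m$residue_type[k], bin[k]] <- counts[m$residue_type[k], bin[k]] + 1L
    }
  }
  structure(
    list(center_type = patch$center_type, counts = counts,
         sum_c = colSums(counts), sum_r = rowSums(counts),
         b = as.integer(b), tau_p = tau_p),
    class = "local_descriptor"
  )
}

#' @export
print.local_descriptor <- function(x, ...) {
  cat(sprintf("<local_descriptor: center %s, %d members, b = %d, tau_p = %g A>\n",
              x$center_type, sum(x$counts), x$b, x$tau_p))
  invisible(x)
}

#' Local descriptors for every patch
#'
#' @param patches A `patch_set`.
#' @inheritParams local_descriptor
#' @return List of `local_descriptor` objects, one per patch.
#' @export
local_descriptors <- function(patches, b = 5L) {
  lapply(patches, local_descriptor, b = b)
}

#' Aggregate local descriptors into the global descriptor
#'
#' For each central residue type, each non-empty patch's `sum_c` and `sum_r`
#' are normalized to probability vectors and averaged element-wise over that
#' type's non-empty patches (the default); with `normalize = "pooled"` the
#' raw counts are pooled per central type and normalized once. Types never
#' central (or central only of empty patches) get all-zero vectors.
#'
#' @param locals List of `local_descriptor` objects sharing `b` and `tau_p`.
#' @param b,tau_p Descriptor parameters; taken from `locals` when NULL.
#' @param normalize `"patch"` (normalize each patch, then average) or
#'   `"pooled"` (pool counts per central type, then normalize).
#' @return A `surface_descriptor` (see [surface_descriptor()]).
#' @export
global_descriptor <- function(locals, b = NULL, tau_p = NULL,
                              normalize = c("patch", "pooled")) {
  normalize <- match.arg(normalize)
  if (length(locals) == 0L) stop_sp("no local descriptors")
  b <- b %||% locals[[1L]]$b
  tau_p <- tau_p %||% locals[[1L]]$tau_p
  for (l in locals) {
    if (l$b != b || l$tau_p != tau_p) {
      stop_sp("local descriptors disagree on b or tau_p")
    }
  }
  blocks <- stats::setNames(vector("list", 20L), AA_ALPHABET)
  nonempty_total <- 0L
  dd1 <- numeric(b)
  for (aa in AA_ALPHABET) {
    of_type <- Filter(function(l) l$center_type == aa, locals)
    nonempty <- Filter(function(l) sum(l$sum_c) > 0L, of_type)
    if (length(nonempty) == 0L) {
      blocks[[aa]] <- list(dd = numeric(b), rc = numeric(20L),
                           n_patches = length(of_type), n_nonempty = 0L)
      next
    }
    if (normalize == "patch") {
      dd <- Reduce(`+`, lapply(nonempty, function(l) l$sum_c / sum(l$sum_c)))
      rc <- Reduce(`+`, lapply(nonempty, function(l) l$sum_r / sum(l$sum_r)))
      dd <- dd / length(nonempty)
      rc <- rc / length(nonempty)
    } else {
      cpool <- Reduce(`+`, lapply(nonempty, `[[`, "sum_c"))
      rpool <- Reduce(`+`, lapply(nonempty, `[[`, "sum_r"))
      dd <- cpool / sum(cpool)
      rc <- rpool / sum(rpool)
    }
    blocks[[aa]] <- list(dd = unname(dd), rc = stats::setNames(unname(rc), AA_ALPHABET),
                         n_patches = length(of_type),
                         n_nonempty = length(nonempty))
    nonempty_total <- nonempty_total + length(nonempty)
  }
  all_nonempty <- Filter(function(l) sum(l$sum_c) > 0L, locals)
  if (length(all_nonempty) > 0L) {
    dd1 <- Reduce(`+`, lapply(all_nonempty, function(l) l$sum_c / sum(l$sum_c))) /
      length(all_nonempty)
  }
  structure(
    list(blocks = blocks, b = as.integer(b), tau_p = tau_p,
         normalize = normalize, dd1 = unname(dd1),
         n_patches = length(locals), n_nonempty = length(all_nonempty),
         structure_id = NA_character_, chain_id = NA_character_),
    class = "surface_descriptor"
  )
}

#' Fit the invariant surface descriptor of a chain
#'
#' The main entry point: builds one circular patch per surface residue,
#' computes the local (20+1) x (b+1) descriptor of each, and averages the
#' per-patch distance distributions and residue co-occurrences over patches
#' sharing a central residue type. The result is invariant to rotation,
#' translation, mirroring and residue input order, and its vector views have
#' fixed length regardless of chain size: DD1 = `b`, DD2 = `20 b`,
#' RC = `400`, DRC = `20 (b + 20)`.
#'
#' @param chain A [surface_chain()].
#' @param tau_p Patch radius in Angstrom (default 10).
#' @param b Number of distance bins (default 5).
#' @param normalize See [global_descriptor()].
#' @return A `surface_descriptor` object; extract matching vectors with
#'   [descriptor_vector()] (or [dd2_vector()], [rc_vector()], [drc_vector()],
#'   [dd1_vector()]).
#' @examples
#' ch <- sample_chain(demo_family_specs()[[1]], seed = 1)
#' g <- surface_descriptor(ch)
#' g
#' length(drc_vector(g))
#' @export
surface_descriptor <- function(chain, tau_p = 10, b = 5L,
                               normalize = c("patch", "pooled")) {
  normalize <- match.arg(normalize)
  patches <- build_patches(chain, tau_p = tau_p)
  locals <- local_descriptors(patches, b = b)
  g <- global_descriptor(locals, b = b, tau_p = tau_p, normalize = normalize)
  g$structure_id <- chain$structure_id
  g$chain_id <- chain$chain_id
  g$n_surface <- nrow(chain$residues)
  g
}

#' @export
print.surface_descriptor <- function(x, ...) {
  cat(sprintf("<surface_descriptor %s/%s: b = %d, tau_p = %g A, %d patches (%d non-empty), %s-normalized>\n",
              x$structure_id, x$chain_id, x$b, x$tau_p,
              x$n_patches, x$n_nonempty, x$normalize))
  invisible(x)
}

#' @export
summary.surface_descriptor <- function(object, ...) {
  counts <- vapply(object$blocks, function(bl) bl$n_nonempty, integer(1))
  cat(sprintf("Surface descriptor for %s chain %s\n",
              object$structure_id, object$chain_id))
  cat(sprintf("  parameters: tau_p = %g A, b = %d bins, %s normalization\n",
              object$tau_p, object$b, object$normalize))
  cat(sprintf("  patches: %d total, %d non-empty\n",
              object$n_patches, object$n_nonempty))
  cat("  non-empty patches per central residue type:\n")
  print(counts)
  cat(sprintf("  vector lengths: DD1 = %d, DD2 = %d, RC = %d, DRC = %d\n",
              object$b, 20L * object$b, 400L, 20L * (object$b + 20L)))
  invisible(counts)
}

#' @export
plot.surface_descriptor <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  edges <- seq(0, x$tau_p, length.out = x$b + 1L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  graphics::barplot(x$dd1, names.arg = sprintf("%.0f", mids),
                    xlab = "center distance (A)", ylab = "probability",
                    main = "pooled distance distribution (DD1)", ...)
  rcm <- t(vapply(x$blocks, function(bl) bl$rc, numeric(20L)))
  graphics::image(seq_len(20L), seq_len(20L), rcm, axes = FALSE,
                  xlab = "central residue", ylab = "co-occurring residue",
                  main = "residue co-occurrences (RC)")
  graphics::axis(1, at = seq_len(20L), labels = AA_ALPHABET, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(20L), labels = AA_ALPHABET, cex.axis = 0.6)
  invisible(x)
}

#' Global descriptor matching vectors
#'
#' `dd2_vector` concatenates the 20 per-central-type mean distance
#' distributions (length `20 b`, estimates Pr(d | Rc)); `rc_vector` the 20
#' mean co-occurrence vectors (length 400, estimates Pr(Ri | Rc));
#' `drc_vector` interleaves both per central type (length `20 (b + 20)`,
#' carries Pr(d | Rc, Ri)); `dd1_vector` is the pooled distance distribution
#' over all non-empty patches regardless of central type (length `b`).
#' Blocks are concatenated in alphabetical 1-letter residue order.
#'
#' @param g A `surface_descriptor`.
#' @return A named numeric vector.
#' @export
dd2_vector <- function(g) {
  stopifnot(inherits(g, "surface_descriptor"))
  v <- unlist(lapply(AA_ALPHABET, function(aa) g$blocks[[aa]]$dd))
  stats::setNames(v, paste0(rep(AA_ALPHABET, each = g$b), "_bin",
                            rep(seq_len(g$b), times = 20L)))
}

#' @rdname dd2_vector
#' @export
rc_vector <- function(g) {
  stopifnot(inherits(g, "surface_descriptor"))
  v <- unlist(lapply(AA_ALPHABET, function(aa) unname(g$blocks[[aa]]$rc)))
  stats::setNames(v, paste0(rep(AA_ALPHABET, each = 20L), "_cooc_",
                            rep(AA_ALPHABET, times = 20L)))
}

#' @rdname dd2_vector
#' @export
drc_vector <- function(g) {
  stopifnot(inherits(g, "surface_descriptor"))
  v <- unlist(lapply(AA_ALPHABET, function(aa) {
    c(g$blocks[[aa]]$dd, unname(g$blocks[[aa]]$rc))
  }))
  nm <- unlist(lapply(AA_ALPHABET, function(aa) {
    c(paste0(aa, "_bin", seq_len(g$b)), paste0(aa, "_cooc_", AA_ALPHABET))
  }))
  stats::setNames(v, nm)
}

#' @rdname dd2_vector
#' @param x For `dd1_vector`: a `surface_descriptor` or a list of
#'   `local_descriptor` objects.
#' @export
dd1_vector <- function(x) {
  if (inherits(x, "surface_descriptor")) {
    return(stats::setNames(x$dd1, paste0("bin", seq_len(x$b))))
  }
  nonempty <- Filter(function(l) sum(l$sum_c) > 0L, x)
  b <- if (length(x) > 0L) x[[1L]]$b else stop_sp("no local descriptors")
  if (length(nonempty) == 0L) return(stats::setNames(numeric(b),
                                                     paste0("bin", seq_len(b))))
  v <- Reduce(`+`, lapply(nonempty, function(l) l$sum_c / sum(l$sum_c))) /
    length(nonempty)
  stats::setNames(unname(v), paste0("bin", seq_len(b)))
}

#' Extract a matching vector by scheme name
#'
#' @param g A `surface_descriptor`.
#' @param scheme One of `"dd1"`, `"dd2"`, `"rc"`, `"drc"`.
#' @return Named numeric vector of the scheme's fixed length.
#' @export
descriptor_vector <- function(g, scheme = c("drc", "dd1", "dd2", "rc")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         dd1 = dd1_vector(g),
         dd2 = dd2_vector(g),
         rc = rc_vector(g),
         drc = drc_vector(g))
}

#' Fixed length of a scheme's matching vector
#' @inheritParams descriptor_vector
#' @param b Number of distance bins.
#' @return Integer vector length.
#' @export
scheme_length <- function(scheme = c("drc", "dd1", "dd2", "rc"), b = 5L) {
  scheme <- match.arg(scheme)
  b <- as.integer(b)
  switch(scheme, dd1 = b, dd2 = 20L * b, rc = 400L, drc = 20L * (b + 20L))
}

#' Write / read a surface descriptor as JSON
#'
#' The JSON records the parameters (`b`, `tau_p`, normalization) and the 20
#' per-central-type blocks keyed by residue letter, so the file is
#' self-describing.
#'
#' @param g A `surface_descriptor`.
#' @param path Output (input) path.
#' @export
write_descriptor_json <- function(g, path) {
  stopifnot(inherits(g, "surface_descriptor"))
  obj <- list(structure_id = g$structure_id, chain_id = g$chain_id,
              b = g$b, tau_p = g$tau_p, normalize = g$normalize,
              n_patches = g$n_patches, n_nonempty = g$n_nonempty,
              dd1 = g$dd1,
              blocks = lapply(g$blocks, function(bl) {
                list(dd = bl$dd, rc = unname(bl$rc),
                     n_patches = bl$n_patches, n_nonempty = bl$n_nonempty)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_descriptor_json
#' @export
read_descriptor_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- lapply(obj$blocks, function(bl) {
    list(dd = as.numeric(bl$dd),
         rc = stats::setNames(as.numeric(bl$rc), AA_ALPHABET),
         n_patches = as.integer(bl$n_patches),
         n_nonempty = as.integer(bl$n_nonempty))
  })
  structure(
    list(blocks = blocks[AA_ALPHABET], b = as.integer(obj$b),
         tau_p = obj$tau_p, normalize = obj$normalize,
         dd1 = as.numeric(obj$dd1), n_patches = as.integer(obj$n_patches),
         n_nonempty = as.integer(obj$n_nonempty),
         structure_id = obj$structure_id, chain_id = obj$chain_id),
    class = "surface_descriptor"
  )
}
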