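# Independent brute-force references and small generators used across the
# test files. Everything here is deliberately naive (explicit loops,
# different summation orders) so it cannot share a defect with the
# package's vectorized paths.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# A quick random surface chain (uniform box, not the package generator).
random_chain <- function(n, seed, id = "rnd") {
  set.seed(seed)
  surface_chain(id, "A", data.frame(
    residue_seq = seq_len(n),
    residue_type = sample(AA20, n, replace = TRUE),
    x = runif(n, -15, 15), y = runif(n, -15, 15), z = runif(n, -15, 15),
    stringsAsFactors = FALSE
  ))
}

# Brute-force local count matrices: explicit double loop over ordered
# residue pairs, explicit bin scan.
oracle_local_counts <- function(chain, tau_p, b) {
  res <- chain$residues
  n <- nrow(res)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    counts <- matrix(0L, 20L, b, dimnames = list(AA20, NULL))
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((res$x[i] - res$x[j])^2 + (res$y[i] - res$y[j])^2 +
                  (res$z[i] - res$z[j])^2)
      if (d > tau_p) next
      bin <- NA_integer_
      for (k in seq_len(b)) {
        lo <- (k - 1) * tau_p / b
        hi <- k * tau_p / b
        inside <- if (k < b) (d >= lo && d < hi) else (d >= lo && d <= tau_p)
        if (inside) { bin <- k; break }
      }
      counts[res$residue_type[j], bin] <- counts[res$residue_type[j], bin] + 1L
    }
    out[[i]] <- list(center_type = res$residue_type[i], counts = counts)
  }
  out
}

# Brute-force global vectors from oracle counts: iterate patches in
# reverse order, accumulate running means per central type.
oracle_global <- function(olocals, b) {
  dd <- matrix(0, 20L, b, dimnames = list(AA20, NULL))
  rc <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
  n_nonempty <- setNames(integer(20L), AA20)
  dd1 <- numeric(b)
  n_all <- 0L
  for (l in rev(olocals)) {
    tot <- sum(l$counts)
    if (tot == 0L) next
    sum_c <- numeric(b)
    sum_r <- setNames(numeric(20L), AA20)
    for (aa in AA20) for (k in seq_len(b)) {
      sum_c[k] <- sum_c[k] + l$counts[aa, k]
      sum_r[aa] <- sum_r[aa] + l$counts[aa, k]
    }
    ct <- l$center_type
    dd[ct, ] <- dd[ct, ] + sum_c / tot
    rc[ct, ] <- rc[ct, ] + sum_r / tot
    n_nonempty[ct] <- n_nonempty[ct] + 1L
    dd1 <- dd1 + sum_c / tot
    n_all <- n_all + 1L
  }
  for (aa in AA20) {
    if (n_nonempty[aa] > 0L) {
      dd[aa, ] <- dd[aa, ] / n_nonempty[aa]
      rc[aa, ] <- rc[aa, ] / n_nonempty[aa]
    }
  }
  dd2_vec <- numeric(0)
  rc_vec <- numeric(0)
  drc_vec <- numeric(0)
  for (aa in AA20) {
    dd2_vec <- c(dd2_vec, dd[aa, ])
    rc_vec <- c(rc_vec, rc[aa, ])
    drc_vec <- c(drc_vec, dd[aa, ], rc[aa, ])
  }
  list(dd2 = unname(dd2_vec), rc = unname(rc_vec), drc = unname(drc_vec),
       dd1 = if (n_all > 0L) dd1 / n_all else dd1)
}

# Random proper rotation (det +1) via QR of a Gaussian matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9L), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

apply_transform <- function(chain, R, shift = c(0, 0, 0)) {
  res <- chain$residues
  xyz <- as.matrix(res[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2L, shift, "+")
  res$x <- xyz[, 1L]; res$y <- xyz[, 2L]; res$z <- xyz[, 3L]
  surface_chain(chain$structure_id, chain$chain_id, res)
}

permute_chain <- function(chain, seed) {
  set.seed(seed)
  res <- chain$residues[sample.int(nrow(chain$residues)), , drop = FALSE]
  surface_chain(chain$structure_id, chain$chain_id, res)
}

# Naive point-counting SASA at the same deterministic lattice.
oracle_sasa <- function(atoms, probe, n_points = 960L) {
  pts <- surfpatch:::sphere_lattice(n_points)
  rad <- surfpatch:::atom_vdw_radius(atoms$atom_name) + probe
  per_res <- setNames(numeric(length(unique(atoms$residue_seq))),
                      sort(unique(atoms$residue_seq)))
  for (i in seq_len(nrow(atoms))) {
    n_free <- 0L
    for (p in seq_len(n_points)) {
      tp <- c(atoms$x[i], atoms$y[i], atoms$z[i]) + pts[p, ] * rad[i]
      free <- TRUE
      for (j in seq_len(nrow(atoms))) {
        if (j == i) next
        d2 <- (tp[1] - atoms$x[j])^2 + (tp[2] - atoms$y[j])^2 +
          (tp[3] - atoms$z[j])^2
        if (d2 < rad[j]^2) { free <- FALSE; break }
      }
      if (free) n_free <- n_free + 1L
    }
    key <- as.character(atoms$residue_seq[i])
    per_res[key] <- per_res[key] + 4 * pi * rad[i]^2 * n_free / n_points
  }
  per_res
}

# Tiny all-atom chain builder for the structure tests: each residue gets a
# CA at `coord` (plus optional extra atoms).
toy_pdb_chain <- function(coords, types, chain_id = "A") {
  atoms <- data.frame(residue_seq = seq_len(nrow(coords)),
                      residue_type = types, atom_name = "CA",
                      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                      occupancy = 1, altloc = " ",
                      stringsAsFactors = FALSE)
  structure(list(chain_id = chain_id, atoms = atoms,
                 residues = data.frame(residue_seq = atoms$residue_seq,
                                       residue_type = types,
                                       x = atoms$x, y = atoms$y, z = atoms$z,
                                       stringsAsFactors = FALSE)),
            class = "pdb_chain")
}
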