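# Patch construction, local descriptor matrices, global descriptor views.

make_patch <- function(center_type, types, distances, tau_p = 10) {
  ord <- order(distances, seq_along(distances))
  list(center_index = 0L, center_type = center_type, tau_p = tau_p,
       members = data.frame(index = seq_along(types)[ord],
                            residue_type = types[ord],
                            distance = distances[ord],
                            stringsAsFactors = FALSE))
}

two_residue_chain <- function(gap) {
  surface_chain("pair", "A", data.frame(
    residue_seq = 1:2, residue_type = c("A", "G"),
    x = c(0, gap), y = 0, z = 0, stringsAsFactors = FALSE))
}

test_that("patch membership follows the strict Euclidean threshold", {
  p <- build_patches(two_residue_chain(5), tau_p = 10)
  expect_length(p, 2L)
  expect_equal(p[[1L]]$members$distance, 5)
  expect_equal(p[[2L]]$members$residue_type, "A")

  p2 <- build_patches(two_residue_chain(10.0001), tau_p = 10)
  expect_equal(vapply(p2, function(q) nrow(q$members), integer(1)), c(0L, 0L))

  # boundary: exactly tau_p is inside
  p3 <- build_patches(two_residue_chain(10), tau_p = 10)
  expect_equal(nrow(p3[[1L]]$members), 1L)
})

test_that("patch membership equals a brute-force all-pairs filter", {
  ch <- sample_chain(family_spec("sph", size_range = c(40L, 40L)), seed = 21)
  patches <- build_patches(ch, tau_p = 10)
  res <- ch$residues
  for (i in seq_len(40L)) {
    want <- integer(0)
    for (j in seq_len(40L)) {
      if (i == j) next
      d <- sqrt(sum((res[i, c("x", "y", "z")] - res[j, c("x", "y", "z")])^2))
      if (d <= 10) want <- c(want, j)
    }
    expect_setequal(patches[[i]]$members$index, want)
    expect_true(all(diff(patches[[i]]$members$distance) >= 0))
  }
})

test_that("local descriptor bins hand-enumerated members correctly", {
  p <- make_patch("A", c("G", "G", "W"), c(3.0, 3.5, 9.9))
  d <- local_descriptor(p, b = 5L)
  expect_equal(unname(d$counts["G", ]), c(0, 2, 0, 0, 0))
  expect_equal(unname(d$counts["W", ]), c(0, 0, 0, 0, 1))
  expect_equal(unname(d$sum_c), c(0, 2, 0, 0, 1))
  expect_equal(unname(d$sum_r[c("G", "W")]), c(2, 1))
  expect_equal(sum(d$sum_r), 3)

  # half-open bins, closed last bin
  expect_equal(unname(local_descriptor(make_patch("A", "G", 2.0), 5L)$sum_c),
               c(0, 1, 0, 0, 0))
  expect_equal(unname(local_descriptor(make_patch("A", "G", 10.0), 5L)$sum_c),
               c(0, 0, 0, 0, 1))

  # empty patch: all-zero matrix
  d0 <- local_descriptor(make_patch("A", character(0), numeric(0)), 5L)
  expect_true(all(d0$counts == 0))

  # broken invariant is detected
  expect_error(local_descriptor(make_patch("A", "G", 11), 5L), "invariant")
})

test_that("marginals equal the count-matrix sums on random chains", {
  for (seed in 1:5) {
    ch <- random_chain(30L, seed)
    locals <- local_descriptors(build_patches(ch, 10), b = 5L)
    for (l in locals) {
      expect_identical(unname(l$sum_c), unname(colSums(l$counts)))
      expect_identical(unname(l$sum_r), unname(rowSums(l$counts)))
      expect_equal(sum(l$counts),
                   sum(l$sum_r))
    }
  }
})

test_that("global averaging is the arithmetic mean of patch distributions", {
  p1 <- make_patch("A", c("G", "G"), c(1, 1.5))      # sum_c -> (1,0,0,0,0)
  p2 <- make_patch("A", c("W"), c(3))                # sum_c -> (0,1,0,0,0)
  g <- global_descriptor(local_descriptors(structure(list(p1, p2))), b = 5L,
                         tau_p = 10)
  expect_equal(g$blocks$A$dd, c(0.5, 0.5, 0, 0, 0))
  expect_equal(unname(g$blocks$A$rc[c("G", "W")]), c(0.5, 0.5))

  # single patch: global block equals that patch's normalized vectors
  g1 <- global_descriptor(local_descriptors(structure(list(p1))), b = 5L,
                          tau_p = 10)
  expect_equal(g1$blocks$A$dd, c(1, 0, 0, 0, 0))
  expect_equal(unname(g1$blocks$A$rc["G"]), 1)
  # types never central get zero vectors
  expect_equal(g1$blocks$W$dd, numeric(5))
})

test_that("whole pipeline equals the reordered-summation oracle", {
  ch <- random_chain(60L, seed = 31)
  g <- surface_descriptor(ch, tau_p = 10, b = 5L)
  oc <- oracle_local_counts(ch, tau_p = 10, b = 5L)
  want <- oracle_global(oc, b = 5L)
  expect_equal(unname(dd2_vector(g)), want$dd2, tolerance = 1e-12)
  expect_equal(unname(rc_vector(g)), want$rc, tolerance = 1e-12)
  expect_equal(unname(drc_vector(g)), want$drc, tolerance = 1e-12)
  expect_equal(unname(dd1_vector(g)), want$dd1, tolerance = 1e-12)
})

test_that("vector views have fixed lengths and consistent assembly", {
  g_small <- surface_descriptor(random_chain(15L, 1))
  g_big <- surface_descriptor(random_chain(90L, 2))
  for (g in list(g_small, g_big)) {
    expect_length(dd1_vector(g), 5L)
    expect_length(dd2_vector(g), 100L)
    expect_length(rc_vector(g), 400L)
    expect_length(drc_vector(g), 500L)
  }
  # DRC interleaves the DD2 and RC blocks per central type
  g <- g_big
  drc <- unname(drc_vector(g))
  dd2 <- unname(dd2_vector(g))
  rc <- unname(rc_vector(g))
  manual <- unlist(lapply(seq_len(20L), function(i) {
    c(dd2[(i - 1L) * 5L + 1:5], rc[(i - 1L) * 20L + 1:20])
  }))
  expect_equal(drc, manual)
  expect_equal(scheme_length("drc"), 500L)
  expect_equal(scheme_length("dd2", b = 7L), 140L)
})

test_that("chain with a single central type fills only its block", {
  ch <- surface_chain("mono", "A", data.frame(
    residue_seq = 1:6, residue_type = c("A", "A", "A", "G", "G", "G"),
    x = c(0, 2, 4, 1, 3, 5), y = 0, z = 0, stringsAsFactors = FALSE))
  g <- surface_descriptor(ch)
  dd2 <- dd2_vector(g)
  expect_true(all(dd2[grep("^A_", names(dd2))] >= 0))
  # only A and G were central: all other blocks are zero
  zero_blocks <- setdiff(AA20, c("A", "G"))
  for (aa in zero_blocks) {
    expect_equal(unname(dd2[grep(paste0("^", aa, "_"), names(dd2))]),
                 numeric(5))
  }
})

test_that("every A-centered patch with only G members gives a G-indicator", {
  p <- list(make_patch("A", c("G", "G"), c(2, 8)),
            make_patch("A", c("G"), c(5)))
  g <- global_descriptor(local_descriptors(structure(p)), b = 5L, tau_p = 10)
  rc <- rc_vector(g)
  blockA <- rc[grep("^A_cooc_", names(rc))]
  expect_equal(unname(blockA), as.numeric(AA20 == "G"))
})

test_that("DD1 pools patches and matches the two stated identities", {
  p1 <- make_patch("A", c("G"), c(1))   # (1,0,0,0,0)
  p2 <- make_patch("W", c("G"), c(9.5)) # (0,0,0,0,1)
  locals <- local_descriptors(structure(list(p1, p2)))
  expect_equal(unname(dd1_vector(locals)), c(0.5, 0, 0, 0, 0.5))
  expect_equal(unname(dd1_vector(locals[1L])), c(1, 0, 0, 0, 0))

  # pooled mean equals combination of DD2 blocks weighted by non-empty
  # patch counts per central type
  ch <- random_chain(50L, seed = 41)
  g <- surface_descriptor(ch)
  w <- vapply(g$blocks, function(bl) bl$n_nonempty, integer(1))
  dd_blocks <- vapply(g$blocks, function(bl) bl$dd, numeric(5))
  expect_equal(unname(dd1_vector(g)),
               unname(as.numeric(dd_blocks %*% w / sum(w))),
               tolerance = 1e-12)
})

test_that("descriptors are invariant to rigid motion, mirroring and order", {
  ch <- random_chain(40L, seed = 51)
  base <- drc_vector(surface_descriptor(ch))

  R <- random_rotation(1)
  moved <- apply_transform(ch, R, shift = c(12, -5, 30))
  expect_equal(drc_vector(surface_descriptor(moved)), base, tolerance = 1e-9)

  mirrored <- apply_transform(ch, diag(c(-1, 1, 1)))
  expect_equal(drc_vector(surface_descriptor(mirrored)), base,
               tolerance = 1e-9)

  perm <- permute_chain(ch, seed = 2)
  expect_equal(drc_vector(surface_descriptor(perm)), base, tolerance = 1e-12)
})

test_that("pooled normalization is a distinct, valid aggregation", {
  ch <- random_chain(40L, seed = 61)
  g_patch <- surface_descriptor(ch, normalize = "patch")
  g_pool <- surface_descriptor(ch, normalize = "pooled")
  for (aa in AA20) {
    for (g in list(g_patch, g_pool)) {
      s <- sum(g$blocks[[aa]]$dd)
      expect_true(abs(s - 1) < 1e-9 || s == 0)
    }
  }
  expect_false(isTRUE(all.equal(dd2_vector(g_patch), dd2_vector(g_pool))))
})

test_that("descriptor JSON round-trips", {
  g <- surface_descriptor(random_chain(30L, 71, id = "io"))
  path <- tempfile(fileext = ".json")
  write_descriptor_json(g, path)
  back <- read_descriptor_json(path)
  expect_equal(drc_vector(back), drc_vector(g))
  expect_equal(back$b, g$b)
  expect_equal(back$structure_id, "io")
})
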