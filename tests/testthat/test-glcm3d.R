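test_that("the displacement set holds all 26 signed unit offsets exactly once", {
  d <- glcm_displacements()
  expect_identical(nrow(d), 26L)
  expect_identical(anyDuplicated(d), 0L)
  expect_false(any(rowSums(d == 0) == 3))
  key <- apply(d, 1, paste, collapse = ",")
  expect_true(all(c("1,0,0", "-1,0,0") %in% key))
  # lexicographic over (dx, dy, dz)
  ord <- order(d[, 1], d[, 2], d[, 3])
  expect_identical(ord, seq_len(26L))
})

test_that("glcm3 counts match hand-checkable configurations", {
  # single-voxel VOI: no pairs for any displacement
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  q1 <- quantize(make_voi(array(rnorm(27), c(3, 3, 3)), one), 2)
  m <- glcm3(q1, c(1, 0, 0))
  expect_identical(m$total, 0L)

  # constant 2x2x2 VOI at level 0, d = (1,0,0): 4 ordered pairs on the diagonal
  qc <- quantize(make_voi(array(1, c(2, 2, 2))), 2)
  mc <- glcm3(qc, c(1, 0, 0))
  expect_identical(mc$counts[1, 1], 4L)
  expect_identical(mc$total, 4L)

  # alternating 4x1x1 line [0,1,0,1] along x, d = (1,0,0)
  arr <- array(c(0, 1, 0, 1), c(4, 1, 1))
  ql <- quantize(make_voi(arr), 1)
  ml <- glcm3(ql, c(1, 0, 0))
  expect_identical(ml$counts[1, 2], 2L)  # 0 -> 1 twice
  expect_identical(ml$counts[2, 1], 1L)  # 1 -> 0 once
  expect_identical(ml$total, 3L)
})

test_that("glcm3 equals the brute-force pair counter on random masked volumes", {
  dset <- glcm_displacements()
  withr::local_seed(99)
  for (s in 1:10) {
    dims <- c(sample(2:6, 1), sample(2:6, 1), sample(2:6, 1))
    v <- rand_voi(dims, seed = 50 + s, mask_prob = 0.6)
    q <- quantize(v, 2)
    for (r in sample(26, 6)) {
      d <- dset[r, ]
      got <- glcm3(q, d)
      want <- oracle_glcm3(q$levels, q$flags, d, q$n_levels)
      expect_identical(got$counts, want)
      expect_identical(got$total, sum(want))
    }
  }
})

test_that("opposite displacements give transposed matrices", {
  v <- rand_voi(c(5, 5, 4), seed = 77, mask_prob = 0.7)
  q <- quantize(v, 3)
  dset <- glcm_displacements()
  for (r in 1:13) {
    d <- dset[r, ]
    expect_identical(glcm3(q, d)$counts, t(glcm3(q, -d)$counts))
  }
})

test_that("co-occurrence measures match closed forms and direct evaluation", {
  mk <- function(counts, n) structure(
    list(counts = counts, total = sum(counts), d = c(1L, 0L, 0L), n_levels = n),
    class = "rad_glcm")
  # all mass on the diagonal
  dg <- mk(diag(c(3L, 0L, 5L, 2L)), 4)
  f <- glcm_features(dg)
  expect_equal(f[["inertia"]], 0)
  expect_equal(f[["abs_contrast"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  # uniform over 16 cells
  un <- mk(matrix(1L, 4, 4), 4)
  fu <- glcm_features(un)
  expect_equal(fu[["entropy"]], 4)
  expect_equal(fu[["energy"]], 1 / 16)
  # point mass at levels (2, 5) of an 8-level matrix
  pm <- matrix(0L, 8, 8); pm[3, 6] <- 7L
  fp <- glcm_features(mk(pm, 8))
  expect_equal(fp[["autocorrelation"]], 10)
  expect_equal(fp[["covariance"]], 0)
  expect_equal(fp[["inertia"]], 9)
  expect_equal(fp[["abs_contrast"]], 3)
  expect_equal(fp[["homogeneity"]], 0.25)
  expect_equal(fp[["energy"]], 1)
  expect_equal(fp[["entropy"]], 0)
  # empty matrix -> zero-filled, flagged
  fe <- glcm_features(mk(matrix(0L, 4, 4), 4))
  expect_true(attr(fe, "degenerate"))
  expect_true(all(fe == 0))
})

test_that("glcm3_block has 364 uniquely named features and mirror symmetry", {
  ph <- generate_phantom(0, phantom_params(grid = c(14, 14, 10), lesion = c(5, 5, 4)),
                         seed = 12)
  v_t2 <- extract_voi(ph$t2, ph$mask)
  v_adc <- extract_voi(ph$adc, ph$mask)
  blk <- glcm3_block(quantize(v_t2), quantize(v_adc))
  expect_length(blk, 364)
  expect_identical(anyDuplicated(names(blk)), 0L)
  expect_identical(sum(startsWith(names(blk), "t2_")), 182L)

  # mirroring along x swaps the features of d and its x-flipped counterpart
  flip_x <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  vf <- make_voi(flip_x(ph$t2$voxels), flip_x(ph$mask$flags))
  q <- quantize(v_t2); qf <- quantize(vf)
  f1 <- glcm_features(glcm3(q, c(1, 0, 0)))
  f2 <- glcm_features(glcm3(qf, c(-1, 0, 0)))
  expect_equal(f1, f2)
  g1 <- glcm_features(glcm3(q, c(1, -1, 1)))
  g2 <- glcm_features(glcm3(qf, c(-1, -1, 1)))
  expect_equal(g1, g2)
})
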