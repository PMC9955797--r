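test_that("lbp2d codes match hand enumeration on 3x3 neighbourhoods", {
  # constant plane: equality gives bit 0 everywhere
  m <- lbp2d(matrix(4, 5, 5))
  expect_true(all(m$codes[m$valid] == 0L))
  # centre darker than all neighbours -> all bits set
  pl <- matrix(1, 3, 3); pl[2, 2] <- 0
  expect_identical(lbp2d(pl)$codes[2, 2], 255L)
  # single brighter neighbour east: bit 0 only
  pl2 <- matrix(5, 3, 3); pl2[2, 2] <- 4; pl2[3, 2] <- 9
  expect_identical(lbp2d(pl2)$codes[2, 2], oracle_lbp_code(pl2))
  expect_identical(oracle_lbp_code(pl2), 255L)   # all neighbours brighter
  # random planes: every interior pixel equals the enumeration oracle
  for (s in 1:5) {
    withr::with_seed(40 + s, pl <- matrix(sample(0:9, 36, TRUE), 6, 6))
    m <- lbp2d(pl)
    for (i in 2:5) for (j in 2:5)
      expect_identical(m$codes[i, j],
                       as.integer(oracle_lbp_code(pl[(i - 1):(i + 1), (j - 1):(j + 1)])))
  }
})

test_that("plane smaller than the neighbourhood yields an empty valid set", {
  m <- lbp2d(matrix(1, 2, 2))
  expect_false(any(m$valid))
})

test_that("uniformity, ri and riu2 follow their definitions", {
  expect_identical(lbp_uniformity(0L), 0L)
  expect_identical(lbp_uniformity(255L), 0L)
  expect_identical(lbp_uniformity(strtoi("00001111", base = 2)), 2L)
  expect_identical(lbp_uniformity(strtoi("01010101", base = 2)), 8L)

  expect_identical(lbp_ri_code(0L), 0L)
  for (j in 0:7) expect_identical(lbp_ri_code(bitwShiftL(1L, j)), 1L)
  expect_identical(lbp_ri_code(strtoi("01100000", base = 2)), 3L)

  expect_identical(lbp_riu2_code(0L), 0L)
  expect_identical(lbp_riu2_code(255L), 8L)
  expect_identical(lbp_riu2_code(strtoi("01010101", base = 2)), 9L)
})

test_that("there are exactly 36 ri codes and 10 riu2 labels for P = 8", {
  codes <- 0:255
  expect_identical(length(unique(lbp_ri_code(codes))), 36L)
  expect_identical(length(unique(lbp_riu2_code(codes))), 10L)
  # mappings are idempotent / consistent under composition
  ri <- lbp_ri_code(codes)
  expect_identical(lbp_ri_code(ri), ri)
  expect_identical(lbp_riu2_code(ri), lbp_riu2_code(codes))
})

test_that("top_lbp_block returns 48 named features with the expected degenerate limits", {
  v <- rand_voi(c(10, 10, 8), seed = 3, mask_prob = 1)
  blk <- top_lbp_block(v)
  expect_length(blk, 48)
  expect_true(all(is.finite(blk)))
  expect_identical(anyDuplicated(names(blk)), 0L)

  # constant VOI: every code 0, point-mass histograms
  blc <- top_lbp_block(make_voi(array(2, c(8, 8, 6))))
  expect_equal(unname(blc["lbp_basic_sd"]), 0)
  expect_equal(unname(blc["lbp_basic_energy"]), 1)
  expect_equal(unname(blc["lbp_riu2_entropy"]), 0)

  # too-small VOI cannot be encoded
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_error(top_lbp_block(make_voi(array(rnorm(125), c(5, 5, 5)), one)),
               "too small")
})

test_that("ri histogram is invariant under in-plane 90-degree rotation", {
  withr::with_seed(11, pl <- matrix(rnorm(144), 12, 12))
  rot <- t(pl)[ncol(pl):1, ]                       # 90-degree rotation
  c1 <- lbp2d(pl); c2 <- lbp2d(rot)
  h1 <- table(lbp_ri_code(c1$codes[c1$valid]))
  h2 <- table(lbp_ri_code(c2$codes[c2$valid]))
  expect_identical(h1, h2)
})

test_that("riu2 features are invariant under a 90-degree volume rotation", {
  # odd isotropic cubic grid so the in-mask centroid is a lattice point
  pp <- phantom_params(grid = c(15, 15, 15), lesion = c(6, 6, 6))
  ph <- generate_phantom(1, pp, seed = 8)
  arr <- ph$t2$voxels; msk <- ph$mask$flags
  rot_z <- function(a) {
    d <- dim(a)
    out <- array(a[0], c(d[2], d[1], d[3]))
    for (k in seq_len(d[3])) out[, , k] <- t(a[, , k])[d[2]:1, ]
    out
  }
  v1 <- make_voi(arr, msk)
  v2 <- make_voi(rot_z(arr), rot_z(msk))
  b1 <- top_lbp_block(v1); b2 <- top_lbp_block(v2)
  riu2 <- grep("^lbp_riu2_", names(b1), value = TRUE)
  expect_equal(b1[riu2], b2[riu2], tolerance = 1e-9)
})
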