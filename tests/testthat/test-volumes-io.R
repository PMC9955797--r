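test_that("NIfTI volume and mask roundtrip preserves grid, values and spacing", {
  withr::with_seed(7, {
    arr <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  })
  vol <- new_volume(arr, spacing = c(0.7, 0.7, 3), modality = "T2W", case_id = "fx")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- load_volume(f, "T2W")
  expect_equal(back$voxels, arr, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, c(0.7, 0.7, 3), tolerance = 1e-6)

  msk <- array(FALSE, c(8, 8, 4)); msk[3:6, 2:7, 2:3] <- TRUE
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(new_mask(msk), fm)
  expect_identical(load_mask(fm, back)$flags, msk)
})

test_that("a synthetic phantom survives a disk roundtrip unchanged", {
  ph <- generate_phantom(1, phantom_params(grid = c(12, 12, 8), lesion = c(4, 4, 3)),
                         seed = 3, case_id = "p1")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$t2, f)
  expect_equal(load_volume(f, "T2W")$voxels, ph$t2$voxels,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected with descriptive errors", {
  f2d <- withr::local_tempfile(fileext = ".nii")
  img <- RNifti::asNifti(matrix(1:9, 3))
  RNifti::writeNifti(img, f2d)
  expect_error(load_volume(f2d, "T2W"), "not a 3D volume")

  vol <- new_volume(array(0, c(8, 8, 8)))
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(new_mask(array(1, c(10, 10, 10))), fm)
  expect_error(load_mask(fm, vol), "10x10x10.*8x8x8")

  expect_error(new_volume(array(c(NA, rep(1, 7)), c(2, 2, 2))), "non-finite")
  expect_error(extract_voi(vol, new_mask(array(FALSE, c(8, 8, 8)))), "empty mask")
})

test_that("nonzero mask values are treated as lesion", {
  vol <- new_volume(array(rnorm(27), c(3, 3, 3)))
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  raw <- array(0, c(3, 3, 3)); raw[1, 2, 3] <- 2; raw[2, 2, 2] <- 1
  img <- RNifti::asNifti(raw); RNifti::writeNifti(img, fm)
  m <- load_mask(fm, vol)
  expect_identical(sum(m$flags), 2L)
  expect_true(m$flags[1, 2, 3] && m$flags[2, 2, 2])
})

test_that("bounding box is tight and matches an exhaustive scan", {
  # single voxel
  msk <- array(FALSE, c(8, 8, 8)); msk[3, 4, 5] <- TRUE
  v <- make_voi(array(rnorm(512), c(8, 8, 8)), msk)
  expect_equal(unname(v$bbox), rbind(c(3, 3), c(4, 4), c(5, 5)))
  # full mask
  v2 <- make_voi(array(rnorm(8), c(2, 2, 2)))
  expect_equal(unname(v2$bbox), rbind(c(1, 2), c(1, 2), c(1, 2)))
  # random masks vs exhaustive scan
  for (s in 1:5) {
    v3 <- rand_voi(c(6, 5, 4), seed = s, mask_prob = 0.3)
    idx <- which(v3$mask$flags, arr.ind = TRUE)
    expect_equal(unname(v3$bbox),
                 cbind(apply(idx, 2, min), apply(idx, 2, max)),
                 ignore_attr = TRUE)
    expect_identical(sum(v3$flags), sum(v3$mask$flags))
  }
})

test_that("quantization follows the min-max binning contract", {
  # constant VOI -> all level 0
  vq <- quantize(make_voi(array(5, c(3, 3, 3))), bits = 4)
  expect_true(all(vq$levels[vq$flags] == 0L))
  # m = 1 splits the span at the midpoint
  arr <- array(seq(0, 100, length.out = 64), c(4, 4, 4))
  q1 <- quantize(make_voi(arr), bits = 1)
  expect_true(all(q1$levels[arr < 50] == 0L))
  expect_true(all(q1$levels[arr >= 50] == 1L))
  # support within [0, 2^m - 1] and monotone in intensity
  for (s in 1:5) {
    v <- rand_voi(c(5, 5, 5), seed = 10 + s)
    q <- quantize(v, bits = 3)
    lv <- q$levels[q$flags]
    expect_true(all(lv >= 0 & lv <= 7))
    ord <- order(v$values)
    expect_true(all(diff(lv[ord]) >= 0))
  }
  expect_error(quantize(make_voi(array(1, c(2, 2, 2))), bits = 9), "\\[1, 8\\]")
})

test_that("out-of-mask voxels never influence the feature vector", {
  msk <- array(FALSE, c(14, 14, 8)); msk[4:11, 4:11, 3:6] <- TRUE
  withr::with_seed(21, {
    arr <- array(rnorm(prod(dim(msk))), dim(msk))
    noise <- array(rnorm(prod(dim(msk)), sd = 50), dim(msk))
  })
  arr2 <- arr; arr2[!msk] <- arr2[!msk] + noise[!msk]
  clin <- clinical_record("c", 1, 4)
  r1 <- assemble_case(make_voi(arr, msk), make_voi(arr, msk, modality = "ADC"),
                      clin, label = 1)
  r2 <- assemble_case(make_voi(arr2, msk), make_voi(arr2, msk, modality = "ADC"),
                      clin, label = 1)
  expect_equal(r1, r2)
})
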