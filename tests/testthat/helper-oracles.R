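# Test helpers: tiny constructors and independent brute-force oracles.

# volume + mask + voi from an array (mask defaults to all-true)
make_voi <- function(arr, mask = NULL, modality = "T2W", case_id = "t") {
  vol <- new_volume(arr, modality = modality, case_id = case_id)
  if (is.null(mask)) mask <- array(TRUE, dim(arr))
  extract_voi(vol, new_mask(mask, case_id = case_id))
}

rand_voi <- function(dims, seed, mask_prob = 0.7, levels = NULL) {
  withr::with_seed(seed, {
    arr <- array(rnorm(prod(dims)), dims)
    msk <- array(runif(prod(dims)) < mask_prob, dims)
    if (sum(msk) == 0) msk[1] <- TRUE
    make_voi(arr, msk)
  })
}

# brute-force GLCM3: triple loop over voxels, counting ordered in-mask pairs
oracle_glcm3 <- function(levels, flags, d, n) {
  counts <- matrix(0L, n, n)
  dims <- dim(levels)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
          kk < 1 || kk > dims[3]) next
      if (!flags[i, j, k] || !flags[ii, jj, kk]) next
      gi <- levels[i, j, k] + 1L; gj <- levels[ii, jj, kk] + 1L
      counts[gi, gj] <- counts[gi, gj] + 1L
    }
  counts
}

# hand enumeration of a single 3x3 LBP code: ring starts east (+row),
# counter-clockwise, bit j = 2^j when neighbour > centre
oracle_lbp_code <- function(nb3x3) {
  ring <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                c(0, -1), c(1, -1))
  ctr <- nb3x3[2, 2]
  as.integer(sum(vapply(1:8, function(j) {
    2^(j - 1) * (nb3x3[2 + ring[j, 1], 2 + ring[j, 2]] > ctr)
  }, numeric(1))))
}

# exhaustive pairwise AUC: positives vs negatives, ties count one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small two-class feature table with optional informative columns
make_table <- function(n = 60, p_noise = 10, informative = TRUE, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), length.out = n)
    tb <- tibble::tibble(case_id = sprintf("c%03d", seq_len(n)),
                         label = label)
    if (informative)
      tb$signal <- label * 2 + rnorm(n, sd = 0.5)
    for (i in seq_len(p_noise)) tb[[paste0("noise", i)]] <- rnorm(n)
    tb
  })
}
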