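# Local binary patterns on three orthogonal planes (TOP-LBP).
#
# 2D LBP codes are computed on the XY, XZ and YZ planes through the
# (rounded) in-mask centroid, in four variants (basic, rotation-invariant,
# uniform, rotation-invariant uniform). Valid codes of the three planes are
# pooled into one histogram per variant and summarized by the 12
# first-order statistics, giving 4 x 12 = 48 features per modality.

lbp_variants <- c("basic", "ri", "u2", "riu2")

# circular neighbour ring: start east, read counter-clockwise, bit j has
# weight 2^j (j = 0..P-1)
lbp_ring <- function(P = 8L, R = 1L) {
  if (P != 8L) abort("only P = 8 neighbours are supported")
  R * rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L), c(-1L, 0L),
            c(-1L, -1L), c(0L, -1L), c(1L, -1L))
}

#' Number of circular 0/1 transitions in an LBP code
#'
#' @param code Integer LBP code(s) in `[0, 2^P - 1]`.
#' @param P Neighbour count (bit length).
#' @return Integer vector of transition counts (the uniformity measure U).
#' @export
lbp_uniformity <- function(code, P = 8L) {
  bits <- code_bits(code, P)
  rot <- bits[, c(2:P, 1), drop = FALSE]
  as.integer(rowSums(bits != rot))
}

#' Rotation-invariant LBP code
#'
#' Minimum value over all `P` circular bit rotations of the code.
#'
#' @inheritParams lbp_uniformity
#' @return Integer vector of rotation-invariant codes.
#' @export
lbp_ri_code <- function(code, P = 8L) {
  bits <- code_bits(code, P)
  w <- 2^(0:(P - 1))
  vals <- matrix(NA_real_, nrow(bits), P)
  for (r in 0:(P - 1)) {
    idx <- ((0:(P - 1) + r) %% P) + 1L
    vals[, r + 1L] <- bits[, idx, drop = FALSE] %*% w
  }
  as.integer(apply(vals, 1, min))
}

#' Rotation-invariant uniform (riu2) LBP label
#'
#' Codes with at most two circular transitions map to their number of set
#' bits (`0..P`); all other codes share the single label `P + 1`.
#'
#' @inheritParams lbp_uniformity
#' @return Integer vector of labels in `[0, P + 1]`.
#' @export
lbp_riu2_code <- function(code, P = 8L) {
  bits <- code_bits(code, P)
  u <- lbp_uniformity(code, P)
  ifelse(u <= 2L, as.integer(rowSums(bits)), P + 1L)
}

code_bits <- function(code, P) {
  code <- as.integer(code)
  if (any(code < 0 | code > 2^P - 1)) abort(sprintf("code out of [0, %d]", 2^P - 1))
  vapply(0:(P - 1), function(j) bitwAnd(code, bitwShiftL(1L, j)) > 0L,
         logical(length(code)))  |>
    matrix(nrow = length(code))
}

# memoised lookup tables for P = 8: per raw code 0..255 its uniformity,
# ri code, riu2 label and the u2 mapping (raw code if uniform, else 256)
.lbp_cache <- new.env(parent = emptyenv())
lbp_tables <- function(P = 8L) {
  key <- as.character(P)
  if (!is.null(.lbp_cache[[key]])) return(.lbp_cache[[key]])
  codes <- 0:(2^P - 1)
  u <- lbp_uniformity(codes, P)
  tab <- list(
    u = u,
    ri = lbp_ri_code(codes, P),
    riu2 = lbp_riu2_code(codes, P),
    u2 = ifelse(u <= 2L, codes, 2L^P)
  )
  tab$domains <- list(
    basic = codes,
    ri = sort(unique(tab$ri)),
    u2 = sort(unique(tab$u2)),
    riu2 = 0:(P + 1)
  )
  .lbp_cache[[key]] <- tab
  tab
}

#' 2D local binary pattern map
#'
#' For each pixel `p` with a full neighbourhood, bit `j` is 1 iff the j-th
#' circular neighbour is strictly brighter than `p` (equality gives 0);
#' neighbours are read starting east, counter-clockwise, and the bit string
#' is decoded with bit `j` weighted `2^j`. When a pixel mask is given, a
#' pixel is valid only if it and all its neighbours are in-mask (so
#' out-of-mask intensities can never leak into a code).
#'
#' @param plane 2D numeric matrix of intensities.
#' @param P Neighbour count; only 8 is supported.
#' @param R Ring radius in pixels (integer, no subpixel interpolation).
#' @param mask Optional logical matrix of the same shape; default all TRUE.
#' @return An object of class `rad_lbp`: integer `codes` matrix and logical
#'   `valid` matrix (codes outside `valid` are `NA`). A plane smaller than
#'   the neighbourhood yields an empty valid set, not an error.
#' @export
lbp2d <- function(plane, P = 8L, R = 1L, mask = NULL) {
  stopifnot(is.matrix(plane))
  ring <- lbp_ring(P, as.integer(R))
  n1 <- nrow(plane); n2 <- ncol(plane)
  codes <- matrix(NA_integer_, n1, n2)
  valid <- matrix(FALSE, n1, n2)
  if (is.null(mask)) mask <- matrix(TRUE, n1, n2)
  stopifnot(identical(dim(mask), dim(plane)))
  if (n1 < 2 * R + 1 || n2 < 2 * R + 1)
    return(structure(list(codes = codes, valid = valid), class = "rad_lbp"))
  i1 <- (R + 1):(n1 - R); i2 <- (R + 1):(n2 - R)
  centre <- plane[i1, i2, drop = FALSE]
  acc <- matrix(0L, length(i1), length(i2))
  ok <- mask[i1, i2, drop = FALSE]
  for (j in seq_len(P)) {
    nb <- plane[i1 + ring[j, 1], i2 + ring[j, 2], drop = FALSE]
    acc <- acc + bitwShiftL(1L, j - 1L) * (nb > centre)
    ok <- ok & mask[i1 + ring[j, 1], i2 + ring[j, 2], drop = FALSE]
  }
  codes[i1, i2] <- ifelse(ok, acc, NA_integer_)
  valid[i1, i2] <- ok
  structure(list(codes = codes, valid = valid), class = "rad_lbp")
}

# planes through the rounded in-mask centroid of the full grid
centroid_planes <- function(voi) {
  co <- arrayInd(which(voi$mask$flags), dim(voi$mask$flags))
  c0 <- round(colMeans(co))
  vox <- voi$volume$voxels; flg <- voi$mask$flags
  d <- dim(vox)
  list(
    XY = list(plane = matrix(vox[, , c0[3]], d[1], d[2]),
              mask = matrix(flg[, , c0[3]], d[1], d[2])),
    XZ = list(plane = matrix(vox[, c0[2], ], d[1], d[3]),
              mask = matrix(flg[, c0[2], ], d[1], d[3])),
    YZ = list(plane = matrix(vox[c0[1], , ], d[2], d[3]),
              mask = matrix(flg[c0[1], , ], d[2], d[3]))
  )
}

#' TOP-LBP feature block (48 features)
#'
#' Extracts the XY, XZ and YZ planes through the rounded in-mask centroid,
#' computes LBP maps per plane, pools the valid codes of the three planes,
#' and summarizes the pooled code histogram of each variant (basic, ri, u2,
#' riu2, in that order) with the 12 first-order statistics. Code histograms
#' use one bin per possible code value (non-uniform codes collapse to a
#' single overflow bin, value `2^P`, in the u2 variant); bin width is one
#' code unit. A plane with fewer than `P + 1` valid pixels contributes
#' nothing; if all three planes are too small the VOI cannot be encoded.
#'
#' @param voi An [`rad_voi`][extract_voi].
#' @param P,R LBP ring parameters (default 8 neighbours, radius 1).
#' @return Named numeric vector of length 48
#'   (`lbp_<variant>_<statistic>`).
#' @export
top_lbp_block <- function(voi, P = 8L, R = 1L) {
  stopifnot(inherits(voi, "rad_voi"))
  planes <- centroid_planes(voi)
  pooled <- integer(0)
  for (pl in planes) {
    m <- lbp2d(pl$plane, P = P, R = R, mask = pl$mask)
    v <- m$codes[m$valid]
    if (length(v) >= P + 1) pooled <- c(pooled, v)
  }
  if (length(pooled) == 0L) abort("VOI too small for TOP-LBP")
  tab <- lbp_tables(P)
  out <- numeric(0)
  for (variant in lbp_variants) {
    mapped <- switch(variant,
      basic = pooled,
      ri = tab$ri[pooled + 1L],
      u2 = tab$u2[pooled + 1L],
      riu2 = tab$riu2[pooled + 1L]
    )
    h <- hist_from_codes(mapped, tab$domains[[variant]])
    st <- histogram_stats(h, mapped)
    names(st) <- paste0("lbp_", variant, "_", fo_stat_names)
    out <- c(out, st)
  }
  out
}
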