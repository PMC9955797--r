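# Mask-aware 3D grey-level co-occurrence matrices (GLCM3).
#
# For a quantized VOI with N grey levels, counts[g_i + 1, g_j + 1] is the
# number of ordered voxel pairs (p, p + d) with both endpoints in-mask and
# inside the grid, level(p) = g_i and level(p + d) = g_j. Matrices are
# directed (not symmetrized): opposite displacements are separate matrices
# related by transposition.

glcm_feature_names <- c("autocorrelation", "homogeneity", "entropy", "energy",
                        "covariance", "inertia", "abs_contrast")

#' The 26 unit displacements
#'
#' All offset triples with components in `{-1, 0, 1}` except `(0, 0, 0)`,
#' in lexicographic order over `(dx, dy, dz)`.
#'
#' @return A 26 x 3 integer matrix with columns `dx`, `dy`, `dz`.
#' @export
glcm_displacements <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))[, c("dx", "dy", "dz")]
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  rownames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

displacement_label <- function(d) {
  paste0("d", paste(sub("-", "m", as.character(d)), collapse = "_"))
}

#' 3D grey-level co-occurrence matrix for one displacement
#'
#' @param q An [`rad_qvoi`][quantize].
#' @param d Integer displacement `(dx, dy, dz)`, components in `{-1, 0, 1}`,
#'   not all zero.
#' @return An object of class `rad_glcm`: `counts` (N x N), `total`, `d`,
#'   `n_levels`. A VOI too thin for `d` yields an all-zero matrix with
#'   `total = 0`.
#' @export
glcm3 <- function(q, d) {
  stopifnot(inherits(q, "rad_qvoi"))
  d <- as.integer(d)
  if (length(d) != 3L || any(abs(d) > 1L) || all(d == 0L))
    abort("`d` must be a non-zero triple with components in {-1, 0, 1}")
  n <- q$n_levels
  dims <- dim(q$levels)
  src <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - d[a]); hi <- min(dims[a], dims[a] - d[a])
    if (lo > hi) integer(0) else lo:hi
  })
  counts <- matrix(0L, n, n)
  if (all(lengths(src) > 0)) {
    A <- q$levels[src[[1]], src[[2]], src[[3]], drop = FALSE]
    B <- q$levels[src[[1]] + d[1], src[[2]] + d[2], src[[3]] + d[3], drop = FALSE]
    MA <- q$flags[src[[1]], src[[2]], src[[3]], drop = FALSE]
    MB <- q$flags[src[[1]] + d[1], src[[2]] + d[2], src[[3]] + d[3], drop = FALSE]
    keep <- MA & MB
    if (any(keep)) {
      idx <- A[keep] * n + B[keep] + 1L
      counts <- matrix(tabulate(idx, nbins = n * n), n, n, byrow = TRUE)
    }
  }
  structure(list(counts = counts, total = sum(counts), d = d, n_levels = n),
            class = "rad_glcm")
}

#' @export
print.rad_glcm <- function(x, ...) {
  cat(sprintf("<rad_glcm> %dx%d, d = (%s), %d pairs\n", x$n_levels,
              x$n_levels, paste(x$d, collapse = ","), x$total))
  invisible(x)
}

#' Seven co-occurrence measures of a GLCM3
#'
#' On the normalized matrix `p(i, j) = counts / total`, with `i`, `j` the
#' grey levels `0..N-1`:
#' autocorrelation `sum(i j p)`; homogeneity `sum(p / (1 + |i - j|))`;
#' entropy `-sum(p log2 p)` over occupied cells; energy `sum(p^2)`;
#' covariance `sum((i - mu_i)(j - mu_j) p)` with marginal means `mu_i`,
#' `mu_j`; inertia `sum((i - j)^2 p)`; absolute contrast (dissimilarity)
#' `sum(|i - j| p)`.
#'
#' An empty matrix (`total = 0`) yields a zero-filled set carrying a
#' `degenerate` attribute.
#'
#' @param M An [`rad_glcm`][glcm3].
#' @return Named numeric vector of length 7 (attribute `degenerate` is TRUE
#'   when the matrix held no pairs).
#' @export
glcm_features <- function(M) {
  stopifnot(inherits(M, "rad_glcm"))
  n <- M$n_levels
  if (M$total == 0) {
    out <- stats::setNames(numeric(7), glcm_feature_names)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- M$counts / M$total
  i <- matrix(0:(n - 1), n, n)           # row level g_i
  j <- t(i)                              # column level g_j
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  occ <- p > 0
  out <- c(
    autocorrelation = sum(i * j * p),
    homogeneity = sum(p / (1 + abs(i - j))),
    entropy = -sum(p[occ] * log2(p[occ])),
    energy = sum(p^2),
    covariance = sum((i - mu_i) * (j - mu_j) * p),
    inertia = sum((i - j)^2 * p),
    abs_contrast = sum(abs(i - j) * p)
  )
  attr(out, "degenerate") <- FALSE
  out
}

# 26 displacements x 7 measures = 182 named values for one modality
glcm_block_one <- function(q, displacements = glcm_displacements()) {
  out <- numeric(0)
  for (r in seq_len(nrow(displacements))) {
    d <- displacements[r, ]
    f <- glcm_features(glcm3(q, d))
    names(f) <- paste0("glcm_", displacement_label(d), "_", glcm_feature_names)
    out <- c(out, f)
  }
  out
}

#' GLCM3 feature block for a T2w/ADC pair (364 features)
#'
#' Per modality, the 26 displacements times 7 measures give 182 values in
#' fixed (displacement, measure) order; the T2w block is followed by the
#' ADC block for a total of 364.
#'
#' @param q_t2,q_adc Quantized VOIs ([`rad_qvoi`][quantize]) of the T2w and
#'   ADC volumes.
#' @return Named numeric vector of length 364
#'   (`t2_glcm_*` then `adc_glcm_*`).
#' @export
glcm3_block <- function(q_t2, q_adc) {
  b_t2 <- glcm_block_one(q_t2)
  b_adc <- glcm_block_one(q_adc)
  names(b_t2) <- paste0("t2_", names(b_t2))
  names(b_adc) <- paste0("adc_", names(b_adc))
  c(b_t2, b_adc)
}
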