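# Seeded synthetic two-class cohorts of paired T2w-like/ADC-like masked
# texture phantoms with clinical covariates.
#
# The lesion texture is a smoothed Gaussian random field: white noise
# convolved with a separable Gaussian kernel whose standard deviation (the
# correlation length, in voxels) differs between classes, plus a
# class-dependent mean shift and additive voxel noise. The three switches
# (correlation length, noise level, mean shift) perturb the GLCM3/LBP,
# first-order spread and first-order location feature families
# independently. The background is independent white noise, so out-of-mask
# voxels carry no class signal. `effect` in [0, 1] interpolates the class-1
# parameters from the class-0 parameters: at 0 the class distributions are
# identical.

#' Phantom generation parameters
#'
#' Per-class vectors are `c(class0, class1_at_effect_1)`; the effective
#' class-1 value is `class0 + effect * (class1 - class0)`.
#'
#' @param grid Volume shape (default `c(32, 32, 16)`).
#' @param lesion Ellipsoid semi-axes in voxels (default `c(9, 9, 5)`); must
#'   fit inside the grid.
#' @param texture_scale Per-class spatial correlation length in voxels
#'   (Gaussian kernel sd; default `c(1.2, 2.6)`).
#' @param noise_sd Per-class additive in-lesion noise sd (default
#'   `c(1.0, 0.5)`; the noise contrast points the same way as the
#'   correlation-length contrast, since additive noise attenuates
#'   co-occurrence correlation).
#' @param mean_shift Per-class in-lesion intensity offset (default
#'   `c(0, 0.8)`).
#' @param effect Scalar in `[0, 1]` scaling the class-1 departure from
#'   class 0 (default 1).
#' @return A list of class `rad_phantom_params`.
#' @export
phantom_params <- function(grid = c(32, 32, 16), lesion = c(9, 9, 5),
                           texture_scale = c(1.2, 2.6),
                           noise_sd = c(1.0, 0.5),
                           mean_shift = c(0, 0.8),
                           effect = 1) {
  if (any(2 * lesion + 1 > grid))
    abort("lesion does not fit inside the grid")
  if (effect < 0 || effect > 1) abort("`effect` must be in [0, 1]")
  structure(list(grid = as.integer(grid), lesion = lesion,
                 texture_scale = texture_scale, noise_sd = noise_sd,
                 mean_shift = mean_shift, effect = effect),
            class = "rad_phantom_params")
}

class_params <- function(params, class_label) {
  interp <- function(v) {
    if (class_label == 1) v[1] + params$effect * (v[2] - v[1]) else v[1]
  }
  list(scale = interp(params$texture_scale),
       noise_sd = interp(params$noise_sd),
       shift = interp(params$mean_shift))
}

# separable Gaussian smoothing of a 3D array (truncated kernel, +-3 sd),
# standardized afterwards to zero mean / unit sd over the grid
gaussian_field3 <- function(grid, sigma) {
  f <- array(rnorm(prod(grid)), grid)
  if (sigma > 0.05) {
    for (axis in 1:3) {
      n <- grid[axis]
      K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
      K[abs(outer(seq_len(n), seq_len(n), "-")) > ceiling(3 * sigma)] <- 0
      perm <- c(axis, setdiff(1:3, axis))
      a <- aperm(f, perm)
      dd <- dim(a)
      a <- K %*% matrix(a, nrow = dd[1])
      dim(a) <- dd
      f <- aperm(a, order(perm))
    }
  }
  (f - mean(f)) / stats::sd(f)
}

ellipsoid_mask <- function(grid, semi) {
  ctr <- (grid + 1) / 2
  x <- (seq_len(grid[1]) - ctr[1]) / semi[1]
  y <- (seq_len(grid[2]) - ctr[2]) / semi[2]
  z <- (seq_len(grid[3]) - ctr[3]) / semi[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

#' Generate one phantom case
#'
#' Draws paired T2w-like and ADC-like volumes independently with shared
#' class parameters, on a common ellipsoidal lesion mask. Deterministic for
#' a fixed seed.
#'
#' @param class_label 0 (non-significant) or 1 (clinically significant).
#' @param params A [phantom_params()].
#' @param seed Integer seed.
#' @param case_id Case identifier.
#' @return A list: `t2`, `adc` ([`rad_volume`][new_volume]), `mask`
#'   ([`rad_mask`][new_mask]), `class_label`, `seed`.
#' @export
generate_phantom <- function(class_label, params = phantom_params(),
                             seed = 1L, case_id = "case") {
  stopifnot(class_label %in% c(0, 1))
  cp <- class_params(params, class_label)
  grid <- params$grid
  mask <- ellipsoid_mask(grid, params$lesion)
  vols <- withr::with_seed(seed, {
    lapply(c(t2 = "T2W", adc = "ADC"), function(modality) {
      vox <- array(rnorm(prod(grid)), grid)          # background texture
      f <- gaussian_field3(grid, cp$scale)
      vox[mask] <- f[mask] + cp$shift + rnorm(sum(mask), 0, cp$noise_sd)
      new_volume(vox, spacing = c(1, 1, 1), modality = modality,
                 case_id = case_id)
    })
  })
  list(t2 = vols$t2, adc = vols$adc,
       mask = new_mask(mask, case_id = case_id),
       class_label = as.integer(class_label), seed = seed)
}

#' Cohort specification
#'
#' Defaults emulate the published cohort structure: 91 cases, 43%
#' clinically significant, a suspicious DRE far more frequent in the
#' significant class, and a PI-RADS-max distribution concentrated at 3 for
#' non-significant and at 5 for significant disease.
#'
#' @param n_cases Number of cases (default 91).
#' @param prevalence Proportion of clinically significant cases in `(0, 1)`
#'   (default 0.43); the realized count is `round(n_cases * prevalence)`.
#' @param dre_prob Per-class probability of a suspicious DRE
#'   (`c(class0, class1)`, default `c(0.2, 0.7)`).
#' @param pirads_probs 2 x 3 matrix of per-class probabilities over
#'   PI-RADS `{3, 4, 5}` (rows class 0 and 1; each row sums to 1).
#' @param seed Integer seed for all cohort-level draws.
#' @return A list of class `rad_cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 91L, prevalence = 0.43,
                        dre_prob = c(0.2, 0.7),
                        pirads_probs = rbind(c(0.70, 0.27, 0.03),
                                             c(0.13, 0.28, 0.59)),
                        seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0, 1)")
  n1 <- round(n_cases * prevalence)
  if (n1 < 2L || n_cases - n1 < 2L)
    abort("`n_cases` too small to hold both classes")
  if (any(abs(rowSums(pirads_probs) - 1) > 1e-8))
    abort("`pirads_probs` rows must sum to 1")
  structure(list(n_cases = as.integer(n_cases), prevalence = prevalence,
                 dre_prob = dre_prob, pirads_probs = pirads_probs,
                 seed = as.integer(seed)),
            class = "rad_cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Exact class counts (`round(n * prevalence)` significant cases in a
#' seeded random order), per-case phantom volumes and masks, and clinical
#' covariates drawn from the class-conditional distributions of the spec.
#' All randomness flows from the single cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @param params A [phantom_params()].
#' @return An object of class `rad_cohort`: `cases` (list of
#'   [generate_phantom()] results), `clinical` (tibble `case_id`, `dre`,
#'   `pirads_max`, `label`), `spec`, `params`.
#' @export
generate_cohort <- function(spec = cohort_spec(), params = phantom_params()) {
  n <- spec$n_cases
  n1 <- round(n * spec$prevalence)
  draws <- withr::with_seed(spec$seed, {
    labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    list(
      labels = labels,
      case_seeds = sample.int(2147483646L, n),
      dre = rbinom(n, 1, spec$dre_prob[labels + 1L]),
      pirads = vapply(labels, function(l)
        sample(3:5, 1, prob = spec$pirads_probs[l + 1L, ]), integer(1))
    )
  })
  ids <- sprintf("case_%03d", seq_len(n))
  cases <- lapply(seq_len(n), function(i)
    generate_phantom(draws$labels[i], params, draws$case_seeds[i], ids[i]))
  clinical <- tibble(case_id = ids, dre = as.numeric(draws$dre),
                     pirads_max = as.numeric(draws$pirads),
                     label = draws$labels)
  structure(list(cases = cases, clinical = clinical, spec = spec,
                 params = params),
            class = "rad_cohort")
}

#' @export
print.rad_cohort <- function(x, ...) {
  cat(sprintf("<rad_cohort> %d cases (%d CS), grid %s, effect %.2f\n",
              x$spec$n_cases, sum(x$clinical$label),
              paste(x$params$grid, collapse = "x"), x$params$effect))
  invisible(x)
}

#' Feature table of an in-memory cohort
#'
#' Runs the full extractor ([assemble_case()]) on every case of a
#' generated cohort.
#'
#' @param cohort An [`rad_cohort`][generate_cohort].
#' @param config A [feature_config()].
#' @return Cohort feature tibble (one row per case).
#' @export
cohort_feature_table <- function(cohort, config = feature_config()) {
  stopifnot(inherits(cohort, "rad_cohort"))
  rows <- lapply(seq_along(cohort$cases), function(i) {
    cs <- cohort$cases[[i]]
    clin <- cohort$clinical[i, ]
    assemble_case(extract_voi(cs$t2, cs$mask),
                  extract_voi(cs$adc, cs$mask),
                  clin, config, label = clin$label)
  })
  bind_rows(rows)
}

#' Write a cohort to disk as NIfTI volume/mask pairs plus a clinical CSV
#'
#' Produces `<case>_t2.nii.gz`, `<case>_adc.nii.gz`, `<case>_mask.nii.gz`
#' per case, a `clinical.csv` (case_id, dre, pirads_max, label) and a
#' `manifest.json` listing every written file and the seed.
#'
#' @param cohort An [`rad_cohort`][generate_cohort].
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return The manifest (invisibly).
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    abort(sprintf("output directory %s exists; use force = TRUE", dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (cs in cohort$cases) {
    id <- cs$t2$case_id
    for (nm in c("t2", "adc", "mask")) {
      fn <- file.path(dir, sprintf("%s_%s.nii.gz", id, nm))
      write_volume(if (nm == "mask") cs$mask else cs[[nm]], fn)
      files <- c(files, basename(fn))
    }
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  files <- c(files, "clinical.csv")
  manifest <- list(seed = cohort$spec$seed, n_cases = cohort$spec$n_cases,
                   effect = cohort$params$effect, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
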