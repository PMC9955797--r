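# Per-case feature assembly and the cohort feature table.
#
# A case contributes 484 image features -- 12 first-order T2w, 12
# first-order ADC, 48 TOP-LBP T2w, 48 TOP-LBP ADC, 182 GLCM3 T2w, 182
# GLCM3 ADC, in that fixed order -- followed by the clinical covariates
# (default: DRE, PIRADSmax), for 486 feature columns by default. The label
# is clinically significant disease: Gleason score >= 7.

#' Feature-extraction configuration
#'
#' @param bits Grey-level quantization bit depth for GLCM3 (default 5,
#'   i.e. 32 levels).
#' @param n_bins First-order intensity histogram bins (default 64).
#' @param lbp_p,lbp_r LBP ring parameters (default 8 neighbours, radius 1).
#' @param clinical Character vector of clinical feature names appended
#'   after the image block (default `c("dre", "pirads_max")`).
#' @return A list of class `rad_feature_config`.
#' @export
feature_config <- function(bits = 5L, n_bins = 64L, lbp_p = 8L, lbp_r = 1L,
                           clinical = c("dre", "pirads_max")) {
  structure(list(bits = as.integer(bits), n_bins = as.integer(n_bins),
                 lbp_p = as.integer(lbp_p), lbp_r = as.integer(lbp_r),
                 clinical = clinical),
            class = "rad_feature_config")
}

#' Clinical covariate record
#'
#' @param case_id Case identifier.
#' @param dre Digital rectal examination: 1 = suspicious, 0 = normal.
#' @param pirads_max Highest PI-RADS score of the patient; 3, 4 or 5
#'   (study inclusion required PI-RADS >= 3).
#' @return A one-row tibble.
#' @export
clinical_record <- function(case_id, dre, pirads_max) {
  if (!dre %in% c(0, 1)) abort("`dre` must be 0 or 1")
  if (!pirads_max %in% 3:5) abort("`pirads_max` must be 3, 4 or 5")
  tibble(case_id = as.character(case_id), dre = as.numeric(dre),
         pirads_max = as.numeric(pirads_max))
}

#' Binary clinically-significant label from a Gleason score
#'
#' Gleason sum >= 7 is clinically significant (1); Gleason 6 and benign
#' biopsies (coded 0) are not (0).
#'
#' @param gleason Gleason sum in `{0, 6, 7, 8, 9, 10}`; 0 codes a benign
#'   (non-cancerous) biopsy.
#' @return Integer 0/1 vector.
#' @export
binarize_gleason <- function(gleason) {
  if (any(!gleason %in% c(0, 6, 7, 8, 9, 10)))
    abort("`gleason` values must be in {0, 6, 7, 8, 9, 10}")
  as.integer(gleason >= 7)
}

# ordered names of the 484-element image block
image_feature_names <- function(config = feature_config()) {
  fo <- fo_stat_names
  lbp <- as.vector(t(outer(lbp_variants, fo_stat_names,
                           function(v, s) paste0("lbp_", v, "_", s))))
  dd <- glcm_displacements()
  glcm <- as.vector(t(outer(
    vapply(seq_len(nrow(dd)), function(r) displacement_label(dd[r, ]), ""),
    glcm_feature_names, function(d, f) paste0("glcm_", d, "_", f))))
  c(paste0("t2_fo_", fo), paste0("adc_fo_", fo),
    paste0("t2_", lbp), paste0("adc_", lbp),
    paste0("t2_", glcm), paste0("adc_", glcm))
}

#' Assemble the feature vector of one case
#'
#' Computes the 484 image features from the T2w and ADC VOIs and appends
#' the clinical covariates. Every feature must come out finite; a
#' non-finite value is an error naming the offending feature.
#'
#' @param t2,adc VOIs ([`rad_voi`][extract_voi]) of the two modalities.
#' @param clinical A one-row tibble from [clinical_record()].
#' @param config A [feature_config()].
#' @param label Optional binary clinically-significant label.
#' @return A one-row tibble: `case_id`, `label`, 484 image features, then
#'   the clinical features.
#' @export
assemble_case <- function(t2, adc, clinical, config = feature_config(),
                          label = NA_integer_) {
  stopifnot(inherits(t2, "rad_voi"), inherits(adc, "rad_voi"))
  fo_t2 <- voi_first_order(t2, config$n_bins)
  fo_adc <- voi_first_order(adc, config$n_bins)
  names(fo_t2) <- paste0("t2_fo_", fo_stat_names)
  names(fo_adc) <- paste0("adc_fo_", fo_stat_names)
  lbp_t2 <- top_lbp_block(t2, P = config$lbp_p, R = config$lbp_r)
  lbp_adc <- top_lbp_block(adc, P = config$lbp_p, R = config$lbp_r)
  names(lbp_t2) <- paste0("t2_", names(lbp_t2))
  names(lbp_adc) <- paste0("adc_", names(lbp_adc))
  glcm <- glcm3_block(quantize(t2, config$bits), quantize(adc, config$bits))
  img <- c(fo_t2, fo_adc, lbp_t2, lbp_adc, glcm)
  if (any(!is.finite(img)))
    abort(sprintf("non-finite feature value: %s",
                  paste(names(img)[!is.finite(img)], collapse = ", ")))
  clin <- clinical[, config$clinical, drop = FALSE]
  bind_cols(
    tibble(case_id = clinical$case_id, label = as.integer(label)),
    as_tibble(as.list(img)),
    clin
  )
}

#' Write / read a cohort feature table
#'
#' The table is stored as CSV with a header row: `case_id`, `label`, then
#' the feature names, at full precision. Duplicate case ids and missing
#' cells are errors.
#'
#' @param table A cohort feature tibble (as built by
#'   [cohort_feature_table()] or [assemble_case()]).
#' @param path CSV file path.
#' @return `path` invisibly (write); the tibble (read).
#' @export
write_cohort_table <- function(table, path) {
  check_cohort_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tb$case_id <- as.character(tb$case_id)
  tb$label <- as.integer(tb$label)
  check_cohort_table(tb)
  tb
}

check_cohort_table <- function(table) {
  if (!all(c("case_id", "label") %in% names(table)))
    abort("cohort table must have `case_id` and `label` columns")
  if (anyDuplicated(table$case_id))
    abort(sprintf("duplicate case ids: %s",
                  paste(unique(table$case_id[duplicated(table$case_id)]),
                        collapse = ", ")))
  na_cells <- which(is.na(as.matrix(table[, setdiff(names(table), "label")])),
                    arr.ind = TRUE)
  if (nrow(na_cells) > 0) {
    cn <- setdiff(names(table), "label")[na_cells[1, 2]]
    abort(sprintf("missing value at row %d, column `%s`",
                  na_cells[1, 1], cn))
  }
  invisible(table)
}

# feature columns (everything but the identifiers)
feature_names_of <- function(table) setdiff(names(table), c("case_id", "label"))
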