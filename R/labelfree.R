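#' Filter records for the label-free global pipeline
#'
#' Keeps phosphorylated precursors with global q-value < `q_max`,
#' site-localisation confidence > `site_conf_min` and phospho q-value <
#' `ptm_q_max` (all strict), and removes decoy-channel rows. A precursor
#' counts as phosphorylated when its modified sequence carries one of the
#' `phospho_tokens` annotations; the token set is configurable because
#' modification spellings differ between report dialects.
#'
#' @param records A `precursor_report`.
#' @param q_max Global precursor q-value threshold (default 0.05).
#' @param site_conf_min Localisation confidence floor (default 0.5).
#' @param ptm_q_max Phospho q-value threshold (default 0.05).
#' @param phospho_tokens Character vector of annotation substrings marking
#'   a phosphorylated sequence.
#' @return Filtered `precursor_report`.
#' @export
filter_labelfree <- function(records, q_max = 0.05, site_conf_min = 0.5,
                             ptm_q_max = 0.05,
                             phospho_tokens = c("UniMod:21", "(ph)", "Phospho")) {
  is_phos <- Reduce(`|`, lapply(phospho_tokens, function(tok) {
    grepl(tok, records$modified_sequence, fixed = TRUE)
  }))
  keep <- records$channel != "decoy" &
    !is.na(records$global_q) & records$global_q < q_max &
    is_phos &
    !is.na(records$ptm_site_conf) & records$ptm_site_conf > site_conf_min &
    !is.na(records$ptm_q) & records$ptm_q < ptm_q_max
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the label-free log10 intensity matrix
#'
#' Precursor MS1 areas are log10-transformed into a features x runs
#' matrix. Duplicate observations of one (feature, run) pair are collapsed
#' by the configured rule (`max`, the most confident detection, by
#' default; `mean` available). No imputation is performed at any stage:
#' a (feature, run) pair absent from the input stays `NA`.
#'
#' @param records Filtered `precursor_report` (see [filter_labelfree()]).
#' @param design A `study_design`; defines and orders the run columns.
#' @param collapse Duplicate-collapse rule, `"max"` or `"mean"`.
#' @return Numeric matrix (precursors x runs) of log10 MS1 areas with
#'   attribute `collapse`.
#' @export
build_log_matrix <- function(records, design, collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  design <- as_study_design(as.data.frame(design))
  runs <- design$run
  rec <- records[!is.na(records$ms1_area) & records$ms1_area > 0, , drop = FALSE]
  rec <- rec[rec$run %in% runs, , drop = FALSE]
  ids <- sort(unique(rec$precursor_id))
  m <- matrix(NA_real_, length(ids), length(runs),
              dimnames = list(ids, runs))
  val <- log10(rec$ms1_area)
  key <- paste(rec$precursor_id, rec$run, sep = "\r")
  agg <- if (collapse == "max") {
    tapply(val, key, max)
  } else {
    tapply(val, key, mean)
  }
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  m[cbind(match(vapply(parts, `[[`, "", 1L), ids),
          match(vapply(parts, `[[`, "", 2L), runs))] <- as.numeric(agg)
  attr(m, "collapse") <- collapse
  m
}

#' Label-free quantification, end to end
#'
#' @param records A `precursor_report`.
#' @param design A `study_design`.
#' @param ... Passed to [filter_labelfree()] and [build_log_matrix()].
#' @inheritParams build_log_matrix
#' @return Log10 intensity matrix as from [build_log_matrix()].
#' @export
labelfree_quantify <- function(records, design, collapse = "max", ...) {
  validate_report_design(records, design)
  filt <- filter_labelfree(records, ...)
  build_log_matrix(filt, design, collapse = collapse)
}

#' Principal component analysis on complete features
#'
#' Convenience wrapper: runs a standard PCA (`stats::prcomp`) on the
#' features identified in every run, the same complete-case subset used
#' for sample-level ordination of the label-free data.
#'
#' @param x Numeric features x runs matrix.
#' @param center,scale. Passed to [stats::prcomp()].
#' @return A `prcomp` object on the run (column) coordinates.
#' @export
pca_complete <- function(x, center = TRUE, scale. = FALSE) {
  complete <- stats::complete.cases(x)
  if (sum(complete) < 2L) stop("fewer than 2 features identified in every run")
  stats::prcomp(t(x[complete, , drop = FALSE]), center = center, scale. = scale.)
}
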