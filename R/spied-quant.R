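#' Select heavy spike-in anchor precursors
#'
#' A precursor qualifies as an anchor when its HEAVY (spike-in) channel
#' passes all four row-level confidence/intensity filters in at least
#' `min_heavy_runs` runs: channel q-value < `channel_q_max`, phospho
#' modification q-value < `ptm_q_max`, site localisation confidence >
#' `site_conf_min`, and heavy intensity > `heavy_min_intensity`. All
#' inequalities are strict, matching the reporting software's conventions,
#' so boundary values fail.
#'
#' @param records A `precursor_report`.
#' @param channel_q_max Channel q-value threshold (default 0.05).
#' @param ptm_q_max Phospho q-value threshold (default 0.05).
#' @param site_conf_min Site-localisation confidence floor (default 0.5).
#' @param heavy_min_intensity Heavy spike-in intensity floor (default 1000).
#' @param min_heavy_runs Minimum number of runs in which the heavy channel
#'   must pass; default `ceiling(0.8 * n_runs)`, which generalizes the
#'   "more than 9 of 12 runs" rule of a 12-run study.
#' @return Data frame of class `spied_anchors` with one row per passing
#'   precursor (`precursor_id`, `modified_sequence`, `stripped_sequence`,
#'   `n_heavy_pass`); attribute `all_counts` holds passing-run counts for
#'   every precursor, attribute `runs` the run universe.
#' @export
filter_heavy_anchors <- function(records,
                                 channel_q_max = 0.05,
                                 ptm_q_max = 0.05,
                                 site_conf_min = 0.5,
                                 heavy_min_intensity = 1000,
                                 min_heavy_runs = NULL) {
  if (!nrow(records)) stop("empty record set")
  stopifnot(channel_q_max > 0, ptm_q_max > 0, site_conf_min > 0,
            heavy_min_intensity > 0)
  runs <- sort(unique(records$run))
  if (is.null(min_heavy_runs)) min_heavy_runs <- ceiling(0.8 * length(runs))
  if (min_heavy_runs > length(runs)) {
    stop("min_heavy_runs (", min_heavy_runs, ") exceeds run count (",
         length(runs), ")")
  }
  h <- records[records$channel == "H", , drop = FALSE]
  pass <- !is.na(h$channel_q) & h$channel_q < channel_q_max &
    !is.na(h$ptm_q) & h$ptm_q < ptm_q_max &
    !is.na(h$ptm_site_conf) & h$ptm_site_conf > site_conf_min &
    !is.na(h$intensity_H) & h$intensity_H > heavy_min_intensity
  counts <- tapply(pass, h$precursor_id, sum)
  all_ids <- unique(records$precursor_id)
  n_pass <- integer(length(all_ids))
  names(n_pass) <- all_ids
  n_pass[names(counts)] <- as.integer(counts)

  keep_ids <- names(n_pass)[n_pass >= min_heavy_runs]
  meta <- unique(records[records$precursor_id %in% keep_ids,
                         c("precursor_id", "modified_sequence",
                           "stripped_sequence", "charge")])
  meta <- meta[order(meta$precursor_id), , drop = FALSE]
  meta$n_heavy_pass <- n_pass[meta$precursor_id]
  rownames(meta) <- NULL
  structure(meta,
            all_counts = n_pass,
            runs = runs,
            min_heavy_runs = min_heavy_runs,
            class = c("spied_anchors", "data.frame"))
}

#' Rescue light-channel quantities under the heavy anchor
#'
#' For every anchored precursor and run, the light (endogenous) intensity
#' is extracted whenever the report carries it, regardless of the light
#' channel q-value: the confidently identified heavy spike-in serves as a
#' detection beacon, uncoupling detection from quantification. Each cell
#' is labelled `detected` (light q below the strict threshold), `rescued`
#' (light present but q at or above it), or `absent` (no light intensity).
#'
#' @param records A `precursor_report`.
#' @param anchors Result of [filter_heavy_anchors()].
#' @param channel_q_strict Strict light-channel confidence threshold that
#'   separates `detected` from `rescued` cells (default 0.05).
#' @return An `anchored_set`: list with feature metadata and
#'   features x runs matrices `H`, `L`, `Lq` and character matrix `flags`.
#' @export
rescue_light <- function(records, anchors, channel_q_strict = 0.05) {
  runs <- attr(anchors, "runs")
  ids <- anchors$precursor_id
  if (!length(ids)) stop("no anchored precursors to rescue")
  empty <- matrix(NA_real_, length(ids), length(runs),
                  dimnames = list(ids, runs))
  H <- L <- Lq <- empty

  fill <- function(M, sub, field) {
    sub <- sub[sub$precursor_id %in% ids, , drop = FALSE]
    M[cbind(match(sub$precursor_id, ids), match(sub$run, runs))] <- sub[[field]]
    M
  }
  hrows <- records[records$channel == "H", , drop = FALSE]
  lrows <- records[records$channel == "L", , drop = FALSE]
  H <- fill(H, hrows, "intensity_H")
  L <- fill(L, lrows, "intensity_L")
  Lq <- fill(Lq, lrows, "channel_q")

  flags <- matrix("absent", length(ids), length(runs),
                  dimnames = list(ids, runs))
  flags[!is.na(L)] <- "rescued"
  flags[!is.na(L) & !is.na(Lq) & Lq < channel_q_strict] <- "detected"

  structure(list(features = as.data.frame(anchors), runs = runs,
                 H = H, L = L, Lq = Lq, flags = flags,
                 channel_q_strict = channel_q_strict),
            class = "anchored_set")
}

#' @export
print.anchored_set <- function(x, ...) {
  cat(sprintf("Anchored precursor set: %d features x %d runs\n",
              nrow(x$H), ncol(x$H)))
  tab <- table(factor(x$flags, levels = c("detected", "rescued", "absent")))
  cat("  light cells:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

.subset_anchored <- function(anchored, keep_ids) {
  i <- match(keep_ids, rownames(anchored$H))
  anchored$features <- anchored$features[
    match(keep_ids, anchored$features$precursor_id), , drop = FALSE]
  for (m in c("H", "L", "Lq", "flags")) {
    anchored[[m]] <- anchored[[m]][i, , drop = FALSE]
  }
  anchored
}

#' Presence/absence filter for anchored features
#'
#' A feature is retained when (a) its light intensity exceeds
#' `light_min_intensity` in at least `min_reps_per_condition` replicates
#' within at least one experimental condition (so comparisons are never
#' noise-to-noise), and (b) its light channel q-value is below
#' `light_q_relaxed` in at least `min_light_runs_relaxed` runs overall.
#' Features whose heavy anchor is consistently present but which fail (a)
#' in every condition are reported as confident-absence calls: the
#' spike-in was seen, the endogenous counterpart never rose above the
#' noise floor.
#'
#' @param anchored An `anchored_set` from [rescue_light()].
#' @param design A `study_design` covering the anchored runs.
#' @param light_min_intensity Light-intensity noise floor (default 900).
#' @param light_q_relaxed Relaxed light confidence threshold (default 0.5).
#' @param min_light_runs_relaxed Minimum runs passing the relaxed
#'   confidence (default 3, the "3 of 12 samples" study rule).
#' @param min_reps_per_condition Minimum above-floor replicates within one
#'   condition (default 2, the "two out of three replicates" study rule).
#' @return List of class `presence_filter` with elements `retained`
#'   (an `anchored_set` restricted to retained features), `absence_calls`
#'   (character vector of feature ids), and `table` (per-feature rule
#'   diagnostics).
#' @export
presence_filter <- function(anchored, design,
                            light_min_intensity = 900,
                            light_q_relaxed = 0.5,
                            min_light_runs_relaxed = 3,
                            min_reps_per_condition = 2) {
  stopifnot(inherits(anchored, "anchored_set"))
  design <- as_study_design(as.data.frame(design))
  runs <- anchored$runs
  if (!all(runs %in% design$run)) {
    stop("run(s) missing from design: ",
         paste(setdiff(runs, design$run), collapse = ", "))
  }
  cond <- design_condition(design)[match(runs, design$run)]
  cond_sizes <- table(cond)
  if (min_reps_per_condition > min(cond_sizes)) {
    stop("min_reps_per_condition (", min_reps_per_condition,
         ") exceeds the smallest per-condition replicate count (",
         min(cond_sizes), ")")
  }

  above <- !is.na(anchored$L) & anchored$L > light_min_intensity
  per_cond <- t(apply(above, 1L, function(z) tapply(z, cond, sum)))
  rule_a <- apply(per_cond, 1L, max) >= min_reps_per_condition
  n_q_ok <- rowSums(!is.na(anchored$Lq) & anchored$Lq < light_q_relaxed)
  rule_b <- n_q_ok >= min_light_runs_relaxed

  retained_ids <- rownames(anchored$L)[rule_a & rule_b]
  absence_ids <- rownames(anchored$L)[!rule_a]
  tab <- data.frame(
    precursor_id = rownames(anchored$L),
    max_reps_above_floor = apply(per_cond, 1L, max),
    n_runs_q_relaxed = n_q_ok,
    rule_condition_presence = rule_a,
    rule_relaxed_confidence = rule_b,
    retained = rule_a & rule_b,
    confident_absence = !rule_a,
    row.names = NULL
  )
  structure(list(
    retained = .subset_anchored(anchored, retained_ids),
    retained_ids = retained_ids,
    absence_calls = absence_ids,
    table = tab,
    params = list(light_min_intensity = light_min_intensity,
                  light_q_relaxed = light_q_relaxed,
                  min_light_runs_relaxed = min_light_runs_relaxed,
                  min_reps_per_condition = min_reps_per_condition)
  ), class = "presence_filter")
}

#' @export
print.presence_filter <- function(x, ...) {
  cat(sprintf("Presence filter: %d retained, %d confident-absence calls (of %d anchored)\n",
              length(x$retained_ids), length(x$absence_calls), nrow(x$table)))
  invisible(x)
}

#' Rescaled ratio quantification matrix
#'
#' For each retained feature a rescaling factor `r` is computed as the
#' median heavy spike-in intensity across the runs where the heavy channel
#' is present; per run, the quantity is `y = log10((L / H) * r)` whenever
#' both channels are present, and missing otherwise. Because the spike-in
#' amount is constant across runs, dividing by `H` cancels run-level
#' variation while multiplying by `r` restores an intensity-like scale.
#'
#' @param anchored An `anchored_set`, typically `presence_filter(...)$retained`.
#' @param rescale_scope `"per-precursor"` (default: each feature uses the
#'   median of its own heavy intensities) or `"global"` (one factor, the
#'   median over all heavy intensities in the set).
#' @return Object of class `spied_matrix`: list with `values` (features x
#'   runs matrix of `y`), `provenance` (per-cell `detected`/`rescued`/
#'   `absent` flags), `rescaling` (named vector `r`), `features` metadata.
#' @export
compute_rescaled_matrix <- function(anchored,
                                    rescale_scope = c("per-precursor", "global")) {
  stopifnot(inherits(anchored, "anchored_set"))
  rescale_scope <- match.arg(rescale_scope)
  H <- anchored$H
  L <- anchored$L
  if (!nrow(H)) stop("no features to quantify")
  all_h_missing <- rowSums(!is.na(H)) == 0L
  if (any(all_h_missing)) {
    stop("feature(s) with no heavy intensity in any run: ",
         paste(utils::head(rownames(H)[all_h_missing], 5L), collapse = ", "))
  }
  r <- if (rescale_scope == "per-precursor") {
    apply(H, 1L, stats::median, na.rm = TRUE)
  } else {
    rep(stats::median(H, na.rm = TRUE), nrow(H))
  }
  names(r) <- rownames(H)
  ok <- !is.na(L) & !is.na(H) & H > 0 & L > 0
  values <- matrix(NA_real_, nrow(H), ncol(H), dimnames = dimnames(H))
  values[ok] <- log10((L[ok] / H[ok]) * r[row(H)[ok]])
  structure(list(values = values,
                 provenance = anchored$flags,
                 rescaling = r,
                 features = anchored$features,
                 rescale_scope = rescale_scope),
            class = "spied_matrix")
}

#' @export
print.spied_matrix <- function(x, ...) {
  cat(sprintf("Rescaled ratio matrix: %d features x %d runs (%.1f%% cells present)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Spike-in enhanced quantification, end to end
#'
#' Chains [filter_heavy_anchors()], [rescue_light()], [presence_filter()]
#' and [compute_rescaled_matrix()] with the study defaults.
#'
#' @param records A `precursor_report`.
#' @param design A `study_design`.
#' @param channel_q_max,ptm_q_max,site_conf_min,heavy_min_intensity,min_heavy_runs
#'   Heavy-anchor thresholds; see [filter_heavy_anchors()].
#' @param channel_q_strict Strict light threshold; see [rescue_light()].
#' @param light_min_intensity,light_q_relaxed,min_light_runs_relaxed,min_reps_per_condition
#'   Presence thresholds; see [presence_filter()].
#' @param rescale_scope See [compute_rescaled_matrix()].
#' @return List with `matrix` (a `spied_matrix`), `anchors`, `presence`,
#'   and `absence_calls`.
#' @export
spied_quantify <- function(records, design,
                           channel_q_max = 0.05, ptm_q_max = 0.05,
                           site_conf_min = 0.5, heavy_min_intensity = 1000,
                           min_heavy_runs = NULL, channel_q_strict = 0.05,
                           light_min_intensity = 900, light_q_relaxed = 0.5,
                           min_light_runs_relaxed = 3,
                           min_reps_per_condition = 2,
                           rescale_scope = "per-precursor") {
  validate_report_design(records, design)
  anchors <- filter_heavy_anchors(records,
                                  channel_q_max = channel_q_max,
                                  ptm_q_max = ptm_q_max,
                                  site_conf_min = site_conf_min,
                                  heavy_min_intensity = heavy_min_intensity,
                                  min_heavy_runs = min_heavy_runs)
  if (!nrow(anchors)) {
    return(list(matrix = NULL, anchors = anchors, presence = NULL,
                absence_calls = character()))
  }
  anchored <- rescue_light(records, anchors,
                           channel_q_strict = channel_q_strict)
  pres <- presence_filter(anchored, design,
                          light_min_intensity = light_min_intensity,
                          light_q_relaxed = light_q_relaxed,
                          min_light_runs_relaxed = min_light_runs_relaxed,
                          min_reps_per_condition = min_reps_per_condition)
  mat <- if (length(pres$retained_ids)) {
    compute_rescaled_matrix(pres$retained, rescale_scope = rescale_scope)
  } else NULL
  list(matrix = mat, anchors = anchors, presence = pres,
       absence_calls = pres$absence_calls)
}
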