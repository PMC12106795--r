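#' Factorial design matrix and synergy contrasts for the 2x2 design
#'
#' Builds a cell-means parameterization of the MEKi x GFmix design
#' (one indicator column per treatment combination) together with the
#' five study contrasts expressed as plain cell-mean differences:
#' `GFmix_wo_MEKi`, `GFmix_w_MEKi`, `MEKi_wo_GFmix`, `MEKi_w_GFmix`,
#' and the synergy contrast
#' `Interaction = (mu11 - mu10) - (mu01 - mu00)`, which equals the
#' difference of the two GFmix effects and, identically, of the two MEKi
#' effects. The stacked contrast set has rank 3.
#'
#' @param design A `study_design` with at least one run per cell.
#' @return Object of class `factorial_design`: list with `design_matrix`
#'   (runs x 4 indicators), `contrasts` (4 x 5 matrix), `contrast_rank`,
#'   and `runs`.
#' @export
build_design_and_contrasts <- function(design) {
  design <- as_study_design(as.data.frame(design))
  cells <- c("MEKi0.GF0", "MEKi0.GF1", "MEKi1.GF0", "MEKi1.GF1")
  cond <- design_condition(design)
  missing_cells <- setdiff(cells, cond)
  if (length(missing_cells)) {
    stop("empty design cell(s): ", paste(missing_cells, collapse = ", "))
  }
  X <- matrix(0, nrow(design), 4L, dimnames = list(design$run, cells))
  X[cbind(seq_len(nrow(design)), match(cond, cells))] <- 1
  C <- cbind(
    GFmix_wo_MEKi = c(-1, 1, 0, 0),
    GFmix_w_MEKi  = c(0, 0, -1, 1),
    MEKi_wo_GFmix = c(-1, 0, 1, 0),
    MEKi_w_GFmix  = c(0, -1, 0, 1),
    Interaction   = c(1, -1, -1, 1)
  )
  rownames(C) <- cells
  structure(list(design_matrix = X, contrasts = C,
                 contrast_rank = qr(C)$rank, runs = design$run),
            class = "factorial_design")
}

#' Per-feature least-squares fits on the factorial design
#'
#' Fits ordinary least squares per feature on its observed runs only.
#' Features with more than `max_missing` missing cells are excluded, as
#' are features whose observed runs no longer span all four design cells
#' (rank loss) or leave no residual degrees of freedom; exclusions are
#' recorded, not fatal. Features are grouped by missingness pattern so
#' each distinct reduced design is factorized once.
#'
#' @param x Numeric features x runs matrix (normalized, log scale).
#' @param fdesign A `factorial_design` whose runs match `colnames(x)`.
#' @param max_missing Maximum missing cells per feature (default 5).
#' @return Object of class `feature_fits`: per-feature coefficient and
#'   contrast estimates, residual variances `sigma2`, residual df `df`,
#'   unscaled contrast standard deviations, per-pattern unscaled contrast
#'   covariances, average expression, and an `excluded` table.
#' @export
fit_feature_models <- function(x, fdesign, max_missing = 5) {
  stopifnot(inherits(fdesign, "factorial_design"), is.matrix(x))
  X <- fdesign$design_matrix
  if (is.null(colnames(x)) || !setequal(colnames(x), rownames(X))) {
    stop("matrix columns must match the design runs")
  }
  x <- x[, rownames(X), drop = FALSE]
  C <- fdesign$contrasts
  n_run <- ncol(x)
  n_coef <- ncol(X)

  n_missing <- rowSums(is.na(x))
  excluded <- data.frame(precursor_id = character(), reason = character())
  drop_missing <- n_missing > max_missing
  if (any(drop_missing)) {
    excluded <- rbind(excluded, data.frame(
      precursor_id = rownames(x)[drop_missing], reason = "missing"))
  }
  keep <- which(!drop_missing)

  pattern_key <- apply(!is.na(x[keep, , drop = FALSE]), 1L,
                       function(z) paste(as.integer(z), collapse = ""))
  ids <- rownames(x)[keep]
  est <- matrix(NA_real_, length(keep), ncol(C),
                dimnames = list(ids, colnames(C)))
  beta <- matrix(NA_real_, length(keep), n_coef,
                 dimnames = list(ids, colnames(X)))
  su <- matrix(NA_real_, length(keep), ncol(C),
               dimnames = list(ids, colnames(C)))
  sigma2 <- stats::setNames(rep(NA_real_, length(keep)), ids)
  dfres <- stats::setNames(rep(NA_real_, length(keep)), ids)
  amean <- stats::setNames(rep(NA_real_, length(keep)), ids)
  pattern_of <- stats::setNames(rep(NA_character_, length(keep)), ids)
  cov_unscaled <- list()
  bad <- logical(length(keep))
  bad_reason <- character(length(keep))

  for (pk in unique(pattern_key)) {
    sel <- which(pattern_key == pk)
    obs <- as.logical(as.integer(strsplit(pk, "")[[1L]]))
    X_o <- X[obs, , drop = FALSE]
    qrX <- qr(X_o)
    if (qrX$rank < n_coef) {
      bad[sel] <- TRUE
      bad_reason[sel] <- "rank"
      next
    }
    d <- sum(obs) - n_coef
    if (d < 1L) {
      bad[sel] <- TRUE
      bad_reason[sel] <- "df"
      next
    }
    XtXinv <- chol2inv(chol(crossprod(X_o)))
    P <- XtXinv %*% t(X_o)
    U <- t(C) %*% XtXinv %*% C
    cov_unscaled[[pk]] <- U
    Y <- x[keep[sel], obs, drop = FALSE]
    B <- Y %*% t(P)
    res <- Y - B %*% t(X_o)
    beta[sel, ] <- B
    est[sel, ] <- B %*% C
    sigma2[sel] <- rowSums(res^2) / d
    dfres[sel] <- d
    su[sel, ] <- matrix(sqrt(diag(U)), length(sel), ncol(C), byrow = TRUE)
    amean[sel] <- rowMeans(Y)
    pattern_of[sel] <- pk
  }
  if (any(bad)) {
    excluded <- rbind(excluded, data.frame(
      precursor_id = ids[bad], reason = bad_reason[bad]))
    keep_final <- !bad
    est <- est[keep_final, , drop = FALSE]
    beta <- beta[keep_final, , drop = FALSE]
    su <- su[keep_final, , drop = FALSE]
    sigma2 <- sigma2[keep_final]
    dfres <- dfres[keep_final]
    amean <- amean[keep_final]
    pattern_of <- pattern_of[keep_final]
  }
  structure(list(estimates = est, coefficients = beta,
                 stdev_unscaled = su, sigma2 = sigma2, df = dfres,
                 ave_expr = amean, pattern = pattern_of,
                 cov_unscaled = cov_unscaled,
                 contrast_rank = fdesign$contrast_rank,
                 contrasts = C, excluded = excluded,
                 zero_variance = sigma2 <= 1e-24 * pmax(1, amean^2)),
            class = "feature_fits")
}

#' Invert the trigamma function
#'
#' Newton iteration on a monotone transform; used to moment-match the
#' prior degrees of freedom of the variance distribution.
#'
#' @param y Positive numeric vector.
#' @return `x` such that `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  out <- y
  omit <- is.na(y)
  big <- !omit & y > 1e7
  out[big] <- 1 / sqrt(y[big])
  small <- !omit & y < 1e-6
  out[small] <- 1 / y[small]
  mid <- !omit & !big & !small
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in seq_len(50L)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s02`
#' of a scaled inverse chi-square prior by moment matching on the log
#' residual variances (digamma/trigamma relations, handling unequal
#' residual df), then forms posterior variances
#' `s2_post = (d0*s02 + d*s2) / (d0 + d)`, moderated t statistics per
#' contrast on `d0 + d` degrees of freedom, and a moderated F over the
#' dependent contrast set using its rank (contrast estimates are
#' orthogonalized through the eigendecomposition of their unscaled
#' covariance). When the log-variances are underdispersed relative to
#' pure sampling noise the prior df is infinite and every posterior
#' variance equals `s02`. Features with zero residual variance enter the
#' moment matching offset to a small quantile of the variance scale
#' (1e-5 of the median variance) and are flagged.
#'
#' @param fits A `feature_fits` object.
#' @param d0,s02 Optional prior values to inject instead of estimating
#'   (e.g. `d0 = 0` reduces to ordinary t statistics; `d0 = Inf` fixes
#'   all posterior variances at `s02`).
#' @return Object of class `moderated_fit` extending `fits` with `d0`,
#'   `s02`, `s2_post`, `df_total`, matrices `t` and `p_t`, vectors `F`
#'   and `p_F`, and the numerator rank `f_rank`.
#' @export
empirical_bayes <- function(fits, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fits, "feature_fits"))
  s2 <- fits$sigma2
  d <- fits$df
  if (length(s2) < 1L) stop("no fitted features")
  if (is.null(d0)) {
    if (sum(d >= 1) < 10L) {
      warning("fewer than 10 features with residual df >= 1; ",
              "prior estimates may be unstable")
    }
    m <- stats::median(s2)
    if (m <= 0) stop("more than half of the residual variances are zero")
    # zero variances are offset to a small quantile of the variance scale
    s2_eff <- pmax(s2, 1e-5 * m)
    e <- log(s2_eff) - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    n <- length(e)
    evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(d / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- mean(s2_eff)
    }
  } else if (is.null(s02)) {
    if (is.infinite(d0)) stop("s02 must be supplied when d0 is infinite")
    s02 <- if (d0 > 0) mean(s2) else NA_real_
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  names(s2_post) <- names(s2)
  df_total <- d0 + d

  tmat <- fits$estimates / (fits$stdev_unscaled * sqrt(s2_post))
  pmat <- 2 * stats::pt(-abs(tmat), df = df_total)

  r <- fits$contrast_rank
  Fstat <- stats::setNames(rep(NA_real_, length(s2)), names(s2))
  for (pk in unique(fits$pattern)) {
    U <- fits$cov_unscaled[[pk]]
    eg <- eigen(U, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-9
    G <- eg$vectors[, pos, drop = FALSE] %*%
      diag(1 / sqrt(eg$values[pos]), nrow = sum(pos))
    sel <- fits$pattern == pk
    W <- fits$estimates[sel, , drop = FALSE] %*% G
    Fstat[sel] <- rowSums(W^2) / r / s2_post[sel]
  }
  p_F <- stats::pf(Fstat, df1 = r, df2 = df_total, lower.tail = FALSE)

  out <- fits
  out$d0 <- d0
  out$s02 <- s02
  out$s2_post <- s2_post
  out$df_total <- df_total
  out$t <- tmat
  out$p_t <- pmat
  out$F <- Fstat
  out$p_F <- p_F
  out$f_rank <- r
  class(out) <- c("moderated_fit", "feature_fits")
  out
}

#' Fit the moderated factorial model to a quantification matrix
#'
#' The main modelling entry point: builds the 2x2 cell-means design and
#' synergy contrasts, fits per-feature least squares honouring
#' missingness, and applies empirical-Bayes variance moderation.
#'
#' @param x Numeric features x runs matrix (log scale, normalized), or a
#'   `spied_matrix`.
#' @param design A `study_design`.
#' @param max_missing Maximum missing cells per feature (default 5).
#' @param d0,s02 Optional prior injection; see [empirical_bayes()].
#' @param feature_meta Optional data frame with `precursor_id` and
#'   `modified_sequence` used to annotate the results table (taken from a
#'   `spied_matrix` automatically).
#' @return Object of class `spied_fit` wrapping the `moderated_fit` plus
#'   the design and a tidy results table (see [contrast_table()]).
#' @export
fit_factorial_model <- function(x, design, max_missing = 5,
                                d0 = NULL, s02 = NULL, feature_meta = NULL) {
  if (inherits(x, "spied_matrix")) {
    if (is.null(feature_meta)) feature_meta <- x$features
    x <- x$values
  }
  fdesign <- build_design_and_contrasts(design)
  fits <- fit_feature_models(x, fdesign, max_missing = max_missing)
  eb <- empirical_bayes(fits, d0 = d0, s02 = s02)
  obj <- structure(list(fdesign = fdesign, fit = eb,
                        feature_meta = feature_meta,
                        design = as_study_design(as.data.frame(design))),
                   class = "spied_fit")
  obj$table <- contrast_table(obj)
  obj
}

#' Tidy per-feature results table
#'
#' One row per tested feature: average expression, per-contrast estimate,
#' moderated t and two-sided p (plus Benjamini-Hochberg adjusted p
#' emitted alongside; the fixed study cut-offs use the raw p-values),
#' and the moderated F with its p-value.
#'
#' @param fit A `spied_fit`.
#' @return A `data.frame`.
#' @export
contrast_table <- function(fit) {
  stopifnot(inherits(fit, "spied_fit"))
  eb <- fit$fit
  ids <- rownames(eb$estimates)
  tab <- data.frame(precursor_id = ids,
                    ave_expr = eb$ave_expr,
                    row.names = NULL)
  if (!is.null(fit$feature_meta) &&
      all(c("precursor_id", "modified_sequence") %in% names(fit$feature_meta))) {
    tab$modified_sequence <- fit$feature_meta$modified_sequence[
      match(ids, fit$feature_meta$precursor_id)]
  }
  for (cn in colnames(eb$estimates)) {
    tab[[paste0("logFC.", cn)]] <- eb$estimates[, cn]
    tab[[paste0("t.", cn)]] <- eb$t[, cn]
    tab[[paste0("p.", cn)]] <- eb$p_t[, cn]
    tab[[paste0("p.adj.", cn)]] <- stats::p.adjust(eb$p_t[, cn], "BH")
  }
  tab$F <- eb$F
  tab$F.p <- eb$p_F
  tab$F.p.adj <- stats::p.adjust(eb$p_F, "BH")
  tab$residual_df <- eb$df
  tab$zero_variance <- eb$zero_variance
  tab
}

#' @export
print.spied_fit <- function(x, ...) {
  eb <- x$fit
  cat(sprintf("Moderated 2x2 factorial fit: %d features tested, %d excluded\n",
              nrow(eb$estimates), nrow(eb$excluded)))
  cat(sprintf("  prior df d0 = %s, prior variance s02 = %.4g\n",
              format(eb$d0, digits = 4), eb$s02))
  cat("  contrasts:", paste(colnames(eb$estimates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spied_fit <- function(object, alpha = 0.05, ...) {
  eb <- object$fit
  sig <- colSums(eb$p_t < alpha, na.rm = TRUE)
  cat(sprintf("Features tested: %d (excluded: %d)\n",
              nrow(eb$estimates), nrow(eb$excluded)))
  cat(sprintf("Prior: d0 = %s, s02 = %.4g\n",
              format(eb$d0, digits = 4), eb$s02))
  cat(sprintf("Significant per contrast at p < %g:\n", alpha))
  for (cn in names(sig)) cat(sprintf("  %-15s %d\n", cn, sig[[cn]]))
  cat(sprintf("Moderated F p < 0.1: %d\n", sum(eb$p_F < 0.1, na.rm = TRUE)))
  invisible(object)
}

#' @export
coef.spied_fit <- function(object, ...) {
  object$fit$estimates
}

#' Collapse precursor results to one row per phosphopeptide sequence
#'
#' For each unique modified sequence the precursor (charge state) with
#' the smallest moderated-F p-value is selected. Exact ties are broken
#' deterministically: higher average expression first, then the
#' lexicographically smaller precursor id.
#'
#' @param tab Results table from [contrast_table()] with a
#'   `modified_sequence` column.
#' @return Subset of `tab`, one row per sequence.
#' @export
aggregate_per_sequence <- function(tab) {
  stopifnot("modified_sequence" %in% names(tab))
  ord <- order(tab$modified_sequence, tab$F.p, -tab$ave_expr,
               tab$precursor_id)
  tab <- tab[ord, , drop = FALSE]
  out <- tab[!duplicated(tab$modified_sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select significantly regulated features
#'
#' @param tab Results table (typically from [aggregate_per_sequence()]).
#' @param f_p_max Moderated-F p-value cut-off, strict (default 0.1).
#' @return Subset of `tab` with `F.p < f_p_max`.
#' @export
select_regulated <- function(tab, f_p_max = 0.1) {
  out <- tab[!is.na(tab$F.p) & tab$F.p < f_p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export per-contrast inputs for external kinase-enrichment tools
#'
#' Two modes. `rank`: per contrast, a table of signed
#' `sign(logFC) * (-log10 p)` scores keyed by the 14-amino-acid site
#' flanking window, restricted to features significantly regulated in at
#' least one test (moderated-F p < `f_p_max`); multiply phosphorylated
#' peptides are split into one row per site window. `foreground`: per
#' contrast, the site list with `|logFC| > fc_min` and `p < p_max`
#' (both strict).
#'
#' @param tab Results table from [contrast_table()] or
#'   [aggregate_per_sequence()].
#' @param site_windows Data frame with columns `precursor_id` and
#'   `site_window` (one row per phosphosite; multiply phosphorylated
#'   precursors contribute several rows).
#' @param mode `"rank"` or `"foreground"`.
#' @param f_p_max Rank-mode F-p restriction (default 0.1).
#' @param fc_min,p_max Foreground-mode thresholds (defaults 0.1, 0.05).
#' @param out_dir Optional directory; when given, one TSV per contrast is
#'   written.
#' @return Named list of per-contrast data frames; attribute
#'   `n_missing_window` counts features skipped for lack of a window.
#' @export
export_enrichment_inputs <- function(tab, site_windows,
                                     mode = c("rank", "foreground"),
                                     f_p_max = 0.1, fc_min = 0.1,
                                     p_max = 0.05, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("precursor_id", "site_window") %in% names(site_windows)))
  contrasts <- sub("^logFC\\.", "", grep("^logFC\\.", names(tab), value = TRUE))
  if (mode == "rank") tab <- tab[!is.na(tab$F.p) & tab$F.p < f_p_max, , drop = FALSE]
  have_window <- tab$precursor_id %in% site_windows$precursor_id
  n_missing <- sum(!have_window)
  if (n_missing) {
    warning(n_missing, " feature(s) skipped: no site flanking window")
  }
  tab <- tab[have_window, , drop = FALSE]
  merged <- merge(tab, site_windows, by = "precursor_id")
  out <- list()
  for (cn in contrasts) {
    fc <- merged[[paste0("logFC.", cn)]]
    p <- merged[[paste0("p.", cn)]]
    if (mode == "rank") {
      df <- data.frame(site_window = merged$site_window,
                       score = sign(fc) * (-log10(p)))
    } else {
      keep <- !is.na(fc) & !is.na(p) & abs(fc) > fc_min & p < p_max
      df <- data.frame(site_window = merged$site_window[keep],
                       logFC = fc[keep], p = p[keep])
    }
    rownames(df) <- NULL
    out[[cn]] <- df
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(df, file.path(out_dir, paste0(mode, "_", cn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  attr(out, "n_missing_window") <- n_missing
  out
}
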