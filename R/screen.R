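#' Remove multivariate outlier replicates from a screen table
#'
#' A replicate observation is removed only when its absolute z-score
#' reaches `z_threshold` for ALL measured analytes simultaneously.
#' Z-scores are computed per (cell line, analyte) across the replicates
#' of all conditions (the within-condition reading is ruled out
#' arithmetically: with n = 4 replicates a |z| >= 3 is unattainable
#' within one condition). Scopes with fewer than 3 values are skipped
#' with a warning; constant scopes give z = 0.
#'
#' @param tab Long-format screen table with columns `cell_line`,
#'   `analyte`, `ligand`, `inhibitor`, `replicate`, `value`.
#' @param z_threshold Absolute z-score threshold (default 3, inclusive).
#' @param scope `"cell_line"` (default: z across all conditions) or
#'   `"condition"` (z within each ligand x inhibitor cell).
#' @return `tab` with outlier replicates removed; attribute `removed`
#'   lists them.
#' @export
remove_outliers <- function(tab, z_threshold = 3,
                            scope = c("cell_line", "condition")) {
  scope <- match.arg(scope)
  req <- c("cell_line", "analyte", "ligand", "inhibitor", "replicate", "value")
  stopifnot(all(req %in% names(tab)))
  grp <- if (scope == "cell_line") {
    interaction(tab$cell_line, tab$analyte, drop = TRUE)
  } else {
    interaction(tab$cell_line, tab$analyte, tab$ligand, tab$inhibitor,
                drop = TRUE)
  }
  z <- rep(NA_real_, nrow(tab))
  for (g in levels(grp)) {
    i <- which(grp == g)
    if (length(i) < 3L) {
      warning("scope '", g, "' has fewer than 3 values; outlier screen skipped")
      z[i] <- 0
      next
    }
    s <- stats::sd(tab$value[i])
    z[i] <- if (is.na(s) || s == 0) 0 else
      (tab$value[i] - mean(tab$value[i])) / s
  }
  # an observation unit is one replicate of one condition in one cell line
  unit <- interaction(tab$cell_line, tab$ligand, tab$inhibitor, tab$replicate,
                      drop = TRUE)
  all_out <- tapply(abs(z) >= z_threshold, unit, all)
  bad_units <- names(all_out)[all_out]
  drop <- unit %in% bad_units
  out <- tab[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- unique(tab[drop, c("cell_line", "ligand",
                                             "inhibitor", "replicate")])
  out
}

#' Log2 fold changes versus the within-cell-line control
#'
#' For each (cell line, analyte), the control level is the mean of the
#' solvent-control replicates (`control_ligand` + `control_inhibitor`);
#' each observation becomes `log2(value) - log2(control mean)`.
#'
#' @param tab Screen table (see [remove_outliers()]); `value` must be a
#'   positive raw readout.
#' @param control_ligand,control_inhibitor Labels of the control
#'   condition (defaults `"BSA"`, `"DMSO"`).
#' @return `tab` with an added `log2fc` column.
#' @export
log2_fc_vs_control <- function(tab, control_ligand = "BSA",
                               control_inhibitor = "DMSO") {
  grp <- interaction(tab$cell_line, tab$analyte, drop = TRUE)
  tab$log2fc <- NA_real_
  for (g in levels(grp)) {
    i <- which(grp == g)
    ctrl <- tab$value[i][tab$ligand[i] == control_ligand &
                           tab$inhibitor[i] == control_inhibitor]
    if (!length(ctrl)) {
      stop("no control replicates (", control_ligand, " + ",
           control_inhibitor, ") for ", g)
    }
    cm <- mean(ctrl)
    if (!is.finite(cm) || cm <= 0) stop("control mean <= 0 for ", g)
    tab$log2fc[i] <- log2(tab$value[i]) - log2(cm)
  }
  tab
}

.screen_cells <- function(tab, cell_line, ligand, analyte, inhibitor,
                          control_ligand, control_inhibitor) {
  s <- tab[tab$cell_line == cell_line & tab$analyte == analyte &
             tab$ligand %in% c(ligand, control_ligand) &
             tab$inhibitor %in% c(inhibitor, control_inhibitor), , drop = FALSE]
  s$stim <- factor(ifelse(s$ligand == ligand, "GF", "CTRL"),
                   levels = c("CTRL", "GF"))
  s$inhib <- factor(ifelse(s$inhibitor == inhibitor, "INHIB", "DMSO"),
                    levels = c("DMSO", "INHIB"))
  s
}

#' Interaction fold change of a 2x2 screen cell
#'
#' The difference-of-differences on mean log2 fold changes:
#' `(mu[GF+inhib] - mu[GF+solvent]) - (mu[ctrl+inhib] - mu[ctrl+solvent])`.
#' It vanishes identically under additive effects.
#'
#' @param tab Screen table with a `log2fc` column
#'   (see [log2_fc_vs_control()]).
#' @param cell_line,ligand Cell line and stimulating ligand of interest.
#' @param analyte Readout analyte (default `"pAKT"`).
#' @param inhibitor Inhibitor label (default `"AZD"`).
#' @param control_ligand,control_inhibitor Control labels.
#' @return Numeric interaction fold change.
#' @export
interaction_fc <- function(tab, cell_line, ligand, analyte = "pAKT",
                           inhibitor = "AZD", control_ligand = "BSA",
                           control_inhibitor = "DMSO") {
  stopifnot("log2fc" %in% names(tab))
  s <- .screen_cells(tab, cell_line, ligand, analyte, inhibitor,
                     control_ligand, control_inhibitor)
  mu <- tapply(s$log2fc, list(s$stim, s$inhib), mean)
  empty <- which(is.na(mu), arr.ind = TRUE)
  if (nrow(empty)) {
    stop("empty screen cell(s): ",
         paste(apply(empty, 1L, function(i) {
           paste(rownames(mu)[i[1L]], colnames(mu)[i[2L]], sep = "+")
         }), collapse = ", "))
  }
  unname((mu["GF", "INHIB"] - mu["GF", "DMSO"]) -
           (mu["CTRL", "INHIB"] - mu["CTRL", "DMSO"]))
}

#' Synergy call from a two-way ANOVA with interaction
#'
#' Fits `log2fc ~ stim * inhib` over the 2x2 replicate cell and tests
#' the interaction term (partial sums of squares; on balanced data this
#' coincides with every classical SS type). Synergy requires all three
#' criteria: (i) interaction p <= `alpha` (inclusive), (ii) positive
#' interaction fold change, (iii) receptor dependency - the ligand's
#' interaction fold change exceeds that of the reference stimulus
#' (`dependency_reference`, default the solvent control, whose
#' interaction fold change is structurally 0).
#'
#' @inheritParams interaction_fc
#' @param alpha Significance level (default 0.05, inclusive).
#' @param dependency_reference Ligand whose interaction fold change is
#'   the dependency baseline (default `control_ligand`).
#' @return List: `p`, `interaction_fc`, `is_synergistic`, and the three
#'   `criteria` flags.
#' @export
synergy_call <- function(tab, cell_line, ligand, analyte = "pAKT",
                         inhibitor = "AZD", control_ligand = "BSA",
                         control_inhibitor = "DMSO", alpha = 0.05,
                         dependency_reference = control_ligand) {
  s <- .screen_cells(tab, cell_line, ligand, analyte, inhibitor,
                     control_ligand, control_inhibitor)
  counts <- table(s$stim, s$inhib)
  if (any(counts == 0L)) {
    stop("empty screen cell(s): ",
         paste(outer(rownames(counts), colnames(counts), paste, sep = "+")[counts == 0L],
               collapse = ", "))
  }
  fit <- stats::lm(log2fc ~ stim * inhib, data = s)
  an <- stats::anova(fit)
  p_int <- an["stim:inhib", "Pr(>F)"]
  ifc <- interaction_fc(tab, cell_line, ligand, analyte, inhibitor,
                        control_ligand, control_inhibitor)
  ifc_ref <- if (identical(dependency_reference, control_ligand)) 0 else
    interaction_fc(tab, cell_line, dependency_reference, analyte, inhibitor,
                   control_ligand, control_inhibitor)
  criteria <- c(significance = p_int <= alpha,
                synergy = ifc > 0,
                receptor_dependency = ifc > ifc_ref)
  list(p = p_int, interaction_fc = ifc,
       is_synergistic = all(criteria), criteria = criteria)
}

#' Synergy calls for every (cell line, ligand) pair in a screen
#'
#' Applies outlier removal, fold-change computation and [synergy_call()]
#' across the whole table.
#'
#' @param tab Raw long-format screen table.
#' @param analyte Readout analyte tested for synergy (default `"pAKT"`).
#' @param z_threshold Outlier threshold; see [remove_outliers()].
#' @param ... Passed to [synergy_call()].
#' @inheritParams synergy_call
#' @return Data frame, one row per (cell line, ligand).
#' @export
screen_synergy <- function(tab, analyte = "pAKT", z_threshold = 3,
                           control_ligand = "BSA", control_inhibitor = "DMSO",
                           ...) {
  tab <- remove_outliers(tab, z_threshold = z_threshold)
  fc <- log2_fc_vs_control(tab, control_ligand = control_ligand,
                           control_inhibitor = control_inhibitor)
  combos <- unique(fc[fc$ligand != control_ligand, c("cell_line", "ligand")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cl <- combos$cell_line[[i]]
    lg <- combos$ligand[[i]]
    res <- synergy_call(fc, cl, lg, analyte = analyte,
                        control_ligand = control_ligand,
                        control_inhibitor = control_inhibitor, ...)
    data.frame(cell_line = cl, ligand = lg, p = res$p,
               interaction_fc = res$interaction_fc,
               is_synergistic = res$is_synergistic, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
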