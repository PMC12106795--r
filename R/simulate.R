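#' Simulation configuration for multichannel report generation
#'
#' Collects the generative model parameters behind
#' [simulate_channel_report()]. The defaults emulate the study
#' conditions of a 2x2 (MEK inhibitor x growth-factor mix) design with
#' three biological replicates: a constant heavy spike-in per precursor
#' with small multiplicative noise, log-normal endogenous light
#' intensities with treatment effects in log10 units, an additive
#' background floor in the 500-1000 intensity range (the reason the
#' light > 900 / heavy > 1000 thresholds exist), logistic
#' intensity-dependent detection (missingness not at random), a fraction
#' of features failing site localisation, truly-absent negative-control
#' features, and decoy-channel rows.
#'
#' @param n_features Number of simulated precursors.
#' @param n_rep Replicates per condition (2x2 design).
#' @param cell_line Cell-line label written into run names.
#' @param heavy_log10_mean,heavy_log10_sd Law of the per-feature heavy
#'   spike intensity (log10).
#' @param heavy_noise_sd Run-level multiplicative noise of the heavy
#'   channel (log10 units).
#' @param light_log10_mean,light_log10_sd Law of the per-feature light
#'   base intensity (log10).
#' @param frac_gf,frac_meki,frac_interaction Fractions of features
#'   carrying a growth-factor main effect, a MEKi main effect, or a pure
#'   interaction (synergy) effect; must sum to <= 1 with `frac_absent`.
#' @param effect_size Effect magnitude in log10 units (default 0.3); the
#'   MEKi main effect is applied with negative sign (inhibition).
#' @param noise_sd Run-level light-channel noise, log10 units
#'   (default 0.05).
#' @param background Additive background floor b (intensity units,
#'   default 600); observed light adds Uniform(0.5 b, 1.5 b).
#' @param frac_absent Fraction of truly-absent negative-control features
#'   (background only).
#' @param frac_locfail Fraction of features failing site localisation.
#' @param decoy_rate Fraction of features that also emit decoy-channel
#'   rows.
#' @param detect_slope,detect_mid Logistic detection model: the
#'   probability that a channel identification passes q < 0.05 is
#'   `plogis(detect_slope * (log10(1 + signal/background) - detect_mid))`.
#' @param present_slope,present_mid Same link for whether a light-channel
#'   row is present in the report at all.
#' @param heavy_present_prob Probability a heavy-channel row is present
#'   in a run (spike-ins are abundant; default 0.98).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_features = 300L, n_rep = 3L, cell_line = "HCT116",
                       heavy_log10_mean = 4.5, heavy_log10_sd = 0.5,
                       heavy_noise_sd = 0.05,
                       light_log10_mean = 3.8, light_log10_sd = 0.6,
                       frac_gf = 0.1, frac_meki = 0.1,
                       frac_interaction = 0.1, effect_size = 0.3,
                       noise_sd = 0.05, background = 600,
                       frac_absent = 0.05, frac_locfail = 0.1,
                       decoy_rate = 0.05,
                       detect_slope = 4, detect_mid = 0.8,
                       present_slope = 3, present_mid = 0.1,
                       heavy_present_prob = 0.98) {
  cfg <- as.list(environment())
  fr <- c(frac_gf, frac_meki, frac_interaction, frac_absent)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("effect/absence fractions must lie in [0,1] and sum to <= 1")
  }
  if (background < 0) stop("background must be >= 0")
  if (n_features < 1L || n_rep < 1L) stop("infeasible config: need >= 1 feature and replicate")
  class(cfg) <- "sim_config"
  cfg
}

.aa <- c("A", "D", "E", "F", "G", "I", "L", "N", "P", "Q", "V", "W", "Y",
         "S", "T", "M", "H")

.random_peptides <- function(n) {
  len <- sample(8:16, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    body <- paste(sample(.aa, len[[i]], replace = TRUE), collapse = "")
    paste0(body, sample(c("K", "R"), 1L))
  }, character(1L))
}

.phospho_annotate <- function(stripped) {
  vapply(stripped, function(s) {
    chars <- strsplit(s, "")[[1L]]
    cand <- which(chars %in% c("S", "T", "Y"))
    pos <- if (length(cand)) sample(rep(cand, 2L), 1L) else 1L
    paste0(substr(s, 1L, pos), "(UniMod:21)",
           substr(s, pos + 1L, nchar(s)))
  }, character(1L), USE.NAMES = FALSE)
}

# log10 signal-to-background; a zero background means signal is always
# clean (infinite SNR) and zero signal is never detectable
.signal_to_noise <- function(S, background) {
  if (background > 0) log10(1 + S / background) else ifelse(S > 0, Inf, 0)
}

.sim_q <- function(p_pass) {
  pass <- stats::runif(length(p_pass)) < p_pass
  ifelse(pass, stats::runif(length(p_pass), 0, 0.05),
         stats::runif(length(p_pass), 0.05, 1))
}

#' Simulate a multichannel DIA precursor report with known ground truth
#'
#' Generates a DIA-NN-style long report (one row per run x precursor x
#' channel) for a 2x2 x replicate treatment design, together with the
#' study design and a truth table. See [sim_config()] for the generative
#' model. The output is deterministic under a fixed seed.
#'
#' @param config A `sim_config`.
#' @param seed Integer RNG seed.
#' @return List with `report` (raw data frame using the default report
#'   column names), `records` (validated `precursor_report`), `design`
#'   (a `study_design`), `truth` (per-feature truth table) and `seed`.
#' @export
simulate_channel_report <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config

  design <- expand.grid(replicate = seq_len(cfg$n_rep), gf = 0:1, meki = 0:1)
  design <- design[c("meki", "gf", "replicate")]
  design$cell_line <- cfg$cell_line
  design$run <- sprintf("%s_MEKi%d_GF%d_R%d", cfg$cell_line, design$meki,
                        design$gf, design$replicate)
  design <- as_study_design(design)
  n_run <- nrow(design)
  nf <- cfg$n_features

  ids <- sprintf("P%04d", seq_len(nf))
  stripped <- .random_peptides(nf)
  modseq <- .phospho_annotate(stripped)
  charge <- sample(2:3, nf, replace = TRUE)
  precursor_id <- paste0(modseq, "_", charge)

  classes <- sample(rep(c("gf", "meki", "interaction", "absent", "null"),
                        times = c(round(cfg$frac_gf * nf),
                                  round(cfg$frac_meki * nf),
                                  round(cfg$frac_interaction * nf),
                                  round(cfg$frac_absent * nf),
                                  nf))[seq_len(nf)])
  gf_eff <- ifelse(classes == "gf", cfg$effect_size, 0)
  meki_eff <- ifelse(classes == "meki", -cfg$effect_size, 0)
  int_eff <- ifelse(classes == "interaction", cfg$effect_size, 0)
  absent <- classes == "absent"
  locfail <- stats::runif(nf) < cfg$frac_locfail
  has_decoy <- stats::runif(nf) < cfg$decoy_rate

  heavy_l10 <- stats::rnorm(nf, cfg$heavy_log10_mean, cfg$heavy_log10_sd)
  light_l10 <- stats::rnorm(nf, cfg$light_log10_mean, cfg$light_log10_sd)

  truth <- data.frame(precursor_id = precursor_id, feature = ids,
                      modified_sequence = modseq,
                      stripped_sequence = stripped, charge = charge,
                      class = classes, gf_effect = gf_eff,
                      meki_effect = meki_eff, interaction_effect = int_eff,
                      absent = absent, locfail = locfail,
                      heavy_log10 = heavy_l10, light_base_log10 = light_l10,
                      row.names = NULL)

  # expand features x runs
  fi <- rep(seq_len(nf), each = n_run)
  ri <- rep(seq_len(n_run), times = nf)
  meki <- design$meki[ri]
  gf <- design$gf[ri]

  mu <- light_l10[fi] + gf_eff[fi] * gf + meki_eff[fi] * meki +
    int_eff[fi] * (meki * gf)
  S <- ifelse(absent[fi], 0, 10^(mu + stats::rnorm(length(fi), 0, cfg$noise_sd)))
  b_draw <- stats::runif(length(fi), 0.5 * cfg$background, 1.5 * cfg$background)
  L_obs <- S + b_draw
  H_obs <- 10^(heavy_l10[fi] + stats::rnorm(length(fi), 0, cfg$heavy_noise_sd))

  snr <- .signal_to_noise(S, cfg$background)
  p_q <- stats::plogis(cfg$detect_slope * (snr - cfg$detect_mid))
  light_q <- .sim_q(p_q)
  heavy_q <- .sim_q(rep(0.97, length(fi)))
  light_present <- stats::runif(length(fi)) <
    stats::plogis(cfg$present_slope * (snr - cfg$present_mid))
  heavy_present <- stats::runif(length(fi)) < cfg$heavy_present_prob

  site_conf <- ifelse(locfail[fi], stats::runif(length(fi), 0, 0.5),
                      stats::runif(length(fi), 0.5, 1))
  ptm_q <- ifelse(locfail[fi], stats::runif(length(fi), 0.05, 0.6),
                  stats::runif(length(fi), 0, 0.05))

  base_row <- function(channel, channel_q, present, ms1) {
    data.frame(
      Run = design$run[ri][present],
      Precursor.Id = precursor_id[fi][present],
      Modified.Sequence = modseq[fi][present],
      Stripped.Sequence = stripped[fi][present],
      Precursor.Charge = charge[fi][present],
      Q.Value = pmin(1, channel_q[present] * stats::runif(sum(present), 0.8, 1.2)),
      Channel = channel,
      Channel.Q.Value = channel_q[present],
      PTM.Q.Value = ptm_q[present],
      PTM.Site.Confidence = site_conf[present],
      Channel.L = L_obs[present],
      Channel.H = H_obs[present],
      Ms1.Area = ms1[present],
      Protein.Group = paste0("PROT_", truth$feature[fi][present]),
      Genes = paste0("GENE_", truth$feature[fi][present]),
      stringsAsFactors = FALSE
    )
  }
  report <- rbind(
    base_row("H", heavy_q, heavy_present, rep(NA_real_, length(fi))),
    base_row("L", light_q, light_present, L_obs)
  )

  dec <- has_decoy[fi] & stats::runif(length(fi)) < 0.6
  if (any(dec)) {
    decoy <- data.frame(
      Run = design$run[ri][dec],
      Precursor.Id = precursor_id[fi][dec],
      Modified.Sequence = modseq[fi][dec],
      Stripped.Sequence = stripped[fi][dec],
      Precursor.Charge = charge[fi][dec],
      Q.Value = stats::runif(sum(dec), 0.01, 1),
      Channel = "decoy",
      Channel.Q.Value = stats::runif(sum(dec), 0.01, 1),
      PTM.Q.Value = ptm_q[dec],
      PTM.Site.Confidence = site_conf[dec],
      Channel.L = stats::runif(sum(dec), 0, 2 * cfg$background),
      Channel.H = stats::runif(sum(dec), 0, 2 * cfg$background),
      Ms1.Area = NA_real_,
      Protein.Group = paste0("PROT_", truth$feature[fi][dec]),
      Genes = paste0("GENE_", truth$feature[fi][dec]),
      stringsAsFactors = FALSE
    )
    report <- rbind(report, decoy)
  }
  report <- report[order(report$Run, report$Precursor.Id, report$Channel), ]
  rownames(report) <- NULL

  list(report = report,
       records = parse_precursor_report(report, source = "simulation"),
       design = design, truth = truth, seed = seed)
}

#' Simulate a spike-in dilution series with known expected ratios
#'
#' The heavy channel is a constant per-feature spike (the detection
#' anchor); the light channel carries the feature's base intensity
#' diluted by `1/f` per sample plus the additive background. Expected
#' log2 ratio relative to the undiluted sample is `-log2(f)`; additive
#' background produces ratio compression for low-intensity features at
#' high dilutions.
#'
#' @param n_features Number of precursors (default 2000).
#' @param factors Dilution factors (default `c(1, 3, 7, 15, 63, 255)`).
#' @param n_rep Technical replicates per dilution (default 3).
#' @param config A `sim_config`; intensity laws, noise, background and
#'   detection parameters are reused.
#' @param seed Integer RNG seed.
#' @return List with `records`, `report`, `dilution_design` (run, factor,
#'   replicate), `truth` (per-feature base intensity and expected ratios)
#'   and `seed`.
#' @export
simulate_dilution_series <- function(n_features = 2000L,
                                     factors = c(1, 3, 7, 15, 63, 255),
                                     n_rep = 3L,
                                     config = sim_config(), seed = 1L) {
  stopifnot(all(factors >= 1))
  set.seed(seed)
  cfg <- config
  dd <- expand.grid(replicate = seq_len(n_rep), f = factors)
  dd$run <- sprintf("dil%g_R%d", dd$f, dd$replicate)
  n_run <- nrow(dd)
  nf <- n_features

  stripped <- .random_peptides(nf)
  modseq <- .phospho_annotate(stripped)
  charge <- sample(2:3, nf, replace = TRUE)
  precursor_id <- paste0(modseq, "_", charge)
  heavy_l10 <- stats::rnorm(nf, cfg$heavy_log10_mean, cfg$heavy_log10_sd)
  light_l10 <- stats::rnorm(nf, cfg$light_log10_mean, cfg$light_log10_sd)

  fi <- rep(seq_len(nf), each = n_run)
  ri <- rep(seq_len(n_run), times = nf)
  f <- dd$f[ri]

  S <- 10^(light_l10[fi] + stats::rnorm(length(fi), 0, cfg$noise_sd)) / f
  b_draw <- stats::runif(length(fi), 0.5 * cfg$background, 1.5 * cfg$background)
  L_obs <- S + b_draw
  H_obs <- 10^(heavy_l10[fi] + stats::rnorm(length(fi), 0, cfg$heavy_noise_sd))

  snr <- .signal_to_noise(S, cfg$background)
  light_q <- .sim_q(stats::plogis(cfg$detect_slope * (snr - cfg$detect_mid)))
  heavy_q <- .sim_q(rep(0.97, length(fi)))
  light_present <- stats::runif(length(fi)) <
    stats::plogis(cfg$present_slope * (snr - cfg$present_mid))
  heavy_present <- stats::runif(length(fi)) < cfg$heavy_present_prob
  site_conf <- stats::runif(length(fi), 0.5, 1)
  ptm_q <- stats::runif(length(fi), 0, 0.05)

  mk <- function(channel, q, present, ms1) {
    data.frame(Run = dd$run[ri][present],
               Precursor.Id = precursor_id[fi][present],
               Modified.Sequence = modseq[fi][present],
               Stripped.Sequence = stripped[fi][present],
               Precursor.Charge = charge[fi][present],
               Q.Value = q[present],
               Channel = channel,
               Channel.Q.Value = q[present],
               PTM.Q.Value = ptm_q[present],
               PTM.Site.Confidence = site_conf[present],
               Channel.L = L_obs[present],
               Channel.H = H_obs[present],
               Ms1.Area = ms1[present],
               Protein.Group = paste0("PROT", fi[present]),
               Genes = paste0("GENE", fi[present]),
               stringsAsFactors = FALSE)
  }
  report <- rbind(mk("H", heavy_q, heavy_present, rep(NA_real_, length(fi))),
                  mk("L", light_q, light_present, L_obs))
  report <- report[order(report$Run, report$Precursor.Id, report$Channel), ]
  rownames(report) <- NULL

  truth <- data.frame(precursor_id = precursor_id,
                      modified_sequence = modseq,
                      light_base_log10 = light_l10,
                      heavy_log10 = heavy_l10, row.names = NULL)
  list(records = parse_precursor_report(report, source = "dilution simulation"),
       report = report, dilution_design = dd, truth = truth, seed = seed)
}

#' Per-observation ratio table from a simulated dilution series
#'
#' For every feature and run with both channels present, computes the
#' light/heavy log2 ratio normalized to the feature's median at the
#' undiluted sample, so the expected value at dilution `f` is
#' `-log2(f)`. The reference intensity (for compression binning) is the
#' feature's median light intensity in the undiluted samples.
#'
#' @param sim Result of [simulate_dilution_series()].
#' @return Data frame with columns `sequence`, `run`, `dilution`,
#'   `ratio`, `ref_intensity`, suitable for [bin_ratio_summary()].
#' @export
dilution_ratio_observations <- function(sim) {
  rec <- sim$records
  lrows <- rec[rec$channel == "L" & !is.na(rec$intensity_L) &
                 !is.na(rec$intensity_H), , drop = FALSE]
  dd <- sim$dilution_design
  lrows$dilution <- dd$f[match(lrows$run, dd$run)]
  lrows$raw_ratio <- log2(lrows$intensity_L / lrows$intensity_H)

  undil <- lrows[lrows$dilution == 1, , drop = FALSE]
  ref_ratio <- tapply(undil$raw_ratio, undil$precursor_id, stats::median)
  ref_int <- tapply(undil$intensity_L, undil$precursor_id, stats::median)
  keep <- lrows$precursor_id %in% names(ref_ratio)
  lrows <- lrows[keep, , drop = FALSE]
  data.frame(sequence = lrows$modified_sequence,
             run = lrows$run,
             dilution = lrows$dilution,
             ratio = lrows$raw_ratio - ref_ratio[lrows$precursor_id],
             ref_intensity = ref_int[lrows$precursor_id],
             row.names = NULL)
}

#' Quantification coverage of rescue versus strict dual-channel filtering
#'
#' Counts, per dilution, the light-channel cells quantified under the
#' heavy anchor (rescue: light extracted whenever present) against those
#' additionally requiring strict light confidence (channel q < 0.05 in
#' the same runs). Rescue coverage is a superset by construction; the
#' gain grows with dilution as light identifications fall below the
#' strict threshold.
#'
#' @param sim Result of [simulate_dilution_series()].
#' @param channel_q_strict Strict light threshold (default 0.05).
#' @param min_heavy_runs Passed to [filter_heavy_anchors()].
#' @return Data frame per dilution: `n_spied`, `n_strict`, `gain`.
#' @export
coverage_by_dilution <- function(sim, channel_q_strict = 0.05,
                                 min_heavy_runs = NULL) {
  anchors <- filter_heavy_anchors(sim$records, min_heavy_runs = min_heavy_runs)
  anchored <- rescue_light(sim$records, anchors,
                           channel_q_strict = channel_q_strict)
  dd <- sim$dilution_design
  f_of_run <- dd$f[match(anchored$runs, dd$run)]
  quant <- !is.na(anchored$L) & !is.na(anchored$H)
  strict <- quant & !is.na(anchored$Lq) & anchored$Lq < channel_q_strict
  out <- data.frame(
    dilution = sort(unique(dd$f)),
    n_spied = as.integer(tapply(colSums(quant), f_of_run, sum)[as.character(sort(unique(dd$f)))]),
    n_strict = as.integer(tapply(colSums(strict), f_of_run, sum)[as.character(sort(unique(dd$f)))]),
    row.names = NULL
  )
  out$gain <- out$n_spied - out$n_strict
  out
}

#' Simulate a 2x2 synergy screen table
#'
#' Long-format readouts for one or more cell lines and stimulating
#' ligands against a solvent control, with replicate noise on the log2
#' scale and a configurable interaction (synergy) effect on `pAKT`.
#'
#' @param cell_lines Character vector of cell-line labels.
#' @param ligands Stimulating ligand labels (control `"BSA"` added
#'   automatically).
#' @param n_rep Replicates per condition (default 4).
#' @param gf_effect,inhib_effect Main effects (log2) of stimulation and
#'   inhibitor on `pAKT`.
#' @param interaction_effect Named numeric: synergy effect (log2) per
#'   `"<cell_line>:<ligand>"`; unnamed scalar applies everywhere.
#' @param noise_sd Replicate noise sd (log2 units, default 0.2).
#' @param base_log2 Baseline readout level (log2, default 10).
#' @param analytes Measured analytes (default `c("pAKT","pERK","pMEK")`);
#'   effects apply to `pAKT`, the others carry main effects only.
#' @param seed Integer RNG seed.
#' @return List with `table` (long data frame) and `truth` (per
#'   cell line x ligand interaction effect).
#' @export
simulate_screen_table <- function(cell_lines = "HCT116", ligands = "EGF",
                                  n_rep = 4L, gf_effect = 1,
                                  inhib_effect = -0.5,
                                  interaction_effect = 1,
                                  noise_sd = 0.2, base_log2 = 10,
                                  analytes = c("pAKT", "pERK", "pMEK"),
                                  seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(cell_line = cell_lines,
                      ligand = c("BSA", ligands),
                      inhibitor = c("DMSO", "AZD"),
                      replicate = seq_len(n_rep),
                      analyte = analytes,
                      stringsAsFactors = FALSE)
  key <- paste(grid$cell_line, grid$ligand, sep = ":")
  ie <- if (is.null(names(interaction_effect))) {
    rep(interaction_effect[[1L]], nrow(grid))
  } else {
    out <- interaction_effect[key]
    out[is.na(out)] <- 0
    unname(out)
  }
  stim <- as.integer(grid$ligand != "BSA")
  inhib <- as.integer(grid$inhibitor == "AZD")
  mu <- base_log2 + gf_effect * stim + inhib_effect * inhib +
    ifelse(grid$analyte == "pAKT", ie * stim * inhib, 0)
  grid$value <- 2^(mu + stats::rnorm(nrow(grid), 0, noise_sd))
  truth <- unique(data.frame(cell_line = grid$cell_line,
                             ligand = grid$ligand,
                             interaction_effect = ifelse(grid$ligand == "BSA", 0, ie),
                             row.names = NULL))
  list(table = grid, truth = truth, seed = seed)
}
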