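# Shared fixtures built in code.

make_design <- function(n_rep = 3L, cell_line = "X") {
  des <- expand.grid(replicate = seq_len(n_rep), gf = 0:1, meki = 0:1)
  des$cell_line <- cell_line
  des$run <- sprintf("%s_m%d_g%d_r%d", cell_line, des$meki, des$gf,
                     des$replicate)
  as_study_design(des)
}

# Minimal in-memory report builder: one row per (run, precursor, channel).
make_report_rows <- function(run, precursor_id, channel,
                             channel_q = 0.01, ptm_q = 0.01,
                             site_conf = 0.9, intensity_L = NA_real_,
                             intensity_H = NA_real_, ms1_area = NA_real_,
                             modified_sequence = paste0("AAS(UniMod:21)AK"),
                             global_q = channel_q) {
  data.frame(
    Run = run, Precursor.Id = precursor_id,
    Modified.Sequence = modified_sequence,
    Stripped.Sequence = gsub("\\(UniMod:21\\)", "", modified_sequence),
    Precursor.Charge = 2L, Q.Value = global_q, Channel = channel,
    Channel.Q.Value = channel_q, PTM.Q.Value = ptm_q,
    PTM.Site.Confidence = site_conf, Channel.L = intensity_L,
    Channel.H = intensity_H, Ms1.Area = ms1_area,
    Protein.Group = "P1", Genes = "G1", stringsAsFactors = FALSE
  )
}

fixture_path <- function(f) {
  system.file("extdata", f, package = "spieddia", mustWork = TRUE)
}

read_fixture_expected <- function() {
  jsonlite::read_json(fixture_path("fixture_expected.json"),
                      simplifyVector = TRUE)
}

# quantification matrix with pure Gaussian noise around per-cell means
sim_gauss_matrix <- function(n_features, design, sd = 0.05, base = 5,
                             interaction_idx = integer(),
                             interaction_effect = 0.3) {
  mg <- design$meki * design$gf
  mu <- matrix(base, n_features, nrow(design))
  if (length(interaction_idx)) {
    mu[interaction_idx, ] <- base +
      interaction_effect * rep(mg, each = length(interaction_idx))
  }
  x <- matrix(stats::rnorm(length(mu), as.vector(mu), sd),
              n_features, nrow(design),
              dimnames = list(sprintf("f%05d", seq_len(n_features)),
                              design$run))
  x
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}
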