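fixture <- read_precursor_report(fixture_path("fixture_report.tsv"))
fixture_design <- read_study_design(fixture_path("fixture_design.tsv"))
expected <- read_fixture_expected()

test_that("heavy-anchor filter retains exactly the hand-derived set", {
  anchors <- filter_heavy_anchors(fixture)
  expect_equal(attr(anchors, "min_heavy_runs"), expected$min_heavy_runs)
  expect_setequal(anchors$precursor_id, expected$anchored_ids)
  counts <- attr(anchors, "all_counts")
  for (id in names(expected$heavy_pass_counts)) {
    expect_equal(unname(counts[id]), expected$heavy_pass_counts[[id]])
  }
})

test_that("boundary heavy intensity (exactly 1000) fails the strict filter", {
  anchors <- filter_heavy_anchors(fixture)
  counts <- attr(anchors, "all_counts")
  # this precursor has H = 1000 in one run and passes the other five
  expect_equal(unname(counts["GGGT(UniMod:21)GGR_2"]), 5L)
})

test_that("anchor filter degenerate inputs error or return empty", {
  expect_error(filter_heavy_anchors(fixture[0, ]), "empty")
  expect_error(filter_heavy_anchors(fixture, min_heavy_runs = 99), "exceeds")
  decoys <- fixture
  decoys$channel <- "decoy"
  expect_equal(nrow(filter_heavy_anchors(decoys, min_heavy_runs = 1)), 0L)
})

test_that("rescue extracts light intensity regardless of confidence and flags provenance", {
  raw <- rbind(
    make_report_rows("r1", "p1", "H", intensity_H = 5000, intensity_L = 100),
    make_report_rows("r2", "p1", "H", intensity_H = 5000, intensity_L = 120),
    make_report_rows("r3", "p1", "H", intensity_H = 5000),
    make_report_rows("r1", "p1", "L", channel_q = 0.30, intensity_L = 100,
                     intensity_H = 5000),
    make_report_rows("r2", "p1", "L", channel_q = 0.01, intensity_L = 120,
                     intensity_H = 5000)
  )
  rec <- parse_precursor_report(raw)
  anchors <- filter_heavy_anchors(rec, min_heavy_runs = 3)
  anchored <- rescue_light(rec, anchors)
  expect_equal(anchored$flags["p1", "r1"], "rescued")
  expect_equal(anchored$flags["p1", "r2"], "detected")
  expect_equal(anchored$flags["p1", "r3"], "absent")
  expect_equal(anchored$L["p1", "r1"], 100)
  expect_true(is.na(anchored$L["p1", "r3"]))
})

test_that("presence filter applies the condition and relaxed-confidence rules", {
  anchors <- filter_heavy_anchors(fixture)
  anchored <- rescue_light(fixture, anchors)
  pres <- presence_filter(anchored, fixture_design)
  expect_setequal(pres$retained_ids, expected$retained_ids)
  expect_setequal(pres$absence_calls, expected$absence_ids)
  expect_error(
    presence_filter(anchored, fixture_design, min_reps_per_condition = 4),
    "smallest per-condition replicate count")
})

test_that("rescaled quantities match independent log-identity arithmetic", {
  H <- c(8000, 10000, 12000)
  L <- c(500, 1000, 2000)
  raw <- do.call(rbind, lapply(1:3, function(i) rbind(
    make_report_rows(paste0("r", i), "p1", "H", intensity_H = H[i],
                     intensity_L = L[i]),
    make_report_rows(paste0("r", i), "p1", "L", intensity_H = H[i],
                     intensity_L = L[i])
  )))
  rec <- parse_precursor_report(raw)
  anchors <- filter_heavy_anchors(rec, min_heavy_runs = 3)
  sm <- compute_rescaled_matrix(rescue_light(rec, anchors))
  expect_equal(unname(sm$rescaling["p1"]), 10000)
  # independent route: y = log10(L) - log10(H) + log10(median(H))
  oracle <- log10(L) - log10(H) + log10(10000)
  expect_equal(unname(sm$values["p1", ]), oracle, tolerance = 1e-9)
  expect_equal(unname(sm$values["p1", "r2"]), 3.0, tolerance = 1e-9)
})

test_that("constant heavy spike reduces y to log10 of the light intensity", {
  raw <- do.call(rbind, lapply(1:3, function(i) rbind(
    make_report_rows(paste0("r", i), "p1", "H", intensity_H = 4000,
                     intensity_L = 10^i),
    make_report_rows(paste0("r", i), "p1", "L", intensity_H = 4000,
                     intensity_L = 10^i)
  )))
  rec <- parse_precursor_report(raw)
  anchors <- filter_heavy_anchors(rec, min_heavy_runs = 3)
  sm <- compute_rescaled_matrix(rescue_light(rec, anchors))
  expect_equal(unname(sm$values["p1", ]), 1:3, tolerance = 1e-12)
})

test_that("rescaled values are scale equivariant in light and invariant in heavy", {
  sim <- simulate_channel_report(sim_config(n_features = 60), seed = 21)
  base_q <- spied_quantify(sim$records, sim$design)
  scale_channel <- function(rec, cols, c) {
    for (col in cols) rec[[col]] <- rec[[col]] * c
    rec
  }
  for (c in c(2, 13.7)) {
    recL <- scale_channel(sim$records, "intensity_L", c)
    qL <- spied_quantify(recL, sim$design)
    common <- intersect(rownames(qL$matrix$values), rownames(base_q$matrix$values))
    dif <- qL$matrix$values[common, ] - base_q$matrix$values[common, ]
    expect_lt(max(abs(dif - log10(c)), na.rm = TRUE), 1e-10)

    recH <- scale_channel(sim$records, "intensity_H", c)
    qH <- spied_quantify(recH, sim$design)
    difH <- qH$matrix$values[common, ] - base_q$matrix$values[common, ]
    expect_lt(max(abs(difH), na.rm = TRUE), 1e-10)
  }
})

test_that("rescue coverage is a superset of strict dual-confidence coverage", {
  sim <- simulate_channel_report(sim_config(n_features = 150), seed = 22)
  anchors <- filter_heavy_anchors(sim$records)
  anchored <- rescue_light(sim$records, anchors)
  quant <- !is.na(anchored$L) & !is.na(anchored$H)
  strict <- quant & !is.na(anchored$Lq) & anchored$Lq < 0.05
  expect_true(all(quant >= strict))
  expect_gt(sum(quant), sum(strict))
})

test_that("truly-absent background-only features are never retained", {
  cfg <- sim_config(n_features = 200, frac_absent = 1, frac_gf = 0,
                    frac_meki = 0, frac_interaction = 0)
  sim <- simulate_channel_report(cfg, seed = 23)
  q <- spied_quantify(sim$records, sim$design)
  expect_equal(length(q$presence$retained_ids), 0L)
  expect_gt(length(q$absence_calls), 0L)
})
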