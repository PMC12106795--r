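des12 <- make_design(3)
fd12 <- build_design_and_contrasts(des12)

test_that("design matrix and contrast set have the forced 2x2 structure", {
  expect_equal(dim(fd12$design_matrix), c(12L, 4L))
  expect_equal(qr(fd12$design_matrix)$rank, 4L)
  expect_equal(fd12$contrast_rank, 3L)
  C <- fd12$contrasts
  expect_equal(C[, "Interaction"],
               C[, "GFmix_w_MEKi"] - C[, "GFmix_wo_MEKi"])
  expect_equal(C[, "Interaction"],
               C[, "MEKi_w_GFmix"] - C[, "MEKi_wo_GFmix"])
})

test_that("noiseless cell means give the algebraic interaction estimate", {
  mu <- c(MEKi0.GF0 = 0, MEKi0.GF1 = 1, MEKi1.GF0 = 0.5, MEKi1.GF1 = 2)
  cond <- design_condition(des12)
  x <- matrix(rep(mu[cond], each = 2), 2, 12, byrow = FALSE,
              dimnames = list(c("f1", "f2"), des12$run))
  x[2, ] <- x[2, ] + 1  # feature-level offset must not matter
  fits <- fit_feature_models(x, fd12)
  expect_equal(unname(fits$estimates[, "Interaction"]), c(0.5, 0.5))
  expect_equal(unname(fits$estimates["f1", "GFmix_wo_MEKi"]), 1)
  expect_true(all(fits$zero_variance))
})

test_that("residual df, missingness cap and rank guard behave as specified", {
  set.seed(51)
  x <- matrix(rnorm(36, 5, 0.1), 3, 12,
              dimnames = list(c("full", "six_missing", "cell_lost"), des12$run))
  x["six_missing", 1:6] <- NA
  # remove every MEKi1.GF1 run: observed design loses a cell
  x["cell_lost", des12$run[des12$meki == 1 & des12$gf == 1]] <- NA
  fits <- fit_feature_models(x, fd12, max_missing = 5)
  expect_equal(unname(fits$df["full"]), 8)
  expect_false("six_missing" %in% rownames(fits$estimates))
  expect_false("cell_lost" %in% rownames(fits$estimates))
  expect_setequal(fits$excluded$reason, c("missing", "rank"))
})

test_that("moderated t and F match an independent closed-form oracle", {
  des6 <- as_study_design(data.frame(
    run = paste0("r", 1:6), cell_line = "X",
    meki = c(0, 0, 0, 1, 1, 1), gf = c(0, 0, 1, 0, 1, 1),
    replicate = c(1, 2, 1, 1, 1, 2)))
  x <- rbind(f1 = c(5.0, 5.2, 5.8, 5.1, 6.5, 6.3),
             f2 = c(4.0, 4.1, 4.5, 4.2, 4.9, 5.2),
             f3 = c(7.0, 6.8, 7.4, 7.1, 7.9, 7.6))
  colnames(x) <- des6$run
  fd <- build_design_and_contrasts(des6)
  eb <- suppressWarnings(empirical_bayes(fit_feature_models(x, fd)))

  # ---- independent oracle: explicit closed-form computation ----
  cond <- design_condition(des6)
  cells <- c("MEKi0.GF0", "MEKi0.GF1", "MEKi1.GF0", "MEKi1.GF1")
  nc <- table(factor(cond, levels = cells))
  C <- cbind(GFmix_wo_MEKi = c(-1, 1, 0, 0), GFmix_w_MEKi = c(0, 0, -1, 1),
             MEKi_wo_GFmix = c(-1, 0, 1, 0), MEKi_w_GFmix = c(0, -1, 0, 1),
             Interaction = c(1, -1, -1, 1))
  d <- 6 - 4
  s2 <- apply(x, 1, function(y) {
    sum((y - ave(y, cond))^2) / d
  })
  est <- t(apply(x, 1, function(y) {
    drop(t(C) %*% tapply(y, factor(cond, levels = cells), mean))
  }))
  U <- t(C) %*% diag(1 / as.numeric(nc)) %*% C
  su <- sqrt(diag(U))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * stats::uniroot(function(z) trigamma(z) - evar,
                             c(1e-6, 1e8), tol = 1e-14)$root
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  s2p <- if (is.infinite(d0)) rep(s02, 3) else (d0 * s02 + d * s2) / (d0 + d)
  t_oracle <- est / outer(sqrt(s2p), su)
  p_oracle <- 2 * pt(-abs(t_oracle), d0 + d)
  sv <- svd(U)
  r <- sum(sv$d > sv$d[1] * 1e-9)
  Uplus <- sv$v[, 1:r] %*% diag(1 / sv$d[1:r], r) %*% t(sv$u[, 1:r])
  F_oracle <- apply(est, 1, function(b) drop(t(b) %*% Uplus %*% b)) / r / s2p
  pF_oracle <- pf(F_oracle, r, d0 + d, lower.tail = FALSE)
  # ---- end oracle ----

  expect_equal(unname(eb$t), unname(t_oracle), tolerance = 1e-8)
  expect_equal(unname(eb$p_t), unname(p_oracle), tolerance = 1e-8)
  expect_equal(unname(eb$F), unname(F_oracle), tolerance = 1e-8)
  expect_equal(unname(eb$p_F), unname(pF_oracle), tolerance = 1e-8)
})

test_that("prior-df limits reduce to ordinary and fixed-variance statistics", {
  set.seed(52)
  x <- sim_gauss_matrix(50, des12, sd = 0.2)
  fits <- fit_feature_models(x, fd12)
  eb0 <- empirical_bayes(fits, d0 = 0)
  ordinary_t <- fits$estimates / (fits$stdev_unscaled * sqrt(fits$sigma2))
  expect_equal(eb0$t, ordinary_t, tolerance = 1e-10)
  expect_equal(unname(eb0$df_total), unname(fits$df))

  ebI <- empirical_bayes(fits, d0 = Inf, s02 = 0.04)
  expect_true(all(ebI$s2_post == 0.04))
  fixed_t <- fits$estimates / (fits$stdev_unscaled * sqrt(0.04))
  expect_equal(ebI$t, fixed_t, tolerance = 1e-10)
})

test_that("equal residual variances take the infinite-prior branch safely", {
  cond <- design_condition(des12)
  mu <- c(MEKi0.GF0 = 0, MEKi0.GF1 = 1, MEKi1.GF0 = 2, MEKi1.GF1 = 3)
  base <- mu[cond] + rep(c(-0.1, 0, 0.1), times = 4)
  # same within-cell spread for every feature: identical s2 everywhere
  x <- rbind(a = base, b = base + 5, c = base * 1, d = base + 2)
  colnames(x) <- des12$run
  fits <- fit_feature_models(x, fd12)
  expect_true(max(abs(fits$sigma2 - fits$sigma2[1])) < 1e-12)
  eb <- suppressWarnings(empirical_bayes(fits))
  expect_identical(eb$d0, Inf)
  expect_equal(unname(eb$s2_post), rep(eb$s02, 4))
})

test_that("prior parameters are recovered from hierarchical variance draws", {
  d0_hat <- s02_hat <- numeric(20)
  for (s in seq_len(20)) {
    set.seed(s)
    sig2 <- 0.05 * 4 / rchisq(200, 4)
    s2 <- sig2 * rchisq(200, 8) / 8
    ff <- structure(list(
      sigma2 = s2, df = rep(8, 200),
      estimates = matrix(0, 200, 1, dimnames = list(NULL, "c")),
      stdev_unscaled = matrix(1, 200, 1), pattern = rep("p", 200),
      cov_unscaled = list(p = matrix(1)), contrast_rank = 1L,
      zero_variance = rep(FALSE, 200)), class = "feature_fits")
    eb <- empirical_bayes(ff)
    d0_hat[s] <- eb$d0
    s02_hat[s] <- eb$s02
  }
  expect_true(all(d0_hat >= 2 & d0_hat <= 8))
  expect_true(all(abs(s02_hat - 0.05) / 0.05 <= 0.3))
})

test_that("moderated F with a single contrast equals the squared moderated t", {
  set.seed(53)
  x <- sim_gauss_matrix(40, des12, sd = 0.1)
  fd1 <- fd12
  fd1$contrasts <- fd12$contrasts[, "Interaction", drop = FALSE]
  fd1$contrast_rank <- 1L
  eb <- empirical_bayes(fit_feature_models(x, fd1))
  expect_equal(unname(eb$F), unname(eb$t[, 1]^2), tolerance = 1e-10)
  expect_equal(unname(eb$p_F), unname(eb$p_t[, 1]), tolerance = 1e-10)
})

test_that("moderated statistics agree with limma on complete data", {
  set.seed(54)
  sds <- sqrt(0.04 * 5 / rchisq(150, 5))
  x <- matrix(rnorm(150 * 12, 5, rep(sds, 12)), 150, 12,
              dimnames = list(sprintf("f%03d", 1:150), des12$run))
  eb <- empirical_bayes(fit_feature_models(x, fd12))
  lfit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(x, fd12$design_matrix), fd12$contrasts))
  expect_equal(eb$d0, lfit$df.prior, tolerance = 1e-10)
  expect_equal(eb$s02, lfit$s2.prior, tolerance = 1e-10)
  expect_equal(unname(eb$t), unname(lfit$t), tolerance = 1e-10)
  expect_equal(unname(eb$F), unname(lfit$F), tolerance = 1e-10)
})

test_that("feature-level offsets cancel and run offsets shift all features equally", {
  set.seed(55)
  x <- sim_gauss_matrix(30, des12, sd = 0.1)
  fits <- fit_feature_models(x, fd12)
  # row constants: contrast coefficients sum to zero, estimates unchanged
  x_row <- x + rnorm(nrow(x))
  expect_equal(fit_feature_models(x_row, fd12)$estimates, fits$estimates,
               tolerance = 1e-12)
  # column constants: every feature's estimate shifts by the same amount
  off <- rnorm(12, 0, 0.3)
  x_col <- sweep(x, 2, off, "+")
  est2 <- fit_feature_models(x_col, fd12)$estimates
  shift <- est2 - fits$estimates
  expect_lt(max(abs(sweep(shift, 2, colMeans(shift), "-"))), 1e-10)
})

test_that("deleting a run from a feature equals fitting the reduced design", {
  set.seed(56)
  x <- sim_gauss_matrix(5, des12, sd = 0.1)
  drop_run <- des12$run[7]
  x_na <- x
  x_na[3, drop_run] <- NA
  fits_na <- fit_feature_models(x_na, fd12)
  des_red <- as_study_design(as.data.frame(des12)[des12$run != drop_run, ])
  fd_red <- build_design_and_contrasts(des_red)
  fits_red <- fit_feature_models(x[, des_red$run, drop = FALSE][3, , drop = FALSE],
                                 fd_red)
  expect_equal(unname(fits_na$estimates[3, ]), unname(fits_red$estimates[1, ]),
               tolerance = 1e-12)
  expect_equal(unname(fits_na$sigma2[3]), unname(fits_red$sigma2[1]),
               tolerance = 1e-12)
  expect_equal(unname(fits_na$df[3]), unname(fits_red$df[1]))
})

test_that("per-sequence aggregation keeps the lowest-F-p precursor with documented tie-breaks", {
  tab <- data.frame(
    precursor_id = c("b_2", "b_3", "c_2", "c_3", "solo_2"),
    modified_sequence = c("B", "B", "C", "C", "SOLO"),
    ave_expr = c(5, 6, 4, 7, 3),
    F.p = c(0.02, 0.2, 0.05, 0.05, 0.5))
  agg <- aggregate_per_sequence(tab)
  expect_equal(agg$precursor_id[agg$modified_sequence == "B"], "b_2")
  # exact tie: higher average intensity wins
  expect_equal(agg$precursor_id[agg$modified_sequence == "C"], "c_3")
  expect_true("solo_2" %in% agg$precursor_id)
  # full tie falls back to lexicographic id
  tie <- data.frame(precursor_id = c("z_3", "z_2"), modified_sequence = "Z",
                    ave_expr = c(1, 1), F.p = c(0.1, 0.1))
  expect_equal(aggregate_per_sequence(tie)$precursor_id, "z_2")
})

test_that("regulated selection uses a strict F-p cut-off", {
  tab <- data.frame(precursor_id = c("a", "b", "c"),
                    F.p = c(0.1, 0.0999, NA))
  expect_equal(select_regulated(tab)$precursor_id, "b")
  expect_equal(nrow(select_regulated(tab, f_p_max = 0.05)), 0L)
})

test_that("enrichment inputs carry signed log-p scores and split per site", {
  tab <- data.frame(
    precursor_id = c("p1", "p2", "p3"),
    modified_sequence = c("M1", "M2", "M3"),
    ave_expr = 5,
    logFC.Interaction = c(-0.5, 0.3, 0.1),
    p.Interaction = c(0.01, 0.001, 0.04),
    F.p = c(0.01, 0.05, 0.05))
  windows <- data.frame(
    precursor_id = c("p1", "p2", "p2"),  # p2 doubly phosphorylated, p3 missing
    site_window = c("AAAAAAASAAAAAAA", "BBBBBBBSBBBBBBB", "CCCCCCCTCCCCCCC"))
  expect_warning(rk <- export_enrichment_inputs(tab, windows, mode = "rank"),
                 "window")
  expect_equal(rk$Interaction$score[rk$Interaction$site_window == "AAAAAAASAAAAAAA"],
               -2)
  expect_equal(sum(rk$Interaction$site_window %in%
                     c("BBBBBBBSBBBBBBB", "CCCCCCCTCCCCCCC")), 2L)
  fg <- suppressWarnings(
    export_enrichment_inputs(tab, windows, mode = "foreground"))
  expect_setequal(unique(fg$Interaction$site_window),
                  c("AAAAAAASAAAAAAA", "BBBBBBBSBBBBBBB", "CCCCCCCTCCCCCCC"))
  # logFC exactly 0.1 is excluded from the foreground (strict >)
  tab2 <- tab
  tab2$logFC.Interaction[1] <- 0.1
  fg2 <- suppressWarnings(
    export_enrichment_inputs(tab2, windows, mode = "foreground"))
  expect_false("AAAAAAASAAAAAAA" %in% fg2$Interaction$site_window)
})
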