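test_that("GMT parsing handles sizes, duplicates and malformed lines", {
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c("KIN_A\tdesc\ts1\ts2\ts3",
               "KIN_B\tdesc\ts1\ts4\ts5\ts6\ts7"), tmp)
  sets <- read_gmt(tmp)
  expect_equal(lengths(sets)[c("KIN_A", "KIN_B")], c(KIN_A = 3L, KIN_B = 5L))

  writeLines(c("KIN_A\tdesc\ts1\ts1\ts2"), tmp)
  expect_equal(lengths(read_gmt(tmp))[["KIN_A"]], 2L)

  writeLines(c("KIN_A\tdesc\ts1", "KIN_EMPTY\tdesc"), tmp)
  expect_error(read_gmt(tmp), "line 2")
})

test_that("enrichment p equals the closed-form hypergeometric upper tail", {
  sigs <- structure(list(S = paste0("m", 1:25)), class = "signature_set")
  universe <- c(paste0("m", 1:25), paste0("u", 1:975))
  members <- c(paste0("m", 1:5), paste0("u", 1:15))
  res <- fisher_enrichment(members, universe, sigs)
  # brute-force enumeration over the hypergeometric support
  brute <- sum(vapply(5:20, function(x) {
    choose(25, x) * choose(975, 20 - x) / choose(1000, 20)
  }, numeric(1)))
  expect_equal(res$p, brute, tolerance = 1e-12)
  expect_equal(res$overlap, 5L)
})

test_that("enrichment p matches brute-force enumeration on exhaustive small tables", {
  worst <- 0
  for (N in c(5L, 9L, 14L, 20L, 24L)) {
    universe <- paste0("u", seq_len(N))
    for (K in 1:N) {
      sigs <- structure(list(S = universe[seq_len(K)]),
                        class = "signature_set")
      for (n in 1:N) {
        for (a in max(0, n + K - N):min(n, K)) {
          members <- c(universe[seq_len(a)],
                       if (n > a) universe[K + seq_len(n - a)])
          p <- fisher_enrichment(members, universe, sigs)$p
          brute <- sum(vapply(a:min(n, K), function(x) {
            choose(K, x) * choose(N - K, n - x) / choose(N, n)
          }, numeric(1)))
          worst <- max(worst, abs(p - brute))
        }
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("enrichment p matches brute force on random large tables", {
  set.seed(61)
  worst <- 0
  for (i in 1:50) {
    N <- sample(30:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    a_vals <- max(0, n + K - N):min(n, K)
    a <- a_vals[sample.int(length(a_vals), 1)]
    universe <- paste0("u", seq_len(N))
    sigs <- structure(list(S = universe[seq_len(K)]), class = "signature_set")
    members <- c(universe[seq_len(a)], if (n > a) universe[K + seq_len(n - a)])
    p <- fisher_enrichment(members, universe, sigs)$p
    brute <- sum(vapply(a:min(n, K), function(x) {
      exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
    }, numeric(1)))
    worst <- max(worst, abs(p - brute))
    # base-R Fisher test as an extra independent route
    ft <- stats::fisher.test(matrix(c(a, n - a, K - a, N - K - n + a), 2),
                             alternative = "greater")$p.value
    worst <- max(worst, abs(p - ft))
  }
  expect_lt(worst, 1e-10)
})

test_that("degenerate enrichment tables give p = 1", {
  universe <- paste0("u", 1:50)
  sigs <- structure(list(DISJOINT = paste0("x", 1:5),
                         INSIDE = universe[1:10]),
                    class = "signature_set")
  res <- fisher_enrichment(universe[1:10], universe, sigs)
  expect_equal(res$p[res$signature == "DISJOINT"], 1)
  res_all <- fisher_enrichment(universe, universe, sigs)
  expect_true(all(res_all$p == 1))
})

test_that("clustering separates synergy-shaped from flat profiles exactly", {
  des <- make_design(3)
  set.seed(62)
  mg <- des$meki * des$gf
  n_syn <- 20; n_flat <- 20
  x <- rbind(
    t(replicate(n_syn, 1.5 * mg + rnorm(12, 0, 0.08))),
    t(replicate(n_flat, 0.8 * des$gf + rnorm(12, 0, 0.08)))
  )
  dimnames(x) <- list(sprintf("f%02d", 1:(n_syn + n_flat)), des$run)
  cl <- cluster_significant(x, des, k = 2)
  truth <- rep(1:2, c(n_syn, n_flat))
  expect_equal(rand_index(unname(cl$membership[rownames(x)]), truth), 1.0)
  # the synergy-shaped cluster scores highest on the ideal profile
  scores <- synergy_profile_score(cl)
  syn_cluster <- unname(cl$membership[["f01"]])
  expect_equal(which.max(scores), syn_cluster)

  expect_equal(length(unique(cluster_significant(x, des, k = 1)$membership)), 1L)
  expect_error(cluster_significant(x, des, k = 1000), "exceeds")
  xz <- rbind(x, flatline = rep(3, 12))
  expect_warning(cluster_significant(xz, des, k = 2), "zero-variance")
})

test_that("row z-scores have mean zero and unit sd on observed cells", {
  des <- make_design(3)
  set.seed(63)
  x <- sim_gauss_matrix(30, des, sd = 0.3)
  x[sample(length(x), 30)] <- NA
  cl <- cluster_significant(x, des, k = 3)
  m <- apply(cl$zmat, 1, mean, na.rm = TRUE)
  s <- apply(cl$zmat, 1, sd, na.rm = TRUE)
  expect_lt(max(abs(m)), 1e-12)
  expect_lt(max(abs(s - 1)), 1e-12)
})

test_that("cluster memberships are invariant under row permutation", {
  des <- make_design(3)
  set.seed(64)
  mg <- des$meki * des$gf
  x <- rbind(t(replicate(10, mg + rnorm(12, 0, 0.1))),
             t(replicate(10, des$meki + rnorm(12, 0, 0.1))))
  dimnames(x) <- list(sprintf("f%02d", 1:20), des$run)
  cl1 <- cluster_significant(x, des, k = 2)
  set.seed(65)
  perm <- sample(nrow(x))
  cl2 <- cluster_significant(x[perm, ], des, k = 2)
  common <- rownames(x)
  expect_equal(rand_index(unname(cl1$membership[common]),
                          unname(cl2$membership[common])), 1.0)
})

test_that("site flanking windows are centered, uppercase and padded", {
  w <- site_flanking_window("MKLSSPTTTRVVVYK", 4)
  expect_equal(nchar(w), 15L)
  expect_equal(substr(w, 8, 8), "S")
  expect_equal(substr(w, 1, 4), "____")
  w2 <- site_flanking_window("aaaaaaaaSaaaaaaaa", 9)
  expect_equal(w2, "AAAAAAASAAAAAAA")
})
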