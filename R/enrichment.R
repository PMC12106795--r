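#' Read kinase signature sets from a GMT file
#'
#' GMT lines are `name <tab> description <tab> member...`. Duplicate
#' members within a set are deduplicated; sets with no members are
#' rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (signature members), class
#'   `signature_set`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3L) {
      stop("malformed GMT line ", i, ": need name, description and >= 1 member")
    }
    nm <- parts[[1L]]
    members <- unique(parts[-(1:2)])
    if (!length(members)) stop("empty signature at GMT line ", i)
    sets[[nm]] <- members
  }
  structure(sets, class = c("signature_set", class(sets)))
}

#' Hierarchically cluster regulated features into profile groups
#'
#' Rows are z-scored feature-wise over their observed cells (mean 0,
#' sd 1); features with zero variance are excluded with a warning, as are
#' features with any condition entirely missing. Agglomerative clustering
#' (default complete linkage, Euclidean distance on per-condition mean
#' profiles) is cut at `k` clusters. The study's heatmap cluster count is
#' chosen manually; `k` is a free parameter here.
#'
#' @param x Numeric features x runs matrix (regulated features).
#' @param design A `study_design` matching the columns of `x`.
#' @param k Number of clusters.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return Object of class `cluster_profiles`: list with `membership`
#'   (named integer vector), `profiles` (per cluster x condition mean and
#'   sd), `sizes`, `zmat` (z-scored matrix), and the `hclust` tree.
#' @export
cluster_significant <- function(x, design, k, linkage = "complete") {
  stopifnot(is.matrix(x))
  design <- as_study_design(as.data.frame(design))
  x <- x[, design$run, drop = FALSE]
  cond <- design_condition(design)

  sds <- apply(x, 1L, stats::sd, na.rm = TRUE)
  zero_var <- !is.na(sds) & sds == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance feature(s) excluded from clustering")
    x <- x[!zero_var, , drop = FALSE]
  }
  cond_means <- t(apply(x, 1L, function(z) {
    tapply(z, cond, mean, na.rm = TRUE)
  }))
  all_cond_present <- rowSums(is.na(cond_means)) == 0L
  if (any(!all_cond_present)) {
    x <- x[all_cond_present, , drop = FALSE]
    cond_means <- cond_means[all_cond_present, , drop = FALSE]
  }
  if (nrow(x) < k) stop("k (", k, ") exceeds usable feature count (", nrow(x), ")")

  zmat <- t(apply(x, 1L, function(z) {
    (z - mean(z, na.rm = TRUE)) / stats::sd(z, na.rm = TRUE)
  }))
  colnames(zmat) <- colnames(x)
  zcond <- t(apply(zmat, 1L, function(z) tapply(z, cond, mean, na.rm = TRUE)))

  hc <- stats::hclust(stats::dist(zcond, method = "euclidean"), method = linkage)
  membership <- stats::cutree(hc, k = k)
  names(membership) <- rownames(zcond)

  profs <- do.call(rbind, lapply(sort(unique(membership)), function(cl) {
    rows <- zcond[membership == cl, , drop = FALSE]
    data.frame(cluster = cl, condition = colnames(rows),
               mean = colMeans(rows, na.rm = TRUE),
               sd = apply(rows, 2L, stats::sd, na.rm = TRUE),
               size = nrow(rows), row.names = NULL)
  }))
  structure(list(membership = membership, profiles = profs,
                 sizes = table(membership), zmat = zmat,
                 cond_means = zcond, hclust = hc, k = k),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: %d features in %d clusters (sizes: %s)\n",
              length(x$membership), x$k,
              paste(as.integer(x$sizes), collapse = ", ")))
  invisible(x)
}

#' Score clusters against the ideal synergy profile
#'
#' Convenience helper (beyond the core procedure, where synergy-shaped
#' clusters are picked by eye): cosine similarity between each cluster's
#' centered condition-mean profile and the centered ideal interaction
#' pattern, in which only the combined-treatment condition responds.
#'
#' @param clusters A `cluster_profiles` object.
#' @param ideal Named numeric vector over conditions; default responds
#'   only in `MEKi1.GF1`.
#' @return Named numeric vector of cosine similarities per cluster.
#' @export
synergy_profile_score <- function(clusters,
                                  ideal = c(MEKi0.GF0 = 0, MEKi0.GF1 = 0,
                                            MEKi1.GF0 = 0, MEKi1.GF1 = 1)) {
  profs <- clusters$profiles
  conds <- sort(unique(profs$condition))
  stopifnot(all(conds %in% names(ideal)))
  iv <- ideal[conds] - mean(ideal[conds])
  vapply(sort(unique(profs$cluster)), function(cl) {
    m <- profs$mean[profs$cluster == cl][match(conds, profs$condition[profs$cluster == cl])]
    mv <- m - mean(m)
    sum(mv * iv) / sqrt(sum(mv^2) * sum(iv^2))
  }, numeric(1L))
}

#' Kinase-signature over-representation by Fisher's exact test
#'
#' For each signature, tests over-representation of its members in the
#' cluster against the quantified universe with the one-sided
#' hypergeometric upper tail (Fisher's exact test for enrichment).
#' Signatures disjoint from the universe are reported with p = 1 and
#' zero overlap.
#'
#' @param members Character vector: feature identifiers in the cluster.
#' @param universe Character vector: all quantified, signature-mappable
#'   identifiers (must contain `members`).
#' @param signatures A `signature_set` (named list of identifier sets).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"` (delegated to [stats::fisher.test()]).
#' @return Data frame per signature: overlap `a`, cluster size, signature
#'   size in universe, universe size, odds ratio, `p`, BH-adjusted `p.adj`,
#'   and comma-separated overlap members.
#' @export
fisher_enrichment <- function(members, universe, signatures,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  members <- unique(members)
  universe <- unique(universe)
  if (!all(members %in% universe)) {
    stop("cluster members must be contained in the universe")
  }
  N <- length(universe)
  n <- length(members)
  rows <- lapply(names(signatures), function(nm) {
    sig <- intersect(signatures[[nm]], universe)
    K <- length(sig)
    hit <- intersect(members, sig)
    a <- length(hit)
    if (K == 0L) {
      p <- 1
      or <- NA_real_
    } else if (alternative == "greater") {
      # hypergeometric upper tail P(X >= a)
      p <- stats::phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
      b <- n - a; cc <- K - a; dd <- N - K - n + a
      or <- (a * dd) / (b * cc)
    } else {
      tab <- matrix(c(a, n - a, K - a, N - K - n + a), 2L, 2L)
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      p <- ft$p.value
      or <- unname(ft$estimate)
    }
    data.frame(signature = nm, overlap = a, cluster_size = n,
               signature_size = K, universe_size = N,
               odds_ratio = or, p = p,
               members = paste(sort(hit), collapse = ","),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p.adj <- stats::p.adjust(out$p, "BH")
  out[order(out$p), ]
}

#' Build 14-residue phosphosite flanking windows
#'
#' Cross-resource site identifier: the amino-acid context centered on the
#' phosphosite, 7 residues on either side (15 characters including the
#' site itself), uppercase, padded with `_` where the protein is shorter
#' than the window.
#'
#' @param sequence Protein (or peptide) amino-acid sequence.
#' @param position 1-based phosphosite position within `sequence`.
#' @param flank Residues on each side (default 7).
#' @return Character flanking window.
#' @export
site_flanking_window <- function(sequence, position, flank = 7L) {
  stopifnot(length(sequence) == length(position))
  vapply(seq_along(sequence), function(i) {
    s <- toupper(sequence[[i]])
    chars <- strsplit(s, "")[[1L]]
    idx <- (position[[i]] - flank):(position[[i]] + flank)
    w <- ifelse(idx >= 1L & idx <= length(chars), chars[pmax(idx, 1L)], "_")
    paste(w, collapse = "")
  }, character(1L))
}
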