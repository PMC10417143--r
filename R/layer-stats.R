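#' Cluster a layer profile and score each cluster
#'
#' Partitions the defined layers, in z order, into `k` contiguous clusters of
#' near-equal size (the first `N mod k` clusters get one extra layer, so 200
#' layers give 20 clusters of 10). Each layer is dichotomized at `cutoff`
#' (1 when `r >= cutoff`) and the cluster score is the fraction of
#' dichotomized layers in the cluster, stored as an exact count/size pair.
#'
#' @param profile A `layer_profile` or any data frame with columns `layer`
#'   and `r` (and optionally `defined`; undefined layers are dropped).
#' @param k Number of clusters (default 20).
#' @param cutoff Dichotomization cutoff on `r` (default 0.05).
#' @return A tibble `cluster`, `n_layers`, `n_above`, `score`.
#' @export
cluster_layers <- function(profile, k = 20L, cutoff = 0.05) {
  stopifnot(is.data.frame(profile), "r" %in% names(profile))
  keep <- if ("defined" %in% names(profile)) profile$defined else !is.na(profile$r)
  r <- profile$r[keep]
  n <- length(r)
  k <- as.integer(k)
  if (n < k) {
    stop("profile has ", n, " defined layers but k = ", k, call. = FALSE)
  }
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  idx <- rep(seq_len(k), times = sizes)
  above <- as.integer(r >= cutoff)
  tibble::tibble(
    cluster = seq_len(k),
    n_layers = sizes,
    n_above = as.integer(tapply(above, idx, sum)),
    score = as.integer(tapply(above, idx, sum)) / sizes
  )
}

#' Pair two subjects' cluster scores for the permutation test
#'
#' @param clusters_a,clusters_b Tibbles from [cluster_layers()] with the same
#'   number of clusters.
#' @param cutoff The dichotomization cutoff the scores came from (metadata).
#' @return A `paired_cluster_series` tibble `cluster`, `m_a`, `n_a`, `m_b`,
#'   `n_b` holding each score as an exact rational count/size pair.
#' @export
paired_cluster_series <- function(clusters_a, clusters_b, cutoff = 0.05) {
  if (nrow(clusters_a) != nrow(clusters_b)) {
    stop("both subjects must have the same number of clusters", call. = FALSE)
  }
  stopifnot(all(clusters_a$n_above <= clusters_a$n_layers),
            all(clusters_b$n_above <= clusters_b$n_layers))
  out <- tibble::tibble(
    cluster = clusters_a$cluster,
    m_a = clusters_a$n_above, n_a = clusters_a$n_layers,
    m_b = clusters_b$n_above, n_b = clusters_b$n_layers
  )
  attr(out, "cutoff") <- cutoff
  class(out) <- c("paired_cluster_series", class(out))
  out
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a %/% gcd2(a, b) * b

# Exact integer representation of the paired score differences: each
# d_i = m_a/n_a - m_b/n_b is scaled by L = lcm of all cluster sizes, so
# tie detection is integer-exact.
scaled_diffs <- function(series) {
  L <- Reduce(lcm2, c(series$n_a, series$n_b))
  e <- L %/% series$n_a * series$m_a - L %/% series$n_b * series$m_b
  list(e = as.numeric(e), L = L)
}

#' Midpoint-tie permutation p-value
#'
#' Upper-tail p-value of an observed statistic ranked among all permutation
#' statistics sorted ascending, with the observed value's tie block assigned
#' the midpoint of its tied ranks:
#' `p = 1 - (rank_smallest + (tie_count - 1)/2) / total`.
#'
#' @param rank_smallest 1-based rank of the first element of the observed
#'   value's tie block.
#' @param tie_count Size of the tie block (>= 1, the observed value itself).
#' @param total Total number of permutation statistics.
#' @return The upper-tail p-value, in `[0, 1)`.
#' @export
midpoint_tie_pvalue <- function(rank_smallest, tie_count, total) {
  if (rank_smallest < 1 || rank_smallest > total) {
    stop("`rank_smallest` must lie in [1, total]", call. = FALSE)
  }
  if (tie_count < 1 || tie_count > total - rank_smallest + 1) {
    stop("`tie_count` must lie in [1, total - rank_smallest + 1]",
         call. = FALSE)
  }
  1 - (rank_smallest + (tie_count - 1) / 2) / total
}

perm_result <- function(statistic, rank_smallest, tie_count, total,
                        method, k, n_below, se = NA_real_) {
  p_upper <- midpoint_tie_pvalue(rank_smallest, tie_count, total)
  # lower tail under the same midrank convention, for the two-sided value
  rank_from_top <- total - n_below - tie_count + 1
  p_lower <- midpoint_tie_pvalue(rank_from_top, tie_count, total)
  structure(
    list(statistic = statistic, rank_smallest = rank_smallest,
         tie_count = tie_count, total = total,
         p_upper = p_upper, p_lower = p_lower,
         p_two_sided = min(1, 2 * min(p_upper, p_lower)),
         k = k, method = method, se = se),
    class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    paste0("Paired sign-flip permutation test (%s, K = %d)\n",
           "  mean score difference = %.4g\n",
           "  rank %s (ties %s) of %s reallocations\n",
           "  p (upper tail, midpoint ties) = %.6g\n",
           "  p (two-sided) = %.6g\n"),
    x$method, x$k, x$statistic,
    format(x$rank_smallest, big.mark = ","),
    format(x$tie_count, big.mark = ","),
    format(x$total, big.mark = ","),
    x$p_upper, x$p_two_sided))
  invisible(x)
}

#' Exact paired sign-flip permutation test
#'
#' Enumerates all `2^K` reallocations of the paired cluster observations
#' (sign flips of the score differences), computes the mean difference for
#' each, and ranks the observed mean difference among them. Differences are
#' scaled to integers by the least common multiple of the cluster sizes, so
#' tie detection is exact. The p-value uses the midpoint-tie convention of
#' [midpoint_tie_pvalue()]; a two-sided value (twice the smaller tail,
#' capped at 1) is reported alongside.
#'
#' @param series A `paired_cluster_series`.
#' @return A `perm_test` object: observed statistic (mean score difference),
#'   `rank_smallest`, `tie_count`, `total = 2^K`, `p_upper`, `p_lower`,
#'   `p_two_sided`.
#' @export
exact_paired_permutation <- function(series) {
  k <- nrow(series)
  if (k > 24L) {
    stop("K = ", k, " exceeds the exact enumeration bound (24); ",
         "use monte_carlo_permutation()", call. = FALSE)
  }
  sd_ <- scaled_diffs(series)
  v <- 0
  for (ei in sd_$e) v <- c(v - ei, v + ei)
  obs <- sum(sd_$e)
  n_below <- sum(v < obs)
  ties <- sum(v == obs)
  perm_result(statistic = obs / (sd_$L * k),
              rank_smallest = n_below + 1, tie_count = ties,
              total = 2^k, method = "exact", k = k, n_below = n_below)
}

#' Monte-Carlo paired sign-flip permutation test
#'
#' Approximates [exact_paired_permutation()] for large `K` by sampling
#' uniform random sign vectors. The observed statistic is pooled with the
#' draws and the same midpoint-tie convention is applied; a binomial
#' standard error for the upper-tail p is reported.
#'
#' @param series A `paired_cluster_series`.
#' @param n_draws Number of random sign vectors (>= 1000).
#' @param seed Integer seed.
#' @return A `perm_test` object with `method = "monte-carlo"` and `se`.
#' @export
monte_carlo_permutation <- function(series, n_draws = 100000L, seed = 1L) {
  if (n_draws < 1000L) stop("`n_draws` must be >= 1000", call. = FALSE)
  withr::local_seed(as.integer(seed))
  k <- nrow(series)
  sd_ <- scaled_diffs(series)
  signs <- matrix(sample(c(-1, 1), k * n_draws, replace = TRUE), nrow = k)
  v <- as.vector(crossprod(signs, sd_$e))
  obs <- sum(sd_$e)
  pool <- c(v, obs)
  n_below <- sum(pool < obs)
  ties <- sum(pool == obs)
  res <- perm_result(statistic = obs / (sd_$L * k),
                     rank_smallest = n_below + 1, tie_count = ties,
                     total = n_draws + 1L, method = "monte-carlo", k = k,
                     n_below = n_below)
  res$se <- sqrt(res$p_upper * (1 - res$p_upper) / n_draws)
  res
}

#' Compare two layer profiles with the permutation test
#'
#' End-to-end convenience: cluster both profiles, dichotomize at `cutoff`,
#' pair the cluster scores, and run the exact (or Monte-Carlo) paired
#' sign-flip permutation test.
#'
#' @param profile_a,profile_b Layer profiles (see [cluster_layers()]).
#' @param k Number of clusters.
#' @param cutoff Dichotomization cutoff.
#' @param method `"exact"` or `"monte-carlo"`.
#' @param n_draws,seed Monte-Carlo settings.
#' @return A `perm_test` object.
#' @export
compare_layer_profiles <- function(profile_a, profile_b, k = 20L,
                                   cutoff = 0.05,
                                   method = c("exact", "monte-carlo"),
                                   n_draws = 100000L, seed = 1L) {
  method <- match.arg(method)
  series <- paired_cluster_series(
    cluster_layers(profile_a, k = k, cutoff = cutoff),
    cluster_layers(profile_b, k = k, cutoff = cutoff),
    cutoff = cutoff)
  if (method == "exact") {
    exact_paired_permutation(series)
  } else {
    monte_carlo_permutation(series, n_draws = n_draws, seed = seed)
  }
}
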