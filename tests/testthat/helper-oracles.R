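# Independent brute-force oracles used to check the fast implementations.

# Naive sign-flip permutation test: enumerate every sign vector with
# expand.grid, sort the list of statistics, and read rank/ties off the
# sorted list. Scores are cleared to integers with a scalar gcd so tie
# detection is exact.
oracle_permutation <- function(m_a, n_a, m_b, n_b) {
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  L <- 1
  for (x in c(n_a, n_b)) L <- L * x / gcd(L, x)
  e <- L * m_a / n_a - L * m_b / n_b
  k <- length(e)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  sums <- as.vector(signs %*% e)
  obs <- sum(e)
  sorted <- sort(sums)
  rank_smallest <- match(obs, sorted)
  ties <- sum(sorted == obs)
  list(rank_smallest = rank_smallest, tie_count = ties,
       p = 1 - (rank_smallest + (ties - 1) / 2) / length(sums))
}

# Per-pixel 2-D median filter with edge replication, written as plainly as
# possible.
oracle_median_filter <- function(x, window) {
  half <- (window - 1) %/% 2
  out <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      ri <- pmin(pmax((i - half):(i + half), 1), nrow(x))
      ci <- pmin(pmax((j - half):(j + half), 1), ncol(x))
      out[i, j] <- median(as.vector(x[ri, ci]))
    }
  }
  out
}

# A layer profile with given per-layer r values (all defined).
profile_from_r <- function(r) {
  out <- tibble::tibble(layer = seq_along(r), marker_count = NA_real_,
                        membrane_count = 1, nuclei_count = NA_real_,
                        r = r, defined = TRUE)
  class(out) <- c("layer_profile", class(out))
  out
}

# A cluster-score table from explicit count/size pairs.
clusters_from_counts <- function(m, n) {
  tibble::tibble(cluster = seq_along(m), n_layers = as.integer(n),
                 n_above = as.integer(m), score = m / n)
}

random_series <- function(k, max_size = 12L) {
  n_a <- sample(1:max_size, k, replace = TRUE)
  n_b <- sample(1:max_size, k, replace = TRUE)
  paired_cluster_series(
    clusters_from_counts(vapply(n_a, function(n) sample(0:n, 1L), integer(1)), n_a),
    clusters_from_counts(vapply(n_b, function(n) sample(0:n, 1L), integer(1)), n_b))
}
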