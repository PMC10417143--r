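#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation test result
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return One-row tibble of the test's components.
#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, rank_smallest = x$rank_smallest,
    tie_count = x$tie_count, total = x$total,
    p_upper = x$p_upper, p_lower = x$p_lower,
    p_two_sided = x$p_two_sided, k = x$k, method = x$method, se = x$se)
}

#' @rdname tidy.perm_test
#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble::tibble(p_upper = x$p_upper, p_two_sided = x$p_two_sided,
                 k = x$k, total = x$total, method = x$method)
}

#' Tidy a cutoff scan
#'
#' @param x A `cutoff_scan`.
#' @param ... Unused.
#' @return The per-cutoff scan tibble.
#' @exportS3Method generics::tidy
tidy.cutoff_scan <- function(x, ...) x$scan

#' @rdname tidy.cutoff_scan
#' @exportS3Method generics::glance
glance.cutoff_scan <- function(x, ...) {
  s <- x$selected
  tibble::tibble(selected_cutoff = s$cutoff, j_max = s$j,
                 n_high = s$n_high, n_low = s$n_low,
                 estimate = s$estimate, se = s$se, p = s$p,
                 n_candidates = nrow(x$scan), outcome = x$outcome)
}

#' Tidy a Kaplan-Meier comparison
#'
#' @param x A `km_compare`.
#' @param ... Unused.
#' @return The per-group survival-curve tibble.
#' @exportS3Method generics::tidy
tidy.km_compare <- function(x, ...) x$curves

#' @rdname tidy.km_compare
#' @exportS3Method generics::glance
glance.km_compare <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p = x$p)
}
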