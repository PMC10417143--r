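#' Paired tumour/normal score comparison
#'
#' Summarises per-patient differences `tumor_score - normal_score` of ordinal
#' 0-3 immunohistochemistry intensities. Rows missing either side are
#' excluded and counted. Both a two-sided paired t-test and a Wilcoxon
#' signed-rank test are reported; when every pair has the same difference the
#' t statistic is undefined and the result carries `p = 1` with a
#' `zero_variance` flag rather than failing.
#'
#' @param table Data frame with columns `tumor_score`, `normal_score`
#'   (values 0-3 or `NA`).
#' @return One-row tibble: `n_paired`, `n_missing_tumor`, `n_missing_normal`,
#'   `mean_diff`, `sd_diff`, `p_t`, `p_wilcoxon`, `zero_variance`.
#' @export
paired_difference_summary <- function(table) {
  stopifnot(all(c("tumor_score", "normal_score") %in% names(table)))
  ok_t <- !is.na(table$tumor_score)
  ok_n <- !is.na(table$normal_score)
  d <- table$tumor_score[ok_t & ok_n] - table$normal_score[ok_t & ok_n]
  if (length(d) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  zero_var <- stats::sd(d) == 0
  if (zero_var) {
    p_t <- 1; p_w <- 1
  } else {
    p_t <- stats::t.test(d)$p.value
    p_w <- suppressWarnings(stats::wilcox.test(d))$p.value
  }
  tibble::tibble(
    n_paired = length(d),
    n_missing_tumor = sum(!ok_t), n_missing_normal = sum(!ok_n),
    mean_diff = mean(d), sd_diff = stats::sd(d),
    p_t = p_t, p_wilcoxon = p_w, zero_variance = zero_var)
}

#' Two-group score summary
#'
#' Mean and SD of tumour and normal score groups (unpaired) with two-sided
#' Student's t and Wilcoxon rank-sum p-values. Both tests are reported since
#' either may be the appropriate one for ordinal scores.
#'
#' @param tumor_scores,normal_scores Numeric vectors (each n >= 2).
#' @return One-row tibble with group means/SDs, `mean_difference`, `p_t`,
#'   `p_wilcoxon`, `zero_variance`.
#' @export
group_summary <- function(tumor_scores, normal_scores) {
  tumor_scores <- tumor_scores[!is.na(tumor_scores)]
  normal_scores <- normal_scores[!is.na(normal_scores)]
  if (length(tumor_scores) < 2L || length(normal_scores) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  pooled_var <- stats::var(tumor_scores) + stats::var(normal_scores)
  zero_var <- pooled_var == 0
  if (zero_var) {
    p_t <- 1; p_w <- 1
  } else {
    p_t <- stats::t.test(tumor_scores, normal_scores,
                         var.equal = TRUE)$p.value
    p_w <- suppressWarnings(
      stats::wilcox.test(tumor_scores, normal_scores))$p.value
  }
  tibble::tibble(
    n_tumor = length(tumor_scores), n_normal = length(normal_scores),
    mean_tumor = mean(tumor_scores), sd_tumor = stats::sd(tumor_scores),
    mean_normal = mean(normal_scores), sd_normal = stats::sd(normal_scores),
    mean_difference = mean(tumor_scores) - mean(normal_scores),
    p_t = p_t, p_wilcoxon = p_w, zero_variance = zero_var)
}

#' Concordant up/down gene filter
#'
#' Genes present in both contrasts with `log2fc > threshold` in the up
#' contrast and `log2fc < -threshold` in the down contrast (strict
#' inequalities by default; `strict = FALSE` uses `>=`/`<=`).
#'
#' @param up_table,down_table Data frames `gene`, `log2fc`.
#' @param threshold Log2 fold-change threshold (default 1).
#' @param strict Use strict inequalities (default `TRUE`).
#' @return Tibble `gene`, `log2fc_up`, `log2fc_down` of concordant genes,
#'   with the count in attribute `n_concordant`.
#' @export
select_concordant_genes <- function(up_table, down_table, threshold = 1,
                                    strict = TRUE) {
  stopifnot(nrow(up_table) > 0L, nrow(down_table) > 0L)
  joined <- dplyr::inner_join(
    dplyr::rename(up_table, log2fc_up = "log2fc"),
    dplyr::rename(down_table, log2fc_down = "log2fc"),
    by = "gene")
  keep <- if (strict) {
    joined$log2fc_up > threshold & joined$log2fc_down < -threshold
  } else {
    joined$log2fc_up >= threshold & joined$log2fc_down <= -threshold
  }
  out <- joined[keep, ]
  attr(out, "n_concordant") <- nrow(out)
  out
}
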