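#' Read a survival table from CSV
#'
#' Expects columns `expression,time,event,age,sex,smoking,alcohol`. Rows with
#' any missing value are dropped and the number removed is recorded in the
#' `n_dropped` attribute (cohort cleaning of the kind that takes a registry
#' from 185 enrolled down to the analysable subset).
#'
#' @param path CSV path with a header row.
#' @return A tibble with attribute `n_dropped`.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.csv(path)
  req <- c("expression", "time", "event", "age", "sex", "smoking", "alcohol")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(df[req])
  out <- tibble::as_tibble(df[keep, req])
  if (any(out$time <= 0)) stop("`time` must be positive", call. = FALSE)
  if (!all(out$event %in% c(0, 1))) stop("`event` must be 0/1", call. = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Youden's index of a binary classifier
#'
#' `J = sensitivity + specificity - 1`, with sensitivity the fraction of
#' positive outcomes classified high and specificity the fraction of negative
#' outcomes classified low.
#'
#' @param high Logical/0-1 classifier (e.g. expression above a cutoff).
#' @param outcome Logical/0-1 outcome (e.g. death observed).
#' @return A list: `j`, `sensitivity`, `specificity` and the 2x2 counts
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
youden_index <- function(high, outcome) {
  if (length(high) != length(outcome)) {
    stop("`high` and `outcome` must have equal length", call. = FALSE)
  }
  high <- as.logical(high); outcome <- as.logical(outcome)
  if (all(outcome) || !any(outcome)) {
    stop("`outcome` must contain both classes", call. = FALSE)
  }
  tp <- sum(high & outcome); fn <- sum(!high & outcome)
  fp <- sum(high & !outcome); tn <- sum(!high & !outcome)
  sens <- tp / (tp + fn); spec <- tn / (fp + tn)
  list(j = sens + spec - 1, sensitivity = sens, specificity = spec,
       tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Covariate-adjusted proportional-hazards fit for a dichotomized group
#'
#' Fits a Cox proportional-hazards model `Surv(time, event) ~ high +
#' covariates` by partial likelihood (Efron tie handling by default) and
#' returns the group coefficient.
#'
#' @param table Survival tibble (see [read_survival_table()]).
#' @param high Logical/0-1 group indicator, one per subject.
#' @param covariates Covariate column names to adjust for.
#' @param ties Tie method passed to [survival::coxph()].
#' @param min_group_size Minimum subjects per group carrying at least one
#'   event; smaller groups are refused.
#' @return One-row tibble `estimate` (log hazard ratio), `se`, `p`,
#'   `converged`, `ties`.
#' @export
fit_adjusted_ph <- function(table, high,
                            covariates = c("age", "sex", "smoking", "alcohol"),
                            ties = "efron", min_group_size = 2L) {
  high <- as.integer(as.logical(high))
  ev <- table$event
  if (min(sum(high == 1L & ev == 1L) > 0, sum(high == 0L & ev == 1L) > 0) < 1 ||
      min(sum(high), sum(1L - high)) < min_group_size) {
    stop("each group needs >= ", min_group_size,
         " subjects and at least one event", call. = FALSE)
  }
  dat <- cbind(table[c("time", "event", covariates)], .high = high)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ .high +",
    paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = ties),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(fml, data = dat, ties = ties))
    })
  if (is.null(fit)) {
    return(tibble::tibble(estimate = NA_real_, se = NA_real_, p = NA_real_,
                          converged = FALSE, ties = ties))
  }
  s <- summary(fit)$coefficients[".high", ]
  conv <- is.finite(s[["coef"]]) && is.finite(s[["se(coef)"]]) &&
    abs(s[["coef"]]) < 15
  tibble::tibble(estimate = s[["coef"]], se = s[["se(coef)"]],
                 p = s[["Pr(>|z|)"]], converged = conv, ties = ties)
}

#' Scan expression cutoffs for the maximum Youden's index
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' expression values. Cutoffs leaving either group below
#' `min_group_frac * n` subjects are inadmissible. For each admissible
#' cutoff, Youden's index is computed against the binary outcome (vital
#' status at last follow-up by default, or status at a fixed `horizon`) and,
#' depending on `fit`, a covariate-adjusted Cox fit supplies the group
#' p-value. The selected cutoff maximizes J; ties go to the smaller cutoff.
#' Non-converged fits are flagged and excluded from selection.
#'
#' @param table Survival tibble.
#' @param covariates Adjustment covariates for the Cox fits.
#' @param min_group_frac Minimum admissible group fraction (default 0.1).
#' @param fit `"all"` (Cox fit at every admissible cutoff), `"selected"`
#'   (only at the selected cutoff), or `"none"`.
#' @param outcome `"event"` uses vital status at last follow-up for J;
#'   `"horizon"` uses death by `horizon`, excluding subjects censored
#'   earlier (their status is unknown).
#' @param horizon Time horizon when `outcome = "horizon"`.
#' @return A `cutoff_scan` object: tibble `scan` (one row per admissible
#'   cutoff: `cutoff`, `n_high`, `n_low`, `j`, `sensitivity`, `specificity`,
#'   `estimate`, `se`, `p`, `converged`) plus `selected`, the max-J row.
#' @export
scan_cutoffs <- function(table,
                         covariates = c("age", "sex", "smoking", "alcohol"),
                         min_group_frac = 0.1,
                         fit = c("all", "selected", "none"),
                         outcome = c("event", "horizon"), horizon = NULL) {
  fit <- match.arg(fit)
  outcome <- match.arg(outcome)
  n <- nrow(table)
  if (n < 20L) stop("need at least 20 subjects", call. = FALSE)
  if (outcome == "horizon") {
    if (is.null(horizon)) stop("`horizon` is required", call. = FALSE)
    known <- table$event == 1L | table$time >= horizon
    otab <- table[known, ]
    out_bin <- otab$event == 1L & otab$time <= horizon
  } else {
    otab <- table
    out_bin <- table$event == 1L
  }
  u <- sort(unique(table$expression))
  if (length(u) < 2L) stop("no admissible cutoff: expression is constant",
                           call. = FALSE)
  cand <- (u[-length(u)] + u[-1]) / 2
  rows <- purrr::map(cand, function(cc) {
    hi_all <- table$expression > cc
    n_high <- sum(hi_all); n_low <- n - n_high
    if (min(n_high, n_low) < min_group_frac * n) return(NULL)
    yj <- youden_index(otab$expression > cc, out_bin)
    tibble::tibble(cutoff = cc, n_high = n_high, n_low = n_low,
                   j = yj$j, sensitivity = yj$sensitivity,
                   specificity = yj$specificity)
  })
  scan <- dplyr::bind_rows(rows)
  if (nrow(scan) == 0L) stop("no admissible cutoff under min_group_frac = ",
                             min_group_frac, call. = FALSE)
  fit_at <- function(cc) fit_adjusted_ph(table, table$expression > cc,
                                         covariates = covariates)
  if (fit == "all") {
    fits <- dplyr::bind_rows(purrr::map(scan$cutoff, fit_at))
    scan <- dplyr::bind_cols(scan, fits[c("estimate", "se", "p", "converged")])
  } else {
    scan$estimate <- NA_real_; scan$se <- NA_real_; scan$p <- NA_real_
    scan$converged <- NA
  }
  eligible <- if (fit == "all") scan$converged else rep(TRUE, nrow(scan))
  idx <- which(eligible)[which.max(scan$j[eligible])]
  if (fit == "selected") {
    f <- fit_at(scan$cutoff[idx])
    scan[idx, c("estimate", "se", "p", "converged")] <-
      f[c("estimate", "se", "p", "converged")]
  }
  structure(list(scan = scan, selected = scan[idx, ],
                 outcome = outcome, min_group_frac = min_group_frac),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  s <- x$selected
  cat(sprintf(
    paste0("Cutoff scan over %d admissible cutoffs (outcome: %s)\n",
           "  selected cutoff = %g (J = %.4g, n_high = %d, n_low = %d)\n"),
    nrow(x$scan), x$outcome, s$cutoff, s$j, s$n_high, s$n_low))
  if (!is.na(s$p)) {
    cat(sprintf("  adjusted log HR = %.4g (se %.3g), p = %.4g\n",
                s$estimate, s$se, s$p))
  }
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' @param table Survival tibble.
#' @param high Logical/0-1 group indicator.
#' @return A `km_compare` object: `curves` tibble (`group`, `time`,
#'   `n_risk`, `n_event`, `surv`), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(table, high) {
  high <- as.logical(high)
  if (!any(high) || all(high)) stop("both groups must be nonempty",
                                    call. = FALSE)
  dat <- data.frame(time = table$time, event = table$event,
                    group = factor(ifelse(high, "high", "low"),
                                   levels = c("low", "high")))
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble::tibble(
    group = sub("^group=", "", strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event, surv = sf$surv)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd_$n) - 1L
  structure(list(curves = curves, chisq = unname(sd_$chisq), df = df,
                 p = stats::pchisq(unname(sd_$chisq), df, lower.tail = FALSE)),
            class = "km_compare")
}

#' @export
print.km_compare <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
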