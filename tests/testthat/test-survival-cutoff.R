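test_that("Youden's index reproduces direct 2x2 arithmetic", {
  out <- c(rep(TRUE, 40), rep(FALSE, 60))
  hi <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 20), rep(FALSE, 40))
  y <- youden_index(hi, out)
  expect_equal(y$j, 30 / 40 + 40 / 60 - 1)
  expect_equal(c(y$tp, y$fn, y$fp, y$tn), c(30, 10, 20, 40))

  perfect <- youden_index(out, out)
  expect_equal(perfect$j, 1)
  expect_equal(youden_index(rep(TRUE, 100), out)$j, 0)
  expect_error(youden_index(rep(TRUE, 5), rep(TRUE, 5)), "both classes")
})

test_that("adjusted PH fit recovers null and planted log hazard ratios", {
  null_tab <- simulate_survival_table(n = 500, hazard_ratio = 1, seed = 21)
  f0 <- fit_adjusted_ph(null_tab, null_tab$expression > 25)
  expect_true(f0$converged)
  expect_lt(abs(f0$estimate), 3 * f0$se)

  alt_tab <- simulate_survival_table(n = 500, hazard_ratio = 4, seed = 22)
  f1 <- fit_adjusted_ph(alt_tab, alt_tab$expression > 25)
  expect_lt(abs(f1$estimate - log(4)), 3 * f1$se)
  expect_equal(f1$ties, "efron")

  expect_error(fit_adjusted_ph(null_tab[1:3, ], c(1, 1, 1)), "group")
})

test_that("uncensored two-group fit matches the exponential rate-ratio limit", {
  set.seed(23)
  n <- 400
  grp <- rep(0:1, each = n / 2)
  tm <- rexp(n, ifelse(grp == 1, 0.09, 0.03))
  tab <- tibble::tibble(time = tm, event = 1L, expression = grp,
                        age = 0, sex = 0, smoking = 0, alcohol = 0)
  fit <- fit_adjusted_ph(tab, grp, covariates = "age")
  closed_form <- log((sum(grp) / sum(tm[grp == 1])) /
                     (sum(1 - grp) / sum(tm[grp == 0])))
  expect_equal(fit$estimate, closed_form, tolerance = 0.05)
})

test_that("cutoff scan selects the max-J cutoff and is scale-equivariant", {
  tab <- simulate_survival_table(n = 200, seed = 24)
  scan <- scan_cutoffs(tab, fit = "all")
  expect_equal(scan$selected$j, max(scan$scan$j[scan$scan$converged]))
  expect_true(all(abs(scan$scan$j -
    (scan$scan$sensitivity + scan$scan$specificity - 1)) < 1e-12))
  # admissibility: both groups keep at least 10% of subjects
  expect_true(all(pmin(scan$scan$n_high, scan$scan$n_low) >= 0.1 * nrow(tab)))

  doubled <- tab
  doubled$expression <- 2 * doubled$expression
  scan2 <- scan_cutoffs(doubled, fit = "none")
  expect_equal(scan2$selected$cutoff, 2 * scan_cutoffs(tab, fit = "none")$selected$cutoff)

  flat <- tab
  flat$expression <- 1
  expect_error(scan_cutoffs(flat), "constant")

  td <- tidy(scan)
  expect_identical(td, scan$scan)
  expect_equal(glance(scan)$selected_cutoff, scan$selected$cutoff)
})

test_that("max-selected cutoff p-values are anti-conservative under the null", {
  # property of maximum selection, documented rather than hidden: with no
  # true hazard step the naive p at the selected cutoff rejects too often
  ps <- vapply(1:40, function(s) {
    tab <- simulate_survival_table(n = 100, hazard_ratio = 1, seed = 100 + s)
    scan_cutoffs(tab, fit = "selected")$selected$p
  }, numeric(1))
  expect_gt(mean(ps <= 0.05, na.rm = TRUE), 0.05)
})

test_that("KM/log-rank matches hand computation and the empirical limit", {
  dup <- tibble::tibble(time = c(3, 5, 7, 9), event = c(1, 1, 0, 1))
  ident <- km_logrank(dplyr::bind_rows(dup, dup),
                      rep(c(TRUE, FALSE), each = 4))
  expect_equal(ident$chisq, 0)
  expect_equal(ident$p, 1)

  # six uncensored subjects, hand-computed log-rank
  t6 <- c(1, 2, 3, 4, 5, 6)
  g6 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  tab6 <- tibble::tibble(time = t6, event = 1L)
  res <- km_logrank(tab6, g6)
  # observed events in high group = 3; expected = sum over death times of
  # (high at risk)/(total at risk): 3/6 + 2/5 + 2/4 + 1/3 + 1/2 + 0/1
  e_high <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 1 / 2 + 0
  v <- sum(c(3 * 3 / 36, 2 * 3 / 25 * (4 / 4), 2 * 2 / 16 * (3 / 3),
             1 * 2 / 9 * (2 / 2), 1 * 1 / 4, 0))
  expect_equal(res$chisq, (3 - e_high)^2 / v, tolerance = 1e-6)

  # with no censoring the KM estimate is the empirical survival function
  high <- res$curves[res$curves$group == "high", ]
  expect_equal(high$surv, c(2 / 3, 1 / 3, 0))

  expect_error(km_logrank(tab6, rep(TRUE, 6)), "nonempty")
})

test_that("survival CSV loader drops incomplete rows and validates schema", {
  tab <- simulate_survival_table(n = 30, seed = 25)
  tab$age[c(2, 9)] <- NA
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  got <- read_survival_table(path)
  expect_equal(nrow(got), 28)
  expect_equal(attr(got, "n_dropped"), 2)

  bad <- tab[, setdiff(names(tab), "alcohol")]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_survival_table(path), "alcohol")
})
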