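#' Simulate a 3-channel tissue z-stack with known ground truth
#'
#' Generates a synthetic cleared-tissue confocal stack in which tumour nests
#' are random spheres and the marker channel follows one of the two spatial
#' distributions seen in tissue: a web of fibrous filaments confined to the
#' stroma (`"stromal-web"`), or diffuse signal confined to the nests
#' (`"nest-confined"`). The membrane channel covers the whole field (the
#' lipophilic membrane dye labels all cellular tissue) and the nuclei channel
#' is sparse bright spots. The realised marker and nest masks are returned as
#' ground truth together with the per-layer relative intensity they imply, so
#' downstream quantification can be checked exactly.
#'
#' @param n_layers Number of z-layers (>= 1).
#' @param height,width Lateral size in pixels (>= 16).
#' @param z_step Micrometres per layer.
#' @param pattern `"stromal-web"` or `"nest-confined"`.
#' @param marker_density Target fraction of the marker's compartment (stroma
#'   or nests) occupied by marker-positive voxels, in `[0, 1]`. The realised
#'   fraction is what enters the ground truth.
#' @param nest_count Number of spherical nests; default fills about a quarter
#'   of the volume.
#' @param nest_radius Nest radius in voxels.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (clamped at zero, rounded to integer grey levels).
#' @param seed Integer seed; identical inputs give identical stacks.
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (list of `nest_mask`, `marker_mask` — logical `[h, w, z]` arrays — and
#'   `expected_profile`, a tibble of per-layer true relative intensity).
#' @export
simulate_stack <- function(n_layers = 200L, height = 64L, width = 64L,
                           z_step = 0.7,
                           pattern = c("stromal-web", "nest-confined"),
                           marker_density = 0.12,
                           nest_count = NULL, nest_radius = 6,
                           noise_sd = 0, seed = 1L) {
  pattern <- match.arg(pattern)
  if (n_layers < 1L) stop("`n_layers` must be >= 1", call. = FALSE)
  if (height < 16L || width < 16L) {
    stop("`height` and `width` must be >= 16", call. = FALSE)
  }
  if (marker_density < 0 || marker_density > 1) {
    stop("`marker_density` must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  withr::local_seed(as.integer(seed))

  dims <- c(height, width, n_layers)
  vol <- prod(dims)
  if (is.null(nest_count)) {
    nest_count <- max(1L, round(0.25 * vol / (4 / 3 * pi * nest_radius^3)))
  }

  nest_mask <- array(FALSE, dims)
  for (i in seq_len(nest_count)) {
    cx <- stats::runif(1, 1, height)
    cy <- stats::runif(1, 1, width)
    cz <- stats::runif(1, 1, n_layers)
    xr <- max(1L, floor(cx - nest_radius)):min(height, ceiling(cx + nest_radius))
    yr <- max(1L, floor(cy - nest_radius)):min(width, ceiling(cy + nest_radius))
    zr <- max(1L, floor(cz - nest_radius)):min(n_layers, ceiling(cz + nest_radius))
    g <- expand.grid(x = xr, y = yr, z = zr)
    inside <- (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= nest_radius^2
    idx <- cbind(g$x[inside], g$y[inside], g$z[inside])
    nest_mask[idx] <- TRUE
  }

  marker_mask <- array(FALSE, dims)
  if (marker_density > 0) {
    if (pattern == "nest-confined") {
      inside <- which(nest_mask)
      on <- inside[stats::runif(length(inside)) < marker_density]
      marker_mask[on] <- TRUE
    } else {
      marker_mask <- draw_filaments(dims, stroma = !nest_mask,
                                    target = marker_density * sum(!nest_mask))
    }
  }

  amp <- 150
  base <- array(0, c(dims, 3L))
  base[, , , 1][marker_mask] <- amp
  base[, , , 2] <- amp                      # membrane dye labels all tissue
  nuc <- stats::runif(vol) < 0.02           # sparse nuclear spots
  base[, , , 3][nuc] <- amp
  if (noise_sd > 0) {
    base <- base + stats::rnorm(length(base), sd = noise_sd)
  }
  base <- round(pmin(pmax(base, 0), 65535))

  expected <- tibble::tibble(
    layer = seq_len(n_layers),
    r = colSums(matrix(marker_mask, height * width, n_layers)) / (height * width)
  )
  list(
    stack = image_stack(base, z_step = z_step),
    truth = list(nest_mask = nest_mask, marker_mask = marker_mask,
                 expected_profile = expected)
  )
}

# Random-walk polyline filaments dilated to ~2 voxels, restricted to stroma.
# Filaments are added until the stromal marker mask reaches `target` voxels.
draw_filaments <- function(dims, stroma, target) {
  mask <- array(FALSE, dims)
  if (target <= 0) return(mask)
  total <- 0
  guard <- 0L
  while (total < target && guard < 10000L) {
    guard <- guard + 1L
    pos <- stats::runif(3) * (dims - 1) + 1
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    len <- 20L + stats::rgeom(1L, 1 / 40)
    pts <- matrix(0, len, 3L)
    for (s in seq_len(len)) {
      dir <- dir + stats::rnorm(3, sd = 0.3)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir
      pts[s, ] <- pos
    }
    # dilate each polyline point to a 2-voxel-thick tube
    offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    for (k in seq_len(nrow(offs))) {
      q <- round(sweep(pts, 2L, offs[k, ], `+`))
      keep <- q[, 1] >= 1 & q[, 1] <= dims[1] &
              q[, 2] >= 1 & q[, 2] <= dims[2] &
              q[, 3] >= 1 & q[, 3] <= dims[3]
      q <- q[keep, , drop = FALSE]
      if (nrow(q) == 0L) next
      ok <- stroma[q] & !mask[q]
      total <- total + sum(ok)
      mask[q[ok, , drop = FALSE]] <- TRUE
    }
  }
  mask
}

#' Simulate a pair of per-layer relative-intensity profiles
#'
#' Each subject's layers are drawn independently so that the probability of a
#' layer lying at or above the dichotomization cutoff equals that subject's
#' `frac_above`. Supra-cutoff values are `cutoff * (1 + Exp(1))`, sub-cutoff
#' values uniform on `[0, cutoff)`; all values are nonnegative.
#'
#' @param n_layers Layers per subject (>= 1).
#' @param frac_above Length-2 vector of supra-cutoff layer probabilities for
#'   subjects a and b.
#' @param cutoff Dichotomization cutoff (default 0.05).
#' @param seed Integer seed.
#' @return A tibble `subject` (`"a"`/`"b"`), `layer`, `r`.
#' @export
simulate_layer_profiles <- function(n_layers = 200L, frac_above = c(0.5, 0.5),
                                    cutoff = 0.05, seed = 1L) {
  if (n_layers < 1L) stop("`n_layers` must be >= 1", call. = FALSE)
  frac_above <- rep_len(frac_above, 2L)
  if (any(frac_above < 0 | frac_above > 1)) {
    stop("`frac_above` must lie in [0, 1]", call. = FALSE)
  }
  withr::local_seed(as.integer(seed))
  draw <- function(frac) {
    above <- stats::runif(n_layers) < frac
    r <- stats::runif(n_layers, 0, cutoff)
    r[above] <- cutoff * (1 + stats::rexp(sum(above)))
    r
  }
  tibble::tibble(
    subject = rep(c("a", "b"), each = n_layers),
    layer = rep(seq_len(n_layers), 2L),
    r = c(draw(frac_above[1]), draw(frac_above[2]))
  )
}

#' Simulate a survival table with a hazard step at a known expression cutoff
#'
#' Emulates a dichotomizable expression biomarker in a surgical cohort:
#' expression is drawn from a two-component mixture centred
#' `expression_sep` units below and above the planted cutoff (so the cutpoint
#' is identifiable) and rounded to integer units, mirroring reported log2
#' expression resolution. Survival times are exponential with the subject's
#' hazard multiplied by `hazard_ratio` when expression exceeds `true_cutoff`,
#' with log-linear covariate effects for age (centred at 58), sex, smoking
#' and alcohol. Censoring is an independent exponential time whose single
#' global rate is solved numerically so the expected censored fraction equals
#' `censor_rate`.
#'
#' @param n Cohort size (>= 20).
#' @param true_cutoff Planted expression cutoff.
#' @param hazard_ratio Hazard multiplier above the cutoff (> 0).
#' @param censor_rate Expected censored fraction, in `[0, 1)`.
#' @param covariate_effects Named log-hazard coefficients for
#'   `age` (per year), `sex`, `smoking`, `alcohol`.
#' @param expression_sep,expression_sd Mixture separation and component sd.
#' @param baseline_median Median survival time of the low group, in months.
#' @param seed Integer seed.
#' @return A tibble `expression`, `time`, `event`, `age`, `sex`, `smoking`,
#'   `alcohol` with no missing values.
#' @export
simulate_survival_table <- function(n = 400L, true_cutoff = 25,
                                    hazard_ratio = 6, censor_rate = 0.2,
                                    covariate_effects = c(age = 0.02, sex = 0.2,
                                                          smoking = 0.3,
                                                          alcohol = 0.2),
                                    expression_sep = 4, expression_sd = 2.5,
                                    baseline_median = 24, seed = 1L) {
  if (n < 20L) stop("`n` must be >= 20", call. = FALSE)
  if (hazard_ratio <= 0) stop("`hazard_ratio` must be positive", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("`censor_rate` must lie in [0, 1)", call. = FALSE)
  }
  withr::local_seed(as.integer(seed))
  comp <- stats::rbinom(n, 1L, 0.5)
  expression <- round(stats::rnorm(
    n, true_cutoff + ifelse(comp == 1L, expression_sep, -expression_sep),
    expression_sd))
  age <- stats::rnorm(n, 58, 8)
  sex <- stats::rbinom(n, 1L, 0.8)
  smoking <- stats::rbinom(n, 1L, 0.6)
  alcohol <- stats::rbinom(n, 1L, 0.6)
  lp <- covariate_effects[["age"]] * (age - 58) +
    covariate_effects[["sex"]] * sex +
    covariate_effects[["smoking"]] * smoking +
    covariate_effects[["alcohol"]] * alcohol
  lambda <- log(2) / baseline_median * exp(lp) *
    ifelse(expression > true_cutoff, hazard_ratio, 1)
  t_event <- stats::rexp(n, lambda)
  if (censor_rate == 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    rate_c <- stats::uniroot(
      function(l) mean(l / (l + lambda)) - censor_rate,
      lower = 1e-12, upper = 1e6, tol = 1e-12)$root
    t_cens <- stats::rexp(n, rate_c)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  tibble::tibble(expression = expression, time = time, event = event,
                 age = age, sex = sex, smoking = smoking, alcohol = alcohol)
}

#' Simulate a pair of log2 fold-change tables with planted concordance
#'
#' Builds an "up" contrast (e.g. marker overexpression vs control) and a
#' "down" contrast (knockdown vs control) in which exactly `n_concordant`
#' genes satisfy `log2fc > lfc_threshold` in the up table and
#' `log2fc < -lfc_threshold` in the down table; every other gene violates at
#' least one of the two conditions.
#'
#' @param n_genes Total genes.
#' @param n_concordant Planted concordant count, `0 <= n_concordant <= n_genes`.
#' @param lfc_threshold Strict log2 fold-change threshold (default 1).
#' @param seed Integer seed.
#' @return A list of tibbles `up` and `down`, each `gene`, `log2fc`.
#' @export
simulate_de_tables <- function(n_genes = 1000L, n_concordant = 922L,
                               lfc_threshold = 1, seed = 1L) {
  if (n_concordant < 0L || n_concordant > n_genes) {
    stop("`n_concordant` must lie in [0, n_genes]", call. = FALSE)
  }
  withr::local_seed(as.integer(seed))
  genes <- sprintf("gene%05d", seq_len(n_genes))
  pass <- function(k) lfc_threshold + 0.05 + stats::rexp(k, 1)
  fail <- function(k) stats::runif(k, -lfc_threshold, lfc_threshold)
  up <- down <- numeric(n_genes)
  conc <- seq_len(n_concordant)
  up[conc] <- pass(n_concordant)
  down[conc] <- -pass(n_concordant)
  n_rest <- n_genes - n_concordant
  if (n_rest > 0L) {
    rest <- (n_concordant + 1L):n_genes
    mode <- sample(1:3, n_rest, replace = TRUE)  # which condition(s) fail
    up[rest] <- ifelse(mode %in% c(1L, 3L), fail(n_rest), pass(n_rest))
    down[rest] <- ifelse(mode %in% c(2L, 3L), fail(n_rest), -pass(n_rest))
  }
  ord <- sample.int(n_genes)
  list(up = tibble::tibble(gene = genes, log2fc = up)[ord, ],
       down = tibble::tibble(gene = genes, log2fc = down)[ord, ])
}
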