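make_stack_from <- function(arr3) {
  # replicate a single-channel [h, w, z] array into all three channels
  v <- array(0, c(dim(arr3), 3L))
  for (ch in 1:3) v[, , , ch] <- arr3
  image_stack(v)
}

test_that("background subtraction matches direct recomputation and edge cases", {
  z <- array(0, c(16, 16, 2))
  s <- make_stack_from(z)
  expect_equal(subtract_background(s, "percentile", 20)$voxels, s$voxels)

  const <- make_stack_from(array(10, c(16, 16, 1)))
  expect_true(all(subtract_background(const, "constant", 10)$voxels == 0))

  set.seed(11)
  vals <- sample(0:255)  # 256 values on a 16x16 layer
  layer <- array(vals, c(16, 16, 1))
  out <- subtract_background(make_stack_from(layer), "percentile", 50)
  expected <- pmax(vals - quantile(vals, 0.5, names = FALSE), 0)
  expect_equal(as.vector(out$voxels[, , 1, 1]), expected)
  # 128 clamped zeros then 0.5, 1.5, ...: the median straddles 0 and 0.5
  expect_equal(median(out$voxels[, , 1, 1]), 0.25)
  expect_equal(max(out$voxels[, , 1, 1]), 127.5)

  expect_error(subtract_background(s, "percentile", 150), "\\[0, 100\\]")
})

test_that("median filter agrees with the per-pixel oracle", {
  s <- make_stack_from(array(runif(8 * 8 * 2), c(8, 8, 2)))
  expect_identical(median_filter(s, 1L), s)

  # isolated bright pixel is removed by a 3x3 window
  z <- array(0, c(8, 8, 1))
  z[4, 5, 1] <- 100
  out <- median_filter(make_stack_from(z), 3L)
  expect_true(all(out$voxels == 0))

  set.seed(7)
  for (window in c(3L, 5L)) {
    patch <- matrix(sample(0:50, 49, replace = TRUE), 7, 7)
    got <- median_filter(make_stack_from(array(patch, c(7, 7, 1))), window)
    expect_equal(got$voxels[, , 1, 1], oracle_median_filter(patch, window),
                 info = paste("window", window))
  }
  expect_error(median_filter(s, 2L), "odd")
})

test_that("pixel counting is exact and monotone in the threshold", {
  z <- array(0, c(16, 16, 3))
  z[sample(16 * 16, 37)] <- 1   # 37 positive pixels in layer 1
  s <- make_stack_from(z)
  counts <- count_channel_pixels(s, threshold = 0)
  expect_equal(counts$marker[1], 37)
  expect_equal(counts$marker[2:3], c(0, 0))
  expect_true(all(count_channel_pixels(s, Inf)[, -1] == 0))

  sim <- simulate_stack(n_layers = 40, height = 24, width = 24,
                        pattern = "nest-confined", noise_sd = 0, seed = 2)
  got <- count_channel_pixels(sim$stack, threshold = 0)
  truth <- colSums(matrix(sim$truth$marker_mask, 24 * 24, 40))
  expect_equal(got$marker, truth)

  # raising the threshold never increases any count
  lo <- count_channel_pixels(sim$stack, threshold = 0)
  hi <- count_channel_pixels(sim$stack, threshold = 100)
  expect_true(all(hi$marker <= lo$marker & hi$membrane <= lo$membrane))
})

test_that("relative intensity handles zero-membrane layers via the defined flag", {
  counts <- tibble::tibble(layer = 1:3, marker = c(50, 0, 3),
                           membrane = c(5000, 800, 0), nuclei = 0)
  prof <- relative_intensity(counts)
  expect_equal(prof$r[1], 0.01)
  expect_equal(prof$r[2], 0)
  expect_true(is.na(prof$r[3]))
  expect_equal(prof$defined, c(TRUE, TRUE, FALSE))
})

test_that("layer selection reproduces the reported contiguous ranges", {
  r <- rep(0.001, 80)
  r[13:60] <- 0.2
  sel <- select_layers(profile_from_r(r), cutoff = 0.01)
  expect_equal(sel$first, 13L)
  expect_equal(sel$last, 60L)
  expect_equal(sel$n_selected, 48L)
  expect_equal(sel$thickness_um, 33.6)

  r2 <- c(rep(0.05, 20), rep(0, 30))
  expect_equal(select_layers(profile_from_r(r2))$thickness_um, 14.0)

  empty <- select_layers(profile_from_r(rep(0.001, 10)))
  expect_equal(empty$n_selected, 0L)
  expect_equal(empty$thickness_um, 0)
  expect_true(is.na(empty$first))

  # raising the cutoff never lengthens the selection
  set.seed(3)
  r3 <- runif(120, 0, 0.1)
  sels <- vapply(c(0.005, 0.01, 0.03, 0.06),
                 function(cc) select_layers(profile_from_r(r3), cc)$n_selected,
                 integer(1))
  expect_true(all(diff(sels) <= 0))

  # non-contiguous mode counts all supra-cutoff layers
  r4 <- c(0.2, 0, 0.2, 0.2, 0)
  expect_equal(select_layers(profile_from_r(r4), contiguous = FALSE)$n_selected, 3L)
  expect_equal(select_layers(profile_from_r(r4), contiguous = TRUE)$n_selected, 2L)
})

test_that("stack thickness reproduces the caption layer/depth pairs", {
  expect_equal(stack_thickness(c(199, 182, 190, 215)),
               c(139.3, 127.4, 133.0, 150.5))
  expect_equal(stack_thickness(0), 0)
  expect_error(stack_thickness(-1), "nonnegative")
})

test_that("sum z-projection conserves intensity exactly", {
  one <- make_stack_from(array(rpois(36, 5), c(6, 6, 1)))
  expect_equal(z_projection(one)$marker, one$voxels[, , 1, 1])

  two <- make_stack_from(array(rep(c(3, 5), each = 16), c(4, 4, 2)))
  expect_true(all(z_projection(two)$membrane == 8))

  set.seed(9)
  s <- make_stack_from(array(sample(0:20, 4 * 8 * 8, TRUE), c(8, 8, 4)))
  proj <- z_projection(s)
  for (ch in names(proj)) {
    expect_identical(sum(proj[[ch]]), sum(s$voxels[, , , ch]))
  }
  expect_error(z_projection(s, mode = "max"), "mode")
})

test_that("TIFF round trip restores the stack and validates channel order", {
  sim <- simulate_stack(n_layers = 6, height = 16, width = 16,
                        pattern = "nest-confined", noise_sd = 3, seed = 4)
  path <- tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  back <- read_stack(path)
  expect_equal(back$voxels, sim$stack$voxels, ignore_attr = TRUE)
  expect_equal(back$z_step, 0.7)

  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$channel_names <- c("membrane", "marker", "nuclei")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(path), "channel order")
})
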