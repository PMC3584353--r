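# Background estimation, nucleus detection, windowed measurement, the
# above-background exclusion, and densities.

test_that("background is the mean of region means and requires three
           regions", {
  expect_equal(estimate_background(replicate(3, matrix(200, 5, 5),
                                             simplify = FALSE))$B, 200)
  regions <- list(matrix(190, 5, 5), matrix(200, 5, 5), matrix(210, 5, 5))
  expect_equal(estimate_background(regions)$B, 200)
  expect_error(estimate_background(regions[1:2]), "at least 3")
  set.seed(3)
  noisy <- replicate(3, matrix(rnorm(10000, 200, 3), 100, 100),
                     simplify = FALSE)
  se <- 3 / sqrt(10000 * 3)
  expect_lt(abs(estimate_background(noisy)$B - 200), 3 * se * sqrt(3))
})

test_that("windowed gray measurement is exact on flat and half-plane
           fields and translation-invariant", {
  f <- uniform_field(127)
  expect_equal(measure_gray(f, c(31, 31)), 127)
  # big disc of 60: window fully inside reads the disc gray
  nuc <- data.frame(x_um = 31, y_um = 31, gray = 60, a_um = 10, b_um = 10,
                    theta = 0)
  fd <- noiseless_field(nuc)
  expect_equal(measure_gray(fd, c(31, 31)), 60)
  # half-plane 60 | 200: window on the boundary averages to ~130
  half <- matrix(60, 310, 310); half[156:310, ] <- 200
  fh <- pixel_field(half, "intensity_62x62um", 0.2, "areax")
  expect_lt(abs(measure_gray(fh, c(31, 31)) - 130), 1)
  # translating field and query by whole pixels leaves the value unchanged
  shifted <- matrix(60, 310, 310); shifted[(156 + 5):310, ] <- 200
  fs <- pixel_field(shifted, "intensity_62x62um", 0.2, "areax")
  expect_equal(measure_gray(fs, c(31 + 5 * 0.2, 31)),
               measure_gray(fh, c(31, 31)))
  expect_error(measure_gray(f, c(0.5, 31)), "beyond")
})

test_that("detection finds rendered nuclei with accurate centroids and
           shape classes", {
  bg <- estimate_background(replicate(3, matrix(200, 10, 10),
                                      simplify = FALSE))
  blank <- uniform_field(200, pixel_scale_um = 0.2)
  expect_equal(nrow(detect_nuclei(blank, bg)), 0)

  nuc <- data.frame(x_um = 20, y_um = 25, gray = 60, a_um = 3, b_um = 3,
                    theta = 0)
  f1 <- noiseless_field(nuc)
  det <- detect_nuclei(f1, bg, detect_frac = 0.85)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - 20), 0.2)
  expect_lt(abs(det$y_um - 25), 0.2)
  expect_lt(det$axis_ratio, 1.3)

  two <- data.frame(x_um = c(15, 40), y_um = c(15, 40), gray = 60,
                    a_um = c(3, 5.2), b_um = c(3, 5.2 / 3),
                    theta = c(0, 0.7))
  f2 <- noiseless_field(two)
  det2 <- detect_nuclei(f2, bg, detect_frac = 0.85)
  expect_equal(nrow(det2), 2)
  expect_equal(sum(det2$axis_ratio >= 2), 1)
  expect_error(detect_nuclei(f1, 0), "B must be")
})

test_that("the exclusion rule removes nuclei within 5% of background and
           routes fusiform nuclei out first", {
  nuclei <- data.frame(
    gray_value = c(195, 150, 189, 191, 100),
    shape = c("round", "round", "round", "round", "fusiform"))
  res <- filter_measurements(nuclei, 200)
  # signal B - g <= 10 is removed: 195 (5) and 191 (9); 189 (11) stays
  expect_equal(sort(res$removed$gray_value), c(191, 195))
  expect_equal(sort(res$kept$gray_value), c(150, 189))
  expect_equal(res$fusiform$gray_value, 100)
  # min_stain_frac = 0 keeps everything above background
  res0 <- filter_measurements(nuclei, 200, min_stain_frac = 0)
  expect_equal(nrow(res0$removed), 0)
  expect_equal(nrow(res0$kept), 4)
})

test_that("densities are counts over sampled area with a flagged
           inside:outside ratio", {
  f <- pixel_field(matrix(200L, 320, 405), "counting_128x162um", 0.4, "areax")
  rep1 <- compute_density(c(intense = 4), list(f))
  expect_equal(unname(rep1$density[["intense"]]), 4 / 0.020736,
               tolerance = 1e-12)
  expect_false(rep1$ratio_defined)

  out_f <- pixel_field(matrix(200L, 320, 405), "counting_128x162um", 0.4,
                       "striatum_outside")
  rep2 <- compute_density(c(intense = 0, weak = 0, fusiform = 6), list(f),
                          outside_counts = c(fusiform = 3),
                          outside_fields = list(out_f))
  expect_true(rep2$ratio_defined)
  expect_equal(rep2$fusiform_inside_outside_ratio, 2)
  rep3 <- compute_density(c(fusiform = 6), list(f),
                          outside_counts = c(fusiform = 0),
                          outside_fields = list(out_f))
  expect_false(rep3$ratio_defined)
  expect_error(compute_density(c(intense = 1), list()), "at least one")
})

test_that("a noise-free field recovers every ground-truth class label at
           wide class separation", {
  cfg <- fast_cfg(background_sd = 0, component_sd_gray = 5,
                  n_intensity_fields = c(3, 3), n_counting_fields = c(0, 0),
                  n_outside_fields = c(0, 0))
  a <- gen_animal(cfg, 1, rng_seed = 17, age_days = 60, group = "NS0h")
  bg <- estimate_background(
    Filter(function(f) f$region == "nidopallium_background", a$fields))
  int_fields <- Filter(function(f) f$geometry == "intensity_62x62um",
                       a$fields)
  meas <- do.call(rbind, lapply(int_fields, measure_field, background = bg))
  truth <- a$truth
  # match detections to ground truth by nearest center within a micron
  for (i in seq_len(nrow(meas))) {
    tr <- truth[truth$field_id == meas$field_id[i], ]
    d <- sqrt((tr$x_um - meas$x_um[i])^2 + (tr$y_um - meas$y_um[i])^2)
    expect_lt(min(d), 1.5)
    true_cls <- tr$true_class[which.min(d)]
    expect_identical(meas$shape[i] == "fusiform", true_cls == "fusiform")
    if (true_cls != "fusiform") {
      # intense vs weak means separated by (170-80)/5 = 18 SD
      expect_identical(meas$gray_value[i] < 125, true_cls == "intense")
    }
  }
})

test_that("intense-class density estimates are unbiased across seeded
           animals", {
  cfg <- fast_cfg(n_intensity_fields = c(2, 2), n_counting_fields = c(4, 4),
                  n_outside_fields = c(0, 0), counting_pixel_scale_um = 0.5)
  age <- 300
  f_true <- 0.03 + (0.40 - 0.03) * exp(-0.004 * age)
  target <- 1200 * f_true
  dens <- vapply(1:12, function(s) {
    a <- gen_animal(cfg, 1, rng_seed = 100 + s, age_days = age,
                    group = "NS0h")
    cnt <- Filter(function(f) f$geometry == "counting_128x162um", a$fields)
    n_int <- sum(a$truth$true_class == "intense" &
                   a$truth$field_id %in% names(cnt))
    compute_density(c(intense = n_int), cnt)$density[["intense"]]
  }, numeric(1))
  area <- 4 * 0.020736
  se <- sqrt(target / area / 12)     # Poisson standard error of the mean
  expect_lt(abs(mean(dens) - target), 3 * se)
})
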