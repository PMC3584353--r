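# Synthetic cohort generation: configuration invariants, determinism,
# ground-truth statistics, and serialization.

test_that("configuration invariants are enforced", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(intense_mean_gray = 180, weak_mean_gray = 170),
               "darker stain")
  expect_error(cohort_config(weak_mean_gray = 210), "darker stain")
  expect_error(cohort_config(intense_fraction_Y0 = 1.2), "intense_fraction_Y0")
  expect_error(cohort_config(intense_fraction_k = -0.1), "intense_fraction_k")
  expect_error(cohort_config(syntax_noise_eps = 2), "syntax_noise_eps")
  expect_error(cohort_config(bout_gap_s = 1.5), "2 s")
  expect_error(cohort_config(jitter_cv0 = 0.01, jitter_cv_floor = 0.05),
               "non-increasing")
})

test_that("the intense-fraction decay evaluates the one-phase curve", {
  cfg <- cohort_config(intense_fraction_Y0 = 0.5,
                       intense_fraction_plateau = 0.05,
                       intense_fraction_k = 0.01)
  expect_equal(stainmix:::intense_fraction_at(cfg, 0), 0.5)
  expect_equal(stainmix:::intense_fraction_at(cfg, Inf), 0.05)
  expect_equal(stainmix:::intense_fraction_at(cfg, 100),
               0.05 + 0.45 * exp(-1))
})

test_that("same seed and config reproduce an animal bit-identically;
           different seeds differ", {
  cfg <- fast_cfg()
  a1 <- gen_animal(cfg, 1, rng_seed = 5)
  a2 <- gen_animal(cfg, 1, rng_seed = 5)
  expect_identical(a1, a2)
  a3 <- gen_animal(cfg, 1, rng_seed = 6)
  expect_false(identical(a1$fields[[1]]$raster, a3$fields[[1]]$raster))
})

test_that("field counts, geometry and gray range obey the configuration", {
  cfg <- fast_cfg()
  a <- gen_animal(cfg, 2, rng_seed = 9, age_days = 400)
  geoms <- vapply(a$fields, function(f) f$geometry, character(1))
  regions <- vapply(a$fields, function(f) f$region, character(1))
  expect_equal(sum(geoms == "intensity_62x62um"), 3)
  expect_equal(sum(geoms == "counting_128x162um" & regions == "areax"), 2)
  expect_equal(sum(regions == "striatum_outside"), 1)
  expect_equal(sum(regions == "nidopallium_background"), 3)
  for (f in a$fields) {
    expect_true(all(f$raster >= 0 & f$raster <= 255))
    expect_equal(dim(f$raster),
                 as.integer(round(stainmix:::FIELD_GEOMETRY[[f$geometry]] /
                                    f$pixel_scale_um)))
  }
})

test_that("a zero intense fraction yields no intense nuclei, and the
           realized fraction tracks the decay within binomial error", {
  cfg0 <- fast_cfg(intense_fraction_Y0 = 0, intense_fraction_plateau = 0)
  a0 <- gen_animal(cfg0, 1, rng_seed = 3, age_days = 200)
  expect_false("intense" %in% a0$truth$true_class)

  # pooled over many counting fields: Y0 0.33, plateau 0.02, k 0.004 at
  # age 600 gives p = 0.02 + 0.31 * exp(-2.4)
  cfg <- fast_cfg(intense_fraction_Y0 = 0.33,
                  intense_fraction_plateau = 0.02,
                  intense_fraction_k = 0.004,
                  n_intensity_fields = c(0, 0),
                  n_counting_fields = c(16, 16),
                  n_outside_fields = c(0, 0),
                  n_background_fields = c(3, 3),
                  round_density_mm2 = 2000,
                  counting_pixel_scale_um = 0.8)
  a <- gen_animal(cfg, 1, rng_seed = 11, age_days = 600)
  round_n <- a$truth[a$truth$true_class != "fusiform", ]
  n <- nrow(round_n)
  p_hat <- mean(round_n$true_class == "intense")
  p <- 0.02 + 0.31 * exp(-0.004 * 600)
  expect_gt(n, 400)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("singing thins the weak class but not the intense class", {
  cfg <- fast_cfg(sing_weak_factor = 0.5, n_intensity_fields = c(8, 8),
                  n_counting_fields = c(8, 8), n_outside_fields = c(0, 0))
  ns <- gen_animal(cfg, 1, rng_seed = 21, age_days = 300, group = "NS0h")
  dir <- gen_animal(cfg, 1, rng_seed = 21, age_days = 300, group = "Dir")
  n_weak <- function(a) sum(a$truth$true_class == "weak")
  n_int <- function(a) sum(a$truth$true_class == "intense")
  expect_lt(n_weak(dir) / n_weak(ns), 0.7)
  expect_gt(n_int(dir), 0.5 * n_int(ns))
})

test_that("song corpora respect bout structure and template labels", {
  cfg <- cohort_config(seed = 1)
  ev <- gen_song_corpus(cfg, age_days = 500, rng_seed = 2)
  co <- segment_bouts(ev)
  expect_gte(max(co$bout), 20)
  expect_true(all(ev$label %in% cfg$motif_template))
  expect_true(all(abs(ev$duration_ms - (ev$offset_s - ev$onset_s) * 1000)
                  < 1))
  expect_error(
    gen_song_corpus(cohort_config(motif_template = "A",
                                  syntax_noise_eps = 1), 100, 1),
    "degenerate")
})

test_that("generated consistency matches the configured syntax noise
           within binomial error", {
  cfg <- cohort_config(motif_template = c("A", "B", "C"),
                       syntax_noise_eps = 0.1, motifs_per_bout = c(1, 1),
                       n_bouts = 20, seed = 1)
  cs <- vapply(1:6, function(s) {
    ev <- gen_song_corpus(cfg, 500, rng_seed = 300 + s)
    strophes <- split(as.character(ev$label), segment_bouts(ev)$strophe)
    song_consistency(strophes)
  }, numeric(1))
  # 20 strophes x 3 transitions, typical fraction ~0.9
  expect_lt(abs(mean(cs) - 0.9), 3 * sqrt(0.9 * 0.1 / 60) / sqrt(6) + 0.02)
})

test_that("colocalization tables reproduce the configured odds ratio", {
  t0 <- gen_colocalization(100, 1000, brdu_rate_weak = 0, odds_ratio = 5,
                           rng_seed = 1)
  expect_equal(t0["pos", "weak"], 0)
  big <- gen_colocalization(1e5, 1e5, 0.03, 10, rng_seed = 2)
  or_hat <- (big[1, 1] * big[2, 2]) / (big[1, 2] * big[2, 1])
  expect_lt(abs(or_hat - 10) / 10, 0.1)
  expect_error(gen_colocalization(0, 10, 0.1, 1, 1), "> 0")
  expect_error(gen_colocalization(10, 10, 1, 1, 1), "brdu_rate_weak")
})

test_that("cohort simulation is deterministic and writes a readable
           plain-text + PNG bundle", {
  cfg <- fast_cfg(n_animals = 2, group_labels = c("NS0h", "Dir"))
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  expect_equal(nrow(co1$animals), 2)
  expect_length(co1$songs, 2)
  expect_length(co1$coloc, 2)

  dir <- withr::local_tempdir()
  write_cohort(co1, dir)
  expect_true(file.exists(file.path(dir, "fields_manifest.csv")))
  back <- read_cohort_fields(dir)
  f0 <- co1$fields[[5]]
  expect_equal(back[[f0$field_id]]$raster, f0$raster)
  expect_equal(back[[f0$field_id]]$pixel_scale_um, f0$pixel_scale_um)
})
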