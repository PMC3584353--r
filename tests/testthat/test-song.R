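# Bout/strophe/motif segmentation and the stereotypy statistics.

test_that("bout and strophe segmentation follows the 2 s and 300 ms rules", {
  ev <- events_from_labels(c("A", "B", "C", "D"), gaps = rep(0.1, 3))
  co <- segment_bouts(ev)
  expect_equal(unique(co$bout), 1)
  expect_equal(unique(co$strophe), 1)

  ev2 <- events_from_labels(rep("A", 4), gaps = c(0.1, 3.0, 0.1))
  expect_equal(unique(segment_bouts(ev2)$bout), c(1, 2))

  ev3 <- events_from_labels(rep("A", 6), gaps = c(0.05, 0.5, 0.05, 3.0, 0.05))
  co3 <- segment_bouts(ev3)
  expect_equal(max(co3$bout), 2)
  expect_equal(length(unique(co3$strophe[co3$bout == 1])), 2)

  expect_error(segment_bouts(ev3[c(2, 1, 3:6), ]), "time-ordered")
  bad <- ev; bad$offset_s[1] <- bad$onset_s[1]
  expect_error(segment_bouts(bad), "offset")
})

test_that("greedy motif identification handles long, short and broken
           renditions", {
  walk <- function(labels, template) {
    ev <- events_from_labels(labels, gaps = rep(0.05, length(labels) - 1))
    co <- identify_motifs(segment_bouts(ev), template)
    co$motif
  }
  expect_equal(walk(c("A","B","C","D","A","B","C","D"), c("A","B","C","D")),
               c(1, 1, 1, 1, 2, 2, 2, 2))
  expect_equal(walk(c("A","B","C","D","A","B","C"), c("A","B","C","D")),
               c(1, 1, 1, 1, 2, 2, 2))
  # ABCABD with template ABC: motifs ABC and AB, stray D unassigned
  expect_equal(walk(c("A","B","C","A","B","D"), c("A","B","C")),
               c(1, 1, 1, 2, 2, NA))
  ev <- events_from_labels(c("X", "Y"), gaps = 0.05)
  expect_warning(identify_motifs(segment_bouts(ev), c("A", "B")), "absent")
})

test_that("linearity matches hand counts with the terminal token", {
  expect_equal(song_linearity(rep(list(c("A","B","C","D")), 20)), 1)
  mixed <- c(rep(list(c("A","B","C")), 10), rep(list(c("A","C","B")), 10))
  expect_equal(song_linearity(mixed), 0.5)   # 3 syllables, 6 transition types
  expect_equal(song_linearity(list("A")), 1) # A -> end only
  expect_error(song_linearity(list(character(0))), "empty")
})

test_that("consistency counts typical transitions; stereotypy is the mean", {
  expect_equal(song_consistency(rep(list(c("A","B","C")), 20)), 1)
  # hand tally: 18 x "A B C", 2 x "A C", 2 x "B C" gives
  # A->B 18 / A->C 2, B->C 20, C->end 22; typical sum 60 of 62 transitions
  s2 <- c(rep(list(c("A","B","C")), 18), rep(list(c("A","C")), 2),
          rep(list(c("B","C")), 2))
  expect_equal(song_consistency(s2), 60 / 62)
  st <- song_stereotypy(c(rep(list(c("A","B","C")), 18),
                          rep(list(c("A","C","B")), 2)))
  expect_equal(st$stereotypy, (st$linearity + st$consistency) / 2)
})

test_that("consistency tie-breaks toward the earliest-observed transition", {
  s <- list(c("A", "B"), c("A", "C"))   # A->B and A->C tie at 1 each
  # typical A-transition is A->B (seen first): 1 typical of 2 A-transitions,
  # B->end and C->end are each their source's mode
  expect_equal(song_consistency(s), (1 + 1 + 1) / 4)
})

test_that("intersyllable interval statistics follow the span-minus-sum rule", {
  m <- data.frame(label = c("A","B","C","D"),
                  onset_s = c(0, 0.2, 0.4, 0.6),
                  offset_s = c(0.15, 0.35, 0.55, 0.8),
                  duration_ms = c(150, 150, 150, 170))
  # span 800 ms, durations sum 620, 3 intervals -> 60 ms
  res <- intersyllable_stats(list(m))
  expect_equal(res$mean_ms, 60)
  zero_gap <- data.frame(label = c("A","B"), onset_s = c(0, 0.1),
                         offset_s = c(0.1, 0.2), duration_ms = c(100, 100))
  expect_equal(intersyllable_stats(list(zero_gap))$mean_ms, 0)
  many <- rep(list(m), 20)
  expect_equal(intersyllable_stats(many)$cv, 0)
  expect_warning(
    res2 <- intersyllable_stats(c(list(m), list(m[1, , drop = FALSE]))),
    "skipped")
  expect_equal(res2$n_motifs, 1)
})

test_that("motif similarity is 100 for identical motifs, scales with length
           mismatch, and is symmetric", {
  ev <- events_from_labels(c("A","B","C","D"), gaps = rep(0.05, 3))
  scales <- setNames(rep(1, 7), stainmix:::SONG_FEATURES)
  expect_equal(motif_similarity(ev, ev, scales), 100)
  expect_equal(motif_similarity(ev, ev[1:2, ], scales), 50)
  set.seed(5)
  b <- ev
  for (f in stainmix:::SONG_FEATURES) b[[f]] <- b[[f]] * (1 + rnorm(4, 0, 0.1))
  expect_equal(motif_similarity(ev, b, scales), motif_similarity(b, ev, scales))
  expect_lt(motif_similarity(ev, b, scales), 100)
  expect_error(motif_similarity(ev, b, scales * 0), "positive")
})

test_that("a jitter-free corpus scores perfect similarity and unit duration
           ratio; a lengthening factor appears in the ratio exactly", {
  cfg0 <- cohort_config(syntax_noise_eps = 0, jitter_cv0 = 0,
                        jitter_cv_floor = 0, motif3_lengthening = 1,
                        motifs_per_bout = c(3, 5), seed = 1)
  ev <- gen_song_corpus(cfg0, age_days = 500, rng_seed = 2)
  co <- identify_motifs(segment_bouts(ev), attr(ev, "template"))
  suite <- bout_similarity_suite(co)
  expect_equal(suite$within, 100)
  expect_equal(suite$across, 100)
  expect_equal(suite$duration_ratio, 1)

  cfg5 <- cohort_config(syntax_noise_eps = 0, jitter_cv0 = 0,
                        jitter_cv_floor = 0, motif3_lengthening = 1.05,
                        motifs_per_bout = c(3, 5), seed = 1)
  ev5 <- gen_song_corpus(cfg5, 500, 2)
  co5 <- identify_motifs(segment_bouts(ev5), attr(ev5, "template"))
  expect_equal(bout_similarity_suite(co5)$duration_ratio, 1.05,
               tolerance = 1e-10)
})

test_that("bouts with fewer than three motifs cannot enter the similarity
           suite", {
  cfg <- cohort_config(motifs_per_bout = c(2, 2), seed = 1)
  ev <- gen_song_corpus(cfg, 500, 3)
  co <- identify_motifs(segment_bouts(ev), attr(ev, "template"))
  expect_error(bout_similarity_suite(co), "not enough song")
})

test_that("feature CVs vanish without jitter and track the configured CV", {
  cfg0 <- cohort_config(syntax_noise_eps = 0, jitter_cv0 = 0,
                        jitter_cv_floor = 0, seed = 1)
  ev <- gen_song_corpus(cfg0, 500, 6)
  co <- identify_motifs(segment_bouts(ev), attr(ev, "template"))
  cv <- feature_cv(co, attr(ev, "template"))
  expect_true(all(cv$by_position == 0, na.rm = TRUE))

  cfg <- cohort_config(syntax_noise_eps = 0, jitter_cv0 = 0.05,
                       jitter_cv_floor = 0.05, n_bouts = 200,
                       motifs_per_bout = c(1, 1), seed = 1)
  ev2 <- gen_song_corpus(cfg, 1000, 7)
  co2 <- identify_motifs(segment_bouts(ev2), attr(ev2, "template"))
  cv2 <- feature_cv(co2, attr(ev2, "template"), n_bouts = 200)
  expect_lt(abs(mean(cv2$by_feature) - 0.05) / 0.05, 0.1)
  expect_true(all(abs(cv2$by_feature - 0.05) / 0.05 < 0.15))
})

test_that("singer classification uses the 90 and 10 motif thresholds", {
  expect_equal(classify_singer(90), "singer")
  expect_equal(classify_singer(250), "singer")
  expect_equal(classify_singer(9), "non_singer")
  expect_equal(classify_singer(0), "non_singer")
  expect_equal(classify_singer(50), "ambiguous")
  expect_error(classify_singer(-1), ">= 0")
})

test_that("segmentation is a lossless partition of the event stream", {
  cfg <- cohort_config(seed = 1)
  ev <- gen_song_corpus(cfg, 800, 9)
  co <- segment_bouts(ev)
  expect_equal(nrow(co), nrow(ev))
  expect_true(!is.unsorted(co$bout))
  expect_true(!is.unsorted(co$strophe))
  expect_equal(co$onset_s, ev$onset_s)
  # gaps across bout boundaries exceed 2 s, within-bout gaps do not
  gaps <- co$onset_s[-1] - co$offset_s[-nrow(co)]
  boundary <- diff(co$bout) > 0
  expect_true(all(gaps[boundary] > 2))
  expect_true(all(gaps[!boundary] <= 2))
})

test_that("consistency decreases with syntax noise and within-bout
           similarity decreases with feature jitter", {
  mean_consistency <- function(eps) {
    cs <- vapply(1:8, function(s) {
      cfg <- cohort_config(syntax_noise_eps = eps, n_bouts = 20, seed = 1)
      ev <- gen_song_corpus(cfg, 500, rng_seed = 1000 + s)
      strophes <- split(as.character(ev$label),
                        segment_bouts(ev)$strophe)
      song_consistency(strophes)
    }, numeric(1))
    mean(cs)
  }
  cons <- vapply(c(0, 0.05, 0.1, 0.2), mean_consistency, numeric(1))
  expect_true(all(diff(cons) < 0))
  expect_equal(cons[1], 1)

  mean_within <- function(cv) {
    ws <- vapply(1:5, function(s) {
      cfg <- cohort_config(syntax_noise_eps = 0, jitter_cv0 = cv,
                           jitter_cv_floor = cv, motifs_per_bout = c(3, 5),
                           seed = 1)
      ev <- gen_song_corpus(cfg, 500, rng_seed = 2000 + s)
      co <- identify_motifs(segment_bouts(ev), attr(ev, "template"))
      bout_similarity_suite(co)$within
    }, numeric(1))
    mean(ws)
  }
  within <- vapply(c(0.02, 0.06, 0.12), mean_within, numeric(1))
  expect_true(all(diff(within) < 0))
})
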