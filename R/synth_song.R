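# Synthetic song corpora: Markov-chain syllable sequences with a dominant
# motif, rendition-to-rendition feature jitter that shrinks with age, and
# bout/strophe timing structure.

# Deterministic per-label feature baselines (units as in SONG_FEATURES).
syllable_baselines <- function(labels) {
  i <- seq_along(labels)
  data.frame(label = labels,
             duration_ms = 60 + 18 * i,
             pitch = 600 + 150 * i,
             fm = 20 + 5 * i,
             am = 10 + 2 * i,
             entropy = -3 + 0.25 * i,
             pitch_goodness = 100 + 20 * i,
             mean_freq = 2500 + 300 * i)
}

# One motif rendition: template labels with probability eps of a deviating
# transition (skip one syllable, or substitute a different template label).
render_motif_labels <- function(template, eps) {
  len <- length(template)
  labs <- template[1L]
  p <- 1L
  while (p < len) {
    nxt <- p + 1L
    if (eps > 0 && runif(1) < eps) {
      if (runif(1) < 0.5 && p + 2L <= len) {
        nxt <- p + 2L                       # omission -> short motif
      } else {
        others <- setdiff(seq_len(len), nxt)
        labs <- c(labs, template[sample(others, 1L)])  # substitution
        p <- nxt
        next
      }
    }
    labs <- c(labs, template[nxt])
    p <- nxt
  }
  labs
}

#' Generate a synthetic song corpus
#'
#' Builds a syllable-event stream of at least 20 bouts, each holding 1-6
#' motif renditions of `cfg$motif_template`. With probability
#' `cfg$syntax_noise_eps` a transition deviates from the template (a skipped
#' or substituted syllable, producing occasional "short" motifs). Each
#' bioacoustic feature of each syllable is jittered multiplicatively with a
#' coefficient of variation given by the config's age function (older birds
#' sing with less jitter). Silent gaps between bouts exceed 2 s; gaps
#' between motifs within a bout stay well under it; the third and later
#' motifs of a bout are lengthened by `cfg$motif3_lengthening`.
#'
#' @param cfg a [cohort_config()].
#' @param age_days the singer's age (controls feature jitter).
#' @param rng_seed integer seed.
#' @return A data frame of syllable events (`label`, `onset_s`, `offset_s`
#'   and the seven features) with attributes `template` and `age_days`.
#' @examples
#' cfg <- cohort_config(syntax_noise_eps = 0, jitter_cv0 = 0,
#'                      jitter_cv_floor = 0, seed = 1)
#' ev <- gen_song_corpus(cfg, age_days = 500, rng_seed = 7)
#' unique(table(ev$label))  # every rendition identical
#' @export
gen_song_corpus <- function(cfg, age_days, rng_seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  template <- as.character(cfg$motif_template)
  if (cfg$syntax_noise_eps >= 1 && length(template) == 1L) {
    stop("degenerate corpus: eps = 1 with a single-syllable template",
         call. = FALSE)
  }
  base <- syllable_baselines(template)
  cv <- feature_jitter_cv_at(cfg, age_days)
  feats <- setdiff(SONG_FEATURES, "duration_ms")

  with_seed(rng_seed, {
    rows <- list()
    t_now <- 0
    for (b in seq_len(cfg$n_bouts)) {
      n_motifs <- draw_count(cfg$motifs_per_bout)
      per_strophe <- draw_count(cfg$strophe_motifs)
      m_in_strophe <- 0L
      for (m in seq_len(n_motifs)) {
        stretch <- if (m >= 3L) cfg$motif3_lengthening else 1
        labs <- render_motif_labels(template, cfg$syntax_noise_eps)
        for (s in seq_along(labs)) {
          bl <- base[base$label == labs[s], ]
          dur <- bl$duration_ms * stretch * max(1 + rnorm(1, 0, cv), 0.1)
          row <- data.frame(label = labs[s], onset_s = t_now,
                            offset_s = t_now + dur / 1000,
                            duration_ms = dur)
          for (f in feats) row[[f]] <- bl[[f]] * (1 + rnorm(1, 0, cv))
          rows[[length(rows) + 1L]] <- row
          t_now <- t_now + dur / 1000
          if (s < length(labs)) {
            t_now <- t_now + 0.060 * stretch * max(1 + rnorm(1, 0, cv), 0.1)
          }
        }
        m_in_strophe <- m_in_strophe + 1L
        if (m < n_motifs) {
          if (m_in_strophe >= per_strophe) {       # next strophe
            t_now <- t_now + runif(1, cfg$inter_strophe_gap_s[1],
                                   cfg$inter_strophe_gap_s[2])
            m_in_strophe <- 0L
            per_strophe <- draw_count(cfg$strophe_motifs)
          } else {                                 # next motif, same strophe
            t_now <- t_now + cfg$intra_strophe_gap_ms / 1000
          }
        }
      }
      t_now <- t_now + cfg$bout_gap_s + runif(1, 0, 1)
    }
    out <- do.call(rbind, rows)
    attr(out, "template") <- template
    attr(out, "age_days") <- age_days
    out
  })
}

#' Generate a BrdU x staining-intensity contingency table
#'
#' Samples a 2x2 table (rows BrdU+/BrdU-, columns intense/weak) in which
#' the odds of BrdU labeling in the intense class equal `odds_ratio` times
#' the odds in the weak class.
#'
#' @param n_intense,n_weak cell counts per intensity class (> 0).
#' @param brdu_rate_weak BrdU labeling probability among weak cells, in
#'   (0, 1).
#' @param odds_ratio multiplicative odds of BrdU labeling for intense cells.
#' @param rng_seed integer seed.
#' @return 2x2 integer matrix with dimnames.
#' @examples
#' gen_colocalization(100, 1000, 0.03, 5, rng_seed = 1)
#' @export
gen_colocalization <- function(n_intense, n_weak, brdu_rate_weak, odds_ratio,
                               rng_seed) {
  if (n_intense <= 0 || n_weak <= 0) stop("counts must be > 0", call. = FALSE)
  if (brdu_rate_weak < 0 || brdu_rate_weak >= 1) {
    stop("brdu_rate_weak must lie in [0, 1)", call. = FALSE)
  }
  if (odds_ratio <= 0) stop("odds_ratio must be > 0", call. = FALSE)
  odds_weak <- brdu_rate_weak / (1 - brdu_rate_weak)
  p_intense <- odds_ratio * odds_weak / (1 + odds_ratio * odds_weak)
  with_seed(rng_seed, {
    a <- rbinom(1L, n_intense, p_intense)
    b <- rbinom(1L, n_weak, brdu_rate_weak)
    matrix(c(a, n_intense - a, b, n_weak - b), 2L, 2L,
           dimnames = list(brdu = c("pos", "neg"),
                           class = c("intense", "weak")))
  })
}
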