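# Song syntax and stereotypy statistics.
#
# A corpus is a data frame of time-ordered syllable events with the seven
# bioacoustic features used throughout: duration_ms, pitch, fm (frequency
# modulation), am (amplitude modulation), entropy, pitch_goodness,
# mean_freq.

SONG_FEATURES <- c("duration_ms", "pitch", "fm", "am", "entropy",
                   "pitch_goodness", "mean_freq")

#' Segment a syllable-event stream into bouts and strophes
#'
#' A new bout starts whenever the silent interval between consecutive
#' syllables exceeds `bout_gap_s` (song bouts are delimited by silences
#' longer than 2 s); within a bout, a new strophe starts whenever the
#' silence exceeds `strophe_gap_ms` (motifs inside a strophe are separated
#' by pauses of no more than a couple hundred milliseconds).
#'
#' @param events data frame with at least `label`, `onset_s`, `offset_s`
#'   (and feature columns), time-ordered and non-overlapping.
#' @param bout_gap_s silence threshold starting a new bout (seconds).
#' @param strophe_gap_ms silence threshold starting a new strophe (ms).
#' @return The events with integer columns `bout` and `strophe` (strophe
#'   numbering is global), as an object of class `song_corpus`; the
#'   thresholds are kept as attributes.
#' @examples
#' ev <- data.frame(label = c("A", "B", "A", "B"),
#'                  onset_s = c(0, 0.2, 5, 5.2),
#'                  offset_s = c(0.1, 0.3, 5.1, 5.3))
#' table(segment_bouts(ev)$bout)
#' @export
segment_bouts <- function(events, bout_gap_s = 2.0, strophe_gap_ms = 300) {
  events <- as.data.frame(events)
  if (!nrow(events)) stop("empty event stream", call. = FALSE)
  if (is.unsorted(events$onset_s)) {
    stop("events must be time-ordered", call. = FALSE)
  }
  if (any(events$offset_s <= events$onset_s)) {
    stop("every offset must exceed its onset", call. = FALSE)
  }
  gaps <- c(Inf, events$onset_s[-1L] - events$offset_s[-nrow(events)])
  if (any(gaps < -1e-9)) stop("events overlap", call. = FALSE)
  events$bout <- cumsum(gaps > bout_gap_s)
  events$strophe <- cumsum(gaps > strophe_gap_ms / 1000)
  structure(events, class = c("song_corpus", "data.frame"),
            bout_gap_s = bout_gap_s, strophe_gap_ms = strophe_gap_ms)
}

#' Identify motifs within each strophe
#'
#' Greedy left-to-right scan: a motif starts at each occurrence of the
#' template's first label and extends through template labels in order;
#' omitted labels are allowed (yielding "short" motifs). A motif must
#' contain at least two template syllables. Syllables outside any motif are
#' left unassigned.
#'
#' @param corpus a `song_corpus` from [segment_bouts()].
#' @param template character vector of syllable labels forming the
#'   (long) motif.
#' @return The corpus with an integer `motif` column (`NA` outside motifs)
#'   and a logical `motif_long` column (motif rendered with no omissions).
#' @examples
#' ev <- data.frame(label = c("A", "B", "C", "A", "B"),
#'                  onset_s = 0:4 / 10 * 3, offset_s = 0:4 / 10 * 3 + 0.1)
#' co <- identify_motifs(segment_bouts(ev), c("A", "B", "C"))
#' table(co$motif)
#' @export
identify_motifs <- function(corpus, template) {
  if (!length(template)) stop("empty template", call. = FALSE)
  corpus$motif <- NA_integer_
  corpus$motif_long <- NA
  if (!any(corpus$label %in% template)) {
    warning("template labels absent from corpus; no motifs identified")
    return(corpus)
  }
  motif_id <- 0L
  for (st in unique(corpus$strophe)) {
    idx <- which(corpus$strophe == st)
    labs <- corpus$label[idx]
    i <- 1L
    while (i <= length(labs)) {
      if (labs[i] != template[1L]) { i <- i + 1L; next }
      pos <- 1L            # position in template of last matched syllable
      members <- i
      j <- i + 1L
      while (j <= length(labs)) {
        nxt <- match(labs[j], template)
        if (is.na(nxt) || nxt <= pos) break
        members <- c(members, j)
        pos <- nxt
        j <- j + 1L
      }
      if (length(members) >= 2L) {
        motif_id <- motif_id + 1L
        corpus$motif[idx[members]] <- motif_id
        corpus$motif_long[idx[members]] <-
          length(members) == length(template)
      }
      i <- j
    }
  }
  corpus
}

# Strophe label sequences with the terminal "end" token appended.
strophe_transitions <- function(strophes) {
  if (!length(strophes) || any(!lengths(strophes))) {
    stop("empty strophes", call. = FALSE)
  }
  do.call(rbind, lapply(strophes, function(s) {
    s <- c(as.character(s), "end")
    data.frame(from = s[-length(s)], to = s[-1L])
  }))
}

#' Song linearity
#'
#' Number of distinct syllable labels divided by the number of distinct
#' ordered transition types, tallied over all strophes with a terminal
#' "end" token appended to each strophe (so a perfectly linear song has
#' exactly one transition type per syllable and linearity 1).
#'
#' @param strophes a list of character vectors of syllable labels, one per
#'   strophe (conventionally 20 strophes).
#' @return Linearity in (0, 1].
#' @examples
#' song_linearity(rep(list(c("A", "B", "C", "D")), 20))  # 1
#' @export
song_linearity <- function(strophes) {
  tr <- strophe_transitions(strophes)
  n_syll <- length(unique(unlist(strophes)))
  n_types <- nrow(unique(tr))
  n_syll / n_types
}

#' Song consistency
#'
#' For each source syllable the "typical" transition is its most frequent
#' outgoing transition (ties broken toward the earliest observed);
#' consistency is the number of typical-transition occurrences divided by
#' the total number of transitions, terminal transitions included.
#'
#' @inheritParams song_linearity
#' @return Consistency in (0, 1].
#' @examples
#' song_consistency(rep(list(c("A", "B", "C")), 20))  # 1
#' @export
song_consistency <- function(strophes) {
  tr <- strophe_transitions(strophes)
  tr$order <- seq_len(nrow(tr))
  total_typical <- 0L
  for (src in unique(tr$from)) {
    out <- tr[tr$from == src, ]
    counts <- table(out$to)
    top <- max(counts)
    cand <- names(counts)[counts == top]
    if (length(cand) > 1L) {     # earliest-observed tie break
      first_seen <- vapply(cand, function(to) min(out$order[out$to == to]),
                           numeric(1))
      cand <- cand[which.min(first_seen)]
    }
    total_typical <- total_typical + top
  }
  total_typical / nrow(tr)
}

#' Sequence stereotypy score
#'
#' The average of linearity and consistency.
#' @inheritParams song_linearity
#' @return List with `linearity`, `consistency`, `stereotypy`.
#' @export
song_stereotypy <- function(strophes) {
  L <- song_linearity(strophes)
  C <- song_consistency(strophes)
  list(linearity = L, consistency = C, stereotypy = (L + C) / 2)
}

# split() with levels in numeric (time) order, not lexicographic
split_numeric <- function(x, ids) {
  split(x, factor(ids, levels = sort(unique(ids))))
}

# Split a motif-annotated corpus into per-motif data frames, in time order.
motif_list <- function(corpus) {
  ok <- !is.na(corpus$motif)
  if (!any(ok)) return(list())
  split_numeric(corpus[ok, , drop = FALSE], corpus$motif[ok])
}

#' Inter-syllable interval statistics
#'
#' Per motif, the mean silent interval is the motif span minus the summed
#' syllable durations, divided by the number of intervals; reported are the
#' mean and coefficient of variation of this quantity over motifs.
#'
#' @param motifs list of per-motif data frames (see [identify_motifs()]);
#'   motifs with fewer than 2 syllables are skipped with a warning.
#' @param n_motifs number of motifs to use (default 20; fewer are used,
#'   if fewer qualify).
#' @return List with `mean_ms`, `cv`, `n_motifs`.
#' @export
intersyllable_stats <- function(motifs, n_motifs = 20L) {
  ok <- vapply(motifs, nrow, integer(1)) >= 2L
  if (any(!ok)) warning(sum(!ok), " single-syllable motif(s) skipped")
  motifs <- head(motifs[ok], n_motifs)
  if (!length(motifs)) stop("no motif with >= 2 syllables", call. = FALSE)
  ivals <- vapply(motifs, function(m) {
    span <- (max(m$offset_s) - min(m$onset_s)) * 1000
    (span - sum(m$duration_ms)) / (nrow(m) - 1L)
  }, numeric(1))
  list(mean_ms = mean(ivals),
       cv = if (mean(ivals) > 0) sd(ivals) / mean(ivals) else 0,
       n_motifs = length(ivals))
}

#' Similarity between two motif renditions
#'
#' A deterministic feature-space similarity standing in for spectrogram
#' cross-correlation scores: syllables are paired by position up to the
#' shorter motif length; each pair's distance is the mean over the seven
#' bioacoustic features of the absolute difference in units of the
#' corpus-wide feature scale, clipped at 3; similarity is
#' `100 * max(0, 1 - mean distance / 3) * (shared length / longer length)`.
#' Symmetric and in \[0, 100\]; identical motifs score 100.
#'
#' @param a,b per-motif data frames with the feature columns.
#' @param feature_scales named positive scales (typically the per-feature
#'   SD over the corpus; see [corpus_feature_scales()]).
#' @return Similarity percentage.
#' @export
motif_similarity <- function(a, b, feature_scales) {
  if (!nrow(a) || !nrow(b)) stop("empty motif", call. = FALSE)
  feats <- SONG_FEATURES
  if (any(!is.finite(feature_scales[feats])) ||
      any(feature_scales[feats] <= 0)) {
    stop("feature scales must be positive (degenerate corpus?)", call. = FALSE)
  }
  n <- min(nrow(a), nrow(b))
  d <- vapply(seq_len(n), function(i) {
    mean(pmin(abs(as.numeric(a[i, feats]) - as.numeric(b[i, feats])) /
                as.numeric(feature_scales[feats]), 3))
  }, numeric(1))
  100 * max(0, 1 - mean(d) / 3) * (n / max(nrow(a), nrow(b)))
}

#' Per-feature scales for motif similarity
#'
#' Standard deviation of each bioacoustic feature over all syllables of the
#' corpus; zero SDs (features constant over the corpus) are replaced by 1 so
#' that a constant feature contributes zero distance rather than an error.
#'
#' @param corpus a `song_corpus`.
#' @return Named numeric vector over the seven features.
#' @export
corpus_feature_scales <- function(corpus) {
  sc <- vapply(SONG_FEATURES, function(f) sd(corpus[[f]]), numeric(1))
  sc[!is.finite(sc) | sc == 0] <- 1
  sc
}

#' Within- and across-bout motif similarity and motif-duration ratio
#'
#' For bouts containing at least 3 motifs: the within-bout similarity
#' compares the first and third motif of each bout; the across-bout
#' similarity compares the first motif of each bout with the first motifs
#' of the preceding and following bouts (averaged); the duration ratio is
#' the mean ratio of third-motif to first-motif duration (motif duration
#' tends to lengthen within a bout, more so in younger birds).
#'
#' @param corpus motif-annotated `song_corpus`.
#' @param n_bouts number of qualifying bouts to use (default 15).
#' @return List with `within`, `across` (percent), `duration_ratio`,
#'   `n_bouts_used`.
#' @export
bout_similarity_suite <- function(corpus, n_bouts = 15L) {
  scales <- corpus_feature_scales(corpus)
  motifs <- motif_list(corpus)
  if (!length(motifs)) stop("no motifs in corpus", call. = FALSE)
  bout_of <- vapply(motifs, function(m) m$bout[1L], numeric(1))
  per_bout <- split_numeric(seq_along(motifs), bout_of)       # motif ids in time order
  qualifying <- names(per_bout)[lengths(per_bout) >= 3L]
  if (length(qualifying) < 3L) {
    stop("fewer than 3 bouts with >= 3 motifs: not enough song", call. = FALSE)
  }
  use <- head(qualifying, n_bouts)

  within <- vapply(use, function(b) {
    ids <- per_bout[[b]]
    motif_similarity(motifs[[ids[1L]]], motifs[[ids[3L]]], scales)
  }, numeric(1))
  dur <- function(m) max(m$offset_s) - min(m$onset_s)
  ratio <- vapply(use, function(b) {
    ids <- per_bout[[b]]
    dur(motifs[[ids[3L]]]) / dur(motifs[[ids[1L]]])
  }, numeric(1))

  all_bouts <- names(per_bout)
  firsts <- lapply(per_bout, function(ids) motifs[[ids[1L]]])
  across <- vapply(use, function(b) {
    i <- match(b, all_bouts)
    neigh <- c(i - 1L, i + 1L)
    neigh <- neigh[neigh >= 1L & neigh <= length(all_bouts)]
    mean(vapply(neigh, function(j) {
      motif_similarity(firsts[[i]], firsts[[j]], scales)
    }, numeric(1)))
  }, numeric(1))

  list(within = mean(within), across = mean(across),
       duration_ratio = mean(ratio), n_bouts_used = length(use))
}

#' Rendition-to-rendition feature variability
#'
#' Coefficient of variation of each bioacoustic feature at each template
#' position, measured across the first motif of the first `n_bouts` bouts;
#' renditions missing a position (short motifs) are excluded for that
#' position.
#'
#' @param corpus motif-annotated `song_corpus`.
#' @param template motif template labels (defines the positions).
#' @param n_bouts number of bouts to use (default 20).
#' @return List with `by_position` (position x feature CV matrix) and
#'   `by_feature` (mean CV per feature across positions).
#' @export
feature_cv <- function(corpus, template, n_bouts = 20L) {
  motifs <- motif_list(corpus)
  if (!length(motifs)) stop("no motifs in corpus", call. = FALSE)
  bout_of <- vapply(motifs, function(m) m$bout[1L], numeric(1))
  per_bout <- split_numeric(seq_along(motifs), bout_of)
  use <- head(per_bout, n_bouts)
  firsts <- lapply(use, function(ids) motifs[[ids[1L]]])
  cvmat <- matrix(NA_real_, length(template), length(SONG_FEATURES),
                  dimnames = list(template, SONG_FEATURES))
  for (p in seq_along(template)) {
    rows <- lapply(firsts, function(m) m[m$label == template[p], , drop = FALSE])
    rows <- rows[vapply(rows, nrow, integer(1)) == 1L]
    if (length(rows) < 2L) next
    vals <- do.call(rbind, rows)
    for (f in SONG_FEATURES) {
      m <- mean(vals[[f]])
      cvmat[p, f] <- if (m != 0) sd(vals[[f]]) / abs(m) else 0
    }
  }
  list(by_position = cvmat,
       by_feature = colMeans(cvmat, na.rm = TRUE))
}

#' Classify a bird as singer or non-singer from its motif count
#'
#' Birds singing at least 90 motifs within the 2-h observation window are
#' singers; birds singing fewer than 10 motifs are non-singers; counts in
#' between are ambiguous and excluded from group contrasts.
#'
#' @param motifs_sung non-negative motif count.
#' @return `"singer"`, `"non_singer"` or `"ambiguous"`.
#' @examples
#' classify_singer(90); classify_singer(9); classify_singer(50)
#' @export
classify_singer <- function(motifs_sung) {
  if (motifs_sung < 0) stop("motif count must be >= 0", call. = FALSE)
  if (motifs_sung >= 90) "singer"
  else if (motifs_sung < 10) "non_singer"
  else "ambiguous"
}

#' Full stereotypy report for one corpus
#'
#' Convenience wrapper computing every song statistic at once.
#'
#' @param corpus motif-annotated `song_corpus` (see [segment_bouts()] and
#'   [identify_motifs()]).
#' @param template motif template labels.
#' @param n_strophes strophes entering the linearity/consistency tallies
#'   (default 20, the conventional sample).
#' @param n_bouts_similarity,n_bouts_cv bout counts for the similarity and
#'   feature-CV analyses.
#' @return List with `linearity`, `consistency`, `stereotypy`, `within`,
#'   `across`, `duration_ratio`, `intersyllable` and `feature_cv`.
#' @export
stereotypy_report <- function(corpus, template, n_strophes = 20L,
                              n_bouts_similarity = 15L, n_bouts_cv = 20L) {
  strophes <- split_numeric(as.character(corpus$label), corpus$strophe)
  syn <- song_stereotypy(head(strophes, n_strophes))
  sim <- bout_similarity_suite(corpus, n_bouts_similarity)
  isi <- intersyllable_stats(motif_list(corpus))
  cvs <- feature_cv(corpus, template, n_bouts_cv)
  c(syn, sim, list(intersyllable = isi, feature_cv = cvs))
}
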