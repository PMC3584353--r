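# End-to-end orchestration: simulate -> quantify -> classify -> song stats
# -> inference, as a pure function of (config, seed).

#' Quantify and classify one animal's fields
#'
#' Estimates the animal's background from its nucleus-free regions,
#' detects and measures every nucleus, applies the above-background
#' exclusion, fits the gray-value mixture on the kept intensity-field
#' measurements (BIC over `K_range`), places the uncertainty-peak cutoff,
#' and computes class densities: weak density from the intensity fields,
#' intense and fusiform densities from the larger counting fields, and the
#' fusiform inside:outside ratio.
#'
#' @param fields list of the animal's `pixel_field`s.
#' @param K_range candidate component counts for [select_model()].
#' @param min_stain_frac exclusion threshold (0 disables the 5% cutoff).
#' @param detect_frac detection threshold fraction.
#' @param rng_seed seed for the EM restarts.
#' @param fallback_sd when the mixture yields no between-class cutoff
#'   (single component, or components too entangled), nuclei darker than
#'   `fallback_sd` SDs below the pooled weak population are labeled
#'   intense instead (default 4).
#' @param ... further arguments (e.g. `n_starts`, `tol`) for [fit_em()].
#' @return List with `background`, `measurements`, `fit`, `classification`,
#'   `cutoff`, `cutoff_type` (`"uncertainty_peak"` or `"tail_threshold"`),
#'   `densities` (named vector: intense, weak, fusiform, fusiform_ratio),
#'   and the kept/removed bookkeeping.
#' @export
quantify_animal <- function(fields, K_range = 1:3, min_stain_frac = 0.05,
                            detect_frac = 0.9, rng_seed = 1L, ...) {
  m <- measure_animal(fields, detect_frac = detect_frac)
  analyze_measurements(m$measurements, fields, m$background,
                       K_range = K_range, min_stain_frac = min_stain_frac,
                       rng_seed = rng_seed, ...)
}

#' Detect and measure all nuclei of one animal
#'
#' The measurement half of [quantify_animal()]: background estimation plus
#' detection and windowed gray measurement over every non-background field.
#'
#' @inheritParams quantify_animal
#' @return List with `background` and `measurements`.
#' @export
measure_animal <- function(fields, detect_frac = 0.9) {
  geom <- vapply(fields, function(f) f$geometry, character(1))
  region <- vapply(fields, function(f) f$region, character(1))
  bg <- estimate_background(fields[region == "nidopallium_background"])
  meas <- lapply(fields[geom != "background_62x62um"], measure_field,
                 background = bg, detect_frac = detect_frac)
  meas <- do.call(rbind, c(meas, list(make.row.names = FALSE)))
  list(background = bg, measurements = meas)
}

#' Classify measured nuclei and compute densities
#'
#' The analysis half of [quantify_animal()], reusable on pre-measured
#' nucleus tables: applies the above-background exclusion, fits the
#' mixture, places the cutoff and derives densities.
#'
#' @param measurements nucleus measurement table (see [measure_field()]).
#' @param fields the animal's `pixel_field`s (for sampled areas).
#' @param background a `background_estimate`.
#' @inheritParams quantify_animal
#' @return As [quantify_animal()].
#' @export
analyze_measurements <- function(measurements, fields, background,
                                 K_range = 1:3, min_stain_frac = 0.05,
                                 rng_seed = 1L, fallback_sd = 4, ...) {
  meas <- measurements
  bg <- background
  geom <- vapply(fields, function(f) f$geometry, character(1))
  region <- vapply(fields, function(f) f$region, character(1))
  is_int <- meas$geometry == "intensity_62x62um"
  int_split <- filter_measurements(meas[is_int, , drop = FALSE], bg,
                                   min_stain_frac)
  values <- int_split$kept$gray_value
  fit <- select_model(values, K_range = K_range, rng_seed = rng_seed, ...)
  cls <- classify_nuclei(fit, values)

  # When the mixture isolates no intense component (K = 1, or components
  # too entangled for a between-class cutoff), fall back to a tail rule:
  # nuclei darker than fallback_sd SDs below the weak population are
  # intense. The weak population is the moment-matched pool of every
  # component except the lowest-mean (intense-candidate) one, so a split
  # weak bulk is re-merged before the threshold is placed. This is the
  # automated stand-in for recognizing the rare, clearly darker nuclei by
  # eye when the per-animal mixture cannot.
  if (cls$cutoff_defined) {
    cutoff <- cls$cutoff
    cutoff_type <- "uncertainty_peak"
  } else {
    pool <- if (fit$K == 1L) 1L else seq(2L, fit$K)
    w <- fit$pi[pool] / sum(fit$pi[pool])
    mu_w <- sum(w * fit$mu[pool])
    sd_w <- sqrt(sum(w * (fit$sigma[pool]^2 + fit$mu[pool]^2)) - mu_w^2)
    cutoff <- mu_w - fallback_sd * sd_w
    cutoff_type <- "tail_threshold"
  }

  label_of <- function(g) ifelse(g < cutoff, "intense", "weak")
  int_fields <- fields[geom == "intensity_62x62um"]
  weak_density <- sum(label_of(values) == "weak") /
    sum(vapply(int_fields, field_area_mm2, numeric(1)))

  cnt_in <- meas$geometry == "counting_128x162um" & meas$region == "areax"
  cnt_out <- meas$region == "striatum_outside"
  cnt_split <- filter_measurements(meas[cnt_in, , drop = FALSE], bg,
                                   min_stain_frac)
  counts_in <- c(
    intense = sum(label_of(cnt_split$kept$gray_value) == "intense"),
    weak = sum(label_of(cnt_split$kept$gray_value) == "weak"),
    fusiform = nrow(cnt_split$fusiform))
  out_meas <- meas[cnt_out, , drop = FALSE]
  cnt_fields <- fields[geom == "counting_128x162um" & region == "areax"]
  dens <- if (length(cnt_fields)) {
    compute_density(
      counts_in, cnt_fields,
      outside_counts = c(fusiform = sum(out_meas$shape == "fusiform")),
      outside_fields = fields[region == "striatum_outside"])
  } else {
    structure(list(counts = counts_in, total_area_mm2 = 0,
                   density = c(intense = NA_real_, weak = NA_real_,
                               fusiform = NA_real_),
                   fusiform_inside_outside_ratio = NA_real_,
                   ratio_defined = FALSE), class = "density_report")
  }

  list(background = bg, measurements = meas, fit = fit,
       classification = cls, cutoff = cutoff, cutoff_type = cutoff_type,
       intensity_kept = int_split$kept, intensity_removed = int_split$removed,
       densities = c(
         intense = unname(dens$density[["intense"]]),
         weak = weak_density,
         fusiform = unname(dens$density[["fusiform"]]),
         fusiform_ratio = dens$fusiform_inside_outside_ratio),
       density_report = dens)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a cohort, quantifies and classifies every animal, computes
#' song stereotypy for singing adults, and runs the inference layer:
#' one-phase decay fits of each density class against age, behavioral-group
#' comparisons (ANOVA + Tukey letters), stereotypy-vs-age and
#' stereotypy-vs-intense-density regressions, and per-animal Fisher tests
#' of the BrdU x intensity association. Re-running with the same config
#' yields an identical report.
#'
#' @param cfg a [cohort_config()]; `cfg$seed` drives all randomness.
#' @param stages character subset of
#'   `c("quantify", "songstats", "infer", "coloc")`; the simulation always
#'   runs, and later stages require `"quantify"`.
#' @param K_range,min_stain_frac,detect_frac quantification settings
#'   (`min_stain_frac = 0` reruns the analysis without the 5% cutoff).
#' @param n_bouts_similarity bouts per similarity suite.
#' @param ... further fitting arguments (e.g. `n_starts`) for [fit_em()].
#' @param out_dir optional directory: the cohort and a JSON report are
#'   written there.
#' @return Object of class `study_report`.
#' @export
run_pipeline <- function(cfg, stages = c("quantify", "songstats", "infer",
                                         "coloc"),
                         K_range = 1:3, min_stain_frac = 0.05,
                         detect_frac = 0.9, n_bouts_similarity = 15L,
                         out_dir = NULL, ...) {
  if (length(stages)) {
    stages <- match.arg(stages, c("quantify", "songstats", "infer", "coloc"),
                        several.ok = TRUE)
  }
  cohort <- simulate_cohort(cfg, include_songs = "songstats" %in% stages,
                            include_coloc = "coloc" %in% stages)
  report <- list(config = cfg, animals = cohort$animals)

  if ("quantify" %in% stages) {
    per_animal <- lapply(seq_len(nrow(cohort$animals)), function(i) {
      id <- cohort$animals$animal_id[i]
      f <- Filter(function(x) x$animal_id == id, cohort$fields)
      quantify_animal(f, K_range = K_range, min_stain_frac = min_stain_frac,
                      detect_frac = detect_frac,
                      rng_seed = derive_seed(cfg$seed, 30000 + i), ...)
    })
    names(per_animal) <- cohort$animals$animal_id
    report$quantification <- per_animal
    report$animals$cutoff <- vapply(per_animal, function(q) {
      q$cutoff %||% NA_real_
    }, numeric(1))
    report$animals$K <- vapply(per_animal, function(q) q$fit$K, numeric(1))
    for (cl in c("intense", "weak", "fusiform", "fusiform_ratio")) {
      report$animals[[paste0("density_", cl)]] <-
        vapply(per_animal, function(q) q$densities[[cl]], numeric(1))
    }
  }

  if ("songstats" %in% stages && length(cohort$songs)) {
    song_stats <- lapply(names(cohort$songs), function(id) {
      ev <- cohort$songs[[id]]
      corpus <- identify_motifs(segment_bouts(ev), attr(ev, "template"))
      stereotypy_report(corpus, attr(ev, "template"),
                        n_bouts_similarity = n_bouts_similarity)
    })
    names(song_stats) <- names(cohort$songs)
    report$song <- song_stats
    take <- function(stat) {
      vapply(report$animals$animal_id, function(id) {
        if (is.null(song_stats[[id]])) NA_real_ else song_stats[[id]][[stat]]
      }, numeric(1))
    }
    report$animals$linearity <- take("linearity")
    report$animals$consistency <- take("consistency")
    report$animals$stereotypy <- take("stereotypy")
    report$animals$within_similarity <- take("within")
    report$animals$duration_ratio <- take("duration_ratio")
  }

  if ("infer" %in% stages && "quantify" %in% stages) {
    an <- report$animals
    adults <- an[!an$group %in% c("PHD35", "PHD50"), , drop = FALSE]
    try_decay <- function(y, form = "decay") {
      tryCatch(fit_one_phase(adults$age_days, y, form = form),
               error = function(e) NULL)
    }
    report$decay <- list(
      intense = try_decay(adults$density_intense),
      weak = try_decay(adults$density_weak),
      fusiform = try_decay(adults$density_fusiform))
    if (all(is.finite(adults$density_fusiform_ratio))) {
      report$decay$fusiform_ratio <- try_decay(adults$density_fusiform_ratio)
    }
    report$group_comparison <- tryCatch(
      compare_groups(an, c("density_intense", "density_weak")),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "comparison_error"))
    if (!is.null(an$within_similarity) &&
        sum(is.finite(an$within_similarity)) >= 4) {
      sung <- an[is.finite(an$within_similarity), , drop = FALSE]
      report$stereotypy_regressions <- list(
        similarity_vs_age = tryCatch(
          fit_one_phase(sung$age_days, sung$within_similarity,
                        form = "association"),
          error = function(e) NULL),
        similarity_vs_intense_density =
          linear_regression(sung$density_intense, sung$within_similarity),
        stereotypy_vs_age = linear_regression(sung$age_days, sung$stereotypy),
        stereotypy_vs_intense_density =
          linear_regression(sung$density_intense, sung$stereotypy))
    }
  }

  if ("coloc" %in% stages && length(cohort$coloc)) {
    report$coloc <- lapply(cohort$coloc, fisher_exact)
  }

  report$cohort <- cohort
  report <- structure(report, class = "study_report")
  if (!is.null(out_dir)) {
    write_cohort(cohort, file.path(out_dir, "cohort"))
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Machine-readable summary of a study report
#'
#' Flattens the fitted quantities of a `study_report` into plain lists
#' suitable for JSON serialization (and byte-identity comparison between
#' runs).
#'
#' @param report a `study_report`.
#' @return A nested list of plain numbers and tables.
#' @export
report_summary <- function(report) {
  decay_to_list <- function(d) {
    if (is.null(d)) return(NULL)
    d[c("form", "Y0", "plateau", "k", "r_squared", "n")]
  }
  out <- list(
    seed = report$config$seed,
    n_animals = nrow(report$animals),
    animals = report$animals,
    decay = lapply(report$decay, decay_to_list),
    stereotypy_regressions = lapply(report$stereotypy_regressions,
                                    function(r) {
                                      if (inherits(r, "decay_fit")) {
                                        decay_to_list(r)
                                      } else {
                                        r
                                      }
                                    })
  )
  if (!is.null(report$group_comparison) &&
      !inherits(report$group_comparison, "comparison_error")) {
    out$group_comparison <- lapply(report$group_comparison, function(g) {
      list(F = g$anova$F, p_value = g$anova$p_value, letters = g$letters)
    })
  }
  if (!is.null(report$coloc)) {
    out$coloc <- lapply(report$coloc, function(x) {
      list(p_value = x$p_value, odds_ratio = x$odds_ratio)
    })
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d animals (seed %d)\n", nrow(x$animals),
              x$config$seed))
  if (!is.null(x$decay)) {
    cat(sprintf("  intense-density decay: k = %.4g /day, R2 = %.3f\n",
                x$decay$intense$k, x$decay$intense$r_squared))
  }
  if (!is.null(x$group_comparison) &&
      !inherits(x$group_comparison, "comparison_error")) {
    for (nm in names(x$group_comparison)) {
      g <- x$group_comparison[[nm]]
      cat(sprintf("  %s ANOVA: F = %.3f, p = %.4g, letters: %s\n", nm,
                  g$anova$F, g$anova$p_value,
                  paste(names(g$letters), g$letters, sep = "=",
                        collapse = " ")))
    }
  }
  invisible(x)
}

#' Compare densities across behavioral or age groups
#'
#' One-way ANOVA with Tukey letters for each response column. Singer
#' classification is applied first: adults whose motif count is ambiguous
#' (10-89 motifs) are dropped from the contrast; juvenile groups (fixed
#' ages) are exempt.
#'
#' @param animals animal table with `group`, `motifs_sung` and the
#'   response columns.
#' @param responses character vector of response column names.
#' @param alpha significance level for the Tukey letters.
#' @return Named list (one element per response) with `anova`, `letters`,
#'   `dropped` (animal ids excluded as ambiguous singers).
#' @export
compare_groups <- function(animals, responses, alpha = 0.05) {
  juvenile <- animals$group %in% c("PHD35", "PHD50")
  status <- vapply(seq_len(nrow(animals)), function(i) {
    if (juvenile[i]) "exempt"
    else if (is.na(animals$motifs_sung[i])) "ambiguous"
    else classify_singer(animals$motifs_sung[i])
  }, character(1))
  keep <- juvenile | status != "ambiguous"
  an <- animals[keep, , drop = FALSE]
  if (length(unique(an$group)) < 2L) {
    stop("need at least 2 groups after singer classification", call. = FALSE)
  }
  out <- lapply(responses, function(resp) {
    groups <- split(an[[resp]], an$group)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) < 2L) stop("insufficient animals", call. = FALSE)
    tk <- tukey_letters(groups, alpha = alpha)
    list(anova = one_way_anova(groups), letters = tk$letters,
         means = tk$means, dropped = animals$animal_id[!keep])
  })
  names(out) <- responses
  out
}
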