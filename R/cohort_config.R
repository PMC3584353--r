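#' Configuration for a synthetic cohort
#'
#' Bundles every parameter of the synthetic-data generator: the gray-value
#' mixture the histology fields emulate, the age-dependence of the
#' intensely-stained fraction and of fusiform-cell density, field geometry
#' and counts, song syntax/jitter structure, and the BrdU association.
#' Gray-value polarity follows the staining convention throughout: darker
#' staining = more antigen = lower gray value, so the intense class is the
#' left tail of the distribution and must have the lowest mean.
#'
#' @param n_animals number of animals in the cohort.
#' @param age_range_days age range (post-hatch days) for adult animals.
#' @param group_labels behavioral/age groups cycled over animals. Recognized
#'   labels: `NS0h`, `NS2h` (non-singing adults), `Dir`, `Undir` (singing
#'   adults), `PHD35`, `PHD50` (juveniles, fixed ages).
#' @param intense_mean_gray,weak_mean_gray,fusiform_mean_gray mean gray
#'   value of each nucleus class (0-255; intense < fusiform <= weak).
#' @param component_sd_gray between-nucleus SD of the class gray values.
#' @param background_gray,background_sd background canvas mean gray and
#'   per-pixel noise SD.
#' @param intense_fraction_Y0,intense_fraction_plateau,intense_fraction_k
#'   one-phase decay of the intense fraction among round nuclei:
#'   `f(age) = plateau + (Y0 - plateau) * exp(-k * age)`.
#' @param fusiform_density_Y0,fusiform_density_plateau,fusiform_density_k
#'   analogous decay for fusiform-cell density inside Area X (cells/mm^2).
#' @param fusiform_density_outside fusiform density outside Area X
#'   (cells/mm^2, age-independent).
#' @param round_density_mm2 total round-nucleus density in counting fields.
#' @param nuclei_per_intensity_field range of round-nucleus counts per
#'   62x62 um intensity field (non-singing animals).
#' @param n_intensity_fields,n_counting_fields,n_background_fields,n_outside_fields
#'   ranges of field counts per animal.
#' @param pixel_scale_um pixel size of intensity/background fields (um/px).
#' @param counting_pixel_scale_um pixel size of the larger counting fields.
#' @param sing_weak_factor multiplicative thinning of the weak class in
#'   singing animals (Dir/Undir); the intense class is unaffected by singing.
#' @param motif_template ordered syllable labels of the long motif.
#' @param syntax_noise_eps probability that a syllable transition deviates
#'   from the template (skip or substitution, producing short motifs).
#' @param jitter_cv0,jitter_cv_floor,jitter_cv_k age function of the
#'   rendition-to-rendition feature CV:
#'   `cv(age) = floor + (cv0 - floor) * exp(-k * age)` (non-increasing).
#' @param bout_gap_s silent gap between generated bouts (must exceed 2 s).
#' @param inter_strophe_gap_s range of gaps between strophes within a bout.
#' @param intra_strophe_gap_ms gap between motifs within a strophe.
#' @param strophe_motifs range of motifs per strophe (default single-motif
#'   strophes, which makes noise-free syntax perfectly linear).
#' @param n_bouts bouts per generated corpus (>= 20).
#' @param motifs_per_bout range of motifs per bout.
#' @param motif3_lengthening duration factor applied to the third and later
#'   motifs of a bout.
#' @param motifs_sung_range range of motif counts for singers (>= 90).
#' @param brdu_odds_ratio odds ratio of BrdU labeling in intense vs weak
#'   cells.
#' @param brdu_rate_weak BrdU labeling rate among weak cells.
#' @param coloc_n_intense,coloc_n_weak cell counts per animal entering the
#'   colocalization table.
#' @param seed integer master seed; all randomness derives from it.
#'
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_animals = 4, seed = 1)
#' cfg$intense_mean_gray
#' @export
cohort_config <- function(
    n_animals = 26L,
    age_range_days = c(100, 3000),
    group_labels = c("NS0h", "NS2h", "Dir", "Undir"),
    intense_mean_gray = 80,
    weak_mean_gray = 170,
    fusiform_mean_gray = 100,
    component_sd_gray = 12,
    background_gray = 200,
    background_sd = 3,
    intense_fraction_Y0 = 0.40,
    intense_fraction_plateau = 0.03,
    intense_fraction_k = 0.004,
    fusiform_density_Y0 = 150,
    fusiform_density_plateau = 10,
    fusiform_density_k = 0.004,
    fusiform_density_outside = 40,
    round_density_mm2 = 1200,
    nuclei_per_intensity_field = c(20L, 30L),
    n_intensity_fields = c(6L, 8L),
    n_counting_fields = c(10L, 15L),
    n_background_fields = c(3L, 4L),
    n_outside_fields = c(4L, 6L),
    pixel_scale_um = 0.2,
    counting_pixel_scale_um = 0.4,
    sing_weak_factor = 0.6,
    motif_template = c("A", "B", "C", "D"),
    syntax_noise_eps = 0.05,
    jitter_cv0 = 0.12,
    jitter_cv_floor = 0.03,
    jitter_cv_k = 0.003,
    bout_gap_s = 3,
    inter_strophe_gap_s = c(0.4, 0.8),
    intra_strophe_gap_ms = 120,
    strophe_motifs = c(1L, 1L),
    n_bouts = 30L,
    motifs_per_bout = c(1L, 6L),
    motif3_lengthening = 1.05,
    motifs_sung_range = c(90L, 250L),
    brdu_odds_ratio = 5,
    brdu_rate_weak = 0.03,
    coloc_n_intense = 150L,
    coloc_n_weak = 1500L,
    seed = 1L) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot_scalar(intense_mean_gray, "intense_mean_gray", 0, 255)
    stopifnot_scalar(weak_mean_gray, "weak_mean_gray", 0, 255)
    stopifnot_scalar(fusiform_mean_gray, "fusiform_mean_gray", 0, 255)
    stopifnot_scalar(background_gray, "background_gray", 0, 255)
    stopifnot_scalar(background_sd, "background_sd", 0, 255)
    stopifnot_scalar(component_sd_gray, "component_sd_gray", 1e-9, 255)
    if (!(intense_mean_gray < weak_mean_gray &&
          weak_mean_gray < background_gray)) {
      stop("need intense_mean_gray < weak_mean_gray < background_gray ",
           "(darker stain = lower gray value)", call. = FALSE)
    }
    for (f in c("intense_fraction_Y0", "intense_fraction_plateau")) {
      stopifnot_scalar(get(f), f, 0, 1)
    }
    for (f in c("intense_fraction_k", "fusiform_density_k")) {
      stopifnot_scalar(get(f), f, 0, Inf)
    }
    stopifnot_scalar(syntax_noise_eps, "syntax_noise_eps", 0, 1)
    stopifnot_scalar(brdu_odds_ratio, "brdu_odds_ratio", 1e-12, Inf)
    stopifnot_scalar(brdu_rate_weak, "brdu_rate_weak", 0, 1)
    stopifnot_scalar(pixel_scale_um, "pixel_scale_um", 1e-3, 10)
    stopifnot_scalar(sing_weak_factor, "sing_weak_factor", 0, 1)
    if (jitter_cv_floor > jitter_cv0) {
      stop("jitter_cv_floor must not exceed jitter_cv0 ",
           "(feature CV is non-increasing in age)", call. = FALSE)
    }
    if (bout_gap_s <= 2) {
      stop("bout_gap_s must exceed the 2 s bout definition", call. = FALSE)
    }
    if (!length(motif_template)) stop("empty motif_template", call. = FALSE)
  })
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort config: %d animals, ages %g-%g PHD, seed %d\n",
    "  gray means (intense/weak/background): %g / %g / %g (sd %g)\n",
    "  intense fraction decay: Y0 = %g, plateau = %g, k = %g /day\n"),
    x$n_animals, x$age_range_days[1], x$age_range_days[2], x$seed,
    x$intense_mean_gray, x$weak_mean_gray, x$background_gray,
    x$component_sd_gray, x$intense_fraction_Y0, x$intense_fraction_plateau,
    x$intense_fraction_k))
  invisible(x)
}

# Intense fraction among round nuclei at a given age.
intense_fraction_at <- function(cfg, age_days) {
  one_phase_curve(age_days, cfg$intense_fraction_Y0,
                  cfg$intense_fraction_plateau, cfg$intense_fraction_k)
}

# Fusiform density (cells/mm^2) inside Area X at a given age.
fusiform_density_at <- function(cfg, age_days) {
  one_phase_curve(age_days, cfg$fusiform_density_Y0,
                  cfg$fusiform_density_plateau, cfg$fusiform_density_k)
}

# Rendition-to-rendition feature CV at a given age.
feature_jitter_cv_at <- function(cfg, age_days) {
  one_phase_curve(age_days, cfg$jitter_cv0, cfg$jitter_cv_floor,
                  cfg$jitter_cv_k)
}
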