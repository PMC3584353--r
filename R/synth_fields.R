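# Synthetic histology fields: rendered 8-bit grayscale rasters with known
# nucleus ground truth.
#
# Raster convention: matrices are indexed [x_px, y_px] (EBImage convention);
# the center of pixel (i, j) lies at ((i - 0.5), (j - 0.5)) * pixel_scale_um.

FIELD_GEOMETRY <- list(
  intensity_62x62um = c(62, 62),
  counting_128x162um = c(128, 162),
  background_62x62um = c(62, 62)
)

#' Construct a pixel field
#'
#' @param raster numeric matrix of 8-bit gray values, indexed `[x, y]`.
#' @param geometry one of `"intensity_62x62um"`, `"counting_128x162um"`,
#'   `"background_62x62um"`.
#' @param pixel_scale_um pixel size in micrometers.
#' @param region `"areax"`, `"striatum_outside"` or
#'   `"nidopallium_background"`.
#' @param field_id,animal_id,section_id identifiers.
#' @return An object of class `pixel_field`.
#' @export
pixel_field <- function(raster, geometry, pixel_scale_um, region,
                        field_id = NA_character_, animal_id = NA_character_,
                        section_id = NA_integer_) {
  geometry <- match.arg(geometry, names(FIELD_GEOMETRY))
  size_um <- FIELD_GEOMETRY[[geometry]]
  expected <- round(size_um / pixel_scale_um)
  if (!all(dim(raster) == expected)) {
    stop(sprintf("raster is %dx%d px but geometry %s at %g um/px needs %dx%d",
                 nrow(raster), ncol(raster), geometry, pixel_scale_um,
                 expected[1], expected[2]), call. = FALSE)
  }
  if (min(raster) < 0 || max(raster) > 255) {
    stop("gray values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(raster = raster, geometry = geometry,
                 pixel_scale_um = pixel_scale_um, region = region,
                 field_id = field_id, animal_id = animal_id,
                 section_id = section_id),
            class = "pixel_field")
}

#' @export
print.pixel_field <- function(x, ...) {
  cat(sprintf("Pixel field %s: %s (%s), %dx%d px at %g um/px\n",
              x$field_id, x$geometry, x$region, nrow(x$raster),
              ncol(x$raster), x$pixel_scale_um))
  invisible(x)
}

field_area_mm2 <- function(field) {
  prod(FIELD_GEOMETRY[[field$geometry]]) / 1e6
}

# Render one field: nuclei as anti-aliased discs/ellipses of their class
# gray on a noisy background canvas, quantized to 8-bit integers.
# nuclei: data frame with x_um, y_um, gray, a_um (semi-major), b_um
# (semi-minor), theta (radians). Uses the caller's RNG stream.
render_field <- function(geometry, pixel_scale_um, background_gray,
                         background_sd, nuclei) {
  size_um <- FIELD_GEOMETRY[[geometry]]
  nx <- round(size_um[1] / pixel_scale_um)
  ny <- round(size_um[2] / pixel_scale_um)
  canvas <- matrix(background_gray, nx, ny)
  if (nrow(nuclei)) {
    xs <- (seq_len(nx) - 0.5) * pixel_scale_um
    ys <- (seq_len(ny) - 0.5) * pixel_scale_um
    for (r in seq_len(nrow(nuclei))) {
      nu <- nuclei[r, ]
      half <- nu$a_um + 2 * pixel_scale_um
      ix <- which(xs >= nu$x_um - half & xs <= nu$x_um + half)
      iy <- which(ys >= nu$y_um - half & ys <= nu$y_um + half)
      if (!length(ix) || !length(iy)) next
      dx <- xs[ix] - nu$x_um
      dy <- ys[iy] - nu$y_um
      ct <- cos(nu$theta); st <- sin(nu$theta)
      u <- outer(dx, dy, function(px, py) px * ct + py * st) / nu$a_um
      v <- outer(dx, dy, function(px, py) -px * st + py * ct) / nu$b_um
      d <- sqrt(u^2 + v^2)
      # coverage ramps over ~1 px at the nucleus edge (anti-aliasing)
      cov <- pmin(pmax((1 - d) * nu$b_um / pixel_scale_um + 0.5, 0), 1)
      canvas[ix, iy] <- canvas[ix, iy] + (nu$gray - background_gray) * cov
    }
  }
  canvas <- canvas + rnorm(length(canvas), 0, background_sd)
  matrix(as.integer(pmin(pmax(round(canvas), 0), 255)), nx, ny)
}

# Rejection-sample nucleus centers with minimum separation of one nucleus
# diameter and a border margin. Returns a 2-column matrix; may place fewer
# than n if the field saturates.
place_centers <- function(n, size_um, min_sep_um, margin_um) {
  if (2 * margin_um >= min(size_um)) {
    stop("field smaller than one nucleus: invalid geometry", call. = FALSE)
  }
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 400L * n) {
    tries <- tries + 1L
    p <- c(runif(1, margin_um, size_um[1] - margin_um),
           runif(1, margin_um, size_um[2] - margin_um))
    if (!nrow(pts) ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep_um) {
      pts <- rbind(pts, p)
    }
  }
  pts
}

# Draw per-nucleus geometry and gray for a vector of classes.
draw_nuclei <- function(cfg, classes, centers) {
  n <- length(classes)
  if (!n) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      true_class = character(0), gray = numeric(0),
                      a_um = numeric(0), b_um = numeric(0),
                      theta = numeric(0), axis_ratio = numeric(0),
                      area_um2 = numeric(0)))
  }
  mean_gray <- c(intense = cfg$intense_mean_gray, weak = cfg$weak_mean_gray,
                 fusiform = cfg$fusiform_mean_gray)[classes]
  gray <- pmin(pmax(rnorm(n, mean_gray, cfg$component_sd_gray), 0), 255)
  fus <- classes == "fusiform"
  axis_ratio <- ifelse(fus, runif(n, 2.2, 3.0), runif(n, 1.0, 1.25))
  area <- ifelse(fus, runif(n, 20, 30), runif(n, 25, 38))
  a <- sqrt(area * axis_ratio / pi)
  data.frame(x_um = centers[, 1], y_um = centers[, 2],
             true_class = classes, gray = gray, a_um = a,
             b_um = a / axis_ratio, theta = runif(n, 0, 2 * pi),
             axis_ratio = axis_ratio, area_um2 = area)
}

# Generate one field plus its ground truth. class_counts is a named vector
# over intense/weak/fusiform.
gen_field <- function(cfg, geometry, pixel_scale_um, region, class_counts,
                      field_id, animal_id, section_id) {
  size_um <- FIELD_GEOMETRY[[geometry]]
  n <- sum(class_counts)
  classes <- rep(names(class_counts), class_counts)
  centers <- place_centers(n, size_um, min_sep_um = 7, margin_um = 4.5)
  classes <- classes[seq_len(nrow(centers))]
  if (length(classes)) classes <- sample(classes)   # shuffle spatial order
  nuclei <- draw_nuclei(cfg, classes, centers)
  raster <- render_field(geometry, pixel_scale_um, cfg$background_gray,
                         cfg$background_sd, nuclei)
  field <- pixel_field(raster, geometry, pixel_scale_um, region,
                       field_id, animal_id, section_id)
  truth <- if (nrow(nuclei)) {
    data.frame(field_id = field_id, animal_id = animal_id,
               nucleus_id = paste0(field_id, "_n", seq_len(nrow(nuclei))),
               nuclei[, c("x_um", "y_um", "true_class", "gray",
                          "axis_ratio", "area_um2")])
  } else {
    NULL
  }
  list(field = field, truth = truth)
}

#' Generate one synthetic animal
#'
#' Produces an animal record, its rendered fields (intensity fields of
#' 62x62 um with ~20-30 round nuclei each, counting fields of 128x162 um
#' inside and outside Area X, and nucleus-free background fields of
#' nidopallium), and the nucleus ground truth. The intense fraction among
#' round nuclei equals the configured one-phase decay evaluated at the
#' animal's age; singing animals (groups Dir/Undir) have their weak class
#' thinned by `sing_weak_factor`, leaving the intense class untouched.
#'
#' @param cfg a [cohort_config()].
#' @param animal_index index of the animal within the cohort.
#' @param rng_seed integer seed; the output is a pure function of
#'   `(cfg, animal_index, rng_seed)`.
#' @param age_days,group optional overrides; by default the group is cycled
#'   from `cfg$group_labels` by `animal_index` and the age drawn
#'   log-uniformly from `cfg$age_range_days` (colony cohorts skew young;
#'   juvenile groups are fixed at 35/50 post-hatch days).
#' @return List with `animal` (one-row data frame: `animal_id`, `age_days`,
#'   `group`, `motifs_sung`), `fields` (list of `pixel_field`) and `truth`
#'   (ground-truth data frame).
#' @examples
#' cfg <- cohort_config(n_animals = 1, n_intensity_fields = c(2, 2),
#'                      n_counting_fields = c(2, 2), seed = 1)
#' a <- gen_animal(cfg, 1, rng_seed = 42)
#' table(a$truth$true_class)
#' @export
gen_animal <- function(cfg, animal_index, rng_seed, age_days = NULL,
                       group = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(rng_seed, {
    group <- group %||%
      cfg$group_labels[(animal_index - 1L) %% length(cfg$group_labels) + 1L]
    # adult ages are drawn log-uniformly: cohorts skew young, and a decay
    # study needs the fast-changing young-adult range well sampled
    age_days <- age_days %||% switch(group,
      PHD35 = 35, PHD50 = 50,
      exp(runif(1, log(cfg$age_range_days[1]), log(cfg$age_range_days[2]))))
    singer_group <- group %in% c("Dir", "Undir")
    motifs_sung <- if (singer_group) {
      draw_count(cfg$motifs_sung_range)
    } else if (group %in% c("PHD35", "PHD50")) {
      NA_integer_
    } else {
      draw_count(c(0L, 5L))
    }
    animal_id <- sprintf("animal%03d", animal_index)
    f_int <- intense_fraction_at(cfg, age_days)
    thin <- if (singer_group) cfg$sing_weak_factor else 1

    fields <- list()
    truth <- list()
    fid <- 0L
    add <- function(geometry, scale, region, counts) {
      fid <<- fid + 1L
      id <- sprintf("%s_f%02d", animal_id, fid)
      out <- gen_field(cfg, geometry, scale, region, counts, id, animal_id,
                       section_id = fid)
      fields[[id]] <<- out$field
      if (!is.null(out$truth)) truth[[id]] <<- out$truth
    }

    for (i in seq_len(draw_count(cfg$n_intensity_fields))) {
      n <- draw_count(cfg$nuclei_per_intensity_field)
      n_intense <- rbinom(1L, n, f_int)
      n_weak <- rbinom(1L, n - n_intense, thin)
      add("intensity_62x62um", cfg$pixel_scale_um, "areax",
          c(intense = n_intense, weak = n_weak,
            fusiform = rpois(1L, 1)))
    }
    area_cnt <- prod(FIELD_GEOMETRY$counting_128x162um) / 1e6
    for (i in seq_len(draw_count(cfg$n_counting_fields))) {
      n <- rpois(1L, cfg$round_density_mm2 * area_cnt)
      n_intense <- rbinom(1L, n, f_int)
      n_weak <- rbinom(1L, n - n_intense, thin)
      add("counting_128x162um", cfg$counting_pixel_scale_um, "areax",
          c(intense = n_intense, weak = n_weak,
            fusiform = rpois(1L, fusiform_density_at(cfg, age_days) * area_cnt)))
    }
    for (i in seq_len(draw_count(cfg$n_outside_fields))) {
      n_weak <- rpois(1L, 0.6 * cfg$round_density_mm2 * area_cnt)
      add("counting_128x162um", cfg$counting_pixel_scale_um,
          "striatum_outside",
          c(intense = 0L, weak = n_weak,
            fusiform = rpois(1L, cfg$fusiform_density_outside * area_cnt)))
    }
    for (i in seq_len(draw_count(cfg$n_background_fields))) {
      add("background_62x62um", cfg$counting_pixel_scale_um,
          "nidopallium_background",
          c(intense = 0L, weak = 0L, fusiform = 0L))
    }

    list(
      animal = data.frame(animal_id = animal_id, age_days = age_days,
                          group = group, motifs_sung = motifs_sung),
      fields = fields,
      truth = do.call(rbind, c(truth, list(make.row.names = FALSE)))
    )
  })
}
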