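# Nucleus detection, windowed gray-value measurement, background
# estimation, the above-background exclusion rule, and areal densities.

#' Estimate background staining from nucleus-free regions
#'
#' The background gray value B is the arithmetic mean of the per-region
#' mean grays, measured over at least three nucleus-free regions
#' (nidopallium sampled in 3-4 sections).
#'
#' @param regions list of `pixel_field` objects (or plain rasters).
#' @return Object of class `background_estimate`: list with `B`,
#'   `n_regions`, `region_means`.
#' @examples
#' r <- replicate(3, matrix(200, 10, 10), simplify = FALSE)
#' estimate_background(r)$B
#' @export
estimate_background <- function(regions) {
  if (length(regions) < 3L) {
    stop("insufficient background: need at least 3 regions", call. = FALSE)
  }
  means <- vapply(regions, function(r) {
    mean(if (inherits(r, "pixel_field")) r$raster else r)
  }, numeric(1))
  structure(list(B = mean(means), n_regions = length(regions),
                 region_means = means),
            class = "background_estimate")
}

#' Detect nuclei in a field
#'
#' Thresholds the raster at `detect_frac * B` (nuclei are darker than
#' background), labels connected components (EBImage), and returns the
#' centroid, major/minor axis ratio and area of every component at least
#' `min_area_um2` large — nuclei substantially smaller than the measurement
#' window are not measured. Components touching the field border are kept
#' only if their centroid lies inside the field.
#'
#' @param field a `pixel_field`.
#' @param background a `background_estimate` (or a scalar B).
#' @param detect_frac pixels darker than `detect_frac * B` are candidate
#'   nucleus pixels (default 0.9, permissive enough to catch nuclei only
#'   5-10% below background).
#' @param min_area_um2 minimum component area (default 13).
#' @return Data frame with `x_um`, `y_um`, `axis_ratio`, `area_um2`, `n_px`.
#' @export
detect_nuclei <- function(field, background, detect_frac = 0.9,
                          min_area_um2 = 13) {
  B <- if (inherits(background, "background_estimate")) background$B
       else background
  if (!is.finite(B) || B <= 0) stop("background B must be > 0", call. = FALSE)
  if (detect_frac <= 0 || detect_frac >= 1) {
    stop("detect_frac must lie in (0, 1)", call. = FALSE)
  }
  raster <- field$raster
  scale <- field$pixel_scale_um
  mask <- raster < detect_frac * B
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      axis_ratio = numeric(0), area_um2 = numeric(0),
                      n_px = integer(0))
  if (!any(mask)) return(empty)
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(labels)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab_of <- labels[labels > 0]
  cx <- (idx[, 1] - 0.5) * scale
  cy <- (idx[, 2] - 0.5) * scale
  # per-component first and second moments, all vectorized over components
  npx <- tabulate(lab_of, nlab)
  sum_by <- function(v) {
    out <- numeric(nlab)
    out[sort(unique(lab_of))] <- rowsum(v, lab_of)[, 1L]
    out
  }
  mx <- sum_by(cx) / npx
  my <- sum_by(cy) / npx
  reg <- scale^2 / 12                 # finite-pixel regularization
  vxx <- sum_by(cx^2) / npx - mx^2 + reg
  vyy <- sum_by(cy^2) / npx - my^2 + reg
  vxy <- sum_by(cx * cy) / npx - mx * my
  half_tr <- (vxx + vyy) / 2
  disc <- sqrt(pmax(((vxx - vyy) / 2)^2 + vxy^2, 0))
  ev_max <- half_tr + disc
  ev_min <- pmax(half_tr - disc, 1e-12)
  out <- data.frame(x_um = mx, y_um = my,
                    axis_ratio = sqrt(ev_max / ev_min),
                    area_um2 = npx * scale^2, n_px = npx)
  out <- out[out$area_um2 >= min_area_um2, , drop = FALSE]
  if (!nrow(out)) return(empty)
  size_um <- FIELD_GEOMETRY[[field$geometry]]
  inside <- out$x_um > 0 & out$x_um < size_um[1] &
            out$y_um > 0 & out$y_um < size_um[2]
  out[inside, , drop = FALSE]
}

#' Measure the windowed gray value at a point
#'
#' Mean gray value over the pixels whose centers fall inside a circular
#' selection window of `window_area_um2` (default 12.9) centered at the
#' query point — small enough to fit within the perimeter of a nucleus.
#'
#' @param field a `pixel_field`.
#' @param center numeric `c(x_um, y_um)`.
#' @param window_area_um2 window area; the radius is
#'   `sqrt(window_area_um2 / pi)`.
#' @return Mean gray value.
#' @details Errors if the window extends beyond the raster; at pipeline
#'   level such nuclei are skipped with a warning.
#' @export
measure_gray <- function(field, center, window_area_um2 = 12.9) {
  scale <- field$pixel_scale_um
  r_um <- sqrt(window_area_um2 / pi)
  size_um <- dim(field$raster) * scale
  if (center[1] - r_um < 0 || center[1] + r_um > size_um[1] ||
      center[2] - r_um < 0 || center[2] + r_um > size_um[2]) {
    stop("measurement window extends beyond the raster", call. = FALSE)
  }
  ix <- which(abs((seq_len(nrow(field$raster)) - 0.5) * scale - center[1]) <= r_um)
  iy <- which(abs((seq_len(ncol(field$raster)) - 0.5) * scale - center[2]) <= r_um)
  dx <- (ix - 0.5) * scale - center[1]
  dy <- (iy - 0.5) * scale - center[2]
  inside <- outer(dx^2, dy^2, "+") <= r_um^2
  mean(field$raster[ix, iy][inside])
}

#' Apply the 5%-above-background exclusion
#'
#' Fusiform-shaped nuclei are first routed out (they are excluded from the
#' intensity analysis and counted separately); among round nuclei, a
#' measurement is removed iff its staining signal `B - g` is at most
#' `min_stain_frac * B` — i.e. the nucleus is stained at background level
#' or only marginally above it. Setting `min_stain_frac = 0` keeps every
#' above-background nucleus (the sensitivity setting).
#'
#' @param nuclei data frame of measurements with columns `gray_value` and
#'   `shape` (`"round"`/`"fusiform"`).
#' @param background a `background_estimate` or scalar B (> 0).
#' @param min_stain_frac exclusion threshold as a fraction of B
#'   (default 0.05).
#' @return List with `kept`, `removed` (round nuclei partitioned by the
#'   rule) and `fusiform`.
#' @export
filter_measurements <- function(nuclei, background, min_stain_frac = 0.05) {
  B <- if (inherits(background, "background_estimate")) background$B
       else background
  if (!is.finite(B) || B <= 0) stop("background B must be > 0", call. = FALSE)
  fus <- nuclei$shape == "fusiform"
  round_n <- nuclei[!fus, , drop = FALSE]
  drop <- (B - round_n$gray_value) <= min_stain_frac * B
  list(kept = round_n[!drop, , drop = FALSE],
       removed = round_n[drop, , drop = FALSE],
       fusiform = nuclei[fus, , drop = FALSE])
}

#' Compute class densities over sampled fields
#'
#' Areal densities (cells per mm^2 of sampled field area) per staining
#' class, plus the inside:outside ratio of fusiform-cell density when
#' fields from both regions are supplied.
#'
#' @param counts named counts over classes (e.g. `c(intense = 4)`).
#' @param fields list of the `pixel_field`s the counts were collected in.
#' @param outside_counts,outside_fields optional counts/fields from the
#'   striatum outside Area X, enabling the fusiform density ratio.
#' @return Object of class `density_report`: counts, total areas (mm^2),
#'   `density` (per class), and `fusiform_inside_outside_ratio` (`NA` with
#'   a flag when the outside density is zero or unsampled).
#' @examples
#' f <- pixel_field(matrix(200L, 320, 405), "counting_128x162um", 0.4, "areax")
#' compute_density(c(intense = 4), list(f))$density  # 4 / 0.020736 mm^2
#' @export
compute_density <- function(counts, fields, outside_counts = NULL,
                            outside_fields = NULL) {
  if (!length(fields)) stop("need at least one counting field", call. = FALSE)
  area <- sum(vapply(fields, field_area_mm2, numeric(1)))
  if (area <= 0) stop("zero total sampled area", call. = FALSE)
  dens <- counts / area
  ratio <- NA_real_
  ratio_defined <- FALSE
  if (!is.null(outside_fields) && length(outside_fields)) {
    area_out <- sum(vapply(outside_fields, field_area_mm2, numeric(1)))
    d_out <- (outside_counts[["fusiform"]] %||% 0) / area_out
    if (d_out > 0) {
      ratio <- (counts[["fusiform"]] %||% 0) / area / d_out
      ratio_defined <- TRUE
    }
  }
  structure(list(counts = counts, total_area_mm2 = area, density = dens,
                 fusiform_inside_outside_ratio = ratio,
                 ratio_defined = ratio_defined),
            class = "density_report")
}

#' Detect and measure every nucleus in a field
#'
#' Composition of [detect_nuclei()] and [measure_gray()]: detects
#' components, assigns shape from the axis ratio (`>= shape_threshold` is
#' fusiform), and measures the windowed gray value of each nucleus; nuclei
#' whose measurement window would leave the raster are skipped with a
#' warning.
#'
#' @param field a `pixel_field`.
#' @param background a `background_estimate` or scalar B.
#' @param detect_frac threshold fraction for [detect_nuclei()].
#' @param shape_threshold axis ratio at or above which a nucleus is
#'   fusiform (default 2).
#' @param window_area_um2 measurement window area.
#' @return Data frame of nucleus measurements (`nucleus_id`, `field_id`,
#'   `region`, `geometry`, `x_um`, `y_um`, `gray_value`, `axis_ratio`,
#'   `area_um2`, `shape`).
#' @export
measure_field <- function(field, background, detect_frac = 0.9,
                          shape_threshold = 2, window_area_um2 = 12.9) {
  det <- detect_nuclei(field, background, detect_frac)
  if (!nrow(det)) {
    return(data.frame(nucleus_id = character(0), field_id = character(0),
                      region = character(0), geometry = character(0),
                      x_um = numeric(0), y_um = numeric(0),
                      gray_value = numeric(0), axis_ratio = numeric(0),
                      area_um2 = numeric(0), shape = character(0)))
  }
  gray <- rep(NA_real_, nrow(det))
  skipped <- 0L
  for (i in seq_len(nrow(det))) {
    gray[i] <- tryCatch(
      measure_gray(field, c(det$x_um[i], det$y_um[i]), window_area_um2),
      error = function(e) { skipped <<- skipped + 1L; NA_real_ })
  }
  if (skipped) {
    warning(sprintf("%d nucle%s skipped: measurement window out of bounds",
                    skipped, if (skipped == 1L) "us" else "i"))
  }
  out <- data.frame(
    nucleus_id = paste0(field$field_id, "_d", seq_len(nrow(det))),
    field_id = field$field_id, region = field$region,
    geometry = field$geometry, x_um = det$x_um, y_um = det$y_um,
    gray_value = gray, axis_ratio = det$axis_ratio,
    area_um2 = det$area_um2,
    shape = ifelse(det$axis_ratio >= shape_threshold, "fusiform", "round"))
  out[!is.na(out$gray_value), , drop = FALSE]
}
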