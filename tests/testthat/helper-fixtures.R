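# Shared fixtures: small, fast cohort configurations used across tests.

# A cohort config with few, coarse fields so rendering stays cheap.
fast_cfg <- function(...) {
  defaults <- list(
    n_animals = 2,
    n_intensity_fields = c(3, 3),
    n_counting_fields = c(2, 2),
    n_outside_fields = c(1, 1),
    n_background_fields = c(3, 3),
    pixel_scale_um = 0.4,
    counting_pixel_scale_um = 0.5,
    seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# A uniform raster wrapped as an intensity pixel field.
uniform_field <- function(gray, pixel_scale_um = 0.5,
                          geometry = "intensity_62x62um") {
  size <- round(c(62, 62) / pixel_scale_um)
  pixel_field(matrix(gray, size[1], size[2]), geometry, pixel_scale_um,
              region = "areax", field_id = "test_field")
}

# Render a field containing the given nuclei (data frame with x_um, y_um,
# gray, a_um, b_um, theta) without pixel noise.
noiseless_field <- function(nuclei, background_gray = 200,
                            pixel_scale_um = 0.2,
                            geometry = "intensity_62x62um") {
  raster <- stainmix:::render_field(geometry, pixel_scale_um,
                                    background_gray, 0, nuclei)
  pixel_field(raster, geometry, pixel_scale_um, region = "areax",
              field_id = "noiseless")
}

# Pre-measured nucleus table from generator ground truth: every generated
# nucleus with its true gray value, as a human observer could measure it.
truth_measurements <- function(truth, fields) {
  geom <- vapply(fields, function(f) f$geometry, character(1))
  region <- vapply(fields, function(f) f$region, character(1))
  data.frame(
    nucleus_id = truth$nucleus_id,
    field_id = truth$field_id,
    region = region[match(truth$field_id, names(fields))],
    geometry = geom[match(truth$field_id, names(fields))],
    x_um = truth$x_um, y_um = truth$y_um,
    gray_value = truth$gray,
    axis_ratio = truth$axis_ratio,
    area_um2 = truth$area_um2,
    shape = ifelse(truth$true_class == "fusiform", "fusiform", "round"))
}

# Build a syllable event table from label sequences and gaps; gaps[i] is
# the silence before sequence element i+1 (seconds). Feature columns are
# filled with label-deterministic values.
events_from_labels <- function(labels, gaps, dur_s = 0.1) {
  onsets <- numeric(length(labels))
  t <- 0
  for (i in seq_along(labels)) {
    onsets[i] <- t
    t <- t + dur_s + if (i <= length(gaps)) gaps[i] else 0
  }
  base <- stainmix:::syllable_baselines(sort(unique(labels)))
  ev <- data.frame(label = labels, onset_s = onsets,
                   offset_s = onsets + dur_s)
  for (f in stainmix:::SONG_FEATURES) {
    ev[[f]] <- base[[f]][match(labels, base$label)]
  }
  ev$duration_ms <- dur_s * 1000
  ev
}
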