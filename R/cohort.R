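# Cohort assembly and plain-text/PNG serialization.

#' Simulate a full synthetic cohort
#'
#' Generates every animal ([gen_animal()]), song corpora for adult animals
#' ([gen_song_corpus()]) and per-animal BrdU colocalization tables
#' ([gen_colocalization()]). All randomness derives from `cfg$seed`; the
#' result is a pure function of the configuration.
#'
#' @param cfg a [cohort_config()].
#' @param include_songs,include_coloc stage toggles.
#' @return Object of class `cohort`: list with `config`, `animals` (data
#'   frame), `fields` (named list of `pixel_field`), `truth` (ground-truth
#'   data frame), `songs` (named list of event data frames) and `coloc`
#'   (named list of 2x2 matrices).
#' @examples
#' cfg <- cohort_config(n_animals = 2, n_intensity_fields = c(2, 2),
#'                      n_counting_fields = c(2, 2), n_outside_fields = c(1, 1),
#'                      seed = 3)
#' co <- simulate_cohort(cfg, include_songs = FALSE, include_coloc = FALSE)
#' co$animals
#' @export
simulate_cohort <- function(cfg, include_songs = TRUE, include_coloc = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  animals <- list(); fields <- list(); truth <- list()
  songs <- list(); coloc <- list()
  for (i in seq_len(cfg$n_animals)) {
    a <- gen_animal(cfg, i, rng_seed = derive_seed(cfg$seed, i))
    animals[[i]] <- a$animal
    fields <- c(fields, a$fields)
    truth[[i]] <- a$truth
    id <- a$animal$animal_id
    if (include_songs && !a$animal$group %in% c("PHD35", "PHD50")) {
      songs[[id]] <- gen_song_corpus(cfg, a$animal$age_days,
                                     rng_seed = derive_seed(cfg$seed, 10000 + i))
    }
    if (include_coloc) {
      coloc[[id]] <- gen_colocalization(cfg$coloc_n_intense, cfg$coloc_n_weak,
                                        cfg$brdu_rate_weak,
                                        cfg$brdu_odds_ratio,
                                        rng_seed = derive_seed(cfg$seed,
                                                               20000 + i))
    }
  }
  structure(list(config = cfg,
                 animals = do.call(rbind, animals),
                 fields = fields,
                 truth = do.call(rbind, truth),
                 songs = songs, coloc = coloc),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals, %d fields, %d nuclei, %d song corpora\n",
              nrow(x$animals), length(x$fields), nrow(x$truth),
              length(x$songs)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Serializes fields as 8-bit grayscale PNGs plus a manifest CSV, the
#' ground truth, animal table and song corpora as CSVs, and the
#' configuration as JSON.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fields"), showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(cohort$fields, function(f) {
    path <- file.path("fields", paste0(f$field_id, ".png"))
    # PNG convention: [row, col] = [y, x]; transpose our [x, y] raster
    png::writePNG(t(f$raster) / 255, file.path(dir, path))
    data.frame(field_id = f$field_id, animal_id = f$animal_id,
               geometry = f$geometry, region = f$region,
               pixel_scale_um = f$pixel_scale_um,
               section_id = f$section_id, path = path)
  }))
  write.csv(manifest, file.path(dir, "fields_manifest.csv"),
            row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  write.csv(cohort$animals, file.path(dir, "animals.csv"), row.names = FALSE)
  if (length(cohort$songs)) {
    songs <- do.call(rbind, lapply(names(cohort$songs), function(id) {
      cbind(animal_id = id, cohort$songs[[id]])
    }))
    write.csv(songs, file.path(dir, "songs.csv"), row.names = FALSE)
  }
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read cohort fields back from a manifest
#'
#' @param dir directory written by [write_cohort()].
#' @return Named list of `pixel_field` objects.
#' @export
read_cohort_fields <- function(dir) {
  manifest <- read.csv(file.path(dir, "fields_manifest.csv"))
  fields <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    img <- png::readPNG(file.path(dir, m$path))
    pixel_field(round(t(img) * 255), m$geometry, m$pixel_scale_um, m$region,
                m$field_id, m$animal_id, m$section_id)
  })
  names(fields) <- manifest$field_id
  fields
}
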