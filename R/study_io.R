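#' Study file formats and small study-design computations
#'
#' CSV dialects for exchanging a study dataset (birds, section metadata,
#' counted markers, and long-format contour vertices), plus the dose-
#' conversion and BrdU-timeline arithmetic of the study design. Coordinates
#' are stored at 0.01 um precision; write-then-read round-trips are lossless
#' at that precision.
#'
#' @name study_interface
NULL

PHENOTYPES <- c("BRDU_HU", "HU_ONLY", "DCX")

#' Dose specification
#'
#' @param animal_dose_mg_kg administered animal dose, mg/kg.
#' @param species_factor body-surface-area conversion factor to a human
#'   equivalent dose (mouse-equivalent 0.08).
#' @param child_dose_range clinical child dose range `c(low, high)`, mg/kg.
#' @return a `dose_spec` list.
#' @export
dose_spec <- function(animal_dose_mg_kg = 40, species_factor = 0.08,
                      child_dose_range = c(0.5, 1.0)) {
  if (animal_dose_mg_kg <= 0) stop("non-positive animal dose")
  stopifnot(species_factor > 0, species_factor <= 1, all(child_dose_range > 0))
  structure(list(animal_dose_mg_kg = animal_dose_mg_kg,
                 species_factor = species_factor,
                 child_dose_range = child_dose_range), class = "dose_spec")
}

#' Human-equivalent dose
#'
#' Animal dose times the species body-surface-area factor (40 mg/kg x 0.08 =
#' 3.2 mg/kg with the defaults).
#'
#' @param d a [dose_spec].
#' @return human-equivalent dose, mg/kg.
#' @export
human_equivalent_dose <- function(d) {
  stopifnot(inherits(d, "dose_spec"))
  d$animal_dose_mg_kg * d$species_factor
}

#' Ratio of the human-equivalent dose to the child dose range
#'
#' @param d a [dose_spec].
#' @return named numeric `c(ratio_low, ratio_high)`: the human-equivalent
#'   dose divided by the low and high ends of the child range.
#' @export
dose_ratio_to_child_range <- function(d) {
  stopifnot(inherits(d, "dose_spec"))
  if (any(d$child_dose_range == 0)) stop("zero child dose range bound")
  hed <- human_equivalent_dose(d)
  c(ratio_low = hed / d$child_dose_range[1L],
    ratio_high = hed / d$child_dose_range[2L])
}

#' BrdU injection schedule
#'
#' @param injection_day_offsets days before perfusion on which injections were
#'   given (consecutive positive integers; default 30, 31, 32).
#' @param injections_per_day injections per day (3).
#' @return a `brdu_schedule` list.
#' @export
brdu_schedule <- function(injection_day_offsets = c(30, 31, 32),
                          injections_per_day = 3L) {
  if (length(injection_day_offsets) == 0) stop("empty BrdU schedule")
  off <- sort(injection_day_offsets)
  stopifnot(all(off > 0))
  if (length(off) > 1 && any(diff(off) != 1)) {
    stop("injection day offsets must be consecutive")
  }
  structure(list(injection_day_offsets = off,
                 injections_per_day = injections_per_day),
            class = "brdu_schedule")
}

#' Cell-age window implied by a BrdU schedule
#'
#' Cells labeled on day `k` before perfusion are `k` days old at perfusion,
#' so the schedule's offsets bound the birthdated cells' ages.
#'
#' @param s a [brdu_schedule].
#' @return named numeric `c(min_age_days, max_age_days)`.
#' @export
brdu_age_window <- function(s) {
  stopifnot(inherits(s, "brdu_schedule"))
  c(min_age_days = min(s$injection_day_offsets),
    max_age_days = max(s$injection_day_offsets))
}

COORD_DIGITS <- 2L   # 0.01 um declared precision

contours_long <- function(study) {
  rows <- list()
  sec <- study$sections
  for (i in seq_len(nrow(sec))) {
    v <- sec$outline[[i]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      bird_id = sec$bird_id[i],
      group = study$birds$group[match(sec$bird_id[i], study$birds$bird_id)],
      region = sec$region[i], section_index = sec$section_index[i],
      cell_id = "REGION", phenotype = "REGION",
      vertex_index = seq_len(nrow(v)), x_um = v[, 1L], y_um = v[, 2L])
  }
  cl <- study$cells
  for (i in seq_len(nrow(cl))) {
    v <- cl$contour[[i]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      bird_id = cl$bird_id[i],
      group = study$birds$group[match(cl$bird_id[i], study$birds$bird_id)],
      region = cl$region[i], section_index = cl$section_index[i],
      cell_id = cl$cell_id[i], phenotype = cl$phenotype[i],
      vertex_index = seq_len(nrow(v)), x_um = v[, 1L], y_um = v[, 2L])
  }
  out <- dplyr::bind_rows(rows)
  out$x_um <- round(out$x_um, COORD_DIGITS)
  out$y_um <- round(out$y_um, COORD_DIGITS)
  out
}

#' Write a study dataset to a directory of CSV files
#'
#' Emits `birds.csv`, `sections.csv`, `markers.csv`, `cells.csv`,
#' `contours.csv` (long format: one row per vertex; region outlines carry
#' `cell_id = "REGION"`), and `truth.json` (seed and per-bird generative
#' parameters when present). Coordinates are rounded to 0.01 um.
#'
#' @param study a `study_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$birds, file.path(dir, "birds.csv"))
  sec <- study$sections[, c("bird_id", "region", "section_index", "thickness_um",
                            "sampling_interval", "lateral_position_um")]
  readr::write_csv(sec, file.path(dir, "sections.csv"))
  mk <- study$markers
  mk$x_um <- round(mk$x_um, COORD_DIGITS); mk$y_um <- round(mk$y_um, COORD_DIGITS)
  readr::write_csv(mk, file.path(dir, "markers.csv"))
  cl <- study$cells[, c("bird_id", "region", "section_index", "cell_id",
                        "phenotype", "x_um", "y_um")]
  cl$x_um <- round(cl$x_um, COORD_DIGITS); cl$y_um <- round(cl$y_um, COORD_DIGITS)
  readr::write_csv(cl, file.path(dir, "cells.csv"))
  readr::write_csv(contours_long(study), file.path(dir, "contours.csv"))
  truth <- list(seed = study$seed,
                deltas = study$effects$deltas,
                bird_params = study$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing study file: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s: missing column(s) %s",
                 basename(path), paste(missing, collapse = ", ")))
  }
  df
}

#' Read a study dataset from a directory of CSV files
#'
#' Reads the dialect written by [write_study], validating the schema
#' (required columns per file), the controlled phenotype vocabulary, contour
#' validity (every outline and cell contour is normalized and must be simple
#' with positive area), and that every marker and cell position lies inside
#' its section's region outline. Violations raise errors naming the file and
#' offending records.
#'
#' @param dir directory holding the study CSV files.
#' @return a `study_dataset`.
#' @export
read_study <- function(dir) {
  birds <- read_checked(file.path(dir, "birds.csv"),
                        c("bird_id", "group", "age_at_treatment_start_d",
                          "treatment_duration_d", "age_at_first_brdu_d",
                          "age_at_perfusion_d"))
  if (!all(birds$group %in% c("statin", "control"))) {
    stop("schema error in birds.csv: group must be 'statin' or 'control'")
  }
  sections <- read_checked(file.path(dir, "sections.csv"),
                           c("bird_id", "region", "section_index", "thickness_um",
                             "sampling_interval", "lateral_position_um"))
  markers <- read_checked(file.path(dir, "markers.csv"),
                          c("bird_id", "region", "section_index", "cell_id",
                            "phenotype", "x_um", "y_um"))
  bad <- !markers$phenotype %in% PHENOTYPES
  if (any(bad)) {
    stop(sprintf("validation error in markers.csv: unknown phenotype '%s' (row %d)",
                 markers$phenotype[which(bad)[1L]], which(bad)[1L]))
  }
  cells_tab <- read_checked(file.path(dir, "cells.csv"),
                            c("bird_id", "region", "section_index", "cell_id",
                              "phenotype", "x_um", "y_um"))
  bad <- !cells_tab$phenotype %in% PHENOTYPES
  if (any(bad)) {
    stop(sprintf("validation error in cells.csv: unknown phenotype '%s' (row %d)",
                 cells_tab$phenotype[which(bad)[1L]], which(bad)[1L]))
  }
  contours <- read_checked(file.path(dir, "contours.csv"),
                           c("bird_id", "region", "section_index", "cell_id",
                             "phenotype", "vertex_index", "x_um", "y_um"))

  key <- function(b, r, s) paste(b, r, s, sep = "|")
  contours <- contours[order(contours$bird_id, contours$region,
                             contours$section_index, contours$cell_id,
                             contours$vertex_index), ]
  is_region <- contours$cell_id == "REGION"
  outline_tab <- contours[is_region, ]
  cell_tab <- contours[!is_region, ]

  build_contours <- function(tab, what) {
    sp <- split(seq_len(nrow(tab)),
                paste(tab$bird_id, tab$region, tab$section_index, tab$cell_id,
                      sep = "|"))
    lapply(sp, function(ix) {
      tryCatch(normalize_contour(cbind(tab$x_um[ix], tab$y_um[ix])),
               error = function(e) {
                 stop(sprintf("validation error in contours.csv: %s '%s': %s",
                              what, sub(".*\\|", "", paste(tab$bird_id[ix[1]],
                                                           tab$cell_id[ix[1]])),
                              conditionMessage(e)), call. = FALSE)
               })
    })
  }
  outls <- build_contours(outline_tab, "region outline")
  # key outlines by section (drop the trailing "REGION" id)
  names(outls) <- vapply(strsplit(names(outls), "\\|", fixed = FALSE), function(p) {
    paste(p[1L], p[2L], p[3L], sep = "|")
  }, "")
  outline_of <- outls[key(sections$bird_id, sections$region, sections$section_index)]
  if (any(vapply(outline_of, is.null, TRUE))) {
    miss <- which(vapply(outline_of, is.null, TRUE))[1L]
    stop(sprintf("validation error in contours.csv: no REGION outline for %s %s section %d",
                 sections$bird_id[miss], sections$region[miss],
                 sections$section_index[miss]))
  }
  sections$outline <- unname(outline_of)
  sections$area_um2 <- vapply(sections$outline, contour_area, 0)

  # every marker must lie inside its section outline
  mk_key <- key(markers$bird_id, markers$region, markers$section_index)
  sec_key <- key(sections$bird_id, sections$region, sections$section_index)
  for (k in unique(mk_key)) {
    si <- match(k, sec_key)
    if (is.na(si)) stop("validation error in markers.csv: marker references unknown section ", k)
    ix <- which(mk_key == k)
    ok <- point_in_contour(markers$x_um[ix], markers$y_um[ix], sections$outline[[si]])
    if (!all(ok)) {
      stop(sprintf("validation error in markers.csv: cell '%s' lies outside its section outline (%s)",
                   markers$cell_id[ix[!ok][1L]], k))
    }
  }

  cell_contours <- build_contours(cell_tab, "cell")
  cid <- paste(cells_tab$bird_id, cells_tab$region, cells_tab$section_index,
               cells_tab$cell_id, sep = "|")
  cells_tab$contour <- cell_contours[cid]
  if (any(vapply(cells_tab$contour, is.null, TRUE))) {
    miss <- which(vapply(cells_tab$contour, is.null, TRUE))[1L]
    stop(sprintf("validation error: no contour for traced cell '%s'",
                 cells_tab$cell_id[miss]))
  }

  truth <- NULL; seed <- NA_integer_; effects <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- tibble::as_tibble(tr$bird_params)
    seed <- tr$seed
  }
  structure(list(birds = birds, sections = sections, markers = markers,
                 cells = cells_tab, truth = truth, seed = seed,
                 effects = effects),
            class = "study_dataset")
}
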