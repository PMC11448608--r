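#' Organ-label synonym map
#'
#' The default normalization vocabulary: names are case-folded input labels,
#' values are canonical organ labels. Users may extend or override it via the
#' `synonyms` argument of [normalize_organ()] and [read_biodist()]. Labels
#' absent from the vocabulary pass through unchanged (case-folded and
#' trimmed) with a log message, never an error, so unusual tissues do not
#' block an analysis.
#'
#' @format Named character vector.
#' @export
organ_synonyms <- c(
  "kidneys"        = "kidney",
  "kidney"         = "kidney",
  "tumour"         = "tumor",
  "tumor"          = "tumor",
  "blood"          = "blood",
  "liver"          = "liver",
  "spleen"         = "spleen",
  "muscle"         = "muscle",
  "bone"           = "bone",
  "femur"          = "bone",
  "heart"          = "heart",
  "lung"           = "lung",
  "lungs"          = "lung",
  "stomach"        = "stomach",
  "intestine"      = "intestine",
  "intestines"     = "intestine",
  "small intestine" = "intestine",
  "pancreas"       = "pancreas",
  "skin"           = "skin",
  "brain"          = "brain",
  "bladder"        = "bladder",
  "salivary glands" = "salivary glands",
  "lymph nodes"    = "lymph nodes"
)

#' Normalize organ labels
#'
#' Case-folds, trims whitespace and maps synonyms ("Kidneys" -> "kidney",
#' "Tumour" -> "tumor") onto canonical labels. Idempotent:
#' `normalize_organ(normalize_organ(x))` equals `normalize_organ(x)`.
#' Unknown labels pass through (folded) with a log message.
#'
#' @param x Character vector of organ labels.
#' @param synonyms Named character vector mapping folded labels to canonical
#'   ones; defaults to [organ_synonyms].
#' @return Character vector of canonical labels, same length as `x`.
#' @export
#' @examples
#' normalize_organ(c("Kidneys", " Tumour", "blood"))
normalize_organ <- function(x, synonyms = organ_synonyms) {
  folded <- trimws(tolower(as.character(x)))
  hit <- folded %in% names(synonyms)
  out <- folded
  out[hit] <- unname(synonyms[folded[hit]])
  unknown <- unique(folded[!hit & !folded %in% unname(synonyms)])
  if (length(unknown) > 0) {
    cd_log("organ label(s) not in vocabulary, passed through: %s",
           paste(unknown, collapse = ", "))
  }
  out
}

biodist_columns <- c("cohort_id", "organ", "time_h", "animal_id",
                     "pct_ia_per_g")

new_biodist_study <- function(measurements, radionuclide,
                              injected_activity_MBq = NA_real_,
                              injected_mass_ug = NA_real_,
                              lag_time_h = NA_real_,
                              decay_corrected = TRUE,
                              provenance = character()) {
  structure(
    as_tibble(measurements),
    radionuclide = radionuclide,
    injected_activity_MBq = injected_activity_MBq,
    injected_mass_ug = injected_mass_ug,
    lag_time_h = lag_time_h,
    decay_corrected = decay_corrected,
    provenance = provenance,
    class = c("biodist_study", class(as_tibble(measurements)))
  )
}

#' Assemble a biodistribution study
#'
#' Builds the validated study container from a long-format per-animal
#' measurement table. A study is a tibble of measurements (one row per
#' animal x organ x time) carrying study-level metadata as attributes:
#' the radionuclide, injected activity and mass, the lag time for two-step
#' (pretargeting) studies, a `decay_corrected` flag and free-text provenance.
#'
#' Times are hours post radioligand injection; for pretargeting studies the
#' clock starts at the radioligand (tetrazine) injection, not the vector
#' injection, because that is the clock cumulated-activity integration uses.
#'
#' @param measurements Data frame with columns `cohort_id`, `organ`,
#'   `time_h`, `animal_id`, `pct_ia_per_g`.
#' @param radionuclide A [radionuclide()] object; defaults to [lu177()].
#' @param injected_activity_MBq,injected_mass_ug Dose metadata (optional).
#' @param lag_time_h Lag between vector and radioligand injection in hours;
#'   `NA` for one-step studies.
#' @param decay_corrected Logical: are the `%IA/g` values decay-corrected to
#'   injection time? Biodistribution tables rarely state this; the flag
#'   travels with the data and [apply_physical_decay()] consumes it.
#' @param provenance Character notes on data origin.
#' @param synonyms Organ synonym map passed to [normalize_organ()].
#'
#' @return A `biodist_study` object (a tibble with metadata attributes).
#' @export
biodist_study <- function(measurements, radionuclide = lu177(),
                          injected_activity_MBq = NA_real_,
                          injected_mass_ug = NA_real_,
                          lag_time_h = NA_real_,
                          decay_corrected = TRUE,
                          provenance = character(),
                          synonyms = organ_synonyms) {
  measurements <- as_tibble(measurements)
  missing_cols <- setdiff(biodist_columns, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is_radionuclide(radionuclide)) {
    stop("`radionuclide` must be a radionuclide object (see `radionuclide()`).",
         call. = FALSE)
  }
  m <- measurements[biodist_columns]
  m$cohort_id <- as.character(m$cohort_id)
  m$animal_id <- as.character(m$animal_id)
  m$organ <- normalize_organ(m$organ, synonyms)
  m$time_h <- as.numeric(m$time_h)
  m$pct_ia_per_g <- as.numeric(m$pct_ia_per_g)

  bad <- which(!is.finite(m$pct_ia_per_g) | m$pct_ia_per_g < 0)
  if (length(bad) > 0) {
    stop("pct_ia_per_g must be finite and non-negative; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad_t <- which(!is.finite(m$time_h) | m$time_h < 0)
  if (length(bad_t) > 0) {
    stop("time_h must be finite and non-negative; offending row(s): ",
         paste(utils::head(bad_t, 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(m$cohort_id, m$organ, m$time_h, m$animal_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (cohort, organ, time, animal) measurement(s); row(s): ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  }
  new_biodist_study(m, radionuclide, injected_activity_MBq, injected_mass_ug,
                    lag_time_h, decay_corrected, provenance)
}

#' @export
print.biodist_study <- function(x, ...) {
  nuc <- attr(x, "radionuclide")
  cat(sprintf(
    "<biodist_study> %d measurements | %d cohort(s) x %d organ(s) | %s | %s\n",
    nrow(x), length(unique(x$cohort_id)), length(unique(x$organ)),
    if (is.null(nuc)) "no nuclide" else nuc$name,
    if (isTRUE(attr(x, "decay_corrected"))) "decay-corrected"
    else "physical activity"
  ))
  NextMethod()
}

#' Read a biodistribution table
#'
#' Reads a delimited per-animal biodistribution file into a validated
#' [biodist_study()]. The file must carry the columns `cohort_id`, `organ`,
#' `time_h`, `animal_id`, `pct_ia_per_g` (any order; comma or tab delimited;
#' decimal point only). Study metadata (radionuclide, injected activity/mass,
#' lag time, decay-correction flag) comes from `metadata`, either a named
#' list or a path to a YAML file with keys `radionuclide`
#' (`name`/`half_life_h`/`mean_energy_per_decay_keV`),
#' `injected_activity_MBq`, `injected_mass_ug`, `lag_time_h`,
#' `decay_corrected`, `provenance`.
#'
#' @param path File path of the measurement table.
#' @param metadata Named list or YAML file path; see Details. Missing keys
#'   fall back to defaults (^177Lu, decay-corrected, no lag).
#' @param synonyms Organ synonym map.
#' @return A `biodist_study`.
#' @seealso [write_biodist()], [read_biodist_summary()]
#' @export
read_biodist <- function(path, metadata = list(), synonyms = organ_synonyms) {
  meta <- resolve_metadata(metadata)
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(biodist_columns, names(tab))
  if (length(missing_cols) > 0) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cd_log("read %d measurements from %s", nrow(tab), path)
  biodist_study(tab,
    radionuclide = meta$radionuclide,
    injected_activity_MBq = meta$injected_activity_MBq,
    injected_mass_ug = meta$injected_mass_ug,
    lag_time_h = meta$lag_time_h,
    decay_corrected = meta$decay_corrected,
    provenance = meta$provenance,
    synonyms = synonyms
  )
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

resolve_metadata <- function(metadata) {
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- yaml::read_yaml(metadata)
  }
  if (!is.list(metadata)) {
    stop("`metadata` must be a named list or a YAML file path.", call. = FALSE)
  }
  nuc <- metadata$radionuclide
  if (is.null(nuc)) {
    nuc <- lu177()
  } else if (!is_radionuclide(nuc)) {
    nuc <- radionuclide(nuc$name %||% "Lu-177",
                        nuc$half_life_h %||% nuclear_constants$lu177_half_life_h,
                        nuc$mean_energy_per_decay_keV %||%
                          nuclear_constants$lu177_mean_energy_keV)
  }
  list(
    radionuclide = nuc,
    injected_activity_MBq = as.numeric(metadata$injected_activity_MBq %||% NA),
    injected_mass_ug = as.numeric(metadata$injected_mass_ug %||% NA),
    lag_time_h = as.numeric(metadata$lag_time_h %||% NA),
    decay_corrected = isTRUE(metadata$decay_corrected %||% TRUE),
    provenance = as.character(metadata$provenance %||% character())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a biodistribution study
#'
#' Writes the measurement table of a study as CSV with the fixed column order
#' `cohort_id, organ, time_h, animal_id, pct_ia_per_g`, readable back by
#' [read_biodist()]. Metadata attributes are not serialized here; pass them
#' to [read_biodist()] via its `metadata` argument (or
#' [write_biodist_metadata()] for a YAML side-car).
#'
#' @param study A `biodist_study` (or any data frame with the study columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_biodist <- function(study, path) {
  df <- as_tibble(as.data.frame(study))[biodist_columns]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write study metadata as a YAML side-car
#'
#' @param study A `biodist_study`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_biodist_metadata <- function(study, path) {
  nuc <- attr(study, "radionuclide")
  meta <- list(
    radionuclide = list(
      name = nuc$name,
      half_life_h = nuc$half_life_h,
      mean_energy_per_decay_keV = nuc$mean_energy_per_decay_keV
    ),
    injected_activity_MBq = attr(study, "injected_activity_MBq"),
    injected_mass_ug = attr(study, "injected_mass_ug"),
    lag_time_h = attr(study, "lag_time_h"),
    decay_corrected = attr(study, "decay_corrected"),
    provenance = attr(study, "provenance")
  )
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Read a summary-format (mean +/- SD) biodistribution table
#'
#' Published biodistribution tables usually print per-organ mean +/- SD with
#' an animal count rather than per-animal values. This reader accepts that
#' layout (columns `cohort_id`, `organ`, `time_h`, `mean_pct_ia_per_g`,
#' `sd_pct_ia_per_g`, `n`) and expands each cell into `n` pseudo-animals
#' whose sample mean and sample SD reproduce the printed values exactly
#' (a centred, scaled symmetric pattern). The expansion is flagged in the
#' study provenance; it lets summary tables flow through the same
#' time-activity machinery but invents no information beyond the two printed
#' moments.
#'
#' @inheritParams read_biodist
#' @return A `biodist_study` with pseudo-animal measurements and
#'   `"pseudo-animals expanded from summary table"` appended to provenance.
#' @export
read_biodist_summary <- function(path, metadata = list(),
                                 synonyms = organ_synonyms) {
  meta <- resolve_metadata(metadata)
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  need <- c("cohort_id", "organ", "time_h", "mean_pct_ia_per_g",
            "sd_pct_ia_per_g", "n")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("summary file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- purrr::pmap(tab[need], function(cohort_id, organ, time_h,
                                          mean_pct_ia_per_g, sd_pct_ia_per_g,
                                          n, ...) {
    vals <- pseudo_animals(mean_pct_ia_per_g, sd_pct_ia_per_g, n)
    tibble(
      cohort_id = cohort_id, organ = organ, time_h = time_h,
      animal_id = sprintf("pseudo%02d", seq_len(n)),
      pct_ia_per_g = vals
    )
  })
  biodist_study(bind_rows(rows),
    radionuclide = meta$radionuclide,
    injected_activity_MBq = meta$injected_activity_MBq,
    injected_mass_ug = meta$injected_mass_ug,
    lag_time_h = meta$lag_time_h,
    decay_corrected = meta$decay_corrected,
    provenance = c(meta$provenance,
                   "pseudo-animals expanded from summary table"),
    synonyms = synonyms
  )
}

# n values with exact sample mean m and sample sd s (sd 0 allowed, n = 1
# gives the mean alone). Centred symmetric pattern scaled to unit sample sd.
pseudo_animals <- function(m, s, n) {
  n <- as.integer(n)
  if (n < 1) stop("animal count must be >= 1", call. = FALSE)
  if (n == 1) return(m)
  z <- seq_len(n) - (n + 1) / 2
  z <- z / stats::sd(z)
  m + (if (is.na(s)) 0 else s) * z
}

#' Read survival records
#'
#' Reads a CSV of per-animal survival records with columns `group`,
#' `time_d` (days since inoculation, > 0) and `event` (1 = death or
#' euthanasia criterion reached, 0 = censored).
#'
#' @param path CSV file path.
#' @return A tibble with the three validated columns.
#' @export
read_survival <- function(path) {
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  validate_survival(tab)
}

#' Validate a survival-record table
#'
#' @param tab Data frame with columns `group`, `time_d`, `event`.
#' @return The validated tibble.
#' @export
validate_survival <- function(tab) {
  tab <- as_tibble(tab)
  need <- c("group", "time_d", "event")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("survival table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$group <- as.character(tab$group)
  tab$time_d <- as.numeric(tab$time_d)
  tab$event <- as.numeric(tab$event)
  bad_e <- which(!tab$event %in% c(0, 1))
  if (length(bad_e) > 0) {
    stop("event must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_e, 10), collapse = ", "), call. = FALSE)
  }
  bad_t <- which(!is.finite(tab$time_d) | tab$time_d <= 0)
  if (length(bad_t) > 0) {
    stop("time_d must be positive; offending row(s): ",
         paste(utils::head(bad_t, 10), collapse = ", "), call. = FALSE)
  }
  tab[need]
}
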