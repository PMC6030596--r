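#' Normalize a species (or tip) name for matching
#'
#' Trims surrounding whitespace and collapses internal whitespace runs to a
#' single underscore, so that `"Pygoscelis  adeliae "` and
#' `"Pygoscelis_adeliae"` refer to the same taxon. Matching between the
#' observation table and tree tip labels is additionally case-insensitive
#' (see [species_key()]).
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_species("  Pygoscelis  adeliae ")
normalize_species <- function(x) {
  x <- trimws(as.character(x))
  gsub("[[:space:]]+", "_", x)
}

#' Case-insensitive matching key for species names
#'
#' @param x character vector of names.
#' @return lower-cased normalized names, used as join keys.
#' @export
species_key <- function(x) tolower(normalize_species(x))

fmr_required_cols <- c("record_id", "study_id", "species", "colony",
                       "latitude_deg", "phase", "mass_g", "fmr_kj_day")
fmr_optional_cols <- c("brood_size", "breeding_pairs")

#' Validate an FMR observation table
#'
#' Checks the field-level invariants of an FMR record: latitude within
#' \[-90, 90\], strictly positive mass and FMR, breeding phase one of
#' `brood`, `incubation`, `creche`, non-negative brood size and strictly
#' positive breeding-pair counts where present, and unique record ids.
#' Optional fields are explicit `NA` when absent, never zero.
#'
#' @param df a data.frame with the FMR schema columns.
#' @return the validated table, classed `fmr_data`, invisibly usable as a
#'   plain data.frame.
#' @export
validate_fmr <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(fmr_required_cols, names(df))
  if (length(missing_cols)) {
    stop("FMR table schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in fmr_optional_cols) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df$record_id <- as.character(df$record_id)
  df$study_id <- as.character(df$study_id)
  df$species <- as.character(df$species)
  df$colony <- as.character(df$colony)
  for (col in c("latitude_deg", "mass_g", "fmr_kj_day",
                "brood_size", "breeding_pairs")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$phase <- as.character(df$phase)

  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("FMR validation error (%s) for record_id: %s", what,
                   paste(df$record_id[idx], collapse = ", ")), call. = FALSE)
    }
  }
  if (anyDuplicated(df$record_id)) {
    stop("FMR validation error: duplicated record_id: ",
         paste(unique(df$record_id[duplicated(df$record_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad(is.na(df$latitude_deg) | df$latitude_deg < -90 | df$latitude_deg > 90,
      "latitude_deg outside [-90, 90]")
  bad(is.na(df$mass_g) | df$mass_g <= 0, "mass_g must be > 0")
  bad(is.na(df$fmr_kj_day) | df$fmr_kj_day <= 0, "fmr_kj_day must be > 0")
  if (any(is.na(df$phase) | !df$phase %in% PHASE_LEVELS)) {
    idx <- which(is.na(df$phase) | !df$phase %in% PHASE_LEVELS)
    stop(sprintf(
      "FMR validation error: phase must be one of {%s}; offending record_id: %s",
      paste(PHASE_LEVELS, collapse = ", "),
      paste(df$record_id[idx], collapse = ", ")), call. = FALSE)
  }
  bad(!is.na(df$brood_size) & df$brood_size < 0, "brood_size must be >= 0")
  bad(!is.na(df$breeding_pairs) & df$breeding_pairs <= 0,
      "breeding_pairs must be > 0")

  class(df) <- unique(c("fmr_data", class(df)))
  df
}

#' Read an FMR observation table from CSV
#'
#' The schema is UTF-8 comma-separated with a header row and columns
#' `record_id, study_id, species, colony, latitude_deg, phase, mass_g,
#' fmr_kj_day, brood_size, breeding_pairs`. Empty cells denote absent
#' optional values. Every row is validated against the record invariants;
#' row order is preserved.
#'
#' @param path path to a CSV file.
#' @param quiet suppress the row-count message.
#' @return a validated `fmr_data` data.frame.
#' @seealso [write_fmr_table()], [validate_fmr()]
#' @export
read_fmr_table <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("FMR table not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df <- validate_fmr(df)
  if (!quiet) message(sprintf("Read %d FMR record(s) from %s", nrow(df), path))
  df
}

#' Write an FMR observation table to CSV
#'
#' Inverse of [read_fmr_table()]: absent optional values are written as empty
#' cells and re-read as absent.
#'
#' @param obs a validated `fmr_data` table (non-empty).
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_fmr_table <- function(obs, path) {
  obs <- validate_fmr(as.data.frame(obs))
  if (nrow(obs) == 0L) stop("cannot write an empty FMR table", call. = FALSE)
  cols <- c(fmr_required_cols, fmr_optional_cols)
  write.csv(obs[, cols], path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Derive model predictors from FMR observations
#'
#' Builds the predictor columns used by the phylogenetic mixed models:
#' log-transformed mass and FMR, absolute latitude, breeding-phase dummy
#' codes (brood as baseline), species average brood size, and
#' colony-relative predation pressure `log_rpp = log(pairs) + (2/3) log(mass)`
#' (the log product of breeding-pair count and mass^(2/3)).
#'
#' Transforms use the configured log base (10 by default; the base is
#' recorded in every fit). Optional terms that a model requires must be
#' present: a missing `breeding_pairs` when `log_rpp` is requested raises a
#' "term unavailable" error rather than producing silent `NA`s.
#'
#' @param obs a validated `fmr_data` table (or coercible data.frame).
#' @param log_base base of all log transforms, 10 or `exp(1)`.
#' @param terms character vector of fixed-effect terms the caller intends to
#'   use; only used to check availability of `brood_size` / `log_rpp`.
#' @return data.frame with columns `record_id, log_mass, abs_latitude,
#'   phase, phase_incubation, phase_creche, brood_size, log_rpp, log_fmr`.
#' @export
derive_predictors <- function(obs, log_base = 10, terms = NULL) {
  obs <- validate_fmr(as.data.frame(obs))
  stopifnot(is.numeric(log_base), length(log_base) == 1L, log_base > 1)
  if ("log_rpp" %in% terms && anyNA(obs$breeding_pairs)) {
    stop("term unavailable: log_rpp requires breeding_pairs for every ",
         "record; missing for record_id: ",
         paste(obs$record_id[is.na(obs$breeding_pairs)], collapse = ", "),
         call. = FALSE)
  }
  if ("brood_size" %in% terms && anyNA(obs$brood_size)) {
    stop("term unavailable: brood_size missing for record_id: ",
         paste(obs$record_id[is.na(obs$brood_size)], collapse = ", "),
         call. = FALSE)
  }
  log_rpp <- ifelse(is.na(obs$breeding_pairs), NA_real_,
                    logb(obs$breeding_pairs, log_base) +
                      (2 / 3) * logb(obs$mass_g, log_base))
  data.frame(
    record_id = obs$record_id,
    log_mass = logb(obs$mass_g, log_base),
    abs_latitude = abs(obs$latitude_deg),
    phase = factor(obs$phase, levels = PHASE_LEVELS),
    phase_incubation = as.numeric(obs$phase == "incubation"),
    phase_creche = as.numeric(obs$phase == "creche"),
    brood_size = obs$brood_size,
    log_rpp = log_rpp,
    log_fmr = logb(obs$fmr_kj_day, log_base),
    stringsAsFactors = FALSE
  )
}
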