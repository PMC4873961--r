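# Per-woman delivery records: schema, CSV I/O, validation.
#
# A facility dataset is a plain data.frame of one row per woman wrapped in a
# light S3 class that carries provenance and a manifest of populated fields.
# Missingness is explicit (NA); no imputation happens anywhere in the package.

# Canonical field names and their storage types.
.woman_field_types <- c(
  record_id                = "character",
  facility_id              = "character",
  country_id               = "character",
  maternal_age             = "integer",
  parity                   = "integer",
  previous_cs              = "integer",
  onset_of_labour          = "enum",
  gestational_age          = "integer",
  presentation             = "enum",
  multiple_pregnancy       = "logical",
  organ_dysfunction_or_icu = "logical",
  placenta_praevia         = "logical",
  abruptio_placentae       = "logical",
  chronic_hypertension     = "logical",
  renal_disease            = "logical",
  hiv                      = "logical",
  preeclampsia_level       = "enum",
  mode_of_delivery         = "enum",
  livebirth                = "logical",
  intrapartum_stillbirth   = "logical",
  neonatal_death_day1      = "logical",
  maternal_death           = "logical",
  maternal_near_miss       = "logical"
)

.enum_levels <- list(
  onset_of_labour    = c("spontaneous", "induced", "prelabour_cs"),
  presentation       = c("cephalic", "breech", "transverse_oblique", "other"),
  preeclampsia_level = c("none", "preeclampsia", "eclampsia"),
  mode_of_delivery   = c("vaginal", "caesarean")
)

# Synonyms accepted for enumeration values, applied after lower-casing and
# normalising separators. Routine registries disagree on spellings; the table
# is extensible at read time via the `synonyms` argument of read_dataset().
.enum_synonyms <- list(
  caesarean          = c("cesarean", "cs", "c_section", "caesarean_section",
                         "cesarean_section", "csection"),
  vaginal            = c("vaginal_delivery", "vd", "normal"),
  spontaneous        = c("spont", "spontaneous_labour", "spontaneous_labor"),
  induced            = c("induction", "induced_labour", "induced_labor"),
  prelabour_cs       = c("prelabor_cs", "cs_before_labour", "cs_before_labor",
                         "pre_labour_cs", "prelabour_caesarean", "elective_cs"),
  cephalic           = c("vertex", "head"),
  transverse_oblique = c("transverse", "oblique", "transverse_lie",
                         "oblique_lie", "transverse_or_oblique"),
  none               = c("absent"),
  preeclampsia       = c("pre_eclampsia", "pe"),
  eclampsia          = character(0)
)

.norm_token <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ /-]+", "_", x)
}

#' Fields of a per-woman delivery record
#'
#' Returns the canonical field names of the record schema: identifiers,
#' the clinical-obstetric characteristics used by the scoring models and the
#' Robson classification, the mode of delivery, and the perinatal/maternal
#' outcome flags used by the facility indicators.
#'
#' @return Character vector of field names.
#' @export
woman_fields <- function() names(.woman_field_types)

#' Default column mapping for CSV input
#'
#' The identity mapping: each schema field is read from a CSV column of the
#' same name. Pass a modified copy (or a key-value config file) to
#' [read_dataset()] when source columns are named differently. Fields removed
#' from the mapping are treated as entirely missing.
#'
#' @return Named character vector mapping field name -> source column name.
#' @export
default_schema <- function() {
  stats::setNames(names(.woman_field_types), names(.woman_field_types))
}

.parse_logical <- function(x) {
  key <- .norm_token(x)
  out <- rep(NA, length(x))
  out[key %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[key %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

.parse_enum <- function(x, field, synonyms) {
  key <- .norm_token(x)
  for (canon in names(synonyms)) {
    key[key %in% .norm_token(synonyms[[canon]])] <- canon
  }
  out <- key
  out[!(out %in% .enum_levels[[field]])] <- NA_character_
  out
}

.parse_integer <- function(x) {
  suppressWarnings(as.integer(round(as.numeric(x))))
}

#' Construct a facility dataset from a data.frame
#'
#' Coerces a data.frame of per-woman records to the canonical schema. Columns
#' absent from the input become all-missing; unknown columns are dropped.
#' Enumeration columns must already hold canonical values (use
#' [read_dataset()] for synonym-tolerant parsing).
#'
#' @param records data.frame with a subset of [woman_fields()] as columns.
#' @param provenance character scalar recorded with the dataset (source path,
#'   seed, fixture name).
#' @return An object of class `facility_dataset`: a list with elements
#'   `records` (data.frame), `provenance`, `manifest` (fields non-missing for
#'   at least one record) and `n_parse_warnings`.
#' @export
facility_dataset <- function(records, provenance = "in-memory") {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  out <- data.frame(row.names = seq_len(max(n, 0L)))
  for (f in names(.woman_field_types)) {
    if (f %in% names(records)) {
      col <- records[[f]]
      col <- switch(.woman_field_types[[f]],
        character = as.character(col),
        integer   = as.integer(col),
        logical   = as.logical(col),
        enum      = {
          col <- as.character(col)
          bad <- !is.na(col) & !(col %in% .enum_levels[[f]])
          if (any(bad)) {
            stop(sprintf("invalid value(s) for '%s': %s", f,
                         paste(unique(col[bad]), collapse = ", ")))
          }
          col
        })
    } else {
      col <- switch(.woman_field_types[[f]],
        character = rep(NA_character_, n),
        integer   = rep(NA_integer_, n),
        logical   = rep(NA, n),
        enum      = rep(NA_character_, n))
    }
    out[[f]] <- col
  }
  if (all(is.na(out$record_id))) out$record_id <- as.character(seq_len(n))
  manifest <- names(out)[vapply(out, function(col) any(!is.na(col)), logical(1))]
  structure(
    list(records = out, provenance = provenance, manifest = manifest,
         n_parse_warnings = 0L),
    class = "facility_dataset")
}

#' @export
print.facility_dataset <- function(x, ...) {
  cat(sprintf("<facility_dataset> %d women, %d facilities (%s)\n",
              nrow(x$records),
              length(unique(stats::na.omit(x$records$facility_id))),
              x$provenance))
  cat("populated fields:", paste(x$manifest, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.facility_dataset <- function(x) dim(x$records)

#' Fields populated in a dataset
#'
#' @param ds A `facility_dataset`.
#' @return Character vector of fields non-missing for at least one record.
#' @export
dataset_manifest <- function(ds) ds$manifest

#' Read a delivery-record CSV
#'
#' Parses an RFC-4180 CSV (UTF-8, header row required) into a
#' `facility_dataset`. Parsing is total: every row yields a record; cells that
#' cannot be interpreted under the target type degrade to missing and are
#' counted, never dropped. Enumeration values are matched case-insensitively
#' against a shipped synonym table. Gestational ages outside 22-44 completed
#' weeks and maternal ages outside 10-60 years are registry noise and are
#' treated as missing with a warning. `previous_cs` may be recorded as a count
#' or as a 0/1 flag; both parse to a count.
#'
#' @param path Path to the CSV file.
#' @param schema Named character vector mapping field names to source column
#'   names (default [default_schema()]), or the path of a key-value config
#'   file with lines `field: column` (or `field = column`).
#' @param na Strings treated as missing (default empty cell and `"NA"`).
#' @param synonyms Optional named list extending the shipped enumeration
#'   synonym table; names are canonical values, elements are extra synonyms.
#' @return A `facility_dataset`; `$n_parse_warnings` counts degraded cells.
#' @export
read_dataset <- function(path, schema = default_schema(),
                         na = c("", "NA"), synonyms = NULL) {
  explicit_schema <- !missing(schema)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (is.character(schema) && length(schema) == 1L && file.exists(schema) &&
      is.null(names(schema))) {
    schema <- read_schema(schema)
  }
  stopifnot(!is.null(names(schema)))
  unknown <- setdiff(names(schema), names(.woman_field_types))
  if (length(unknown) > 0) {
    stop("schema maps unknown field(s): ", paste(unknown, collapse = ", "))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  absent <- setdiff(unname(schema), names(raw))
  if (length(absent) > 0) {
    if (explicit_schema) {
      stop("mapped column(s) absent from header: ",
           paste(absent, collapse = ", "))
    }
    # default identity mapping: columns not present are simply missing fields
    schema <- schema[!(unname(schema) %in% absent)]
  }
  syn <- .enum_synonyms
  for (canon in names(synonyms)) {
    syn[[canon]] <- unique(c(syn[[canon]], synonyms[[canon]]))
  }
  n <- nrow(raw)
  n_warn <- 0L
  out <- data.frame(row.names = seq_len(max(n, 0L)))
  for (f in names(.woman_field_types)) {
    if (!(f %in% names(schema))) {
      out[[f]] <- switch(.woman_field_types[[f]],
        character = rep(NA_character_, n), integer = rep(NA_integer_, n),
        logical = rep(NA, n), enum = rep(NA_character_, n))
      next
    }
    cell <- raw[[schema[[f]]]]
    cell[cell %in% na] <- NA_character_
    present <- !is.na(cell)
    parsed <- switch(.woman_field_types[[f]],
      character = cell,
      integer   = .parse_integer(cell),
      logical   = .parse_logical(cell),
      enum      = .parse_enum(cell, f, syn))
    degraded <- present & is.na(parsed)
    # plausibility windows: out-of-range values degrade to missing
    if (f == "gestational_age") {
      bad <- !is.na(parsed) & (parsed < 22L | parsed > 44L)
      parsed[bad] <- NA_integer_
      degraded <- degraded | bad
    }
    if (f == "maternal_age") {
      bad <- !is.na(parsed) & (parsed < 10L | parsed > 60L)
      parsed[bad] <- NA_integer_
      degraded <- degraded | bad
    }
    if (f %in% c("parity", "previous_cs")) {
      bad <- !is.na(parsed) & parsed < 0L
      parsed[bad] <- NA_integer_
      degraded <- degraded | bad
    }
    if (any(degraded)) {
      n_warn <- n_warn + sum(degraded)
      warning(sprintf("%d cell(s) in column '%s' could not be parsed as %s; set to missing",
                      sum(degraded), schema[[f]], f), call. = FALSE)
    }
    out[[f]] <- parsed
  }
  ds <- facility_dataset(out, provenance = path)
  ds$n_parse_warnings <- n_warn
  ds
}

#' Read a column-mapping config file
#'
#' One mapping per line, `field: column` or `field = column`; blank lines and
#' `#` comments ignored.
#'
#' @param path Config file path.
#' @return Named character vector usable as `schema` in [read_dataset()].
#' @export
read_schema <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.+)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed schema line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(trimws(vapply(m, `[`, character(1), 3L)),
                  vapply(m, `[`, character(1), 2L))
}

#' Write a facility dataset as CSV
#'
#' Writes the canonical schema (all columns, canonical names, empty cell for
#' missing) so that `read_dataset(write_dataset(ds))` round-trips
#' field-for-field.
#'
#' @param ds A `facility_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "facility_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a facility dataset
#'
#' Checks the record-level consistency invariants and record_id uniqueness,
#' and reports violation counts with up to 10 example record ids per rule.
#' Reporting only: the dataset is never modified.
#'
#' Rules checked:
#' \itemize{
#'   \item `previous_cs_implies_parity`: previous_cs > 0 requires parity > 0;
#'   \item `prelabour_cs_implies_caesarean`: prelabour CS onset requires
#'     caesarean mode when the mode is recorded;
#'   \item `stillbirth_implies_no_livebirth`: an intrapartum stillbirth cannot
#'     be a livebirth;
#'   \item `record_id_unique`: duplicated record ids.
#' }
#'
#' @param ds A `facility_dataset`.
#' @return A `validation_report`: list of per-rule `n_violations` and
#'   `example_record_ids`, plus `n_records`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "facility_dataset"))
  r <- ds$records
  viol <- list(
    previous_cs_implies_parity =
      !is.na(r$previous_cs) & r$previous_cs > 0L &
      !is.na(r$parity) & r$parity == 0L,
    prelabour_cs_implies_caesarean =
      !is.na(r$onset_of_labour) & r$onset_of_labour == "prelabour_cs" &
      !is.na(r$mode_of_delivery) & r$mode_of_delivery != "caesarean",
    stillbirth_implies_no_livebirth =
      !is.na(r$intrapartum_stillbirth) & r$intrapartum_stillbirth &
      !is.na(r$livebirth) & r$livebirth,
    record_id_unique = duplicated(r$record_id)
  )
  rules <- lapply(viol, function(v) {
    list(n_violations = sum(v),
         example_record_ids = utils::head(r$record_id[v], 10L))
  })
  structure(list(n_records = nrow(r), rules = rules),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d records\n", x$n_records))
  for (rule in names(x$rules)) {
    cat(sprintf("  %-32s %d violation(s)\n", rule, x$rules[[rule]]$n_violations))
  }
  invisible(x)
}
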