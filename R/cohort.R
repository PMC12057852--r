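#' Column schema of a participant-level cohort table
#'
#' One row per expected column: name, storage type, declared range (closed
#' unless `exclusive_min`), and, for categorical columns, the admissible
#' levels. The schema mirrors a knee-replacement cohort with demographic
#' variables, the five-repetition sit-to-stand time, the Charlson Comorbidity
#' Index (CCI), the CES-D depression score, the three WOMAC subscales, and
#' SF-12 physical/mental component summaries (PCS/MCS) preoperatively and at
#' 1 and 2 years after surgery.
#'
#' @return a data.frame with columns `name`, `type` (`id`, `categorical`,
#'   `numeric`, `integer`), `min`, `max`, `exclusive_min`, `levels`
#'   (pipe-separated string or `NA`).
#' @export
cohort_schema <- function() {
  num <- function(name, min, max, integer = FALSE, exclusive_min = FALSE) {
    data.frame(name = name, type = if (integer) "integer" else "numeric",
               min = min, max = max, exclusive_min = exclusive_min,
               levels = NA_character_, stringsAsFactors = FALSE)
  }
  cat_ <- function(name, levels) {
    data.frame(name = name, type = "categorical", min = NA_real_,
               max = NA_real_, exclusive_min = FALSE,
               levels = paste(levels, collapse = "|"),
               stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(name = "participant_id", type = "id", min = NA_real_,
               max = NA_real_, exclusive_min = FALSE,
               levels = NA_character_, stringsAsFactors = FALSE),
    cat_("sex", c("female", "male")),
    num("age", 0, 130),
    cat_("joint_type", c("unilateral", "bilateral")),
    num("sit_to_stand_s", 0, Inf, exclusive_min = TRUE),
    num("bmi", 0, Inf, exclusive_min = TRUE),
    num("cci", 0, Inf, integer = TRUE),
    num("cesd", 0, 60, integer = TRUE),
    num("womac_pain", 0, 20),
    num("womac_stiffness", 0, 8),
    num("womac_physfunc", 0, 68),
    num("pcs_pre", 0, 100),
    num("pcs_1y", 0, 100),
    num("pcs_2y", 0, 100),
    num("mcs_pre", 0, 100),
    num("mcs_1y", 0, 100),
    num("mcs_2y", 0, 100)
  )
}

#' Validate a cohort table against the schema
#'
#' Checks column presence, types, missingness and declared ranges. Violations
#' are errors naming the offending row and column: out-of-range cells are
#' rejected, never clamped, and missing values are rejected rather than
#' imputed (the analysis assumes a complete-case cohort).
#'
#' @param x a data.frame with one row per participant.
#' @param schema schema as returned by [cohort_schema()].
#' @return `x`, invisibly, with class `cohort_table` prepended.
#' @export
validate_cohort <- function(x, schema = cohort_schema()) {
  if (!is.data.frame(x)) stop_("cohort must be a data.frame")
  missing_cols <- setdiff(schema$name, names(x))
  if (length(missing_cols) > 0) {
    stop_("schema error: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  n <- nrow(x)
  if (n < 1) stop_("cohort has no rows")
  for (i in seq_len(nrow(schema))) {
    col <- schema$name[i]
    v <- x[[col]]
    na <- is.na(v) | (is.character(v) & trimws(as.character(v)) == "")
    if (any(na)) {
      stop_("validation error: missing value in column '%s', row %d",
            col, which(na)[1])
    }
    switch(schema$type[i],
      id = {
        if (anyDuplicated(v)) {
          stop_("validation error: duplicate participant_id '%s'",
                v[duplicated(v)][1])
        }
      },
      categorical = {
        levs <- strsplit(schema$levels[i], "|", fixed = TRUE)[[1]]
        bad <- !(v %in% levs)
        if (any(bad)) {
          stop_("validation error: column '%s', row %d: value '%s' not one of {%s}",
                col, which(bad)[1], v[which(bad)[1]],
                paste(levs, collapse = ", "))
        }
      },
      {
        if (!is.numeric(v)) stop_("validation error: column '%s' is not numeric", col)
        lo <- schema$min[i]; hi <- schema$max[i]
        bad <- if (schema$exclusive_min[i]) v <= lo | v > hi else v < lo | v > hi
        bad <- bad | !is.finite(v)
        if (any(bad)) {
          stop_("validation error: column '%s', row %d: value %s outside declared range",
                col, which(bad)[1], format(v[which(bad)[1]]))
        }
        if (schema$type[i] == "integer" && any(v != floor(v))) {
          stop_("validation error: column '%s', row %d: non-integer value",
                col, which(v != floor(v))[1])
        }
      }
    )
  }
  if (!inherits(x, "cohort_table")) class(x) <- c("cohort_table", class(x))
  invisible(x)
}

#' Read a participant-level cohort table from CSV
#'
#' Reads a comma-separated, UTF-8, header-first file with one participant per
#' row and validates it against the schema. All cells must be present and
#' inside their declared ranges; errors name the offending row and column.
#'
#' @param path path to a CSV file.
#' @param schema schema as returned by [cohort_schema()].
#' @return a validated `cohort_table` data.frame, row order preserved.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols) > 0) {
    stop_("schema error: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  out <- raw[schema$name]
  for (i in seq_len(nrow(schema))) {
    if (schema$type[i] %in% c("numeric", "integer")) {
      col <- schema$name[i]
      s <- trimws(out[[col]])
      v <- suppressWarnings(as.numeric(s))
      bad <- is.na(v) & !is.na(s) & s != "" & s != "NA"
      if (any(bad)) {
        stop_("validation error: column '%s', row %d: non-numeric value '%s'",
              col, which(bad)[1], s[which(bad)[1]])
      }
      out[[col]] <- v
    }
  }
  validate_cohort(out, schema)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` field for field at double precision.
#'
#' @param x a cohort table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
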