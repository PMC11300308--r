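# Domain model: one row per patient-timepoint, columns in canonical units.
# Missing cells are NA (empty string on disk); no sentinel numerics, so a
# missing lab can never fire a threshold rule.

esas_item_names <- function() {
  c("pain", "tiredness", "drowsiness", "nausea", "appetite",
    "shortness_of_breath", "depression", "anxiety", "wellbeing")
}

cpc_domain_names <- function() {
  c("emotional", "informational", "practical", "spiritual", "social",
    "family", "physical")
}

sex_levels <- function() c("female", "male")
race_levels <- function() c("NHW", "AA", "HL")
tumor_stage_levels <- function() c("I", "II", "III", "IV", "unknown")
treatment_levels <- function() {
  c("surgery_only", "nonsurgical_only", "multimodal", "other")
}
event_levels <- function() c("death", "censored")

#' Column schema of a cachexia cohort
#'
#' One row per column of the canonical cohort table: name, storage type, and
#' canonical unit (`""` for unitless / categorical fields). Laboratory units:
#' CRP mg/L, albumin g/dL, hemoglobin g/dL, WBC and differential counts
#' cells/uL, CA19-9 U/mL, platelets 10^3/uL, bilirubin mg/dL; weights kg;
#' survival months.
#'
#' @return data.frame with columns `name`, `type`, `unit`.
#' @export
cohort_schema <- function() {
  col <- function(name, type, unit = "") data.frame(name = name, type = type,
                                                    unit = unit)
  rows <- list(
    col("patient_id", "character"),
    col("sex", "character"),
    col("race_ethnicity", "character"),
    col("age_at_diagnosis", "numeric", "years"),
    col("bmi", "numeric", "kg/m2"),
    col("weight_current", "numeric", "kg"),
    col("weight_6mo_prior", "numeric", "kg"),
    col("crp_soc", "numeric", "mg/L"),
    col("crp_research", "numeric", "mg/L"),
    col("albumin", "numeric", "g/dL"),
    col("wbc", "numeric", "cells/uL"),
    col("hgb", "numeric", "g/dL"),
    col("neutrophils", "numeric", "cells/uL"),
    col("lymphocytes", "numeric", "cells/uL"),
    col("ca19_9", "numeric", "U/mL"),
    col("platelets", "numeric", "1e3/uL"),
    col("bilirubin", "numeric", "mg/dL"),
    col("pgsga_box1", "character"),
    col("pgsga_box2", "integer"),
    col("pgsga_box3", "integer"),
    col("pgsga_box4", "integer"),
    col("grip_hand", "character"),
    col("grip_fingers", "character")
  )
  rows <- c(rows, lapply(paste0("esas_", esas_item_names()),
                         col, type = "integer"))
  rows <- c(rows, lapply(paste0("cpc_", cpc_domain_names()),
                         col, type = "character"))
  rows <- c(rows, lapply(sprintf("qlq%02d", 1:30), col, type = "integer"))
  rows <- c(rows, lapply(sprintf("pan%02d", 1:26), col, type = "integer"))
  rows <- c(rows, list(
    col("tumor_stage", "character"),
    col("treatment", "character"),
    col("survival_months", "numeric", "months"),
    col("event", "character")
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# multiplicative conversions into canonical units, keyed "field:declared_unit"
unit_conversions <- function() {
  c("hgb:g/L" = 0.1,
    "albumin:g/L" = 0.1,
    "crp_soc:mg/dL" = 10,
    "crp_research:mg/dL" = 10,
    "wbc:1e9/L" = 1000,
    "neutrophils:1e9/L" = 1000,
    "lymphocytes:1e9/L" = 1000,
    "platelets:1e9/L" = 1)
}

#' Construct a cachexia cohort from a data.frame
#'
#' Ensures every schema column exists (absent optional columns are filled
#' with `NA`), coerces storage types, and attaches the
#' `"cachexia_cohort"` class. Does not validate values; see
#' [validate_cohort()].
#'
#' @param df data.frame with a `patient_id` column and any subset of the
#'   remaining schema columns.
#' @return a `cachexia_cohort` data.frame with the full canonical column set.
#' @export
as_cachexia_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  schema <- cohort_schema()
  if (!"patient_id" %in% names(df)) {
    stop("schema error: missing mandatory column(s): patient_id")
  }
  extra <- setdiff(names(df), schema$name)
  if (length(extra)) {
    warning("dropping non-schema column(s): ", paste(extra, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    v <- if (nm %in% names(df)) df[[nm]] else rep(NA, nrow(df))
    v <- switch(schema$type[i],
                character = as.character(v),
                numeric = as.numeric(v),
                integer = {
                  vv <- as.numeric(v)
                  if (any(!is.na(vv) & vv != round(vv))) {
                    stop("non-integer value in integer column ", nm)
                  }
                  as.integer(round(vv))
                })
    out[[nm]] <- v
  }
  class(out) <- c("cachexia_cohort", "data.frame")
  out
}

#' Read a cohort table from delimited text
#'
#' Reads a UTF-8 CSV with a header row into a validated cohort. An optional
#' schema/config file (JSON) may rename file columns to canonical fields and
#' declare units for fields recorded in a supported alternate unit
#' (converted exactly once on ingest, e.g. hemoglobin g/L -> g/dL by /10).
#'
#' The config JSON may contain:
#' \describe{
#'   \item{columns}{object mapping canonical field -> file column name}
#'   \item{units}{object mapping canonical field -> declared unit string}
#'   \item{mandatory}{array of canonical fields that must be present}
#' }
#'
#' @param path path to the CSV file.
#' @param config optional path to a JSON schema/config file.
#' @param validate if `TRUE` (default) stop on range violations that make a
#'   row uninterpretable (e.g. an ESAS item outside 0-10), naming the
#'   offending `patient_id`s.
#' @return a `cachexia_cohort` data.frame.
#' @export
read_cohort <- function(path, config = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (!is.null(config)) jsonlite::read_json(config,
                                                   simplifyVector = TRUE)
         else list()
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE,
                         colClasses = "character")
  # rename file columns to canonical fields
  if (!is.null(cfg$columns)) {
    for (field in names(cfg$columns)) {
      filecol <- cfg$columns[[field]]
      if (!filecol %in% names(raw)) {
        stop("schema error: config maps ", field, " to absent column ",
             filecol)
      }
      names(raw)[names(raw) == filecol] <- field
    }
  }
  mandatory <- unique(c("patient_id", cfg$mandatory))
  absent <- setdiff(mandatory, names(raw))
  if (length(absent)) {
    stop("schema error: missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  # unit conversion, exactly once at ingest
  if (!is.null(cfg$units)) {
    conv <- unit_conversions()
    schema <- cohort_schema()
    for (field in names(cfg$units)) {
      declared <- cfg$units[[field]]
      canonical <- schema$unit[schema$name == field]
      if (length(canonical) == 1 && identical(declared, canonical)) next
      key <- paste0(field, ":", declared)
      if (!key %in% names(conv)) {
        stop("schema error: no conversion from unit '", declared,
             "' for field ", field)
      }
      raw[[field]] <- as.numeric(raw[[field]]) * conv[[key]]
    }
  }
  cohort <- as_cachexia_cohort(raw)
  if (validate) {
    viol <- validate_cohort(cohort)
    hard <- viol[grepl("^esas_", viol$field), , drop = FALSE]
    if (nrow(hard)) {
      stop("validation error: ESAS item out of range 0-10 for patient_id: ",
           paste(unique(hard$patient_id), collapse = ", "))
    }
  }
  cohort
}

#' Write a cohort table to delimited text
#'
#' Missing values are written as empty cells; [read_cohort()] on the written
#' file reproduces the cohort field-for-field.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cachexia_cohort"))
  ok <- tryCatch({
    utils::write.csv(cohort, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Validate a cohort against the type invariants
#'
#' Violations are data, not exceptions: each row of the result names the
#' patient, the field, and the rule broken. An empty result means every
#' invariant holds.
#'
#' @param cohort a `cachexia_cohort` data.frame.
#' @return data.frame with columns `patient_id`, `field`, `rule`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cachexia_cohort"))
  v <- list()
  bad <- function(idx, field, rule) {
    if (any(idx, na.rm = TRUE)) {
      v[[length(v) + 1]] <<- data.frame(
        patient_id = cohort$patient_id[which(idx)],
        field = field, rule = rule)
    }
  }
  enum_check <- function(field, levels) {
    x <- cohort[[field]]
    bad(!is.na(x) & !x %in% levels, field,
        paste0("must be one of {", paste(levels, collapse = ", "), "}"))
  }
  enum_check("sex", sex_levels())
  enum_check("race_ethnicity", race_levels())
  enum_check("tumor_stage", tumor_stage_levels())
  enum_check("treatment", treatment_levels())
  enum_check("event", event_levels())
  for (item in esas_item_names()) {
    f <- paste0("esas_", item)
    x <- cohort[[f]]
    bad(!is.na(x) & (x < 0 | x > 10), f, "must be in [0, 10]")
  }
  pos <- function(field, strict = TRUE) {
    x <- cohort[[field]]
    if (strict) bad(!is.na(x) & x <= 0, field, "must be > 0")
    else bad(!is.na(x) & x < 0, field, "must be >= 0")
  }
  pos("bmi"); pos("weight_current"); pos("weight_6mo_prior")
  for (lab in c("crp_soc", "crp_research", "albumin", "wbc", "hgb",
                "neutrophils", "lymphocytes", "ca19_9", "platelets",
                "bilirubin")) pos(lab, strict = FALSE)
  pos("survival_months", strict = FALSE)
  for (b in c("pgsga_box2", "pgsga_box3", "pgsga_box4")) {
    pos(b, strict = FALSE)
  }
  # a CPC item must belong to exactly one domain within a record
  cpc <- lapply(cpc_domain_names(),
                function(d) strsplit(cohort[[paste0("cpc_", d)]], ";"))
  dup <- vapply(seq_len(nrow(cohort)), function(i) {
    items <- unlist(lapply(cpc, function(dom) dom[[i]]))
    items <- items[!is.na(items) & nzchar(items)]
    anyDuplicated(items) > 0
  }, logical(1))
  bad(dup, "cpc", "an item may be ticked in only one domain")
  if (!length(v)) {
    return(data.frame(patient_id = character(), field = character(),
                      rule = character()))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
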