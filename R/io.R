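# Validated CSV interchange. CSV is the sole tabular format; every reader
# validates types, units (concentrations strictly molar), ranges and
# duplicate condition keys with row-level diagnostics before any analysis
# sees the table.

.col_spec <- function(type, min = -Inf, allow_na = FALSE) {
  list(type = type, min = min, allow_na = allow_na)
}

.schemas <- list(
  dose_response = list(
    cols = list(agonist_conc_M = .col_spec("numeric", min = 0),
                antagonist_id = .col_spec("character", allow_na = TRUE),
                antagonist_conc_M = .col_spec("numeric", min = 0),
                response = .col_spec("numeric"),
                replicate = .col_spec("integer", min = 1)),
    key = c("agonist_conc_M", "antagonist_id", "antagonist_conc_M",
            "replicate")),
  timeseries = list(
    cols = list(time_s = .col_spec("numeric", min = 0),
                fluorescence_au = .col_spec("numeric"),
                agonist_conc_M = .col_spec("numeric", min = 0),
                antagonist_id = .col_spec("character", allow_na = TRUE),
                antagonist_conc_M = .col_spec("numeric", min = 0),
                replicate = .col_spec("integer", min = 1),
                plate_id = .col_spec("character")),
    key = c("time_s", "agonist_conc_M", "antagonist_id",
            "antagonist_conc_M", "replicate", "plate_id")),
  polarization = list(
    cols = list(IVV = .col_spec("numeric", min = 0),
                IVH = .col_spec("numeric", min = 0),
                IHV = .col_spec("numeric", min = 0),
                IHH = .col_spec("numeric", min = 0),
                protein_conc_M = .col_spec("numeric", min = 0),
                atp_conc_M = .col_spec("numeric", min = 0),
                drug_id = .col_spec("character", allow_na = TRUE),
                drug_conc_M = .col_spec("numeric", min = 0),
                replicate = .col_spec("integer", min = 1)),
    key = c("protein_conc_M", "atp_conc_M", "drug_id", "drug_conc_M",
            "replicate")),
  patch = list(
    cols = list(cell_id = .col_spec("character"),
                construct = .col_spec("character"),
                state_during_MTS = .col_spec("character"),
                I_before_nA = .col_spec("numeric"),
                I_after_nA = .col_spec("numeric"),
                dtt_pretreated = .col_spec("logical")),
    key = "cell_id"))

#' Validate a table against a named schema
#'
#' Checks column presence, types (concentrations parsed strictly as molar
#' floats), lower bounds, finiteness, and duplicate condition keys.
#' Problems are collected and reported together with row numbers.
#'
#' @param df Data frame to validate.
#' @param schema One of `"dose_response"`, `"timeseries"`,
#'   `"polarization"`, `"patch"`.
#' @return The validated data frame (replicate columns coerced to
#'   integer), invisibly unchanged otherwise.
#' @export
validate_table <- function(df, schema) {
  if (!schema %in% names(.schemas))
    stop("unknown schema '", schema, "'", call. = FALSE)
  sc <- .schemas[[schema]]
  problems <- character(0)
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing))
    stop("schema '", schema, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in names(sc$cols)) {
    spec <- sc$cols[[nm]]
    v <- df[[nm]]
    if (spec$type %in% c("numeric", "integer")) {
      if (!is.numeric(v)) {
        problems <- c(problems,
                      paste0("column ", nm, " is not numeric"))
        next
      }
      bad <- which(!is.finite(v) | v < spec$min)
      if (length(bad))
        problems <- c(problems, paste0(
          "column ", nm, ": non-finite or out-of-range value at row(s) ",
          paste(utils::head(bad, 5), collapse = ", "),
          if (length(bad) > 5) " ..."))
      if (spec$type == "integer" && any(v[is.finite(v)] %% 1 != 0))
        problems <- c(problems,
                      paste0("column ", nm, " must be whole numbers"))
    } else if (spec$type == "character") {
      if (!spec$allow_na && any(is.na(v)))
        problems <- c(problems, paste0("column ", nm, " has NA values"))
    } else if (spec$type == "logical") {
      if (!is.logical(v))
        problems <- c(problems,
                      paste0("column ", nm, " is not logical"))
    }
  }
  keys <- sc$key[sc$key %in% names(df)]
  if (length(keys)) {
    kk <- do.call(paste, c(df[keys], sep = "\r"))
    dup <- which(duplicated(kk) | duplicated(kk, fromLast = TRUE))
    if (length(dup)) {
      first_pair <- which(kk == kk[dup[1]])
      problems <- c(problems, paste0(
        "duplicated (condition, replicate) key, e.g. rows ",
        paste(first_pair, collapse = " and ")))
    }
  }
  if (length(problems))
    stop("validation of '", schema, "' table failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  for (nm in names(sc$cols))
    if (sc$cols[[nm]]$type == "integer")
      df[[nm]] <- as.integer(df[[nm]])
  df
}

.read_validated <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema)
}

#' Read a validated dose-response CSV
#' @param path CSV path with columns `agonist_conc_M`, `antagonist_id`,
#'   `antagonist_conc_M`, `response`, `replicate`.
#' @return Validated data frame.
#' @export
read_dose_response <- function(path) .read_validated(path, "dose_response")

#' Read a validated uptake time-series CSV
#' @param path CSV path in the `timeseries.csv` schema.
#' @return Validated data frame.
#' @export
read_timeseries <- function(path) .read_validated(path, "timeseries")

#' Read a validated polarization CSV
#' @param path CSV path in the `polarization.csv` schema.
#' @return Validated data frame.
#' @export
read_polarization <- function(path) .read_validated(path, "polarization")

#' Read a validated patch-clamp CSV
#' @param path CSV path in the `patch.csv` schema.
#' @return Validated data frame.
#' @export
read_patch <- function(path) .read_validated(path, "patch")

#' Write a table as CSV
#'
#' Thin, quiet wrapper so every pipeline artifact is written the same way
#' (no row names, no quoting surprises) and can be re-read by the module
#' that produced it.
#'
#' @param df Data frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-drug mechanism report table
#'
#' Assembles the model-selection summary for a multi-drug dose-response
#' panel: one row per antagonist with both mechanisms' SS and R-squared,
#' the extra-SS F statistic and p-value, the fitted KB under each
#' mechanism, and the verdict.
#'
#' @param panel Dose-response data frame covering one or more values of
#'   `antagonist_id`.
#' @param alpha Significance level for the verdicts.
#' @return Data frame with one row per drug.
#' @export
mechanism_report <- function(panel, alpha = 0.05) {
  stopifnot(is.data.frame(panel), "antagonist_id" %in% names(panel))
  drugs <- setdiff(unique(panel$antagonist_id), NA)
  rows <- lapply(drugs, function(dr) {
    pts <- panel[panel$antagonist_id %in% c(dr, NA) |
                   panel$antagonist_conc_M == 0, , drop = FALSE]
    res <- compare_mechanisms(pts, alpha = alpha)
    cmp <- res$comparison
    data.frame(
      antagonist_id = dr,
      KB_competitive_M = if (!is.null(res$competitive))
        res$competitive$params$KB else NA_real_,
      KB_noncompetitive_M = if (!is.null(res$noncompetitive))
        res$noncompetitive$params$KB else NA_real_,
      SS_competitive = if (!is.null(cmp)) cmp$SS_competitive else NA_real_,
      SS_noncompetitive = if (!is.null(cmp)) cmp$SS_noncompetitive
        else NA_real_,
      R2_competitive = if (!is.null(cmp)) cmp$R2_competitive else NA_real_,
      R2_noncompetitive = if (!is.null(cmp)) cmp$R2_noncompetitive
        else NA_real_,
      F = if (!is.null(cmp)) cmp$F else NA_real_,
      p = if (!is.null(cmp)) cmp$p else NA_real_,
      verdict = res$verdict)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
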