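# File formats: record CSV, LMS parameter TSV, centile table TSV,
# flat key-value configuration. Missing values are empty fields; all
# writers emit a stable row order (week ascending, male before female).

RECORD_COLS <- c("sex", "gest_weeks", "weight_g", "year", "outcome",
                 "karyotype")

#' Read and write birth-record CSV files
#'
#' Header `sex,gest_weeks,weight_g,year,outcome,karyotype`; columns are
#' matched by name, so any order is accepted. Empty fields are missing
#' values. Unknown enum values and non-positive weights are rejected
#' with the offending row number.
#'
#' @param path file path.
#' @param records data.frame of birth records.
#' @return `read_records`: a typed data.frame of records;
#'   `write_records`: the path, invisibly.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       colClasses = "character")
  missing_cols <- setdiff(RECORD_COLS, names(d))
  if (length(missing_cols)) {
    stop_("record file ", path, " lacks column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  d <- d[RECORD_COLS]
  out <- data.frame(
    sex = d$sex,
    gest_weeks = suppressWarnings(as.integer(d$gest_weeks)),
    weight_g = suppressWarnings(as.numeric(d$weight_g)),
    year = suppressWarnings(as.integer(d$year)),
    outcome = d$outcome,
    karyotype = d$karyotype,
    stringsAsFactors = FALSE
  )
  check_enum <- function(col, allowed) {
    bad <- which(!is.na(out[[col]]) & !(out[[col]] %in% allowed))
    if (length(bad)) {
      stop_("invalid ", col, " '", out[[col]][bad[1]], "' at row ", bad[1])
    }
  }
  check_enum("sex", SEXES)
  check_enum("outcome", OUTCOMES)
  check_enum("karyotype", KARYOTYPES)
  for (col in c("gest_weeks", "weight_g", "year")) {
    bad <- which(!is.na(d[[col]]) & is.na(out[[col]]))
    if (length(bad)) {
      stop_("non-numeric ", col, " '", d[[col]][bad[1]], "' at row ", bad[1])
    }
  }
  bad <- which(!is.na(out$weight_g) & out$weight_g <= 0)
  if (length(bad)) {
    stop_("non-positive weight_g at row ", bad[1])
  }
  out
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  records <- as.data.frame(records)[RECORD_COLS]
  fmt <- records
  fmt$weight_g <- ifelse(is.na(records$weight_g), NA,
                         format(records$weight_g, digits = 15,
                                scientific = FALSE, trim = TRUE))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

SEX_CODES <- c(male = "M", female = "F")

#' Read and write LMS parameter tables (TSV)
#'
#' Tab-separated with header `week sex L M S`, sex coded `M`/`F`, one
#' row per (week, sex). The same format serves fitted output and
#' user-transcribed external reference charts. On reading, week coverage
#' is validated to be gap-free and identical for the sexes.
#'
#' @param path file path.
#' @param table an [lms_table()].
#' @return `read_lms_table`: an [lms_table()]; writers return the path,
#'   invisibly.
#' @export
read_lms_table <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("week", "sex", "L", "M", "S")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop_("LMS table file ", path, " lacks column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  if (!all(d$sex %in% SEX_CODES)) {
    stop_("sex must be coded ", paste(SEX_CODES, collapse = "/"),
          " in ", path)
  }
  d$sex <- names(SEX_CODES)[match(d$sex, SEX_CODES)]
  lms_table(d)
}

#' @rdname read_lms_table
#' @export
write_lms_table <- function(table, path) {
  table <- if (inherits(table, "lms_table")) table else lms_table(table)
  out <- as.data.frame(table)
  out$sex <- unname(SEX_CODES[out$sex])
  out <- out[order(out$week, match(out$sex, SEX_CODES)), ]
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Write one sex of a centile table (TSV)
#'
#' One row per week, first column `week`, then one integer-gram column
#' per centile label.
#'
#' @param ct a `centile_table` from [make_centile_table()].
#' @param path file path.
#' @param sex `"male"` or `"female"`.
#' @export
write_centile_table <- function(ct, path, sex) {
  sex <- match.arg(sex, SEXES)
  m <- ct[[sex]]
  out <- data.frame(week = as.integer(rownames(m)), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a
#' comment; values are parsed as numbers or logicals where possible and
#' comma-separated values become vectors. Keys mirror the
#' [fit_config()] / [simulation_config()] argument names.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop_("cannot parse config line: '", ln, "'")
    vals <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    parsed <- if (!anyNA(num)) num else if (all(toupper(vals) %in%
                                                c("TRUE", "FALSE"))) {
      as.logical(toupper(vals))
    } else vals
    out[[m[2]]] <- parsed
  }
  out
}

# Write the bundled pipeline outputs into a directory.
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_lms_table(report$lms_table, file.path(out_dir, "lms_table.tsv"))
  write_centile_table(report$centiles, file.path(out_dir,
                                                 "centiles_male.tsv"), "male")
  write_centile_table(report$centiles, file.path(out_dir,
                                                 "centiles_female.tsv"),
                      "female")
  diag <- list(
    selection = c(list(total = report$selection$total,
                       retained = report$selection$retained),
                  list(stages = report$selection$stages)),
    fit = list(iterations = report$model$iterations,
               converged = report$model$converged,
               loglik = report$model$loglik,
               edf_actual = as.list(report$model$edf_actual),
               delta = report$model$delta,
               delta_se = report$model$delta_se),
    sex_difference = report$sex_difference,
    modal_gestation = report$modal_gestation$mode,
    trend = unclass(report$trend),
    missingness = report$missingness
  )
  jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  if (!is.null(report$comparison)) {
    utils::write.table(as.data.frame(report$comparison),
                       file.path(out_dir, "comparison.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  log_lines <- c(
    paste0("records_total=", report$selection$total),
    paste0("records_retained=", report$selection$retained),
    paste0("converged=", report$model$converged),
    paste0("modal_week=", report$modal_gestation$mode)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
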