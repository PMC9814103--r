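# Campaign record files: CSV with the documented header
#   entry,mixer,equiv,tfoh_mol_pct,temp_c,conc_m,flow_ml_min,yield_pct
# plus optional residence_min, note, acq_value, round columns. Validation
# errors carry the offending CSV line number.

records_required_cols <- function(space)
  c("entry", param_names(space), "yield_pct")

records_optional_cols <- c("residence_min", "note", "acq_value", "round")

#' Read a campaign record file
#'
#' Reads and validates a CSV of flow-experiment records. Required columns
#' are `entry`, one column per space parameter, and `yield_pct`; optional
#' columns are `residence_min` (informational; recomputed as `V/(2f)` when
#' absent and the space carries mixer volumes), `note`, `acq_value`,
#' `round`. All validation errors name the CSV line (header = line 1).
#'
#' @param path CSV file path.
#' @param space the `flowbo_space` the conditions must satisfy (default
#'   [widened_space()]).
#' @param allow_pending if `TRUE`, rows may have an empty `yield_pct`
#'   (proposed but not yet run); otherwise a missing yield is an error.
#' @return validated data.frame of records.
#' @export
read_records <- function(path, space = widened_space(), allow_pending = FALSE) {
  if (!file.exists(path)) stopf("records file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  req <- records_required_cols(space)
  unknown <- setdiff(names(df), c(req, records_optional_cols))
  if (length(unknown))
    stopf("%s: unknown column '%s'", path, unknown[1L])
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("%s: missing required column '%s'", path, miss[1L])

  n <- nrow(df)
  line <- function(i) i + 1L  # header is line 1

  parse_num <- function(col, i, allow_na = FALSE) {
    raw <- trimws(df[[col]][i])
    if (!nzchar(raw) || is.na(raw)) {
      if (allow_na) return(NA_real_)
      stopf("%s line %d: column '%s' is empty", path, line(i), col)
    }
    v <- suppressWarnings(as.numeric(raw))
    if (is.na(v))
      stopf("%s line %d: column '%s' value '%s' is not a number",
            path, line(i), col, raw)
    v
  }

  entry <- integer(n); yield <- numeric(n)
  conds <- vector("list", n)
  for (i in seq_len(n)) {
    e <- parse_num("entry", i)
    if (e < 1 || e != round(e))
      stopf("%s line %d: entry must be a positive integer", path, line(i))
    entry[i] <- as.integer(e)
    cc <- list()
    for (p in space$params) {
      cc[[p$name]] <- if (p$type == "continuous") parse_num(p$name, i)
                      else trimws(df[[p$name]][i])
    }
    conds[[i]] <- tryCatch(validate_condition(space, cc), error = function(e)
      stopf("%s line %d: %s", path, line(i), conditionMessage(e)))
    y <- parse_num("yield_pct", i, allow_na = TRUE)
    if (is.na(y) && !allow_pending)
      stopf("%s line %d: missing yield_pct (use allow_pending for proposals)",
            path, line(i))
    if (!is.na(y) && (y < 0 || y > 100))
      stopf("%s line %d: yield_pct %g outside [0, 100]", path, line(i), y)
    yield[i] <- y
  }
  dup <- which(duplicated(entry))
  if (length(dup))
    stopf("%s line %d: duplicate entry number %d", path, line(dup[1L]),
          entry[dup[1L]])

  notes <- if ("note" %in% names(df)) {
    nn <- as.character(df$note); nn[is.na(nn)] <- ""; nn
  } else NULL
  out <- records_frame(space, conds, yield, entry, notes)
  if ("residence_min" %in% names(df)) {
    out$residence_min <- vapply(seq_len(n), function(i)
      parse_num("residence_min", i, allow_na = TRUE), numeric(1))
  }
  for (col in c("acq_value", "round")) {
    if (col %in% names(df))
      out[[col]] <- vapply(seq_len(n), function(i)
        parse_num(col, i, allow_na = TRUE), numeric(1))
  }
  out
}

#' Write a campaign record file
#'
#' Inverse of [read_records()]: writes the record schema as plain CSV
#' (numbers at full precision, no quoting of numeric fields), so that
#' write-then-read round-trips are lossless.
#'
#' @param records data.frame of records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  df <- records
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      v <- vapply(df[[col]], function(x)
        if (is.na(x)) "" else format(x, digits = 15, scientific = FALSE,
                                     trim = TRUE), "")
      df[[col]] <- v
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Append run-log events for a proposal
#'
#' Writes a plain-text audit block -- timestamp, config hash, seed, fitted
#' kernel hyperparameters and the proposed conditions with acquisition
#' values -- so that every proposal is traceable to a logged seed and
#' configuration.
#'
#' @param proposal a `flowbo_proposal`.
#' @param path log file path (appended to).
#' @return `path`, invisibly.
#' @export
log_proposal <- function(proposal, path) {
  pv <- proposal$provenance
  cfg_hash <- substr(paste(
    unlist(pv$config), collapse = "|"), 1L, 200L)
  lines <- c(
    sprintf("[%s] proposal round=%d seed=%d kind=%s q=%d",
            format(Sys.time(), "%Y-%m-%d %H:%M:%S"), proposal$round,
            pv$seed, pv$config$kind, length(proposal$conditions)),
    sprintf("  config=%s", cfg_hash),
    sprintf("  kernel: signal_var=%.6g noise_var=%.6g lengthscales=%s",
            pv$kernel$signal_var, pv$kernel$noise_var,
            paste(sprintf("%.6g", pv$kernel$lengthscales), collapse = ",")),
    vapply(seq_along(proposal$conditions), function(i) {
      cc <- proposal$conditions[[i]]
      sprintf("  %d: %s acq=%.4f", i,
              paste(names(cc), vapply(cc, function(v) format(v, digits = 6), ""),
                    sep = "=", collapse = " "),
              proposal$acq_values[i])
    }, "")
  )
  cat(lines, file = path, sep = "\n", append = TRUE)
  cat("\n", file = path, append = TRUE)
  invisible(path)
}
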