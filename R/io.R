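#' Read a surveillance table into a case series
#'
#' Reads delimited incidence tables into a validated [case_series()].
#' Two dialects are supported: `"wonder"`, the tab-delimited export
#' format of the CDC Wonder database (a header row, data rows, and a
#' trailing notes block introduced by a line whose first field is
#' `"---"` or starts with `"Notes"`; rows with an empty time label are
#' discarded), and `"plain"`, an ordinary comma-separated file with a
#' header row. Delimiters are fixed per dialect; there is no
#' auto-detection.
#'
#' Counts reported as suppressed or missing (`"Suppressed"`,
#' `"Missing"`, `"Not Applicable"`, or empty cells) are an error: the
#' model has no missing-data pathway, so such rows must be resolved
#' upstream.
#'
#' @param path Path to the file.
#' @param dialect `"plain"` (comma) or `"wonder"` (tab).
#' @param column_map Named character vector mapping roles to column
#'   names. Roles `time`, `count`, `population` are required; `group`
#'   and `age` are optional.
#' @return A [case_series()].
#' @export
read_surveillance <- function(path,
                              dialect = c("plain", "wonder"),
                              column_map = c(time = "Year", count = "Count",
                                             population = "Population")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  column_map <- unlist(column_map)
  req <- c("time", "count", "population")
  if (!all(req %in% names(column_map)))
    stop("column_map must name `time`, `count` and `population` columns",
         call. = FALSE)

  sep <- if (dialect == "wonder") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  if (dialect == "wonder") {
    first_field <- sub(paste0(sep, ".*$"), "", lines)
    first_field <- gsub("\"", "", first_field)
    foot <- which(first_field == "---" | startsWith(first_field, "Notes"))
    if (length(foot)) lines <- lines[seq_len(min(foot) - 1L)]
  }
  df <- read.delim(text = paste(lines, collapse = "\n"), sep = sep,
                   header = TRUE, colClasses = "character",
                   check.names = FALSE, strip.white = TRUE)

  missing_cols <- setdiff(unname(column_map[req]), names(df))
  if (length(missing_cols))
    stop("missing column(s) in header: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  time_raw <- trimws(df[[column_map[["time"]]]])
  keep <- !is.na(time_raw) & time_raw != ""
  df <- df[keep, , drop = FALSE]
  time_raw <- time_raw[keep]
  if (!nrow(df)) stop("no data rows found in ", path, call. = FALSE)

  suppressed_tokens <- c("Suppressed", "Missing", "Not Applicable", "")
  parse_num <- function(col, what) {
    vals <- trimws(df[[column_map[[col]]]])
    bad <- which(vals %in% suppressed_tokens | is.na(vals))
    if (length(bad))
      stop(what, " suppressed/missing at data row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    num <- suppressWarnings(as.numeric(gsub(",", "", vals)))
    notnum <- which(is.na(num))
    if (length(notnum))
      stop("unparseable ", what, " at data row(s): ",
           paste(notnum, collapse = ", "), " (value(s): ",
           paste(vals[notnum], collapse = ", "), ")", call. = FALSE)
    num
  }
  count <- parse_num("count", "count")
  population <- parse_num("population", "population")

  group <- if ("group" %in% names(column_map) &&
               column_map[["group"]] %in% names(df))
    trimws(df[[column_map[["group"]]]]) else rep("all", nrow(df))
  age <- if ("age" %in% names(column_map) &&
             column_map[["age"]] %in% names(df))
    trimws(df[[column_map[["age"]]]]) else rep("all", nrow(df))

  # period order: numeric when labels parse as numbers, file order otherwise
  times <- unique(time_raw)
  tnum <- suppressWarnings(as.numeric(times))
  if (!anyNA(tnum)) times <- times[order(tnum)]
  groups <- unique(group)
  strata <- unique(age)  # order of first appearance, matched at standardization

  n <- length(times); k <- length(groups); m <- length(strata)
  counts <- array(NA_real_, c(n, k, m))
  pops <- array(NA_real_, c(n, k, m))
  ti <- match(time_raw, times); gi <- match(group, groups); si <- match(age, strata)
  idx <- cbind(ti, gi, si)
  if (anyDuplicated(idx))
    stop("duplicate (time, group, stratum) rows in ", path, call. = FALSE)
  counts[idx] <- count
  pops[idx] <- population
  if (anyNA(counts)) {
    holes <- which(is.na(counts), arr.ind = TRUE)
    miss <- apply(holes, 1L, function(r)
      paste0("(", times[r[1]], ", ", groups[r[2]], ", ", strata[r[3]], ")"))
    stop("non-rectangular panel; missing cells: ",
         paste(utils::head(miss, 10L), collapse = " "), call. = FALSE)
  }

  case_series(counts, pops, time = times, groups = groups, strata = strata)
}

#' Write a case series to a delimited surveillance table
#'
#' Inverse of [read_surveillance()]; used to materialize synthetic data
#' as fixtures in either dialect. The `wonder` dialect appends a
#' minimal `"---"` / `"Notes"` footer block like real exports carry.
#'
#' @param series A [case_series()].
#' @param path Output path.
#' @param dialect `"plain"` or `"wonder"`.
#' @return `path`, invisibly.
#' @export
write_caseseries <- function(series, path, dialect = c("plain", "wonder")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(series, "case_series"))
  df <- as.data.frame(series)
  out <- data.frame(Year = df$time, Group = df$group, Age = df$stratum,
                    Count = format(df$count, scientific = FALSE, trim = TRUE),
                    Population = format(df$population, scientific = FALSE,
                                        trim = TRUE),
                    stringsAsFactors = FALSE)
  sep <- if (dialect == "wonder") "\t" else ","
  lines <- c(paste(names(out), collapse = sep),
             apply(out, 1L, paste, collapse = sep))
  if (dialect == "wonder")
    lines <- c(lines, "\"---\"", "\"Notes\"",
               "\"Generated by the ratetrends synthetic-data module.\"")
  writeLines(lines, path)
  invisible(path)
}

#' Write posterior summaries to CSV
#'
#' Writes a tidy CSV with columns `time`, `group`, `stratum`,
#' `quantity`, `mean`, `lwr_2.5`, `upr_97.5` — one row per summarized
#' period and quantity. Values round-trip through [read.csv()] to
#' within 1e-9.
#'
#' @param summaries A `rate_summary` data frame (or several,
#'   `rbind`-ed), as returned by [summarize_draws()] and the
#'   `summary()` methods of derived quantities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  if (is.null(summaries) || !NROW(summaries))
    stop("`summaries` must be a non-empty rate_summary data frame",
         call. = FALSE)
  cols <- c("time", "group", "stratum", "quantity", "mean",
            "lwr_2.5", "upr_97.5")
  if (!all(cols %in% names(summaries)))
    stop("summaries lack required columns: ",
         paste(setdiff(cols, names(summaries)), collapse = ", "),
         call. = FALSE)
  out <- as.data.frame(summaries)[, cols]
  ok <- tryCatch({
    write.csv(format(out, digits = 15, scientific = FALSE, trim = TRUE),
              path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
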