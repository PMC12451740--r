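#' Read a PLUMED COLVAR time-series file
#'
#' COLVAR files are whitespace-delimited tables whose first line is a
#' `#! FIELDS time <names...>` header.  Additional comment lines (starting
#' with `#`) are skipped.
#'
#' @param path Path to the COLVAR file.
#' @return A data frame of class `fcv_timeseries` with the header's column
#'   names; the `time` column is in ps.
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) .stopf("cannot read COLVAR file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#!\\s*FIELDS\\s+", lines[1]))
    .stopf("'%s' is not a COLVAR file: missing '#! FIELDS' header", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  data <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(data) == 0L) {
    df <- as.data.frame(matrix(numeric(0), ncol = length(fields)))
    names(df) <- fields
    return(new_timeseries(df))
  }
  parts <- strsplit(trimws(data), "\\s+")
  w <- lengths(parts)
  if (any(w != length(fields)))
    .stopf("'%s' has ragged rows: expected %d columns, found %s",
           path, length(fields), paste(unique(w[w != length(fields)]), collapse = ","))
  df <- as.data.frame(matrix(as.numeric(unlist(parts)), ncol = length(fields), byrow = TRUE))
  names(df) <- fields
  new_timeseries(df)
}

#' Construct a time-series table
#'
#' @param df Data frame of numeric columns; a `time` column (ps) is added
#'   as the row index if absent.
#' @return The data frame with class `fcv_timeseries` prepended.
#' @export
new_timeseries <- function(df) {
  df <- as.data.frame(df)
  if (!"time" %in% names(df)) df <- cbind(time = seq_len(nrow(df)) - 1, df)
  if (nrow(df) > 1 && any(diff(df$time) <= 0))
    .stopf("time column must be strictly increasing")
  class(df) <- c("fcv_timeseries", "data.frame")
  df
}

#' Write a COLVAR time-series file
#'
#' The round trip [write_colvar()] then [read_colvar()] reproduces values
#' to at least 6 significant digits and preserves column order.
#'
#' @param ts An `fcv_timeseries` (or plain data frame of numerics).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(ts, path) {
  ts <- as.data.frame(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(ts), collapse = " ")), con)
  if (nrow(ts) > 0) {
    body <- do.call(paste, c(lapply(ts, function(x) sprintf("%.10g", x)), sep = " "))
    writeLines(body, con)
  }
  invisible(path)
}
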