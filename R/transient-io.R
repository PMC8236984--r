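#' Read an OJIP transient from an instrument-export-style text file
#'
#' Parses a two-column delimited text file (time, fluorescence). Lines starting
#' with `#` are treated as comments; `# key: value` lines are collected into
#' the transient's metadata. A single non-numeric leading line is accepted as a
#' column header when `header = "auto"`. Dialect options are explicit — no
#' delimiter or unit sniffing beyond header detection.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter: `","` (default), `"\t"` or `";"`.
#' @param decimal Decimal separator, `"."` (default) or `","` (only valid with
#'   a non-comma delimiter).
#' @param time_unit Unit of the time column: `"us"` (default), `"ms"` or
#'   `"s"`. Times are normalised to microseconds on read.
#' @param header `"auto"` (default) to skip one leading non-numeric line,
#'   `TRUE` to always skip one line, `FALSE` to parse from the first line.
#' @return A validated [ojip_transient].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("0,100", "1000000,30000"), f)
#' read_transient(f)
#' @export
read_transient <- function(path, delimiter = ",", decimal = ".",
                           time_unit = c("us", "ms", "s"),
                           header = "auto") {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (decimal == "," && delimiter == ",") {
    stop("decimal separator ',' cannot be combined with a comma delimiter",
         call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  if (!length(raw) || all(!nzchar(trimws(raw)))) {
    stop("empty transient file: ", path, call. = FALSE)
  }
  is_comment <- startsWith(trimws(raw), "#")
  metadata <- parse_metadata_comments(raw[is_comment])
  lines <- raw[!is_comment]
  line_no <- seq_along(raw)[!is_comment]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; line_no <- line_no[keep]
  if (!length(lines)) stop("no data rows in ", path, call. = FALSE)

  parse_row <- function(line) {
    fields <- trimws(strsplit(line, delimiter, fixed = TRUE)[[1]])
    if (decimal == ",") fields <- gsub(",", ".", fields, fixed = TRUE)
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_row(lines[1])
  skip_first <- isTRUE(header) ||
    (identical(header, "auto") && anyNA(first))
  if (skip_first) {
    lines <- lines[-1]; line_no <- line_no[-1]
    if (!length(lines)) stop("no data rows after header in ", path,
                             call. = FALSE)
  }
  parsed <- lapply(lines, parse_row)
  bad <- which(vapply(parsed, function(p) length(p) < 2L || anyNA(p[1:2]),
                      logical(1)))
  if (length(bad)) {
    stop("malformed row at line ", line_no[bad[1]], " of ", path, ": ",
         dQuote(lines[bad[1]]), call. = FALSE)
  }
  times <- vapply(parsed, `[`, numeric(1), 1L)
  fl <- vapply(parsed, `[`, numeric(1), 2L)
  factor <- c(us = 1, ms = 1e3, s = 1e6)[[time_unit]]
  ojip_transient(times * factor, fl, metadata = metadata)
}

parse_metadata_comments <- function(comments) {
  meta <- list()
  for (cm in comments) {
    body <- sub("^\\s*#\\s*", "", cm)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      num <- suppressWarnings(as.numeric(val))
      if (nzchar(key)) meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Write an OJIP transient to a delimited text file
#'
#' Writes metadata as `# key: value` comment lines, a `time_us,fluorescence`
#' header, and one `time,fluorescence` row per sample, at full double
#' precision so that [read_transient()] reproduces the transient exactly.
#'
#' @param transient An [ojip_transient].
#' @param path Output path.
#' @param delimiter Field delimiter (default `","`).
#' @return Invisibly, `path`.
#' @export
write_transient <- function(transient, path, delimiter = ",") {
  assert_transient(transient)
  meta <- transient$metadata
  hdr <- character(0)
  if (length(meta)) {
    hdr <- sprintf("# %s: %s", names(meta),
                   vapply(meta, function(v) format(v, digits = 17),
                          character(1)))
  }
  rows <- paste(format_full(transient$times),
                format_full(transient$fluorescence), sep = delimiter)
  out <- c(hdr, paste("time_us", "fluorescence", sep = delimiter), rows)
  tryCatch(writeLines(out, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

#' Read a sample table (Table 3/4/5-shaped data)
#'
#' Reads a delimited table with a header row into one record per water sample.
#' Recognised columns: `sample_id` (required), `integral_area` or
#' `integral_area_1e10`, `chl_a_mg_L`, `cell_density_per_uL`,
#' `productivity_mgC_m3_d` — each optionally with a display-scale suffix such
#' as `_1e10`, `_1e5` or `_1e2`. Display scales are applied on read so stored
#' values are always base-unit; unknown columns are ignored.
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter (default `","`).
#' @return A data frame with columns `sample_id`, `integral_area` (a.u.*us),
#'   `chl_a` (mg/L), `cell_density` (cells/uL), `productivity`
#'   (mg C m-3 d-1); unavailable fields are `NA`.
#' @export
read_sample_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  nm <- names(df)
  if (!"sample_id" %in% nm) {
    stop("sample table must have a `sample_id` column; found: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  pick <- function(base) {
    # exact column, or the same base name with a _1eK display-scale suffix
    hit <- which(nm == base)
    scale <- 1
    if (!length(hit)) {
      pat <- paste0("^", base, "_1e([0-9]+)$")
      hit <- grep(pat, nm)
      if (length(hit) > 1L) {
        stop("multiple columns match ", base, " in ", path, call. = FALSE)
      }
      if (length(hit)) scale <- 10^as.numeric(sub(pat, "\\1", nm[hit]))
    }
    if (!length(hit)) return(rep(NA_real_, nrow(df)))
    vals <- as.numeric(df[[hit]]) * scale
    bad <- which(!is.na(vals) & vals < 0)
    if (length(bad)) {
      stop("negative value in column ", nm[hit], ", row ", bad[1],
           " of ", path, call. = FALSE)
    }
    vals
  }
  data.frame(
    sample_id = as.character(df$sample_id),
    integral_area = pick("integral_area"),
    chl_a = pick("chl_a_mg_L"),
    cell_density = pick("cell_density_per_uL"),
    productivity = pick("productivity_mgC_m3_d"),
    stringsAsFactors = FALSE
  )
}
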