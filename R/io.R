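#' Read a generator matrix from CSV
#'
#' Expects a square numeric block, optionally preceded by a header row of
#' state labels.
#'
#' @param path file path.
#' @return a validated `generator`.
#' @export
read_generator_csv <- function(path) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  m <- as.matrix(utils::read.csv(path, header = has_header))
  labels <- if (has_header) colnames(m) else NULL
  validate_generator(unname(m), labels = labels)
}

#' Write a generator matrix to CSV
#'
#' @param Q generator matrix.
#' @param path file path.
#' @param labels write a header row of state labels (default yes).
#' @export
write_generator_csv <- function(Q, path, labels = TRUE) {
  Q <- as_generator(Q)
  utils::write.table(format(unclass(Q), digits = 17, trim = TRUE),
                     path, sep = ",", row.names = FALSE,
                     col.names = if (labels) rownames(Q) else FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a numeric vector (distribution or observable) as one-row CSV
#'
#' @param path file path.
#' @return numeric vector.
#' @export
read_vector_csv <- function(path) {
  as.numeric(strsplit(readLines(path, n = 1), ",")[[1]])
}

#' @rdname read_vector_csv
#' @param x numeric vector to write.
#' @export
write_vector_csv <- function(x, path) {
  writeLines(paste(format(x, digits = 17, trim = TRUE), collapse = ","), path)
  invisible(path)
}

#' Read a sectioned key-value configuration file
#'
#' INI-style format: `[section]` headers followed by `key = value` lines;
#' `#` starts a comment. Values are parsed as numeric vectors where possible
#' (comma-separated), otherwise kept as strings.
#'
#' @param path file path.
#' @return named list of sections, each a named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "default"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    raw <- trimws(strsplit(kv[2], ",")[[1]])
    num <- suppressWarnings(as.numeric(raw))
    cfg[[section]][[key]] <- if (any(is.na(num))) raw else num
  }
  cfg
}

#' Write generator diagnostics as JSON
#'
#' @param Q generator matrix.
#' @param path output file.
#' @return the diagnostics list, invisibly.
#' @export
write_diagnostics_json <- function(Q, path) {
  d <- generator_diagnostics(Q)
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA)
  invisible(d)
}
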