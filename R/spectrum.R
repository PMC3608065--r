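#' Validate and construct a spectrum table
#'
#' A spectrum is a tibble with columns `mz` (strictly increasing m/z values,
#' Th) and `intensity` (non-negative abundances).  All pipeline functions
#' accept any data frame with these two columns; `as_spectrum()` validates
#' and canonicalizes it.
#'
#' @param x A data frame with columns `mz` and `intensity` (or a two-column
#'   numeric data frame taken as m/z, intensity in that order).
#' @return A tibble with columns `mz`, `intensity`, sorted by `mz`.
#' @examples
#' as_spectrum(data.frame(mz = c(100, 100.1), intensity = c(0, 5)))
#' @export
as_spectrum <- function(x) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame of (mz, intensity) pairs.")
  }
  if (!all(c("mz", "intensity") %in% names(x))) {
    if (ncol(x) == 2L && all(vapply(x, is.numeric, logical(1)))) {
      names(x) <- c("mz", "intensity")
    } else {
      abort("`x` must have columns `mz` and `intensity`.")
    }
  }
  s <- tibble(mz = as.numeric(x$mz), intensity = as.numeric(x$intensity))
  if (nrow(s) < 2L) abort("A spectrum needs at least 2 data points.")
  if (anyNA(s$mz) || anyNA(s$intensity) || !all(is.finite(s$mz)) || !all(is.finite(s$intensity))) {
    abort("Spectrum contains non-finite m/z or intensity values.")
  }
  if (any(s$intensity < 0)) {
    abort("Spectrum intensities must be non-negative.")
  }
  if (is.unsorted(s$mz)) {
    warn("Spectrum m/z values were not sorted; sorting.")
    s <- arrange(s, .data$mz)
  }
  if (anyDuplicated(s$mz)) {
    warn("Duplicate m/z values found; averaging their intensities.")
    s <- s |>
      group_by(.data$mz) |>
      dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
      arrange(.data$mz)
  }
  s
}

#' Read a profile-mode spectrum from disk
#'
#' Text format: two whitespace- or comma-separated columns (m/z, intensity),
#' optional header line.  mzML files are read through the `mzR` package
#' (first spectrum by default).
#'
#' @param path Path to the file.
#' @param format `"text"` or `"mzml"`; `"auto"` guesses from the extension.
#' @param scan For mzML input, which spectrum (scan index) to read.
#' @return A validated spectrum tibble (see [as_spectrum()]).
#' @export
read_spectrum <- function(path, format = c("auto", "text", "mzml"), scan = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "text"
  }
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort("Reading mzML requires the `mzR` package.")
    }
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle), add = TRUE)
    pk <- mzR::peaks(handle, scan)
    return(as_spectrum(as.data.frame(pk)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("Empty spectrum file: ", path))
  start <- 1L
  if (!grepl("^\\s*[-+0-9.eE]", lines[[1L]])) start <- 2L  # header line
  if (start > length(lines)) abort(paste0("No data rows in: ", path))
  rows <- lapply(seq(start, length(lines)), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "[,;\t ]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      abort(paste0("Malformed spectrum row at line ", i, " of ", path))
    }
    vals[1:2]
  })
  m <- do.call(rbind, rows)
  as_spectrum(tibble(mz = m[, 1L], intensity = m[, 2L]))
}

#' Write a spectrum as two-column text
#'
#' @param spectrum A spectrum data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  s <- as_spectrum(spectrum)
  utils::write.table(
    data.frame(mz = sprintf("%.6f", s$mz), intensity = format(s$intensity, digits = 10, trim = TRUE)),
    path, sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Index of the datum nearest to each query m/z.
nearest_index <- function(mz_grid, x) {
  idx <- findInterval(x, mz_grid, all.inside = TRUE)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz_grid))
  ifelse(abs(mz_grid[lo] - x) <= abs(mz_grid[hi] - x), lo, hi)
}
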