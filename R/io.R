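#' Write a data table with a metadata header
#'
#' Tab-separated text with `#`-prefixed `key: value` metadata lines before
#' the column header — the on-disk dialect shared by all modalities
#' (waveforms, temperature series, spectra, relaxation tables).
#'
#' @param data A data frame.
#' @param path Output file path.
#' @param meta Named list of scalar metadata (written as `# key: value`).
#' @return `path`, invisibly.
#' @export
write_lyo_table <- function(data, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 15)), con)
  }
  utils::write.table(data, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metadata-headed data table
#'
#' @param path File written by [write_lyo_table()] (or any TSV whose
#'   comment lines start with `#`).
#' @return A tibble; parsed metadata is attached as attribute `"meta"`
#'   (numeric-looking values are converted).
#' @export
read_lyo_table <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (l in sub("^#\\s*", "", lines[hdr])) {
    kv <- strsplit(l, ":\\s*")[[1]]
    if (length(kv) == 2) {
      val <- suppressWarnings(as.numeric(kv[2]))
      meta[[kv[1]]] <- if (is.na(val)) kv[2] else val
    }
  }
  body <- lines[!hdr]
  .assert(length(body) >= 2, "No data rows found.")
  df <- utils::read.delim(text = body, check.names = FALSE)
  out <- as_tibble(df)
  attr(out, "meta") <- meta
  out
}

#' Write / read a terahertz waveform
#'
#' Two-column (time ps, amplitude) table; role, thickness and temperature
#' travel in the metadata header and are restored as attributes on read.
#'
#' @param waveform Waveform tibble.
#' @param path File path.
#' @return `write_thz_waveform()` returns `path` invisibly;
#'   `read_thz_waveform()` returns the waveform tibble.
#' @export
write_thz_waveform <- function(waveform, path) {
  meta <- list(modality = "thz_waveform", units = "ps, a.u.")
  for (a in c("role", "temperature", "thickness")) {
    v <- attr(waveform, a, exact = TRUE)
    if (!is.null(v) && !all(is.na(v))) meta[[a]] <- v
  }
  write_lyo_table(waveform[, c("time", "amplitude")], path, meta)
}

#' @rdname write_thz_waveform
#' @export
read_thz_waveform <- function(path) {
  out <- read_lyo_table(path)
  m <- attr(out, "meta")
  for (a in c("role", "temperature", "thickness")) attr(out, a) <- m[[a]]
  out
}

#' Write / read an NMR relaxation series
#'
#' Two-column (delay s, magnetisation) table; the experiment kind and
#' component tag travel in the metadata header.
#'
#' @param series Relaxation series tibble (attributes `kind`, `component`).
#' @param path File path.
#' @return `write_relaxation_series()` returns `path` invisibly;
#'   `read_relaxation_series()` returns the series tibble.
#' @export
write_relaxation_series <- function(series, path) {
  meta <- list(modality = "nmr_relaxation", units = "s, a.u.")
  for (a in c("kind", "component", "label")) {
    v <- attr(series, a, exact = TRUE)
    if (!is.null(v) && !all(is.na(v))) meta[[a]] <- v
  }
  write_lyo_table(series[, c("delay", "magnetisation")], path, meta)
}

#' @rdname write_relaxation_series
#' @export
read_relaxation_series <- function(path) {
  out <- read_lyo_table(path)
  m <- attr(out, "meta")
  for (a in c("kind", "component", "label")) attr(out, a) <- m[[a]]
  out
}

#' Write optical constants as four-column text
#'
#' Columns: frequency (THz), refractive index, absorption coefficient
#' (cm^-1), usable-band mask (0/1).
#'
#' @param optics Tibble from [thz_extract_constants()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_optical_constants <- function(optics, path) {
  df <- data.frame(frequency = optics$frequency, n = optics$n,
                   alpha = optics$alpha, usable = as.integer(optics$usable))
  meta <- list(modality = "optical_constants",
               units = "THz, -, cm^-1, mask")
  d <- attr(optics, "thickness", exact = TRUE)
  if (!is.null(d)) meta$thickness_cm <- d
  write_lyo_table(df, path, meta)
}
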