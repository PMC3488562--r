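# File I/O: plain-matrix recordings, EDF/BDF biosignal files, event tables,
# and pair-series matrices with their JSON geometry sidecars.

#' Read a multichannel recording
#'
#' Two on-disk dialects are supported. `plain_matrix` is a whitespace-delimited
#' text matrix (rows = channels) preceded by a single header line `fs=<Hz>`;
#' it is the normative interchange format for this package. `edf_family` reads
#' continuous EDF (16-bit) and BDF (24-bit) biosignal files, applying the
#' per-channel physical/digital calibration from the header.
#'
#' @param path File to read.
#' @param format `"plain_matrix"` or `"edf_family"`.
#' @return An [new_recording()] object. Units are taken as stored (microvolts
#'   by convention for `plain_matrix`).
#' @export
read_recording <- function(path, format = c("plain_matrix", "edf_family")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: no such file: ", path)
  switch(format,
         plain_matrix = read_plain_matrix(path),
         edf_family = read_edf(path))
}

read_plain_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^fs=", lines[1]))
    stop_format(path, ": line 1 must be a header of the form fs=<Hz>")
  fs <- suppressWarnings(as.numeric(sub("^fs=", "", lines[1])))
  if (is.na(fs) || fs <= 0)
    stop_format(path, ": line 1: sampling rate must be a positive number")
  meta <- list()
  body_start <- 2L
  while (body_start <= length(lines) && grepl("^#", lines[body_start])) {
    kv <- sub("^#\\s*", "", lines[body_start])
    if (grepl("=", kv)) {
      key <- sub("=.*", "", kv)
      meta[[key]] <- sub("^[^=]*=", "", kv)
    }
    body_start <- body_start + 1L
  }
  body <- lines[body_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(body, function(l) {
    suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop_format(path, ": ragged rows: line ",
                body_start + which(lens != lens[1])[1] - 1L,
                " has ", lens[lens != lens[1]][1],
                " values, expected ", lens[1])
  if (any(vapply(rows, anyNA, TRUE)))
    stop_format(path, ": non-numeric value in matrix body")
  labels <- if (!is.null(meta$labels))
    strsplit(meta$labels, ",")[[1]] else NULL
  meta$labels <- NULL
  new_recording(do.call(rbind, rows), fs = fs, labels = labels, meta = meta)
}

#' Write a recording as plain-matrix text
#'
#' Inverse of [read_recording()] for the `plain_matrix` dialect: one `fs=`
#' header line, a `# labels=` comment, then one whitespace-delimited row per
#' channel at full double precision (round-trips losslessly).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%s", format(rec$fs, digits = 17)), con)
  writeLines(paste0("# labels=", paste(rec$labels, collapse = ",")), con)
  for (m in setdiff(names(rec$meta), "labels"))
    writeLines(paste0("# ", m, "=", paste(format(unlist(rec$meta[[m]])),
                                          collapse = ",")), con)
  utils::write.table(format(rec$data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Minimal continuous EDF/BDF reader: ASCII header, little-endian int16 (EDF)
# or int24 (BDF) data records, physical calibration applied per channel.
# Annotation channels are dropped.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  is_bdf <- magic[1] == as.raw(255L)
  hdr_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_str(80); hdr_str(80); hdr_str(8); hdr_str(8)   # ids and dates
  n_hdr <- as.integer(hdr_str(8))
  hdr_str(44)
  n_rec <- as.integer(hdr_str(8))
  rec_dur <- as.numeric(hdr_str(8))
  ns <- as.integer(hdr_str(4))
  if (is.na(ns) || ns < 1L) stop_format(path, ": bad EDF header (ns)")
  labels <- vapply(seq_len(ns), function(i) hdr_str(16), "")
  vapply(seq_len(ns), function(i) hdr_str(80), "")    # transducer
  vapply(seq_len(ns), function(i) hdr_str(8), "")     # units
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) hdr_str(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) hdr_str(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) hdr_str(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) hdr_str(8), ""))
  vapply(seq_len(ns), function(i) hdr_str(80), "")    # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) hdr_str(8), ""))
  vapply(seq_len(ns), function(i) hdr_str(32), "")    # reserved
  if (n_rec < 0L) stop_format(path, ": unknown record count in EDF header")
  keep <- !grepl("Annotations", labels)
  if (length(unique(spr[keep])) != 1L)
    stop_format(path, ": channels with differing rates are unsupported")
  fs <- spr[keep][1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  nbytes <- if (is_bdf) 3L else 2L
  out <- matrix(0, sum(keep), spr[keep][1] * n_rec)
  for (r in seq_len(n_rec)) {
    ki <- 0L
    for (s in seq_len(ns)) {
      if (is_bdf) {
        raw3 <- readBin(con, "raw", 3L * spr[s])
        b1 <- as.integer(raw3[seq(1, length(raw3), 3)])
        b2 <- as.integer(raw3[seq(2, length(raw3), 3)])
        b3 <- as.integer(raw3[seq(3, length(raw3), 3)])
        v <- b1 + 256L * b2 + 65536L * b3
        v <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        v <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      }
      if (keep[s]) {
        ki <- ki + 1L
        cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
        out[ki, cols] <- v * gain[s] + offset[s]
      }
    }
  }
  new_recording(out, fs = fs, labels = make.unique(labels[keep]),
                meta = list(source = if (is_bdf) "bdf" else "edf"))
}

#' Read an event table from tab-separated text
#'
#' Expects a TSV with header columns `onset_sample` (0-based) and `code`;
#' onsets must be strictly increasing and codes must come from
#' [event_codes()].
#'
#' @param path File to read.
#' @param fs Sampling rate (Hz) the onsets are expressed in.
#' @return An [event_table()].
#' @export
read_events <- function(path, fs) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset_sample", "code")
  if (!all(need %in% names(df)))
    stop_format(path, ": events TSV must have columns onset_sample, code")
  event_table(df$onset_sample, df$code, fs = fs)
}

#' Write an event table as tab-separated text
#' @param events An [event_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events[c("onset_sample", "code")]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write pair-series files
#'
#' A pair series is stored as a columnar text matrix (`<path>`, rows = pairs,
#' columns = windows) together with a JSON sidecar (`<path>.json`) holding the
#' window geometry (`window_len`, `hop`, `fs`, `window_centers`), the pair
#' list, and the series kind — a language-neutral, diff-able layout.
#'
#' @param series A [new_pair_series()] object.
#' @param path Matrix file; the sidecar is written next to it as
#'   `paste0(path, ".json")`.
#' @return `write_pair_series()` returns `path` invisibly;
#'   `read_pair_series()` returns the reconstructed `pair_series`.
#' @export
write_pair_series <- function(series, path) {
  stopifnot(inherits(series, "pair_series"))
  utils::write.table(format(series$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  sidecar <- list(kind = series$kind, window_len = series$window_len,
                  hop = series$hop, fs = series$fs,
                  window_centers = series$window_centers,
                  n_channels = attr(series$pair_index, "n_channels"),
                  pairs_i = series$pair_index$i, pairs_j = series$pair_index$j)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pair_series
#' @export
read_pair_series <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path))
  dimnames(vals) <- NULL
  pi <- make_pair_index(side$n_channels)
  if (!identical(as.integer(side$pairs_i), as.integer(pi$i)) ||
      !identical(as.integer(side$pairs_j), as.integer(pi$j))) {
    pi <- tibble::tibble(i = as.integer(side$pairs_i),
                         j = as.integer(side$pairs_j))
    attr(pi, "n_channels") <- as.integer(side$n_channels)
    class(pi) <- c("pair_index", class(pi))
  }
  new_pair_series(vals, side$window_centers, side$window_len, side$hop,
                  side$fs, pi, kind = side$kind)
}
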