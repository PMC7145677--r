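#' Read peaks from a BED file
#'
#' Parses BED3/BED5/BED6 (and wider) files into a [peak_dataset()]. All
#' coordinates are kept in the BED convention: 0-based half-open. Lines
#' starting with `#`, `track` or `browser` are skipped. Gzip-compressed files
#' are read transparently.
#'
#' The paper-style processed files do not declare which column carries fold
#' enrichment; by convention the BED score column (column 5) is used, which
#' `signal_column` overrides. Lines lacking the signal column get signal 1.
#'
#' @param path Path to a BED file (optionally `.gz`).
#' @param signal_column 1-based column index of the numeric signal
#'   (fold enrichment); default 5, the BED score column.
#' @param name Dataset name; defaults to the file name.
#' @param track_type Evidence track of the dataset (one of [TRACK_TYPES]).
#' @param one_based Set `TRUE` for 1-based inclusive input (e.g. intervals
#'   lifted from GFF); starts are shifted by -1. Off by default — 1-based
#'   coordinates are never silently accepted.
#' @param add_chr_prefix Prepend `"chr"` to chromosome names lacking it
#'   (reconciles `"1"` vs `"chr1"` naming); off by default.
#' @return A `PeakDataset`, sorted, in 0-based half-open coordinates.
#' @export
read_bed <- function(path, signal_column = 5L, name = basename(path),
                     track_type = "Histone", one_based = FALSE,
                     add_chr_prefix = FALSE) {
  fields <- read_interval_lines(path)
  if (length(fields$rows) == 0L) {
    warning("no data lines in '", path, "'; returning empty dataset")
    return(peak_dataset(peaks(), name = name, track_type = track_type))
  }
  n <- length(fields$rows)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  signal <- rep(1, n)
  for (i in seq_len(n)) {
    f <- fields$rows[[i]]
    ln <- fields$lineno[i]
    if (length(f) < 3L) {
      stop("line ", ln, ": expected at least 3 tab-separated columns")
    }
    chrom[i] <- f[1]
    start[i] <- parse_coord(f[2], ln, "start")
    end[i] <- parse_coord(f[3], ln, "end")
    if (one_based) start[i] <- start[i] - 1
    if (end[i] <= start[i]) {
      stop("line ", ln, ": end (", f[3], ") <= start (", f[2], ")")
    }
    if (length(f) >= signal_column) {
      v <- suppressWarnings(as.numeric(f[signal_column]))
      if (is.na(v)) {
        stop("line ", ln, ": signal column ", signal_column,
             " is not numeric ('", f[signal_column], "')")
      }
      signal[i] <- v
    }
  }
  if (add_chr_prefix) chrom <- ifelse(startsWith(chrom, "chr"), chrom,
                                      paste0("chr", chrom))
  peak_dataset(peaks(chrom, start, end, signal = signal),
               name = name, track_type = track_type)
}

#' Read peaks from an ENCODE narrowPeak file
#'
#' narrowPeak is 10-column BED6+4; the signal is taken from column 7
#' (signalValue) and the summit offset from column 10 (`peak`); a value of
#' -1 there means no summit was called.
#'
#' @inheritParams read_bed
#' @return A `PeakDataset` with per-peak summits where available.
#' @export
read_narrowpeak <- function(path, name = basename(path),
                            track_type = "Histone", add_chr_prefix = FALSE) {
  fields <- read_interval_lines(path)
  if (length(fields$rows) == 0L) {
    warning("no data lines in '", path, "'; returning empty dataset")
    return(peak_dataset(peaks(), name = name, track_type = track_type))
  }
  n <- length(fields$rows)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  signal <- numeric(n); summit <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- fields$rows[[i]]
    ln <- fields$lineno[i]
    if (length(f) != 10L) {
      stop("line ", ln, ": expected 10 columns (narrowPeak), got ", length(f))
    }
    chrom[i] <- f[1]
    start[i] <- parse_coord(f[2], ln, "start")
    end[i] <- parse_coord(f[3], ln, "end")
    if (end[i] <= start[i]) {
      stop("line ", ln, ": end (", f[3], ") <= start (", f[2], ")")
    }
    signal[i] <- suppressWarnings(as.numeric(f[7]))
    if (is.na(signal[i])) stop("line ", ln, ": signalValue is not numeric")
    pk <- suppressWarnings(as.numeric(f[10]))
    if (is.na(pk)) stop("line ", ln, ": peak (summit) column is not numeric")
    if (pk >= 0) {
      if (pk >= end[i] - start[i]) {
        stop("line ", ln, ": summit offset ", f[10], " outside peak")
      }
      summit[i] <- pk
    }
  }
  if (add_chr_prefix) chrom <- ifelse(startsWith(chrom, "chr"), chrom,
                                      paste0("chr", chrom))
  peak_dataset(peaks(chrom, start, end, signal = signal, summit = summit),
               name = name, track_type = track_type)
}

read_interval_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)  # file() decompresses gzip transparently
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  list(rows = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

parse_coord <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) || v != floor(v)) {
    stop("line ", lineno, ": ", what, " is not an integer ('", s, "')")
  }
  if (v < 0) stop("line ", lineno, ": negative ", what)
  v
}

#' Write peaks or a consensus track to a BED file
#'
#' Output is deterministic: sorted by (chrom, start, end), tab-separated,
#' numbers printed to 6 significant digits so that a write/read/write cycle
#' is byte-stable. A `PeakDataset` or `Track` is written as BED5
#' (chrom, start, end, name, signal). A `ConsensusTrack` writes the
#' comma-joined supporting-track list in column 4 and the combined score in
#' column 5. Paths ending in `.gz` are gzip-compressed.
#'
#' @param x A `PeakDataset`, `Track` or `ConsensusTrack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) UseMethod("write_bed")

#' @export
write_bed.PeakDataset <- function(x, path) {
  write_bed_peaks(x$peaks, x$name, path)
}

#' @export
write_bed.Track <- function(x, path) {
  write_bed_peaks(x$peaks, x$track_type, path)
}

#' @export
write_bed.ConsensusTrack <- function(x, path) {
  p <- x$peaks
  lines <- if (nrow(p) == 0L) character() else {
    paste(p$chrom, fmt_int(p$start), fmt_int(p$end),
          p$supporting, fmt_num(p$score), sep = "\t")
  }
  write_text_lines(lines, path)
}

#' @export
write_bed.data.frame <- function(x, path) {
  write_bed_peaks(as_peaks(x), "peak", path)
}

write_bed_peaks <- function(p, stem, path) {
  lines <- if (nrow(p) == 0L) character() else {
    paste(p$chrom, fmt_int(p$start), fmt_int(p$end),
          paste0(stem, "_", seq_len(nrow(p))), fmt_num(p$signal), sep = "\t")
  }
  write_text_lines(lines, path)
}

write_text_lines <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

fmt_int <- function(x) formatC(x, format = "d")
fmt_num <- function(x) sprintf("%.6g", x)
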