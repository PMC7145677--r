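#' Evidence track types
#'
#' The twelve experiment classes whose peak calls can contribute evidence for
#' enhancer activity: enhancer-marking ChIP-seq (P300, POLR2A, histone marks,
#' sequence-specific TF binding), chromatin accessibility (DHS/ATAC, FAIRE,
#' MNase), nascent-transcription assays detecting eRNAs (GRO, CAGE),
#' high-throughput reporter assays (MPRA, STARR) and chromatin-interaction
#' anchors (ChIA-PET).
#'
#' @format Character vector of length 12.
#' @export
TRACK_TYPES <- c(
  "P300", "POLR2A", "Histone", "TF-binding", "DHS", "FAIRE",
  "MNase", "GRO", "CAGE", "MPRA", "STARR", "ChIA-PET"
)

## half-up rounding; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Build a peak table
#'
#' Canonical in-memory form of a set of peaks: a data frame with columns
#' `chrom`, `start`, `end` (0-based half-open, as in BED), `signal`
#' (fold enrichment, non-negative) and `summit` (offset from `start` in bp,
#' `NA` when unknown). Rows are sorted by (chrom, start, end); the sort is
#' stable, so ties keep input order.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions (bp).
#' @param end Exclusive end positions (bp); must satisfy `end > start`.
#' @param signal Per-peak fold enrichment; recycled; default 1.
#' @param summit Offset of the signal summit from `start`, or `NA`; recycled.
#' @return A sorted, validated `data.frame` with the five columns above.
#' @export
peaks <- function(chrom = character(), start = numeric(), end = numeric(),
                  signal = 1, summit = NA_real_) {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0L || length(start) == 0L) n <- 0L
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    signal = rep_len(as.numeric(signal), n),
    summit = rep_len(as.numeric(summit), n),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
  sort_peaks(df)
}

PEAK_COLS <- c("chrom", "start", "end", "signal", "summit")

as_peaks <- function(df) {
  if (is.null(df$signal)) df$signal <- 1
  if (is.null(df$summit)) df$summit <- NA_real_
  df <- df[PEAK_COLS]
  validate_peaks(df)
  sort_peaks(df)
}

validate_peaks <- function(df) {
  stopifnot(is.data.frame(df), all(PEAK_COLS %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$end <= df$start)
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": require start >= 0 and end > start")
  }
  if (any(df$signal < 0, na.rm = TRUE)) stop("peak signal must be non-negative")
  len <- df$end - df$start
  badsum <- which(!is.na(df$summit) & (df$summit < 0 | df$summit >= len))
  if (length(badsum)) {
    stop("summit offset outside peak at row(s) ",
         paste(utils::head(badsum, 5), collapse = ", "))
  }
  invisible(df)
}

sort_peaks <- function(df) {
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## 0-based half-open data frame <-> 1-based closed GRanges
peaks_gr <- function(df, seqlevels = NULL) {
  sn <- if (is.null(seqlevels)) df$chrom else factor(df$chrom, levels = seqlevels)
  GenomicRanges::GRanges(
    seqnames = sn,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

## two peak tables as GRanges on one shared seqlevels set, so that
## combination and overlap ops never merge disjoint Seqinfo objects
grs_common <- function(a, b) {
  lv <- sort(unique(c(a$chrom, b$chrom)))
  list(a = peaks_gr(a, lv), b = peaks_gr(b, lv))
}

gr_peaks <- function(gr, signal = 1, summit = NA_real_) {
  as_peaks(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    signal = signal,
    summit = summit,
    stringsAsFactors = FALSE
  ))
}

## merge overlapping (>= 1 shared bp) intervals; adjacency does NOT merge
reduce0 <- function(gr) GenomicRanges::reduce(gr, min.gapwidth = 0L)

## total merged bp coverage of a peak table
peak_coverage <- function(df) {
  if (nrow(df) == 0L) return(0)
  sum(GenomicRanges::width(reduce0(peaks_gr(df))))
}

#' Construct a peak dataset
#'
#' One experiment's peak calls plus metadata: a dataset name, the evidence
#' track it belongs to (one of [TRACK_TYPES]) and a flag recording whether
#' signals have been normalized to a length-weighted mean of one.
#'
#' @param peaks A peak table as produced by [peaks()] (any data frame with
#'   `chrom`, `start`, `end` and optionally `signal`, `summit` is accepted).
#' @param name Dataset identifier.
#' @param track_type One of the twelve evidence types in [TRACK_TYPES].
#' @param normalized Logical; `TRUE` once [normalize_signals()] has run.
#' @return An object of class `PeakDataset`.
#' @export
peak_dataset <- function(peaks, name = "dataset", track_type = "Histone",
                         normalized = FALSE) {
  track_type <- match.arg(track_type, TRACK_TYPES)
  structure(
    list(name = name, track_type = track_type,
         peaks = as_peaks(peaks), normalized = isTRUE(normalized)),
    class = "PeakDataset"
  )
}

#' @export
print.PeakDataset <- function(x, ...) {
  cat(sprintf("PeakDataset '%s' [%s]%s: %d peaks, %d bp merged coverage\n",
              x$name, x$track_type,
              if (x$normalized) " (normalized)" else "",
              nrow(x$peaks), peak_coverage(x$peaks)))
  invisible(x)
}

#' Construct an evidence track
#'
#' One evidence type after within-track merging: a non-overlapping peak set
#' with a representative normalized signal per peak, and the number of source
#' datasets merged into it.
#'
#' @param peaks Peak table (non-overlapping after assembly).
#' @param track_type One of [TRACK_TYPES].
#' @param source_count Number of datasets merged (>= 1).
#' @return An object of class `Track`.
#' @export
track <- function(peaks, track_type, source_count = 1L) {
  track_type <- match.arg(track_type, TRACK_TYPES)
  stopifnot(source_count >= 1L)
  structure(
    list(track_type = track_type, peaks = as_peaks(peaks),
         source_count = as.integer(source_count)),
    class = "Track"
  )
}

#' @export
print.Track <- function(x, ...) {
  cat(sprintf("Track [%s]: %d peaks from %d dataset(s)\n",
              x$track_type, nrow(x$peaks), x$source_count))
  invisible(x)
}

## uniform accessor: Track, PeakDataset or bare peak table
get_peaks <- function(x) {
  if (inherits(x, c("PeakDataset", "Track"))) x$peaks
  else as_peaks(as.data.frame(x))
}
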