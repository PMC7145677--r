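#' Merge datasets of one evidence type into a track
#'
#' A single dataset passes through unchanged. Multiple datasets are merged by
#' average-summit / average-width (ASW) clustering: all peaks are pooled,
#' partitioned into clusters of transitively overlapping peaks (single
#' linkage, >= 1 shared bp), and each cluster is replaced by one peak
#' centered at the arithmetic mean of the member summits with width equal to
#' the rounded mean of the member lengths. A peak's summit is `start +
#' summit` when a summit offset is recorded, else the interval midpoint. The
#' merged signal is the mean of the member (normalized) signals. Merged
#' starts are clipped at 0.
#'
#' Because widths are averaged, adjacent cluster outputs can re-overlap; the
#' merge is re-applied until the track is overlap-free (at most 10 rounds).
#'
#' @param datasets A list of normalized `PeakDataset`s of one track type.
#' @return A `Track` with non-overlapping peaks.
#' @export
assemble_track <- function(datasets) {
  if (length(datasets) == 0L) stop("assemble_track: empty dataset list")
  stopifnot(all(vapply(datasets, inherits, logical(1), "PeakDataset")))
  types <- unique(vapply(datasets, `[[`, character(1), "track_type"))
  if (length(types) != 1L) {
    stop("assemble_track: mixed track types: ", paste(types, collapse = ", "))
  }
  if (!all(vapply(datasets, `[[`, logical(1), "normalized"))) {
    warning("assemble_track: merging datasets with unnormalized signals")
  }
  if (length(datasets) == 1L) {
    return(track(datasets[[1]]$peaks, types, source_count = 1L))
  }
  pooled <- do.call(rbind, lapply(datasets, get_peaks))
  merged <- asw_merge_to_fixed_point(as_peaks(pooled))
  track(merged, types, source_count = length(datasets))
}

asw_merge_to_fixed_point <- function(p, max_iter = 10L) {
  for (i in seq_len(max_iter)) {
    out <- asw_merge_once(p)
    if (!has_internal_overlap(out)) return(out)
    p <- out
  }
  stop("ASW merging failed to converge after ", max_iter, " iterations")
}

has_internal_overlap <- function(p) {
  if (nrow(p) < 2L) return(FALSE)
  gr <- peaks_gr(p)
  length(reduce0(gr)) < length(gr)
}

## one ASW pass: cluster by transitive overlap, emit one peak per cluster
asw_merge_once <- function(p) {
  if (nrow(p) == 0L) return(p)
  gr <- peaks_gr(p)
  clusters <- reduce0(gr)
  cl <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, clusters))
  len <- p$end - p$start
  summit_pos <- ifelse(is.na(p$summit), (p$start + p$end) / 2,
                       p$start + p$summit)
  center <- tapply(summit_pos, cl, mean)
  width <- pmax(1, round_half_up(tapply(len, cl, mean)))
  signal <- tapply(p$signal, cl, mean)
  chrom <- tapply(p$chrom, cl, `[`, 1L)
  start <- pmax(0, round_half_up(center - width / 2))
  end <- start + width
  summit <- pmin(pmax(round_half_up(center) - start, 0), width - 1)
  as_peaks(data.frame(chrom = as.character(chrom), start = as.numeric(start),
                      end = as.numeric(end), signal = as.numeric(signal),
                      summit = as.numeric(summit), stringsAsFactors = FALSE))
}
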