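#' Bundle exclusion annotations
#'
#' Promoter, exon and CTCF-defined insulator intervals: peaks overlapping any
#' of these regions are removed before consensus calling, because they mark
#' transcription start sites, coding sequence or domain boundaries rather
#' than distal enhancers. Each collection is internally merged (overlapping
#' intervals collapsed) and sorted; any collection may be empty.
#'
#' @param promoters,exons,insulators Data frames with `chrom`, `start`, `end`
#'   (0-based half-open), or `NULL` for none.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(promoters = NULL, exons = NULL, insulators = NULL) {
  norm <- function(df) {
    if (is.null(df) || nrow(df) == 0L) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    }
    gr_df(reduce0(peaks_gr(as_peaks(as.data.frame(df)))))
  }
  structure(
    list(promoters = norm(promoters), exons = norm(exons),
         insulators = norm(insulators)),
    class = "AnnotationSet"
  )
}

gr_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

new_filter_report <- function(name, peaks_in,
                              removed_length = 0L, removed_annotation = 0L,
                              dataset_dropped = FALSE,
                              drop_reason = NA_character_) {
  peaks_out <- if (dataset_dropped) 0L else {
    peaks_in - removed_length - removed_annotation
  }
  data.frame(dataset = name, peaks_in = peaks_in,
             removed_length = removed_length,
             removed_annotation = removed_annotation,
             dataset_dropped = dataset_dropped,
             drop_reason = drop_reason,
             peaks_out = peaks_out,
             stringsAsFactors = FALSE)
}

#' Remove over-long peaks
#'
#' Drops every peak whose length (end - start) exceeds `max_len`; very long
#' intervals are unlikely to be single enhancers. Peaks of exactly `max_len`
#' are kept. Idempotent; order preserved.
#'
#' @param dataset A `PeakDataset`.
#' @param max_len Maximum retained peak length in bp (default 2500).
#' @return A list with elements `dataset` (filtered `PeakDataset`) and
#'   `report` (one-row audit data frame).
#' @export
filter_peak_length <- function(dataset, max_len = 2500) {
  stopifnot(inherits(dataset, "PeakDataset"))
  p <- dataset$peaks
  keep <- (p$end - p$start) <= max_len
  dataset$peaks <- sort_peaks(p[keep, , drop = FALSE])
  list(dataset = dataset,
       report = new_filter_report(dataset$name, nrow(p),
                                  removed_length = sum(!keep)))
}

#' Gate out irregular datasets by coverage
#'
#' Experiments yielding too little or too much covered genome are dropped
#' wholesale — they typically reflect failed or unthresholded peak calling.
#' "Size" is operationalized as the total merged base-pair coverage of the
#' dataset's peaks (format-independent, unlike file size or raw peak count):
#' a dataset is dropped iff coverage < `min_cov` or coverage > `max_cov`.
#'
#' @param dataset A `PeakDataset`.
#' @param min_cov Minimum merged coverage in bp (default 5 kb).
#' @param max_cov Maximum merged coverage in bp (default 10 Mb).
#' @return A list with `keep` (logical), `dataset` (unchanged) and `report`.
#' @export
gate_dataset_size <- function(dataset, min_cov = 5000, max_cov = 1e7) {
  stopifnot(inherits(dataset, "PeakDataset"))
  cov <- peak_coverage(dataset$peaks)
  reason <- if (cov < min_cov) sprintf("coverage %d bp below %d bp", cov, min_cov)
  else if (cov > max_cov) sprintf("coverage %d bp above %d bp", cov, max_cov)
  else NA_character_
  drop <- !is.na(reason)
  list(keep = !drop, dataset = dataset,
       report = new_filter_report(dataset$name, nrow(dataset$peaks),
                                  dataset_dropped = drop,
                                  drop_reason = reason))
}

#' Remove peaks overlapping annotated non-enhancer regions
#'
#' A peak is removed in full (never truncated) if it shares at least 1 bp
#' with any promoter, exon or insulator interval, on the same chromosome;
#' strand is ignored. Half-open adjacency is not overlap: a peak ending where
#' an annotation starts is kept.
#'
#' @param dataset A `PeakDataset`.
#' @param annotations An [annotation_set()].
#' @return A list with `dataset` (filtered) and `report`.
#' @export
exclude_annotated <- function(dataset, annotations) {
  stopifnot(inherits(dataset, "PeakDataset"),
            inherits(annotations, "AnnotationSet"))
  p <- dataset$peaks
  ann <- rbind(annotations$promoters, annotations$exons,
               annotations$insulators)
  if (nrow(p) == 0L || nrow(ann) == 0L) {
    return(list(dataset = dataset,
                report = new_filter_report(dataset$name, nrow(p))))
  }
  grs <- grs_common(p, as_peaks(ann))
  hit <- IRanges::overlapsAny(grs$a, grs$b)
  dataset$peaks <- sort_peaks(p[!hit, , drop = FALSE])
  list(dataset = dataset,
       report = new_filter_report(dataset$name, nrow(p),
                                  removed_annotation = sum(hit)))
}

#' Normalize peak signals to a length-weighted mean of one
#'
#' Makes fold-enrichment values comparable across experiments: each signal
#' s_i is divided by the dataset's length-weighted mean signal
#' sum(s_i * l_i) / sum(l_i), where l_i is the peak length. After
#' normalization the length-weighted mean of the signals is exactly 1.
#' Applied after all peak-level filters so removed peaks do not contribute
#' to the denominator.
#'
#' @param dataset A non-empty `PeakDataset` with at least one positive signal.
#' @return The `PeakDataset` with scaled signals and `normalized = TRUE`.
#' @export
normalize_signals <- function(dataset) {
  stopifnot(inherits(dataset, "PeakDataset"))
  p <- dataset$peaks
  if (nrow(p) == 0L || !any(p$signal > 0)) {
    stop("cannot normalize zero-signal dataset '", dataset$name, "'")
  }
  len <- p$end - p$start
  denom <- sum(p$signal * len) / sum(len)
  dataset$peaks$signal <- p$signal / denom
  dataset$normalized <- TRUE
  dataset
}

#' Candidate enhancers from ChIA-PET interaction anchors
#'
#' Chromatin-interaction anchors that fall outside gene bodies and promoters
#' are candidate enhancers (roughly half of POLR2A ChIA-PET interactions are
#' enhancer-related). Anchors overlapping any gene-body or promoter interval
#' by >= 1 bp are removed; survivors pass through unchanged as a
#' `ChIA-PET`-type dataset.
#'
#' @param anchors A `PeakDataset` (or peak table) of interaction end-points.
#' @param genes Gene-body intervals (`chrom`, `start`, `end`), or `NULL`.
#' @param promoters Promoter intervals, or `NULL`.
#' @return A `PeakDataset` with `track_type = "ChIA-PET"`.
#' @export
chiapet_anchor_enhancers <- function(anchors, genes = NULL, promoters = NULL) {
  p <- get_peaks(anchors)
  nm <- if (inherits(anchors, "PeakDataset")) anchors$name else "chiapet_anchors"
  excl <- rbind(
    if (!is.null(genes)) as_peaks(as.data.frame(genes))[, PEAK_COLS] else NULL,
    if (!is.null(promoters)) as_peaks(as.data.frame(promoters))[, PEAK_COLS] else NULL
  )
  if (!is.null(excl) && nrow(excl) > 0L && nrow(p) > 0L) {
    grs <- grs_common(p, excl)
    hit <- IRanges::overlapsAny(grs$a, grs$b)
    p <- p[!hit, , drop = FALSE]
  }
  peak_dataset(p, name = nm, track_type = "ChIA-PET")
}

#' Run the full per-dataset preprocessing chain
#'
#' Applies, in fixed order: the peak-length cap, annotation exclusion, the
#' coverage gate, and (for kept datasets) signal normalization. The order is
#' deliberate — normalization comes last so filtered-out peaks do not enter
#' the length-weighted denominator.
#'
#' @inheritParams filter_peak_length
#' @inheritParams gate_dataset_size
#' @param annotations An [annotation_set()], or `NULL` to skip exclusion.
#' @return A list with `keep`, `dataset` (filtered; normalized when kept)
#'   and `report` (one row combining all filter counts).
#' @export
preprocess_dataset <- function(dataset, annotations = NULL, max_len = 2500,
                               min_cov = 5000, max_cov = 1e7) {
  n_in <- nrow(dataset$peaks)
  st1 <- filter_peak_length(dataset, max_len = max_len)
  st2 <- if (is.null(annotations)) {
    list(dataset = st1$dataset,
         report = new_filter_report(dataset$name, nrow(st1$dataset$peaks)))
  } else exclude_annotated(st1$dataset, annotations)
  st3 <- gate_dataset_size(st2$dataset, min_cov = min_cov, max_cov = max_cov)
  out <- st3$dataset
  if (st3$keep) out <- normalize_signals(out)
  list(keep = st3$keep, dataset = out,
       report = new_filter_report(
         dataset$name, n_in,
         removed_length = st1$report$removed_length,
         removed_annotation = st2$report$removed_annotation,
         dataset_dropped = !st3$keep,
         drop_reason = st3$report$drop_reason))
}
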