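#' Run the full consensus-enhancer pipeline
#'
#' Composes the whole method for one tissue/cell type: per-dataset filtering
#' and normalization ([preprocess_dataset()]), within-track ASW merging
#' ([assemble_track()]), inter-track similarity and weighting
#' ([similarity_matrix()], [track_weights()]) and the supported, weighted
#' consensus ([build_consensus()]). Deterministic: identical inputs and
#' options give identical output.
#'
#' Tracks emptied by filtering are dropped before the similarity matrix, so
#' the track count m reflects surviving tracks only. Fewer than two
#' surviving tracks is an error; exactly two triggers the both-track support
#' rule with a warning (three or more tracks are recommended).
#'
#' @param datasets A list of `PeakDataset`s (each knows its track type), or
#'   a manifest data frame accepted by [load_manifest()].
#' @param annotations An [annotation_set()] or `NULL`.
#' @param cell_type Label for the consensus track.
#' @param max_len,min_cov,max_cov Filter parameters, see
#'   [preprocess_dataset()].
#' @param min_support_fraction,score_overlap,jaccard_mode See
#'   [build_consensus()].
#' @return A list with `consensus` (`ConsensusTrack`), `tracks` (named list
#'   of assembled `Track`s), `similarity`, `weights` and `reports` (the
#'   per-dataset filter audit table).
#' @export
run_pipeline <- function(datasets, annotations = NULL,
                         cell_type = "consensus",
                         max_len = 2500, min_cov = 5000, max_cov = 1e7,
                         min_support_fraction = 0.5,
                         score_overlap = c("full", "clipped"),
                         jaccard_mode = c("regions", "bp")) {
  if (is.data.frame(datasets)) datasets <- load_manifest(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "PeakDataset")))
  score_overlap <- match.arg(score_overlap)
  jaccard_mode <- match.arg(jaccard_mode)

  pre <- lapply(datasets, preprocess_dataset, annotations = annotations,
                max_len = max_len, min_cov = min_cov, max_cov = max_cov)
  reports <- do.call(rbind, lapply(pre, `[[`, "report"))
  rownames(reports) <- NULL
  kept <- pre[vapply(pre, `[[`, logical(1), "keep")]
  kept <- lapply(kept, `[[`, "dataset")

  by_type <- split(kept, vapply(kept, `[[`, character(1), "track_type"))
  tracks <- lapply(by_type, assemble_track)
  tracks <- Filter(function(t) nrow(t$peaks) > 0L, tracks)
  ## stable canonical ordering of tracks
  tracks <- tracks[order(match(names(tracks), TRACK_TYPES))]

  m <- length(tracks)
  if (m < 2L) {
    stop("only ", m, " non-empty track(s) survive filtering; ",
         "consensus requires >= 2 tracks")
  }
  if (m == 2L) {
    warning("only two tracks available; consensus enhancers must be ",
            "supported by both (>= 3 tracks recommended)")
  }
  S <- similarity_matrix(tracks, mode = jaccard_mode)
  w <- track_weights(S)
  consensus <- build_consensus(tracks, weights = w,
                               min_support_fraction = min_support_fraction,
                               score_overlap = score_overlap,
                               cell_type = cell_type,
                               jaccard_mode = jaccard_mode)
  list(consensus = consensus, tracks = tracks, similarity = S, weights = w,
       reports = reports)
}

#' Load datasets listed in a manifest
#'
#' The manifest maps peak files to evidence tracks: a data frame (or TSV
#' file with a header) with columns `path`, `track_type` and optionally
#' `name`, `format` (`"bed"` or `"narrowpeak"`; default bed) and
#' `signal_column` (for BED input).
#'
#' @param manifest A data frame or path to a tab-separated file.
#' @param base_dir Directory that relative `path` entries are resolved
#'   against (defaults to the manifest's own directory for file input).
#' @return A named list of `PeakDataset`s.
#' @export
load_manifest <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(manifest),
            all(c("path", "track_type") %in% names(manifest)))
  if (is.null(base_dir)) base_dir <- "."
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    path <- if (file.exists(row$path)) row$path else file.path(base_dir, row$path)
    nm <- if (!is.null(row$name) && !is.na(row$name)) row$name
    else basename(row$path)
    fmt <- if (!is.null(row$format) && !is.na(row$format)) row$format else "bed"
    if (identical(fmt, "narrowpeak")) {
      read_narrowpeak(path, name = nm, track_type = row$track_type)
    } else {
      sc <- if (!is.null(row$signal_column) && !is.na(row$signal_column)) {
        as.integer(row$signal_column)
      } else 5L
      read_bed(path, signal_column = sc, name = nm,
               track_type = row$track_type)
    }
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write all pipeline outputs to a directory
#'
#' Writes `consensus.bed` (supporting tracks in column 4, combined score in
#' column 5), `similarity.tsv`, `weights.tsv` and `filter_reports.tsv`.
#'
#' @param result The list returned by [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(result$consensus, file.path(dir, "consensus.bed"))
  utils::write.table(result$similarity, file.path(dir, "similarity.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(
    data.frame(track = names(result$weights), weight = result$weights),
    file.path(dir, "weights.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$reports, file.path(dir, "filter_reports.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
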