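#' Jaccard similarity between two evidence tracks
#'
#' Measures how much two tracks agree on where enhancers are, counted over
#' candidate regions rather than base pairs so that agreement is weighted
#' toward enhancer loci instead of the vast non-enhancer genome. In the
#' default `"regions"` mode the union intervals of both tracks are merged
#' (single linkage, >= 1 bp overlap); the index is the number of merged
#' intervals containing at least one peak from *each* track, divided by the
#' total number of merged intervals. `"bp"` mode returns the conventional
#' base-pair intersection-over-union instead. Two empty tracks give 0.
#'
#' @param a,b `Track`s, `PeakDataset`s or peak tables.
#' @param mode `"regions"` (count merged union regions; default) or `"bp"`.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b, mode = c("regions", "bp")) {
  mode <- match.arg(mode)
  grs <- grs_common(get_peaks(a), get_peaks(b))
  gra <- grs$a
  grb <- grs$b
  if (length(gra) == 0L && length(grb) == 0L) return(0)
  if (mode == "regions") {
    u <- reduce0(c(gra, grb))
    if (length(u) == 0L) return(0)
    both <- IRanges::overlapsAny(u, gra) & IRanges::overlapsAny(u, grb)
    sum(both) / length(u)
  } else {
    ra <- reduce0(gra); rb <- reduce0(grb)
    inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ra, rb)))
    uni <- sum(GenomicRanges::width(GenomicRanges::union(ra, rb)))
    if (uni == 0) 0 else inter / uni
  }
}

#' Pairwise Jaccard similarity matrix of a track set
#'
#' @param tracks A list of >= 2 `Track`s (or objects accepted by [jaccard()]).
#' @param mode Passed to [jaccard()].
#' @return A symmetric m x m numeric matrix with track types as dimnames;
#'   diagonal entries are 1 for non-empty tracks.
#' @export
similarity_matrix <- function(tracks, mode = c("regions", "bp")) {
  mode <- match.arg(mode)
  m <- length(tracks)
  if (m < 2L) stop("consensus requires >= 2 tracks")
  ids <- make.unique(vapply(seq_len(m), function(i) {
    t <- tracks[[i]]
    if (inherits(t, c("Track", "PeakDataset"))) t$track_type else paste0("track", i)
  }, character(1)))
  J <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    J[i, i] <- jaccard(tracks[[i]], tracks[[i]], mode = mode)
    if (i < m) for (j in seq((i + 1), m)) {
      J[i, j] <- J[j, i] <- jaccard(tracks[[i]], tracks[[j]], mode = mode)
    }
  }
  J
}

#' Track weights from a similarity matrix
#'
#' A track that agrees with many other tracks earns more weight. The weight
#' of track t is its off-diagonal row sum divided by the sum of all
#' off-diagonal entries of the matrix, so the weights always sum to 1. If no
#' pair of tracks overlaps at all (all off-diagonal entries zero), uniform
#' weights 1/m are used with a warning.
#'
#' @param S A symmetric similarity matrix as from [similarity_matrix()].
#' @return A named numeric vector of weights summing to 1.
#' @export
track_weights <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  m <- nrow(S)
  if (m < 2L) stop("consensus requires >= 2 tracks")
  num <- rowSums(S) - diag(S)
  denom <- sum(num)
  if (denom <= 0) {
    warning("all inter-track similarities are zero; using uniform weights")
    w <- rep(1 / m, m)
  } else {
    w <- num / denom
  }
  names(w) <- rownames(S)
  w
}

#' Build the consensus enhancer track
#'
#' Candidate regions are the single-linkage merged union intervals over all
#' tracks' peaks. A candidate's support is the number of distinct tracks
#' with at least one peak overlapping it (>= 1 bp); candidates supported by
#' fewer than `ceil(min_support_fraction * m)` tracks are discarded. At the
#' default 50% rule at least two supporting tracks are always required, so
#' with two tracks a consensus enhancer must be supported by both.
#'
#' A retained enhancer's interval is the merged span of the peaks from its
#' *supporting* tracks only (a stray overlap from a non-supporting track
#' never widens the enhancer), and its combined score is
#'
#'   Score = sum_p w_t(p) * L_p * s_p / L_combined
#'
#' over every contributing peak p (a supporting track's peak overlapping the
#' region), with w_t the track weight, L_p the peak length, s_p its
#' normalized signal and L_combined the consensus interval length. By
#' default L_p is the full peak length; `score_overlap = "clipped"` uses the
#' length of the peak's intersection with the consensus interval instead.
#'
#' @param tracks A list of >= 2 `Track`s.
#' @param weights Named weights as from [track_weights()]; computed from
#'   [similarity_matrix()] when `NULL`.
#' @param min_support_fraction Minimum fraction of tracks that must support
#'   a region (default 0.5).
#' @param score_overlap `"full"` (default) or `"clipped"` contribution length.
#' @param cell_type Label stored on the result.
#' @param jaccard_mode Passed to [similarity_matrix()] when weights are
#'   computed here.
#' @return A `ConsensusTrack`: sorted non-overlapping consensus peaks with
#'   scores, supporting-track lists and per-peak contribution details, plus
#'   the weights and similarity matrix used.
#' @export
build_consensus <- function(tracks, weights = NULL,
                            min_support_fraction = 0.5,
                            score_overlap = c("full", "clipped"),
                            cell_type = "consensus",
                            jaccard_mode = c("regions", "bp")) {
  score_overlap <- match.arg(score_overlap)
  m <- length(tracks)
  if (m < 2L) stop("consensus requires >= 2 tracks")
  stopifnot(min_support_fraction >= 0, min_support_fraction <= 1)

  S <- similarity_matrix(tracks, mode = match.arg(jaccard_mode))
  if (is.null(weights)) weights <- track_weights(S)
  ids <- colnames(S)
  if (is.null(names(weights))) names(weights) <- ids
  stopifnot(setequal(names(weights), ids))

  min_tracks <- ceiling(min_support_fraction * m)
  ## a lone track is never a consensus: at the >= 50% rule require two
  if (min_support_fraction >= 0.5) min_tracks <- max(min_tracks, 2L)

  pool <- do.call(rbind, lapply(seq_len(m), function(i) {
    p <- get_peaks(tracks[[i]])
    if (nrow(p) == 0L) return(NULL)
    p$track <- ids[i]
    p
  }))
  empty <- consensus_track(empty_consensus_peaks(), weights, S, cell_type)
  if (is.null(pool) || nrow(pool) == 0L) return(empty)

  pool_gr <- peaks_gr(pool)
  cand <- reduce0(pool_gr)
  hits <- GenomicRanges::findOverlaps(pool_gr, cand)
  by_cand <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))

  rows <- lapply(by_cand, function(idx) {
    sup <- unique(pool$track[idx])
    if (length(sup) < min_tracks) return(NULL)
    contrib <- pool[idx[pool$track[idx] %in% sup], , drop = FALSE]
    cstart <- min(contrib$start); cend <- max(contrib$end)
    L_comb <- cend - cstart
    L_p <- if (score_overlap == "full") contrib$end - contrib$start
    else pmin(contrib$end, cend) - pmax(contrib$start, cstart)
    score <- sum(weights[contrib$track] * L_p * contrib$signal) / L_comb
    list(chrom = contrib$chrom[1], start = cstart, end = cend,
         score = score, n_support = length(sup),
         supporting = paste(ids[ids %in% sup], collapse = ","),
         contributing = data.frame(track = contrib$track,
                                   length = L_p,
                                   score = contrib$signal,
                                   weight = unname(weights[contrib$track]),
                                   stringsAsFactors = FALSE))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)

  peaks <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    n_support = vapply(rows, `[[`, integer(1), "n_support"),
    supporting = vapply(rows, `[[`, character(1), "supporting"),
    stringsAsFactors = FALSE
  )
  ord <- order(peaks$chrom, peaks$start, peaks$end, method = "radix")
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$contributing <- lapply(rows, `[[`, "contributing")[ord]
  consensus_track(peaks, weights, S, cell_type)
}

empty_consensus_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             score = numeric(), n_support = integer(),
             supporting = character(), stringsAsFactors = FALSE)
}

consensus_track <- function(peaks, weights, similarity, cell_type) {
  structure(
    list(cell_type = cell_type, peaks = peaks, weights = weights,
         similarity = similarity),
    class = "ConsensusTrack"
  )
}

#' @export
print.ConsensusTrack <- function(x, ...) {
  cat(sprintf("ConsensusTrack '%s': %d consensus enhancers from %d tracks\n",
              x$cell_type, nrow(x$peaks), length(x$weights)))
  if (length(x$weights)) {
    cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                            collapse = " "), "\n")
  }
  invisible(x)
}
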