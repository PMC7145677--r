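# Shared fixtures and independent brute-force oracles.
# Oracles work at base-pair resolution with plain logical vectors, never via
# the package's own interval machinery, so they can arbitrate its results.

random_peak_table <- function(n, max_coord = 50000, min_len = 20,
                              max_len = 800, chroms = c("chrA", "chrB"),
                              max_signal = 10) {
  if (n == 0L) {
    return(peaks())
  }
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample(0:(max_coord - l), 1), numeric(1))
  peaks(sample(chroms, n, replace = TRUE), start, start + len,
        signal = stats::runif(n, 0.1, max_signal))
}

# region-count Jaccard by explicit sweep: merge the pooled intervals with
# single linkage on strict (>= 1 bp) overlap — adjacency does not merge —
# then count merged regions touched by both tracks.
oracle_jaccard_regions <- function(pa, pb) {
  pool <- rbind(pa[, c("chrom", "start", "end")],
                pb[, c("chrom", "start", "end")])
  if (nrow(pool) == 0L) return(0)
  n_union <- 0L
  n_both <- 0L
  for (ch in unique(pool$chrom)) {
    rows <- pool[pool$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$start, rows$end), , drop = FALSE]
    cs <- rows$start[1]; ce <- rows$end[1]
    regions <- NULL
    for (i in seq_len(nrow(rows))[-1]) {
      if (rows$start[i] < ce) {
        ce <- max(ce, rows$end[i])
      } else {
        regions <- rbind(regions, c(cs, ce))
        cs <- rows$start[i]; ce <- rows$end[i]
      }
    }
    regions <- rbind(regions, c(cs, ce))
    a_ch <- pa[pa$chrom == ch, , drop = FALSE]
    b_ch <- pb[pb$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(regions))) {
      n_union <- n_union + 1L
      in_a <- any(a_ch$start < regions[k, 2] & a_ch$end > regions[k, 1])
      in_b <- any(b_ch$start < regions[k, 2] & b_ch$end > regions[k, 1])
      if (in_a && in_b) n_both <- n_both + 1L
    }
  }
  n_both / n_union
}

# does each peak share >= 1 bp with any annotation interval?
oracle_overlaps_annotation <- function(p, ann) {
  vapply(seq_len(nrow(p)), function(i) {
    rows <- ann[ann$chrom == p$chrom[i], , drop = FALSE]
    any(rows$start < p$end[i] & rows$end > p$start[i])
  }, logical(1))
}

make_dataset <- function(..., name = "ds", track_type = "Histone",
                         normalized = FALSE) {
  peak_dataset(peaks(...), name = name, track_type = track_type,
               normalized = normalized)
}

# plain-R sweep merge of overlapping peaks (fixture building only)
merge_plain <- function(p) {
  out <- NULL
  for (ch in unique(p$chrom)) {
    rows <- p[p$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$start, rows$end), , drop = FALSE]
    cs <- rows$start[1]; ce <- rows$end[1]; sig <- rows$signal[1]; k <- 1
    for (i in seq_len(nrow(rows))[-1]) {
      if (rows$start[i] < ce) {
        ce <- max(ce, rows$end[i]); sig <- sig + rows$signal[i]; k <- k + 1
      } else {
        out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce,
                                     signal = sig / k))
        cs <- rows$start[i]; ce <- rows$end[i]; sig <- rows$signal[i]; k <- 1
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce,
                                 signal = sig / k))
  }
  out
}

# a Track with internally non-overlapping peaks built from arbitrary ones
make_track <- function(p, track_type) {
  if (nrow(p) == 0L) return(track(p, track_type))
  track(merge_plain(p), track_type)
}

track_is_nonoverlapping <- function(p) {
  if (nrow(p) < 2L) return(TRUE)
  ok <- TRUE
  for (ch in unique(p$chrom)) {
    rows <- p[p$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1L && any(rows$start[-1] < rows$end[-nrow(rows)])) {
      ok <- FALSE
    }
  }
  ok
}

# random non-overlapping track for consensus/jaccard tests
random_track <- function(n, track_type, max_coord = 50000) {
  make_track(random_peak_table(n, max_coord = max_coord), track_type)
}
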