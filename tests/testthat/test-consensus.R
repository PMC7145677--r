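test_that("region-count Jaccard matches hand-evaluated cases", {
  a <- peaks("chr1", c(0, 20), c(10, 30))
  b <- peaks("chr1", 5, 15)
  # merged union {[0,15),[20,30)}: one region holds both tracks
  expect_equal(jaccard(a, b), 0.5)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, peaks("chr2", 0, 10)), 0)
  expect_equal(jaccard(peaks(), peaks()), 0)
  # adjacency is not overlap: [0,10) and [10,20) are separate regions
  expect_equal(jaccard(peaks("chr1", 0, 10), peaks("chr1", 10, 20)), 0)
})

test_that("bp-mode Jaccard is intersection over union of coverage", {
  a <- peaks("chr1", 0, 100)
  b <- peaks("chr1", 50, 150)
  expect_equal(jaccard(a, b, mode = "bp"), 50 / 150)
  expect_equal(jaccard(a, a, mode = "bp"), 1)
})

test_that("jaccard is symmetric, bounded and agrees with the bp oracle", {
  set.seed(71)
  for (rep in 1:25) {
    a <- random_peak_table(sample(0:120, 1), max_coord = 20000)
    b <- random_peak_table(sample(0:120, 1), max_coord = 20000)
    j <- jaccard(a, b)
    expect_equal(j, jaccard(b, a))
    expect_gte(j, 0); expect_lte(j, 1)
    expect_equal(j, oracle_jaccard_regions(a, b))
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(72)
  tracks <- list(random_track(40, "Histone"), random_track(40, "DHS"),
                 random_track(40, "P300"))
  S <- similarity_matrix(tracks)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(colnames(S), c("Histone", "DHS", "P300"))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(S[i, j], jaccard(tracks[[i]], tracks[[j]]))
  }
  expect_error(similarity_matrix(tracks[1]), ">= 2 tracks")

  ident <- list(tracks[[1]], tracks[[1]], tracks[[1]])
  expect_equal(unname(similarity_matrix(ident)), matrix(1, 3, 3))
})

test_that("track weights follow off-diagonal row sums and sum to one", {
  nm <- c("Histone", "DHS", "P300")
  S <- matrix(c(1, .6, .2, .6, 1, .4, .2, .4, 1), 3, 3,
              dimnames = list(nm, nm))
  w <- track_weights(S)
  expect_equal(unname(w), c(1 / 3, 5 / 12, 1 / 4))
  expect_equal(sum(w), 1)

  # identical tracks share weight equally; m = 2 always splits 50/50
  S1 <- matrix(1, 4, 4)
  expect_equal(unname(track_weights(S1)), rep(1 / 4, 4))
  S2 <- matrix(c(1, .123, .123, 1), 2, 2)
  expect_equal(unname(track_weights(S2)), c(0.5, 0.5))

  # disjoint tracks fall back to uniform weights with a warning
  expect_warning(w0 <- track_weights(diag(2)), "uniform")
  expect_equal(unname(w0), c(0.5, 0.5))
})

test_that("combined score weights peak lengths and signals as specified", {
  t1 <- track(peaks("chr1", 0, 100, signal = 2), "Histone")
  t2 <- track(peaks("chr1", 50, 150, signal = 4), "DHS")
  ct <- build_consensus(list(t1, t2), weights = c(Histone = 0.5, DHS = 0.5))
  expect_equal(nrow(ct$peaks), 1)
  expect_equal(ct$peaks$start, 0)
  expect_equal(ct$peaks$end, 150)
  # (0.5*100*2 + 0.5*100*4) / 150
  expect_equal(ct$peaks$score, 2)
  expect_equal(ct$peaks$supporting, "Histone,DHS")

  # clipped mode pro-rates each contribution to its overlap with the region
  ct2 <- build_consensus(list(t1, t2), weights = c(Histone = 0.5, DHS = 0.5),
                         score_overlap = "clipped")
  expect_equal(ct2$peaks$score, 2)  # both peaks lie inside the region

  # every consensus score re-derives from its contribution table
  for (i in seq_len(nrow(ct$peaks))) {
    co <- ct$peaks$contributing[[i]]
    L <- ct$peaks$end[i] - ct$peaks$start[i]
    expect_equal(ct$peaks$score[i],
                 sum(co$weight * co$length * co$score) / L,
                 tolerance = 1e-9)
  }
})

test_that("regions supported by one of two tracks are absent", {
  t1 <- track(peaks("chr1", c(0, 1000), c(100, 1100), signal = 1), "Histone")
  t2 <- track(peaks("chr1", 0, 80, signal = 1), "DHS")
  ct <- build_consensus(list(t1, t2), weights = c(Histone = 0.5, DHS = 0.5))
  expect_equal(nrow(ct$peaks), 1)   # [1000,1100) has only Histone support
  expect_equal(ct$peaks$n_support, 2)
})

test_that("m identical tracks sharing one peak return that peak's score", {
  for (m in 2:6) {
    s <- 3.7
    tracks <- lapply(TRACK_TYPES[seq_len(m)], function(tt) {
      track(peaks("chr1", 0, 100, signal = s), tt)
    })
    w <- rep(1 / m, m)
    names(w) <- TRACK_TYPES[seq_len(m)]
    ct <- build_consensus(tracks, weights = w)
    expect_equal(nrow(ct$peaks), 1)
    expect_equal(ct$peaks$score, s, tolerance = 1e-9)
  }
})

test_that("all-empty tracks give an empty consensus", {
  ct <- build_consensus(list(track(peaks(), "Histone"),
                             track(peaks(), "DHS")),
                        weights = c(Histone = 0.5, DHS = 0.5))
  expect_equal(nrow(ct$peaks), 0)
})

test_that("support is monotone: adding a peak never drops a region", {
  set.seed(73)
  for (rep in 1:5) {
    tracks <- lapply(c("Histone", "DHS", "P300", "TF-binding"),
                     function(tt) random_track(30, tt))
    w <- track_weights(similarity_matrix(tracks))
    before <- build_consensus(tracks, weights = w)
    extra <- random_peak_table(1)
    aug <- tracks
    aug[[1]] <- make_track(rbind(tracks[[1]]$peaks, extra), "Histone")
    after <- build_consensus(aug, weights = w)
    if (nrow(before$peaks) > 0) {
      found <- score_against_truth(after, before$peaks[, c("chrom", "start", "end")])
      expect_equal(found$recall, 1)
    }
  }
})

test_that("support fraction sweep behaves at its extremes", {
  set.seed(74)
  tracks <- lapply(c("Histone", "DHS", "P300"), function(tt) {
    random_track(40, tt)
  })
  w <- track_weights(similarity_matrix(tracks))
  # fraction 0: every merged union region is a consensus peak
  all_regions <- build_consensus(tracks, weights = w,
                                 min_support_fraction = 0)
  pooled <- do.call(rbind, lapply(tracks, function(t) t$peaks))
  expect_equal(nrow(all_regions$peaks), nrow(merge_plain(pooled)))
  # fraction 1: every consensus peak is supported by every track
  unanimous <- build_consensus(tracks, weights = w,
                               min_support_fraction = 1)
  if (nrow(unanimous$peaks) > 0) {
    expect_true(all(unanimous$peaks$n_support == 3))
  }
  expect_lte(nrow(unanimous$peaks), nrow(all_regions$peaks))
})

test_that("run_pipeline composes the stages and enforces track minima", {
  sc <- synthetic_scenario(seed = 11, n_true = 60,
                           genome = c(chr1 = 1e7, chr2 = 1e7),
                           n_tracks = 3)
  gen <- generate_scenario(sc)
  res <- run_pipeline(gen$datasets, gen$annotations, cell_type = "synthetic")
  expect_s3_class(res$consensus, "ConsensusTrack")
  expect_equal(res$consensus$cell_type, "synthetic")
  expect_equal(sum(res$weights), 1, tolerance = 1e-9)
  expect_equal(nrow(res$reports), 3)
  expect_true(all(res$reports$peaks_out ==
                    res$reports$peaks_in - res$reports$removed_length -
                    res$reports$removed_annotation))
  expect_true(track_is_nonoverlapping(res$consensus$peaks))

  expect_error(run_pipeline(gen$datasets[1], gen$annotations), ">= 2 tracks")
  expect_warning(run_pipeline(gen$datasets[1:2], gen$annotations),
                 "supported by both")
})
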