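test_that("peak-length cap removes strictly-over-threshold peaks only", {
  ds <- make_dataset("chr1", c(0, 1000, 5000), c(100, 3500, 7501))
  out <- filter_peak_length(ds, max_len = 2500)
  expect_equal(out$dataset$peaks$end - out$dataset$peaks$start, c(100, 2500))
  expect_equal(out$report$removed_length, 1)
  # identity when nothing exceeds the cap; empty result at max_len = 0
  expect_equal(filter_peak_length(out$dataset)$dataset$peaks,
               out$dataset$peaks)
  expect_equal(nrow(filter_peak_length(ds, max_len = 0)$dataset$peaks), 0)
})

test_that("coverage gate drops datasets below 5 kb or above 10 Mb", {
  two3k <- make_dataset("chr1", c(0, 10000), c(3000, 13000))
  expect_true(gate_dataset_size(two3k)$keep)  # merged coverage 6000

  small <- make_dataset("chr1", 0, 4999)
  g <- gate_dataset_size(small)
  expect_false(g$keep)
  expect_match(g$report$drop_reason, "below")

  # 10,001 disjoint 1-kb peaks: coverage 10,001,000 bp
  starts <- seq(0, by = 2000, length.out = 10001)
  big <- make_dataset("chr1", starts, starts + 1000)
  g2 <- gate_dataset_size(big)
  expect_false(g2$keep)
  expect_match(g2$report$drop_reason, "above")

  # overlapping peaks are counted once: two copies of 3 kb stay below 5 kb
  dup <- make_dataset("chr1", c(0, 0), c(3000, 3000))
  expect_false(gate_dataset_size(dup)$keep)
})

test_that("annotation exclusion removes whole peaks on >= 1 bp overlap", {
  ann <- annotation_set(promoters = data.frame(chrom = "chr1", start = 199,
                                               end = 300))
  ds <- make_dataset("chr1", c(100, 400), c(200, 500))
  out <- exclude_annotated(ds, ann)
  expect_equal(out$dataset$peaks$start, 400)
  expect_equal(out$report$removed_annotation, 1)

  # half-open adjacency is not overlap
  ann2 <- annotation_set(promoters = data.frame(chrom = "chr1", start = 200,
                                                end = 300))
  expect_equal(nrow(exclude_annotated(ds, ann2)$dataset$peaks), 2)

  # a peak inside an exon goes; empty annotation set is the identity
  ann3 <- annotation_set(exons = data.frame(chrom = "chr1", start = 0,
                                            end = 1000))
  expect_equal(nrow(exclude_annotated(ds, ann3)$dataset$peaks), 0)
  expect_equal(exclude_annotated(ds, annotation_set())$dataset$peaks,
               ds$peaks)
})

test_that("annotation exclusion agrees with a per-base-pair oracle", {
  set.seed(33)
  for (rep in 1:5) {
    p <- random_peak_table(sample(50:1000, 1), max_coord = 30000)
    ann_df <- random_peak_table(40, max_coord = 30000)[, c("chrom", "start", "end")]
    ds <- peak_dataset(p, name = "r")
    res <- exclude_annotated(ds, annotation_set(promoters = ann_df))
    hit <- oracle_overlaps_annotation(p, ann_df)
    expect_equal(nrow(res$dataset$peaks), sum(!hit))
    expect_equal(res$dataset$peaks[, c("chrom", "start", "end")],
                 p[!hit, c("chrom", "start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("filters are idempotent", {
  set.seed(34)
  p <- random_peak_table(200, max_len = 4000)
  ds <- peak_dataset(p, name = "idem")
  ann <- annotation_set(exons = random_peak_table(20)[, c("chrom", "start", "end")])
  once <- exclude_annotated(filter_peak_length(ds)$dataset, ann)$dataset
  twice <- exclude_annotated(filter_peak_length(once)$dataset, ann)$dataset
  expect_equal(twice$peaks, once$peaks)
})

test_that("signal normalization divides by the length-weighted mean", {
  # equal signals stay at the mean: both become 1
  d1 <- make_dataset("chr1", c(0, 1000), c(100, 1200), signal = 2)
  expect_equal(normalize_signals(d1)$peaks$signal, c(1, 1))
  # lengths 100 and 300, signals 3 and 1: denominator 1.5
  d2 <- make_dataset("chr1", c(0, 1000), c(100, 1300), signal = c(3, 1))
  expect_equal(normalize_signals(d2)$peaks$signal, c(2, 2 / 3))
  # a single peak self-normalizes to 1 whatever its signal
  d3 <- make_dataset("chr1", 0, 500, signal = 17.3)
  expect_equal(normalize_signals(d3)$peaks$signal, 1)
  expect_true(normalize_signals(d3)$normalized)
  # all-zero signals cannot be normalized
  d4 <- make_dataset("chr1", 0, 500, signal = 0)
  expect_error(normalize_signals(d4), "cannot normalize zero-signal")
})

test_that("normalized datasets have length-weighted mean signal exactly 1", {
  set.seed(35)
  for (rep in 1:20) {
    ds <- peak_dataset(random_peak_table(sample(1:300, 1)), name = "n")
    p <- normalize_signals(ds)$peaks
    len <- p$end - p$start
    expect_equal(sum(p$signal * len) / sum(len), 1, tolerance = 1e-12)
  }
})

test_that("ChIA-PET anchors in genes or promoters are filtered out", {
  anchors <- make_dataset("chr1", c(0, 5000, 10000, 20000),
                          c(500, 5500, 10500, 20500),
                          track_type = "ChIA-PET")
  genes <- data.frame(chrom = "chr1", start = 4900, end = 8000)
  promoters <- data.frame(chrom = "chr1", start = 10400, end = 10900)
  out <- chiapet_anchor_enhancers(anchors, genes = genes,
                                  promoters = promoters)
  expect_s3_class(out, "PeakDataset")
  expect_equal(out$track_type, "ChIA-PET")
  expect_equal(out$peaks$start, c(0, 20000))  # intergenic anchors survive
  # with no exclusion intervals all anchors pass through
  expect_equal(nrow(chiapet_anchor_enhancers(anchors)$peaks), 4)
})

test_that("preprocess_dataset applies cap, exclusion, gate then normalize", {
  ds <- make_dataset("chr1",
                     c(0, 1000, 10000, 20000, 40000),
                     c(5000, 3600, 11000, 23000, 42000))
  ann <- annotation_set(promoters = data.frame(chrom = "chr1", start = 10500,
                                               end = 10600))
  out <- preprocess_dataset(ds, ann)
  # [0,5000) and [1000,3600) over the cap; [10000,11000) hits the promoter;
  # survivors [20000,23000)? no - that is 3000 bp, also capped
  expect_equal(out$report$removed_length, 3)
  expect_equal(out$report$removed_annotation, 1)
  # only [40000,42000) remains: 2000 bp coverage, below the 5 kb gate
  expect_false(out$keep)
  expect_true(out$report$dataset_dropped)
})
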