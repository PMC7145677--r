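#' Describe a synthetic multi-track benchmarking scenario
#'
#' Defines the ground truth and noise model for a simulated tissue/cell
#' type: `n_true` non-overlapping enhancers are planted on a small genome;
#' each evidence track observes each enhancer with probability `sensitivity`,
#' with Gaussian jitter on the peak centre and width, log-normal fold
#' enrichment, and an independent load of uniformly placed noise peaks
#' (`noise_rate` noise peaks per planted enhancer, Poisson-distributed).
#' Promoter, exon and insulator intervals are planted as well, together with
#' contaminating peaks over them, so annotation exclusion has work to do.
#'
#' The generator emulates replicate peak calls that agree on true enhancers
#' but disagree on noise; it does not emulate read-level data, signal
#' autocorrelation along the genome, or assay-specific peak-shape biases.
#'
#' @param seed Master RNG seed (integer).
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param n_true Number of planted enhancers.
#' @param true_len_range Min/max planted enhancer length (bp).
#' @param n_tracks Number of evidence tracks m (<= 12).
#' @param sensitivity Probability a planted enhancer is observed by a track.
#' @param jitter_sd SD of the peak-centre jitter (bp).
#' @param width_jitter_sd SD of the peak-width jitter (bp).
#' @param noise_rate Expected noise peaks per planted enhancer per dataset.
#' @param signal_meanlog,signal_sdlog Log-normal fold-enrichment parameters.
#' @param n_datasets_per_track Datasets generated per track.
#' @param n_promoters,n_exons,n_insulators Planted annotation counts.
#' @param promoter_len,exon_len,insulator_len Annotation interval lengths (bp).
#' @param annotation_peak_rate Probability a dataset emits a contaminating
#'   peak over each planted promoter/exon.
#' @return An object of class `SyntheticScenario` (a validated list).
#' @export
synthetic_scenario <- function(seed = 1L,
                               genome = c(chr1 = 25e6, chr2 = 25e6,
                                          chr3 = 25e6, chr4 = 25e6),
                               n_true = 200L,
                               true_len_range = c(500, 2000),
                               n_tracks = 4L,
                               sensitivity = 0.8,
                               jitter_sd = 50,
                               width_jitter_sd = 50,
                               noise_rate = 1.0,
                               signal_meanlog = 1, signal_sdlog = 0.5,
                               n_datasets_per_track = 1L,
                               n_promoters = 100L, promoter_len = 1000,
                               n_exons = 200L, exon_len = 300,
                               n_insulators = 20L, insulator_len = 5000,
                               annotation_peak_rate = 0.1) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            annotation_peak_rate >= 0, annotation_peak_rate <= 1,
            all(genome > 0), length(names(genome)) == length(genome),
            true_len_range[1] > 0, true_len_range[2] >= true_len_range[1],
            n_tracks >= 1, n_tracks <= length(TRACK_TYPES),
            n_datasets_per_track >= 1, noise_rate >= 0)
  structure(as.list(environment()), class = "SyntheticScenario")
}

#' Generate a synthetic scenario's datasets
#'
#' Fully determined by the scenario's seed: the same scenario always yields
#' identical truth, datasets and annotations. Per-track generation uses
#' child seeds drawn from the master stream, and within a dataset the
#' observe/skip decision for every planted enhancer is drawn before any
#' other quantity, so raising `sensitivity` (all else equal) only ever adds
#' observed peaks.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `truth` (a `PeakDataset` of the planted enhancers,
#'   labelled `STARR` since reporter assays are the direct activity
#'   readout), `datasets` (named list of `PeakDataset`s), `manifest`
#'   (data frame mapping dataset name to track type), `annotations`
#'   (an `AnnotationSet`) and `scenario`.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  sc <- scenario
  set.seed(sc$seed)

  true_len <- round_half_up(stats::runif(sc$n_true, sc$true_len_range[1],
                                         sc$true_len_range[2]))
  truth <- place_disjoint(sc$genome, true_len, occupied = NULL,
                          what = "planted enhancers")
  occ <- truth
  prom <- place_disjoint(sc$genome, rep(sc$promoter_len, sc$n_promoters),
                         occupied = occ, what = "promoters")
  occ <- rbind(occ, prom)
  exon <- place_disjoint(sc$genome, rep(sc$exon_len, sc$n_exons),
                         occupied = occ, what = "exons")
  occ <- rbind(occ, exon)
  insu <- place_disjoint(sc$genome, rep(sc$insulator_len, sc$n_insulators),
                         occupied = occ, what = "insulators")
  occ <- rbind(occ, insu)

  types <- TRACK_TYPES[seq_len(sc$n_tracks)]
  n_ds <- sc$n_tracks * sc$n_datasets_per_track
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_ds)

  datasets <- list()
  k <- 0L
  for (t in seq_len(sc$n_tracks)) {
    for (d in seq_len(sc$n_datasets_per_track)) {
      k <- k + 1L
      nm <- sprintf("%s_d%d", types[t], d)
      datasets[[nm]] <- simulate_dataset(sc, truth, occ, prom, exon,
                                         child_seeds[k], nm, types[t])
    }
  }
  manifest <- data.frame(
    name = names(datasets),
    track_type = vapply(datasets, `[[`, character(1), "track_type"),
    stringsAsFactors = FALSE
  )
  rownames(manifest) <- NULL
  list(
    truth = peak_dataset(truth, name = "truth", track_type = "STARR"),
    datasets = datasets,
    manifest = manifest,
    annotations = annotation_set(promoters = prom, exons = exon,
                                 insulators = insu),
    scenario = sc
  )
}

## place n disjoint intervals uniformly on the genome, avoiding `occupied`
place_disjoint <- function(genome, lengths, occupied = NULL,
                           what = "intervals", max_tries = 200L) {
  n <- length(lengths)
  out <- data.frame(chrom = character(n), start = numeric(n),
                    end = numeric(n), stringsAsFactors = FALSE)
  if (is.null(occupied)) {
    occupied <- data.frame(chrom = character(), start = numeric(),
                           end = numeric())
  }
  occ_chrom <- occupied$chrom
  occ_start <- occupied$start
  occ_end <- occupied$end
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      pos <- draw_position(genome, lengths[i])
      pe <- pos$start + lengths[i]
      hit <- any(occ_chrom == pos$chrom & occ_start < pe &
                   occ_end > pos$start)
      if (!hit) {
        out$chrom[i] <- pos$chrom
        out$start[i] <- pos$start
        out$end[i] <- pe
        occ_chrom <- c(occ_chrom, pos$chrom)
        occ_start <- c(occ_start, pos$start)
        occ_end <- c(occ_end, pe)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("genome too small to place ", n, " disjoint ", what)
    }
  }
  out
}

draw_position <- function(genome, len) {
  ok <- genome >= len
  if (!any(ok)) stop("genome too small for an interval of ", len, " bp")
  g <- genome[ok]
  chrom <- names(g)[1L + findInterval(stats::runif(1) * sum(g),
                                      cumsum(g), left.open = TRUE)]
  start <- floor(stats::runif(1) * (genome[[chrom]] - len + 1))
  list(chrom = chrom, start = start)
}

simulate_dataset <- function(sc, truth, occupied, prom, exon, seed, name,
                             track_type) {
  set.seed(seed)
  n <- nrow(truth)
  ## observe/skip first: common-random-numbers across sensitivity settings
  u <- stats::runif(n)
  cjit <- stats::rnorm(n, 0, sc$jitter_sd)
  wjit <- stats::rnorm(n, 0, sc$width_jitter_sd)
  sig <- stats::rlnorm(n, sc$signal_meanlog, sc$signal_sdlog)
  obs <- u < sc$sensitivity

  centers <- (truth$start + truth$end) / 2 + round_half_up(cjit)
  widths <- pmax(50, round_half_up(truth$end - truth$start + wjit))
  starts <- pmax(0, round_half_up(centers - widths / 2))
  ends <- unname(pmin(starts + widths, sc$genome[truth$chrom]))
  true_part <- data.frame(chrom = truth$chrom, start = starts, end = ends,
                          signal = sig, stringsAsFactors = FALSE)[obs, ,
                                                                  drop = FALSE]

  n_noise <- stats::rpois(1, sc$noise_rate * n)
  noise_w <- round_half_up(stats::runif(n_noise, sc$true_len_range[1],
                                        sc$true_len_range[2]))
  noise_sig <- stats::rlnorm(n_noise, sc$signal_meanlog, sc$signal_sdlog)
  noise_part <- place_noise(sc$genome, noise_w, occupied)
  noise_part$signal <- noise_sig[seq_len(nrow(noise_part))]

  ## contaminating peaks over planted promoters/exons (removed downstream
  ## by annotation exclusion)
  ann <- rbind(prom, exon)
  hit <- stats::runif(nrow(ann)) < sc$annotation_peak_rate
  ann_part <- ann[hit, , drop = FALSE]
  ann_part$signal <- if (nrow(ann_part)) {
    stats::rlnorm(nrow(ann_part), sc$signal_meanlog, sc$signal_sdlog)
  } else numeric()

  all <- rbind(true_part, noise_part, ann_part)
  peak_dataset(all, name = name, track_type = track_type)
}

## uniform noise placement avoiding truth/annotations; noise peaks may
## overlap each other (they are independent false positives)
place_noise <- function(genome, lengths, occupied, max_tries = 100L) {
  keep <- logical(length(lengths))
  chrom <- character(length(lengths))
  start <- numeric(length(lengths))
  for (i in seq_along(lengths)) {
    for (try in seq_len(max_tries)) {
      pos <- draw_position(genome, lengths[i])
      pe <- pos$start + lengths[i]
      hit <- any(occupied$chrom == pos$chrom & occupied$start < pe &
                   occupied$end > pos$start)
      if (!hit) {
        keep[i] <- TRUE
        chrom[i] <- pos$chrom
        start[i] <- pos$start
        break
      }
    }
  }
  data.frame(chrom = chrom[keep], start = start[keep],
             end = start[keep] + lengths[keep],
             signal = rep(1, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Compare a consensus track against planted truth
#'
#' Recall is the fraction of truth enhancers overlapped by at least 1 bp of
#' a consensus peak; precision is the fraction of consensus peaks
#' overlapping at least 1 bp of truth.
#'
#' @param consensus A `ConsensusTrack`, `PeakDataset`, `Track` or peak table.
#' @param truth The planted-enhancer `PeakDataset` (or peak table).
#' @return A list with numeric `precision` and `recall`; with empty truth,
#'   recall is `NaN` with a warning; with an empty consensus, precision is
#'   `NaN`.
#' @export
score_against_truth <- function(consensus, truth) {
  cons_df <- if (inherits(consensus, "ConsensusTrack")) consensus$peaks
  else get_peaks(consensus)
  truth_df <- get_peaks(truth)
  lv <- sort(unique(c(cons_df$chrom, truth_df$chrom)))
  cons_gr <- GenomicRanges::GRanges(
    factor(cons_df$chrom, lv),
    IRanges::IRanges(cons_df$start + 1, cons_df$end))
  truth_gr <- peaks_gr(truth_df, lv)
  if (length(truth_gr) == 0L) {
    warning("empty truth set; recall is undefined")
    recall <- NaN
  } else {
    recall <- mean(IRanges::overlapsAny(truth_gr, cons_gr))
  }
  precision <- if (length(cons_gr) == 0L) NaN
  else mean(IRanges::overlapsAny(cons_gr, truth_gr))
  list(precision = precision, recall = recall)
}

#' Write a generated scenario to disk
#'
#' Writes `truth.bed`, one BED per dataset, `manifest.tsv` and the three
#' annotation BEDs, so a scenario can be fed back through the file-based
#' interface (or the command-line tool).
#'
#' @param generated The list returned by [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(generated$truth, file.path(dir, "truth.bed"))
  paths <- character(length(generated$datasets))
  for (i in seq_along(generated$datasets)) {
    ds <- generated$datasets[[i]]
    paths[i] <- paste0(ds$name, ".bed")
    write_bed(ds, file.path(dir, paths[i]))
  }
  manifest <- generated$manifest
  manifest$path <- paths
  utils::write.table(manifest[, c("path", "track_type", "name")],
                     file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- generated$annotations
  write_bed(as_peaks(ann$promoters), file.path(dir, "promoters.bed"))
  write_bed(as_peaks(ann$exons), file.path(dir, "exons.bed"))
  write_bed(as_peaks(ann$insulators), file.path(dir, "insulators.bed"))
  invisible(dir)
}
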