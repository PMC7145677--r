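# enhcons — consensus enhancer calling from multi-assay peak evidence

Enhancers are distal cis-regulatory DNA elements, and no single genome-wide
assay finds them reliably: P300/POLR2A and histone-mark ChIP-seq, TF
binding, chromatin accessibility (DNase/ATAC, FAIRE, MNase), nascent
transcription (GRO-seq, CAGE), reporter assays (MPRA, STARR-seq) and
ChIA-PET interaction anchors each capture a different, noisy slice of the
enhancer complement. `enhcons` is for genomicists who have peak calls from
several such evidence *tracks* for one tissue or cell type and want a
single, scored consensus enhancer track.

## Method

For a cell type with *m* evidence tracks:

1. **Filter** each dataset: drop peaks longer than 2500 bp; drop peaks
   overlapping promoters, exons or CTCF-defined insulators (≥ 1 bp,
   whole-peak removal); drop datasets whose merged peak coverage falls
   outside 5 kb – 10 Mb.
2. **Normalize** each dataset's fold enrichments to a length-weighted mean
   of one: `s'_i = s_i / (Σ s_i l_i / Σ l_i)`.
3. **Merge within each track** (average-summit/average-width): clusters of
   transitively overlapping peaks become one peak centered at the mean
   summit with the mean width and the mean normalized signal.
4. **Weight the tracks** by mutual agreement, using a region-count Jaccard
   index `J_ij = Num(A_i ∩ A_j) / Num(A_i ∪ A_j)` over merged union
   intervals; the weight of track *t* is its off-diagonal row sum over all
   off-diagonal entries, so `Σ w_t = 1`.
5. **Call the consensus**: merged union regions supported by ≥ 50 % of
   tracks (at least two; with two tracks, both) are kept and scored
   `Score_combined = Σ w_t L_t Score_t / L_combined` over all contributing
   peaks.

A synthetic-data module generates multi-track scenarios with known planted
enhancers, so the whole pipeline is testable offline.

## Worked example

```r
library(enhcons)

# four simulated evidence tracks, 200 planted enhancers, matched noise
gen <- generate_scenario(synthetic_scenario(seed = 1))
res <- run_pipeline(gen$datasets, gen$annotations, cell_type = "synthetic")

res$weights
#>      P300    POLR2A   Histone TF-binding
#> 0.2507497 0.2379124 0.2596772  0.2516607

score_against_truth(res$consensus, gen$truth)
#> $precision 0.960199    $recall 0.965
```

The weights are near-uniform because the four simulated tracks are equally
reliable; on real data better-corroborated tracks earn more weight. The
consensus recovers 96.5 % of the planted enhancers at 96 % precision,
while each individual track sits near 45 % precision — corroboration
across assays is what removes the noise.

Per-peak output (BED: supporting tracks in column 4, combined score in
column 5):

```
chr1  610923  612709  P300,POLR2A,Histone,TF-binding  1.1177
chr1  1091175 1092315 P300,POLR2A,Histone,TF-binding  0.633573
chr1  1763520 1764601 POLR2A,TF-binding               0.501096
```

File-based use goes through a manifest (TSV: `path`, `track_type`,
optional `name`/`format`/`signal_column`) and the thin CLI:

```sh
Rscript inst/cli/enhcons.R synth --seed 1 --out synth/
Rscript inst/cli/enhcons.R build --manifest synth/manifest.tsv \
    --promoters synth/promoters.bed --exons synth/exons.bed \
    --insulators synth/insulators.bed --out out/
```

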