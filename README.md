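# ancestrypaint

Visualization of global and local ancestry inferred by **RFMIX2**.

Admixed individuals carry genomic segments from multiple source
populations. Local-ancestry inference software such as RFMIX2 reports, per
chromosome, (i) each individual's **global ancestry** — the genome-wide
proportion *q<sub>k</sub>* of each reference ancestry *k* (`.rfmix.Q`
files) — and (ii) **local ancestry** — the most probable ancestry code of
every genomic window on each of the two haplotypes (`.msp.tsv` files).
RFMIX2 has no built-in way to visualize either. `ancestrypaint` fills that
gap for population geneticists and genetic epidemiologists:

- **GAP** (Global Ancestry Painting): combine per-chromosome `.rfmix.Q`
  files, compute each individual's unweighted mean ancestry components
  across chromosomes, optionally sort individuals by one component, and
  render a stacked bar plot (one bar per individual, legend of ancestry
  origins).
- **LAP** (Local Ancestry Painting): combine per-chromosome `.msp.tsv`
  files, collapse windows into maximal constant-ancestry **tracts** per
  haplotype, export them as per-haplotype BED files
  (`<sample>_hap1.bed` / `<sample>_hap2.bed`), and render a diploid
  karyogram — one row per chromosome, two color bands per row — on a
  4210 × 1663 canvas. White regions are unknown ancestry or missing SNP
  data. Up to 10 ancestry components receive colors; components beyond the
  10th are not displayed (a warning is logged).
- **Locus composition**: for a query interval (e.g. the *MCM6* regulatory
  region), assign each haplotype in the cohort the ancestry with the
  largest base-pair overlap and report counts and 1-decimal percentages.
- **Synthetic data**: a generator that emulates RFMIX2 output from a
  ground-truth tract model (exponential tract lengths, i.i.d. tract
  ancestries), so the whole pipeline is testable with no external data.

All coordinates are 0-based half-open throughout (msp windows, BED,
region strings).

## Worked example

```r
library(ancestrypaint)

# simulate a 5-individual cohort, 22 chromosomes, known ground truth
cfg <- sim_config(n_samples = 5,
                  genome = setNames(rep(2e7, 22), as.character(1:22)),
                  seed = 42)
d <- tempfile(); res <- write_fixture(cfg, d)

# GAP: combine, average, sort by the Middle Eastern component
mat <- sort_by_ancestry(combine_and_average(read_q_files(res$prefix, 1:22)),
                        "MiddleEast")
print(mat)
#> <mean_ancestry> 5 sample(s), K = 3
#>   sample MiddleEast    Europe SubSaharanAfrica n_chroms
#> 1    S02  0.6040264 0.2820602        0.1139134       22
#> 2    S03  0.6002387 0.2282411        0.1715202       22
#> 3    S04  0.5638462 0.2880605        0.1480932       22
#> 4    S05  0.5388443 0.2584598        0.2026958       22
#> 5    S01  0.5180953 0.3492831        0.1326217       22
```

Each row is one individual's mean ancestry fractions across the 22
chromosomes (rows sum to 1), ordered largest-to-smallest Middle Eastern
component; `render_gap(mat, "gap.svg", "svg")` draws the bar plot.

```r
# LAP + locus composition
msp <- combine_msp(read_msp_files(res$prefix, 1:22))
tracts <- rbind(windows_to_tracts(msp, "S02", 0L),
                windows_to_tracts(msp, "S02", 1L))
render_lap(tracts, build_palette(msp$codebook), chromosome_lengths(msp),
           "lap.png", format = "png")   # exactly 4210 x 1663 pixels

print(locus_composition(msp, "2:1000000-1050000"))
#> <locus_composition> 2:1000000-1050000 over 10 haplotypes (majority rule)
#>   MiddleEast                    5   50.0%
#>   Europe                        4   40.0%
#>   SubSaharanAfrica              1   10.0%
#>   Unknown                       0    0.0%
```

Of the 10 haplotypes (2 × 5 individuals), 5 carry a Middle Eastern
segment across the interval, 4 a European one, 1 a sub-Saharan African
one; percentages are counts / haplotypes, rounded half-up to 1 decimal.

## Command line

The same pipelines as subcommands (`inst/exec/ancestrypaint`, or call
`ancestrypaint::ap_main()`):

```sh
ancestrypaint simulate -o data --seed 7
ancestrypaint gap combine --input-prefix data/fixture --chromosomes 1-22 \
    --sort-ancestry MiddleEast -o gap.tsv
ancestrypaint gap plot --input gap.tsv --format pdf -o gap.pdf
ancestrypaint lap combine --input-prefix data/fixture --bed-out beds \
    -o all.msp.tsv
ancestrypaint lap plot --input all.msp.tsv --sample S01 --format png \
    --highlight 2:136545000-136594750:MCM6 -o lap.png
ancestrypaint locus summarize --input all.msp.tsv \
    --region 2:136545000-136594750 -o report.tsv
```

Exit codes: 0 success, 1 format/validation error, 2 usage error.

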