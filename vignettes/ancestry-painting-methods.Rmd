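---
title: "Methods: painting global and local ancestry from RFMIX2 output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: painting global and local ancestry from RFMIX2 output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestrypaint)
```

## The problem

RFMIX2 infers, for a cohort of admixed individuals, which reference
ancestry each genomic window of each haplotype derives from. Its output
is numerical: per chromosome, a `.rfmix.Q` table of per-sample global
ancestry proportions, and a `.msp.tsv` table of per-window most-probable
ancestry codes (two columns per sample, one per haplotype). This package
turns those files into the two standard summaries of admixture — a
per-individual stacked bar plot of genome-wide proportions, and a
per-individual chromosome "painting" — plus a locus-level composition
report, and provides a synthetic generator so all of it can be validated
against known ground truth.

## Models and procedures

### Global ancestry (GAP)

Let $q_{ick}$ be sample $i$'s reported fraction of ancestry $k$ on
chromosome $c$. The displayed quantity is the **unweighted** chromosome
mean $\bar q_{ik} = \frac{1}{C_i}\sum_{c} q_{ick}$, where $C_i$ is the
number of chromosomes on which $i$ appears. Chromosomes count equally
regardless of physical length or SNP count; this is the plain reading of
"mean across chromosomes", and since RFMIX2 reports per-chromosome
proportions on very different chromosome sizes, the unweighted and
length-weighted means genuinely differ. A weighted mean is available via
the `weights=` argument of `combine_and_average()` but is not the
default. Samples absent from some chromosomes are averaged over the
chromosomes they have, with `n_chroms` recorded and a warning — failing
soft but with provenance.

Sorting (`sort_by_ancestry()`) is descending in one component with ties
broken by sample id (ascending, C collation), which makes bar order
fully deterministic.

### Local ancestry (LAP)

A **tract** is a maximal run of constant ancestry along one haplotype.
Windows are merged into tracts when and only when they abut
(`epos == next spos`) and share a code. A coordinate gap — regions where
RFMIX2 had no SNPs — always breaks the tract, even between equal codes,
so those regions keep the background color in the karyogram rather than
being bridged by an invented call. Tract coverage therefore equals
window coverage exactly (an invariant the tests check as integer
equality).

The karyogram canvas is exactly 4210 × 1663 units (pixels for PNG); one
row per chromosome in ascending natural order, each row two parallel
bands with haplotype 0 above haplotype 1. The horizontal axis is
physical position; genetic positions (`sgpos`/`egpos`) are parsed and
preserved but not used for layout. Chromosome lengths default to the
maximum observed window end and can only be overridden *upward* by a
chrom-sizes file (an override below an observed coordinate is an error,
since a tract would overrun its chromosome).

Colors: at most 10, assigned in codebook order from the default sequence
`#FF8C00, #800080, #1E90FF, #228B22, #DC143C, #8B4513, #20B2AA, #FF69B4,
#708090, #BDB76B` (the first three echo the conventional orange = Middle
East, purple = Europe, blue = sub-Saharan Africa mapping; the rest chosen
for pairwise contrast). Components beyond the 10th receive no color: in
LAP their tracts are simply not drawn; in GAP their bar mass is omitted
**without renormalizing** — a bar then visibly falls short of 1.0, which
is more honest than silently rescaling the displayed components — and a
warning is always raised.

### Locus composition

For a query interval, each haplotype is assigned the ancestry with the
largest base-pair overlap between the interval and that haplotype's
windows (majority-by-overlap). Ties go to the lower ancestry code;
haplotypes with zero overlapping coverage count as `Unknown`, so
ancestry counts plus unknown always equal $2N$ exactly. The majority
rule is a deliberate design choice for intervals containing a
recombination breakpoint: a one-call-per-haplotype rule is what lets one
say "this region is Middle Eastern on 53.7% of chromosomes". Per-bp
fractional accounting is available with `per_base = TRUE` for users who
prefer mass over calls. Percentages are rounded half-up to one decimal
(`floor(10x + 0.5)/10`, with a tiny epsilon against binary
representation of exact halves), matching the precision such reports are
conventionally printed at.

## The synthetic generator: what it emulates and what it does not

`sim_config()` describes a stated world: ancestry names and ground-truth
proportions $p$ (default 0.55/0.30/0.15 over three components), a genome
(default 22 chromosomes × 100 Mb), 30 diploid samples, mean tract length
5 Mb, 500 kb msp windows with 300 SNPs each, seed 1729. Tracts are laid
left-to-right with i.i.d. exponential lengths (truncated at the
chromosome end) and i.i.d. ancestries drawn from $p$, merging equal-code
neighbours. Drawing ancestries independently — rather than a no-self-
transition Markov chain — makes the expected bp share of each ancestry
equal $p$ exactly, which is precisely what parameter-recovery tests need
to check against. The defaults are of the order seen in recently admixed
human populations (a 5 Mb mean tract corresponds to admixture a few
dozen generations ago), but the generator emulates *file structure and
marginal statistics only*: no recombination map, no LD, no drift, no
inference error (window codes are exact majority calls on the truth). A
green recovery test therefore establishes that the *pipeline arithmetic*
is faithful, not that RFMIX2 itself is accurate on real data.

Determinism: every (chromosome, sample, haplotype) triple draws from its
own seed derived from the config seed (all below $2^{31}$), so a single
haplotype can be re-simulated reproducibly in isolation and a fixture
written twice is byte-identical.

`realized_q()` converts truth tracts into exact per-chromosome Q tables
(fractions of bp per ancestry over both haplotypes; rows sum to 1
exactly), and `tracts_to_msp()` discretizes tracts into windows by
majority-bp within each window (ties to the lower code), mapping genetic
position at 1 cM/Mb. Discretization moves breakpoints by at most one
window, a bound the tests verify.

## Numerical and rendering choices

- Q row sums are validated to 1 ± 1e-4 (RFMIX2 prints rounded decimals);
  all fraction writers print 6 decimals, making write→read round trips
  lossless at that precision.
- Coordinates are treated as 0-based half-open everywhere. Whether
  RFMIX2's `spos` is 0- or 1-based is not documented; half-open is the
  convention that makes adjacent windows tile exactly and carries through
  to BED unchanged.
- `hap1`/`hap2` BED files correspond to the `.0`/`.1` msp columns. They
  are often described as maternal/paternal, but phase alone cannot
  establish parental origin, so this package treats them as arbitrary
  haplotype indices.
- SVG output is generated by a small retained-mode scene writer rather
  than a graphics device: element order, number formatting (fixed
  2-decimal) and attributes are fully determined by the input, so
  identical inputs produce byte-identical files — a testable
  reproducibility contract no device backend guarantees. PDF and PNG use
  cairo devices over the same scene; PNG maps one scene unit to one
  pixel so the 4210 × 1663 canvas is exact. PNG export exists precisely
  to make that dimension machine-checkable.
- Per-chromosome files are discovered as `<prefix>.chr<N>.rfmix.Q` /
  `<prefix>.chr<N>.msp.tsv`; missing chromosomes are skipped with a
  warning rather than failing the run, since partial runs are common.

## Degenerate inputs and tie-breaks (summary)

| Situation | Behaviour |
|---|---|
| Q row sum off by > 1e-4 | validation error naming the sample |
| window overlap / disorder | validation error with coordinates |
| empty mean-ancestry table | error: nothing to plot |
| equal sort keys | sample id ascending |
| equal locus overlap | lower ancestry code |
| equal bp in a window (synth) | lower ancestry code |
| > 10 components | first 10 drawn, warning, no renormalization |
| interval with no coverage | haplotype counted as Unknown |

## Known limitations

- Not a population-genetic simulator; tract-length and switch-point
  statistics of real admixed genomes (which depend on recombination maps
  and admixture timing) are only caricatured.
- No cytobands, centromeres, or multi-sample composite karyograms; one
  individual per LAP figure.
- The per-bp locus mode reports mass, not calls, so its `counts` field is
  `NA` by design.
- GAP bar labels become cramped beyond a few hundred individuals; the
  canvas widens linearly (40 units/bar) but font size is fixed.
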