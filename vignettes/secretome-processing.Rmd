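---
title: "Precursor processing grammar and secretome inference with secretopep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precursor processing grammar and secretome inference with secretopep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretopep)
library(dplyr)
```

## The biological model

Classical neuropeptide biosynthesis runs through a conserved enzymatic
relay. A precursor protein enters the secretory pathway via an N-terminal
signal peptide, which is removed co-translationally. Subtilisin-like
prohormone convertases (PCs) then cleave the precursor after single or
paired basic residues — the consensus is (K/R)X~n~(K/R)↓, with the scissile
bond after the C-terminal basic residue. Furin, which unlike PC1/PC2 does
not need an acidic compartment, recognizes the stricter RX(K/R)R↓
consensus. Carboxypeptidase-B-like exopeptidases (CPE/CPD) next trim the
C-terminal Lys/Arg left by endoproteolysis, and peptidylglycine
α-amidating monooxygenase (PAM) converts any product that now ends in Gly
into a des-Gly peptide-amide: the Gly is consumed and the preceding residue
carries the amide.

`secretopep` implements this relay as a motif grammar plus a product
enumerator, and surrounds it with the bookkeeping needed to apply it to a
real secretome experiment: selection of signal-peptide-positive, membrane-
helix-free proteins; replicate merging of label-free spectral counts;
membrane-topology classification; and intact-versus-cleaved inference from
gel-slice-resolved peptide evidence. Everything takes and returns tibbles
so stages chain with the pipe.

## The motif grammar and its parameters

All coordinates are 1-based inclusive and cleavage points are expressed as
"after residue *i*". Matching is overlap-aware: every match is reported,
nested and overlapping ones included, because deduplication is a
product-enumeration concern (overlapping sites that share a cut point
collapse to a single cut).

* **PC sites** (K/R)X~n~(K/R): the spacing set is configurable.
  `motif_config()` defaults to n ∈ {0, 2, 4, 6}; a restricted preset
  (`preset = "results-spacings"`, n ∈ {0, 2}) is provided because both
  conventions are in active use for this grammar and the two scans differ
  in sensitivity. X is any residue, including K, R or G.
* **Furin sites** RX(K/R)R: screened separately; cleavage after the final
  R. A furin site whose X is Gly (RG(K/R)R) is *amidatable*: after
  cleavage and CPB trimming the product ends in Gly.
* **Amidation signatures**: G(K/R)(K/R), (K/R)X~n~G(K/R) with n ∈ {1, 3},
  and RG(K/R)R. Each records the Gly that ends up donating the amide.
* **Direct C-terminal amidation**: a protein ending in -Gly, or in
  -Gly-(Lys/Arg)~n~ with n ≤ `max_basic_tail` (default 3), can be amidated
  without prior endoproteolysis.
* **Known-motif mode**: a user-replaceable table of cleavage patterns over
  {K, R, X}. Published known-motif tables for this style of prediction are
  not standardized, so the shipped default is the mono-/dibasic plus
  spaced set (KR, RR, KK, RK, KXXK, KXXR, RXXR, RXXK) with the exclusions
  RK, KXXK and KXXR applied *after* matching, reflecting cleavages not
  observed in mollusk-trained motif sets. Users reproducing a specific
  published scan should substitute that scan's motif table via
  `motif_config(known_motifs = ...)`.

Sites overlapping the annotated signal peptide are flagged (`in_signal`)
and excluded from product enumeration: the signal peptide is removed before
the convertases ever see the chain.

## Product enumeration

`cleave()` cuts the mature chain simultaneously at all predicted sites.
The real enzymes act in an ordered series, but for counting products the
order is irrelevant, so kinetics are deliberately not modeled. The
resulting peptides tile the mature chain exactly — a conservation law the
tests enforce. `trim_and_amidate()` then applies the CPB/PAM rules:
iteratively strip C-terminal K/R, and if the remainder ends in Gly *and
retains at least one further residue*, mark the peptide amidated. A peptide
trimmed to nothing, or to a lone Gly, is flagged degenerate (an amide of
nothing is meaningless); the minimum amidated product length is therefore
one residue. Amidated peptides are counted per (precursor, span):
identical sequences arising from different precursors count separately.

```{r example}
prot <- tibble::tibble(protein_id = "demo",
                       sequence = "MKWVSAEGKRSFLDRGRRTTG",
                       signal_end = 4L)
sites <- bind_rows(find_pc_sites(prot), find_furin_sites(prot))
cleave(prot, filter(sites, !in_signal)) %>% trim_and_amidate()
```

`summarize_proteome()` wraps the whole scan and returns a
`proteome_summary` with broom-style `tidy()`/`glance()` methods and an
`autoplot()` of the amidated-residue histogram.

## Secretome merging

Label-free spectral counts from replicate runs are merged by
`merge_and_filter()`:

* **Normalization**: each sample is scaled to the mean per-sample total
  ("equal-total" normalized spectral counts). The exact formula behind
  published "normalized spectral counts" varies by software; equal-total
  scaling is the conventional choice and can be switched off
  (`normalize = "none"`).
* **Presence filter**: proteins seen in fewer than `min_presence` samples
  (default 4, for a six-sample design) are dropped. Absent samples
  contribute **zero** — not missing — to the per-protein mean and SEM,
  because the published averages of this design are over all six samples.
  SEM uses the n−1 sample standard deviation over all samples divided by
  √n.
* **Ranking**: descending mean normalized total; ties broken
  lexicographically by id for determinism. `rank_and_share()` reports the
  fraction of total counts carried by the top-n proteins.

`triage_signal_peptide()` implements the localization triage: a protein is
signal-peptide-containing when its predicted localization is SP, or when it
is O/NA but carries a predicted signal peptide; chloroplast- and
mitochondrion-assigned proteins are excluded even when a signal peptide is
predicted, since those localization calls dominate. `dataset_census()`
reports per-dataset, union and intersection identification counts rather
than a single combined number, because published per-dataset and combined
totals are not always mutually consistent.

## Topology classification

`classify_topology()` uses only two booleans — signal peptide present,
TM helix present — to assign secreted / Type I / Type II / other. Helix
*position* is deliberately ignored: a protein whose only helix sits near
the C-terminus but that lacks a cleavable signal peptide is still Type II
under this rule set, which reproduces the published grouping of all 21
S8-peptidase-domain proteins of *C. reinhardtii* (7 secreted, 1 Type I,
6 Type II, 7 other; annotations packaged under `inst/extdata/`).

## Gel-slice cleavage inference

A protein digested in-gel leaves its tryptic peptides in the slice where it
migrated. `call_cleavage()` compares each evidence slice against the
protein's intact mass:

* slices with `mass_high < (1 − tolerance_fraction) × intact mass` are
  *sub-intact*; `tolerance_fraction = 0.2` absorbs the imprecision of gel
  migration (no threshold is standard, so this is a stated package
  default).
* sub-intact slices carrying at least `min_counts = 2` summed spectral
  counts trigger a **cleaved** call — two counts guard against a single
  stray peptide-spectrum match.
* fragment regions are the per-slice hulls of the contributing peptide
  spans (the region the peptides came from), merged when they overlap,
  and labeled N-terminal / C-terminal / internal using a 40%-of-length
  cutoff at each end — a heuristic matching how fragment diagrams are read
  qualitatively.
* a protein whose evidence sits entirely at or above its intact-mass slice
  is **intact**; anything else (evidence below the intact slice but within
  the tolerance band, or too few sub-intact counts) is **ambiguous**.

Raising the tolerance can only shrink the sub-intact set, so it never
converts an intact call into a cleaved one — a monotonicity property the
tests check. Intact masses come from an annotation table;
`mass_from_sequence()` offers an average-residue-mass approximation as a
clearly-labeled fallback, which will underestimate heavily glycosylated
cell-wall proteins.

## The synthetic-data generator

Every stage is testable without downloads because the generators plant
ground truth:

* `generate_precursor()` builds signal peptide + alternating spacers and
  motif blocks. Spacers are drawn from an alphabet excluding K, R and G,
  so the false-positive expectation in spacer regions is exactly zero, and
  spacer length (default 8) exceeds the largest PC spacing so adjacent
  blocks cannot combine into unplanned motifs. Planted `GKR` blocks yield
  exactly one amidated peptide each, with a known amide residue.
* `generate_secretome()` draws a presence level per protein (1–6 samples)
  and strictly positive negative-binomial counts (mean 20, size 2). Real
  spectral counts are overdispersed; the negative binomial is a harness
  choice, not a claim about the data-generating process of any instrument.
* `generate_gel_dataset()` places intact proteins' evidence in or above
  their intact-mass slice and cleaved proteins' evidence inside a planted
  terminal fragment in a slice below 0.7× the intact mass.

All generators are pure functions of (parameters, seed) and restore the
caller's RNG state. What passing these tests shows is that the
implementation is faithful to its stated rules; it does not show that the
rules capture every feature of real data — real secretomes contain shared
tryptic peptides, protein groups, glycosylation-shifted migration and
annotation errors that the generators deliberately do not emulate.

## Numerical and testing choices

Determinism is enforced end to end: identical inputs and configuration
produce byte-identical TSV exports, and each pipeline run writes a manifest
with a configuration hash and input MD5 checksums. The oracle tests
compare every motif finder against an exhaustive brute-force matcher on
1000 seeded random sequences (lengths 10–500), and the analytic check
verifies that the mean number of spacing-n PC sites in i.i.d. sequences of
length L with per-residue basic probability p matches (L − n − 1)p² within
three Monte-Carlo standard errors over 10,000 simulated sequences —
problem sizes chosen to make the statistical comparison sharp while
keeping the suite quick on a laptop. Synthetic-recovery tests use 20–300
proteins per scenario for the same reason.

## Known limitations

* Genome-scale reproduction of published precursor counts requires the
  original proteome FASTA and SignalP/TMHMM annotation tables, which are
  not redistributable here; with pinned inputs the pipeline is
  deterministic, and any residual count differences trace to the
  known-motif table choice discussed above.
* No mass-spectrometric observability, PTM or disulfide modeling: a
  predicted peptide is a sequence-level object.
* Protein grouping/parsimony of search engines is out of scope; counts are
  consumed per reported protein id.
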