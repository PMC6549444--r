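---
title: "Methods: strain-diagnostic marker analysis for fall armyworm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-diagnostic marker analysis for fall armyworm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fawstrain)
```

## The problem

Fall armyworm (*Spodoptera frugiperda*) comprises two host strains —
corn-strain and rice-strain — that cannot be told apart morphologically.
Field surveys therefore genotype specimens at diagnostic single-nucleotide
polymorphisms in two genes: the maternally inherited mitochondrial *COI*
(a ~603-bp amplicon, COIB) and the Z-linked nuclear *Tpi* (an exon-4
segment, TpiE4, and the adjacent fourth intron, TpiI4). In Lepidoptera,
females are the heterogametic sex (ZW), so females carry one *Tpi* copy
and males two. This package implements the complete analysis from Sanger
consensus sequences (or pre-tabulated counts) to strain frequencies,
concordance tables, regional tests, and intron trees.

## The marker panel and coordinates

All classification is driven by a panel directory: segment reference
sequences, diagnostic sites, and reference haplotypes
(see `?read_marker_panel`). Site positions are 1-based offsets from each
segment's biological origin — the predicted translational start for *COI*,
the 5′ exon start for TpiE4, the 5′ intron start for TpiI4 — so the
familiar site names (mCOI1164D, gTpi183Y, gTpiI4[131]R) are used directly.
Each segment record carries the origin coordinate of its first reference
base, and queries are never indexed by absolute offset: every read of a
site goes through a pairwise alignment, because amplicons start at primer
positions and introns carry indels.

The packaged default panel's reference sequences are **synthetic**
stand-ins (the deposited field sequences are not redistributed with the
package): random backbones into which every documented diagnostic allele
state has been placed — the h-configuration states of mCOI1164D and
mCOI1287R, the five strain-biased COIB sites, the eight TpiE4 site states
implied by the heterozygote class names, and the ~200-bp insertion
distinguishing one intron haplotype. Classification logic is exercised
fully by this panel; analyses of real collections should transcribe the
laboratory's own reference states into a panel directory of the same
layout.

One numbering note: the intron core is described as running from intron
nucleotide 10 to 172, which is 163 bases inclusive; the package uses the
stated span. The poor-signal intron site is taken at position 131 with
consensus base G forced before matching; the position is configurable in
the panel file because published descriptions of this site's numbering
are inconsistent.

## Anchoring alignment

`anchor_to_reference()` aligns a query to its segment reference with an
ends-free ("overlap") gap-affine alignment: match +1, mismatch −1, gap
open 12, gap extension 0.25; IUPAC ambiguity codes score as a match
against any base they admit. The extension cost is deliberately set well
below the mismatch cost: a long biological insertion (such as the 200-bp
intron insertion) must be cheaper to keep as one contiguous gap than to
shred into chance matches against the flanking reference — with extension
costs near the mismatch cost the optimal alignment of a random-content
insert fragments, losing diagnostic sites. Above the default 80% identity
floor the exact parameter values do not otherwise affect calls; queries
below the floor raise a classed `fawstrain_unalignable` error. A
diagnostic site falling in a query gap fails that site only; other sites
on the same sequence remain callable.

## Classification rules

* **COI strain** (mCOI1164D): T → RS, A or G → CS, C (never observed in
  the species) → unknown with a QC flag; ambiguity → failed (mitochondrial
  sequences should not be heterozygous).
* **h-configuration** (mCOI1164D × mCOI1287R): h1 = A/A, h2 = A/G,
  h3 = G/A, h4 = G/G for corn-strain sequences; rice-strain (T₁₁₆₄) is
  not-applicable. The h-set and the strain call agree by construction:
  a sequence is h1–h4 exactly when it is CS.
* **COIB haplotype**: exact allele-vector match over all panel sites; no
  match is `novel` with its mismatch profile attached, and novel vectors
  can be added under deterministic auto-labels (strain prefix + next free
  index + optional run suffix) so repeated runs agree.
* **Species QC**: minimum Hamming distance over aligned, ungapped columns
  to any panel COIB haplotype must be ≤ 1, mirroring the survey's
  inclusion rule.
* **TpiE4 genotype**: an unambiguous vector matching a panel haplotype is
  a hemizygous/homozygous call. A vector with two-allele ambiguity codes
  is decoded as the unique unordered pair of panel haplotypes whose
  site-wise IUPAC union reproduces it (C-YY = Ca1/Ca2, H-CC = Ca1/Ra1,
  H-YY = Ca2/Ra1). With three panel haplotypes this decoding is a
  bijection, which the tests verify exhaustively; more than one consistent
  pair (possible only in extended panels) is reported as ambiguous with
  candidates. Codes a site's definition does not admit (e.g. N) fail the
  specimen for this marker, matching the surveys' silent exclusion of
  unscorable specimens.
* **TpiI4 haplotype**: the poor-signal site is forced to consensus, then
  any remaining ambiguity in the core — or indel evidence incompatible
  with every panel haplotype — means an unresolvable heterozygote, which
  is reported only as a lump count and excluded from haplotype
  frequencies. Otherwise exact match of core sequence plus insertion
  features (length and position within a ±10 bp tolerance) assigns the
  label.

## Counting and the sex-linkage adjustment

`tabulate_collection()` excludes a specimen from a marker's counts only
when that marker's call failed; specimens failing species QC are dropped
entirely. `adjust_tpi_counts()` converts specimen counts to chromosome
counts: each unambiguous specimen contributes *m* chromosomes of its
allele — *m* = 2 in male-only pheromone-trap collections, *m* = 1.5 in
larval collections of unknown sex under an assumed 1:1 ratio (the average
of 2 male and 1 female copies; the ratio is a parameter) — and each
heterozygote contributes one chromosome to each constituent allele.
Reported values are rounded half-up (58.5 → 59), which reproduces every
half-valued cell of the published survey table; raw (unrounded) values
are kept alongside and used for frequencies.

A subtlety worth knowing: on larval collections the ×1.5 estimator is
*not* exactly consistent even when the true sex ratio is 1:1. Conditioning
on "unambiguous" enriches for hemizygous females (probability ∝ (1−s)p)
over homozygous males (∝ s·p²), so weighting the class by the average 1.5
chromosomes over-counts single-chromosome carriers. At allele frequencies
(0.6, 0.3, 0.1) the asymptotic estimate of the first allele is 0.589
rather than 0.600; the bias grows as the true ratio departs from 1:1. The
property tests assert this closed form. Male-only collections are exactly
unbiased (E[raw]/n = 2p), and the package's recovery checks use them.

## Frequencies, means and the regional test

Two summaries are exposed and must not be conflated:
`frequency_summary()` computes per-collection proportions and averages
them **unweighted** (each collection one unit, with sample SD) — this is
the form that reproduces the published mean-frequency rows —
while `pooled_shares()` pools counts over specimens first, reproducing
statements like "99% of the COI-defined corn-strain group". The two
differ whenever collection sizes differ.

The regional comparison (`compare_regions()`) is a two-sided t-test on
per-collection proportions. The published analysis states only "two-tailed
t-test"; this package defaults to the Welch unequal-variance flavour
because the compared groups (3 western collections vs 10 others) have very
different sizes and spreads, with the pooled-variance Student form
available via `var_equal = TRUE`. Significance letters are assigned at
α = 0.05. No multiple-testing correction is applied, matching the
single-test design; this is noted in output metadata rather than silently
"improved". On the packaged fixture the corn-strain *COI* frequency of
{TOGa, TOGb, STP} vs the rest gives p ≈ 7×10⁻⁶.

The packaged fixtures transcribe the published observed counts. Their
pooled sums (e.g. 365/369 corn-strain specimens) differ slightly from two
pooled totals printed in the source survey's text (372/376); the package
reports what the fixture computes and does not force agreement — the
rounded percentages coincide anyway.

## Intron distances and trees

`tn93_distance()` implements the Tamura–Nei (1993) maximum-likelihood
distance with base frequencies estimated from the pooled pair and
**pairwise deletion** of gap/ambiguity columns. Pairwise (not complete)
deletion matters here: complete deletion would discard the insertion
region of every pair because one haplotype carries a 200-bp insert.
Saturation (non-positive log argument) returns `Inf` rather than an
error, and pairs sharing fewer than 20 comparable sites are undefined.
Unequal-length pairs are globally aligned first with the same IUPAC-aware
scoring as anchoring.

`nj_tree()` is Saitou–Nei neighbor-joining with the standard Q-criterion,
exact on additive matrices. Two determinism choices: Q-ties are broken by
the lexicographic order of the candidate pair's smallest member tip
labels, and subtrees are serialized smaller-key-first, so the same matrix
yields byte-identical newick regardless of row order. Negative
branch-length estimates are clamped to zero with the deficit transferred
to the sibling edge, preserving the joined pair's distance — standard
practice that keeps the newick valid. The published figure this module
stands in for was drawn from an externally computed maximum-likelihood
tree; this package deliberately uses TN93 distances + NJ (both also part
of the published workflow) to reproduce the figure's *qualitative* claim —
that the African rice-strain intron haplotype falls in a clade of
rice-strain-annotated Western Hemisphere sequences — not the external
program's exact output. `clade_composition()` reports, for each nested
clade containing a focal tip from the smallest outward, the fraction of
member tips per host class and per COI strain; duplicate sequences are
collapsed to unique haplotypes first (`collapse_duplicates()`), mirroring
the published filtering.

## The synthetic-data generator

`sim_config()` defaults *are* the emulated study conditions, chosen once:
the 13 collections with their published sizes and source types (one
male-only pheromone-trap set, twelve larval), COIB haplotype frequencies
at the continental means (0.33, 0.01, 0.63, 0.02, 0.005, 0.005), Tpi
allele frequencies at the adjusted continental means (0.59, 0.31, 0.10),
intron haplotypes drawn conditionally on the exon allele with the rare
insertion variant at 0.3%, sex ratio 0.5, and zero sequencing-failure and
site-error rates. Mito–nuclear coupling defaults to independent draws —
the decoupling actually observed in the invasive range — with an optional
single-parameter discordance model (probability that the mitochondrial
strain class disagrees with the Tpi-derived one) for controlled
experiments.

Sequences are constructed by editing the panel references at diagnostic
sites plus indel features, not by simulating sequence evolution: the
pipeline reads only those positions, so richer evolution would add
nothing the classifier can see. Male heterozygotes are emitted as one
consensus sequence with IUPAC codes where their alleles differ. Intron
heterozygotes whose alleles differ by an indel are emitted as the shared
core with N from the indel point onward, imitating the unreadable
superimposed traces downstream of an indel in real Sanger data; any N in
the core is then called heterozygous, which closes the loop with the
reporting rule. What the generator does **not** emulate: base-quality
variation, chromatogram artifacts, PCR chimeras, novel haplotypes outside
the panel, and within-collection population structure. Passing recovery
tests therefore validate the pipeline's bookkeeping and the estimator's
sampling behaviour, not robustness to real-world sequencing noise.

Everything is reproducible from a single integer seed
(`simulate_study(cfg, seed)`); identical seed and configuration give
byte-identical outputs.

## Problem sizes and numerical choices

The test-suite simulations use one 2000-specimen male-trap collection for
the headline recovery check (estimates within 3 binomial SE of the
realized truth), 200 replicate 30-specimen collections for the
unbiasedness property, and 1500-specimen larval collections for the
sex-ratio bias closed form; classification memoizes identical sequences,
so these sizes run in seconds. Alignment-based tests verify the anchoring
against a brute-force dynamic-programming oracle on 60-bp windows, and
distance/tree code against closed forms, hand-evaluated formulas and an
independent reference implementation. Tolerances follow the quantity:
exact integer equality for adjusted counts, two decimals where the
published tables print two, 10⁻⁸–10⁻¹² for closed-form identities.

## Known limitations

* The default panel's reference backbones are synthetic; real-survey
  reclassification requires transcribing laboratory reference states.
* Heterozygosity is inferred solely from IUPAC codes in consensus
  sequences; chromatogram (.ab1) evidence is out of scope.
* The larval ×1.5 adjustment carries the conditioning bias described
  above; treat larval-only frequency contrasts near the 1% level with
  care.
* TpiI4 heterozygotes are a lump count; no attempt is made to deconvolve
  multi-haplotype combinations.
* Maximum-likelihood tree inference, bootstrap support and model
  selection are out of scope; the NJ tree is a qualitative stand-in.
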