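---
title: "Methods: coding-alignment diversity and trait association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding-alignment diversity and trait association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erucaseq)
```

`erucaseq` analyses an in-frame protein-coding DNA alignment — its motivating
case is the *FAE1* gene of Brassicaceae, whose variation tracks the
erucic-acid content of seeds — and tests whether that variation is structured
by a categorical phenotype. This vignette records the statistical model
behind each operation, the conventions and tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## The alignment substrate and coordinates

A `coding_alignment` is a set of equal-length sequences over `A,C,G,T,N,-`
with per-record taxon metadata and a `coding_offset`: the coding-region
position (1-based from the reference start codon) of alignment column 1. The
default offset of 431 describes a *FAE1* amplicon whose 892 columns span
coding positions 431–1322; under it, column 1 sits at phase 2 of codon 144,
so the first *fully covered* codon is 145. All codon-level operations use
only codons fully inside the matrix; partial flanking codons are reported as
`not_assessable` rather than guessed.

Two coordinate conventions coexist in this literature (alignment columns vs
coding positions) and published indel positions are ambiguous between them,
so `detect_indel_events()` reports every event in both systems. Gap runs
touching the alignment edge are flagged `terminal` and treated as missing
data, not deletions: many real records are partial amplicons, and calling
their missing flanks "frameshifts" would flood the report. Internal runs are
frameshifting iff their length is not a multiple of 3. `N` is treated as
missing at every site-level computation.

## Site classification

A column is *variable* when it carries ≥ 2 distinct non-gap, non-`N` states
and *parsimony-informative* when ≥ 2 states each occur in ≥ 2 records. Two
gap policies are offered because both conventions appear in practice:
`complete_deletion` (default) drops gap-containing columns from matrix
counts, matching the rule of excluding indels from most calculations;
`indel_as_one_site` counts every column and adds one polymorphic site per
internal indel event.

The silent/replacement *kind* of a column is defined relative to the
column's majority codon (ties broken lexicographically, for determinism):

* polymorphic column — `silent` if every observed variant codon encodes the
  majority codon's amino acid, `replacement` if every variant changes it,
  `mixed` otherwise;
* monomorphic column — classified by mutational opportunity: `silent` if all
  three possible substitutions at that position are synonymous and non-stop,
  `replacement` if none is, `mixed` otherwise.

The exact silent-site rule used by classic desktop software is not published;
this rule is therefore declared explicitly and kept in one place
(`site_kinds()`) so a different convention is a local change. One useful
consequence, exercised in the tests, is that every monomorphic second-codon-
position column is `replacement` under the standard code.

## Diversity, divergence, Ka/Ks

Pairwise distance is the uncorrected proportion of differing sites with
pairwise deletion of gaps/`N`. Nucleotide diversity π is the equal-weight
mean of pairwise differences per site — the haplotype-frequency form without
the n/(n−1) small-sample correction, matching the classical formulation for
sequence samples; if the corrected variant is ever needed it is a
multiplication by n/(n−1), not a new code path. Multi-sequence statistics
use *complete deletion* (columns gap/`N`-free in every analysed record), so
site counts are reproducible and do not depend on which pair is compared.

Between-group divergence reports π<sub>between</sub>, the mean p-distance
over all cross-group pairs, and D<sub>xy</sub>, its Jukes–Cantor correction
−(3/4)·ln(1 − (4/3)p). The correction is undefined at p ≥ 3/4; the package
returns the observed π<sub>between</sub> together with `NA` and a warning
rather than failing, because the raw proportion is still meaningful.

Ka/Ks follows Nei & Gojobori (1986). Per sense codon, the synonymous site
count is the fraction of the nine possible single-nucleotide changes that
are synonymous *and* non-stop; changes to stops count as nonsynonymous, so
S + N = 3 × codons for every subset — an invariant the tests assert.
Differences between a codon pair are averaged with equal weight over all
minimal substitution pathways (≤ 6) that avoid stop codons; when every
pathway is blocked (rare), all pathways are used with stop steps counted as
nonsynonymous. Codons are used only when fully covered and sense in every
analysed sequence. Pair counts are pooled (Σsd / ΣS̄ over pairs) before one
Jukes–Cantor correction; `ratio` is `NA` when Ks = 0. A 61×61 pathway table
is computed once and cached, so the estimator is a table lookup per codon
pair.

Sliding windows advance in *silent-site ordinals*: each window holds a fixed
number of silent columns (default 25) and successive windows are displaced
by a fixed number of silent columns (default 10); a trailing partial window
is dropped. π inside a window is computed over the window's silent columns
under complete deletion. Windowing in silent ordinals rather than base pairs
keeps the per-window information content constant across regions of
different constraint.

## Diagnostic sites and fixed differences

A state is *diagnostic* for a group when every assessable (non-gap, non-`N`)
member carries it and no assessable non-member does. The *relaxed fixed
difference* between two groups reports any state whose frequency strictly
exceeds `f_high` (default 0.70) among assessable members of one group and is
strictly below `f_low` (default 0.30) in the other; strict inequalities
mirror the published "> 70 % / < 30 %" wording, and the boundary cases
`f_high = 1` / `f_low = 0` are interpreted as "exactly 1" / "exactly 0",
giving the classical fixed-difference set. Frequencies are computed over
assessable members only, with a minimum of two assessable members per group
per column (partial sequences dominate real data, and a frequency over one
record is not a frequency). Note that a single column can contribute two
qualifying states (the derived state in one group and the alternative state
in the other); consumers who want *sites* rather than *states* should count
unique columns. Gap characters are never diagnostic or fixed states by
default, since deletions are reported separately as events.

## Phenotype categories and the Fst permutation test

Erucic-acid contents (% of seed fatty acids, range 0–100) are categorized by
fixed cut points — defaults 10.5, 20.5, 31.11, 41.1 with labels L, M1, M2,
M3, H — using half-open intervals with each cut point belonging to the upper
category, which is the convention that reproduces the published category
labels at the boundary values (10.50 → M1, 41.10 → H). The boundaries are
configuration, not inference: they are the observed gaps in the published
phenotype distribution, and automatic widest-gap detection would choose
different ones (the 3.03→8.27 gap is wider than 9.21→10.5), so auto-detection
is deliberately excluded.

Association is measured by a diversity-based Fst = 1 − H<sub>w</sub>/H<sub>b</sub>,
where H<sub>w</sub> pools all within-category pairwise distances and
H<sub>b</sub> all between-category ones. Pooling (rather than weighting each
category equally) matches defining between-group diversity from *all
possible pairs*; with unequal category sizes an equal-weight variant would
differ, and pooling is the documented choice. The permutation null shuffles
category labels among sequenced records, preserving category sizes, and the
add-one estimate p = (#{Fst\* ≥ Fst} + 1)/(B + 1) is reported (B = 10 000 by
default; the seed is mandatory). Categories with fewer than two sequenced
members are excluded from the test and reported as such. Fst can be negative
when within-category diversity exceeds between-category diversity; that is a
meaningful "no structure" outcome, not an error. The exact permutation
count behind any published p-value is typically unstated, so agreement with a
published p is treated as a stochastic property, never an exact target.

## What the generator emulates — and what it does not

`synth_config()` defaults describe the study conditions the analysis
assumes: 60 taxa in 5 clades (cut from a pure-birth tree by repeatedly
splitting the largest clade), 300 codons (900 columns), transition bias
κ = 2, nonsynonymous acceptance ω = 0.1 (strong purifying selection), 16
fixed differences injected between the two largest clades, two internal
deletions (1 bp frameshifting, 3 bp in-frame), and clade-correlated
phenotypes drawn from truncated normals with means 2, 15, 24, 35, 48 and
sd = 1 — means sitting > 4 sd inside the default category intervals, so
sampled values respect the category gaps with overwhelming probability.
`branch_scale = 0.065` (substitution attempts per site per unit branch
length) was calibrated once so that total nucleotide diversity lands near
0.10, the regime of a conserved nuclear gene sampled across a plant family.

Evolution is simulated at codon granularity with an explicit
accept/reject rule (synonymous changes always accepted, nonsynonymous with
probability ω, stops never) rather than a full rate-matrix exponential.
This realizes ω-controlled silent/replacement structure with exact
seedability at desk scale; it does not implement among-site rate variation,
codon-frequency bias, realistic indel evolution, recombination, or gene
duplication/polyploidy (the multi-copy isoform story of real crucifer
genomes is context, not simulation scope). Injection guarantees monomorphic
ground truth within each target clade — the edited column is a strict fixed
difference and the ledger records exactly which columns were edited — but a
tree-structured background *also* accumulates genuine fixed differences on
clade stems; recovery is therefore evaluated against the ledger with the
pre-injection background as baseline. Root codons are drawn uniformly from
the 61 sense codons.

Consequently, passing tests demonstrate correctness of the estimators and
detectors under a clean codon model with known truth; they do not certify
behaviour under alignment error, sequencing artefacts, rate heterogeneity or
selection regimes the model does not contain.

## Test and acceptance problem sizes

The oracle-equivalence suite uses 100 random matrices up to 20×120 against
brute-force enumerations (π, p-distance, divergence, site flags, diagnostic
sites, fixed differences, all to 1e−12 or exactly). Ka/Ks is checked against
a recursive pathway-enumeration oracle on 50 random codon-sequence pairs,
and on 40 seeded ω = 0.1 simulations (40 taxa × 300 codons) the estimated
ratio must fall below 1 in ≥ 95 % of replicates. Ground-truth recovery uses
the generator defaults (60 taxa × 300 codons, gap-free for the injection
check), and phenotype structure is tested over 20 seeds at 999 permutations:
clade-correlated contents must give p ≤ 0.01 in ≥ 95 % of seeds and
label-shuffled contents p > 0.05 in ≥ 90 %. Pipeline determinism is verified
by byte-comparing all reports across repeated runs at three seeds. These
sizes were chosen as the smallest at which the stochastic properties are
stable.

## Known limitations

* The silent/replacement column rule is majority-codon-relative; other
  software may classify low-frequency multi-hit codons differently.
* π and D<sub>xy</sub> use complete deletion; with very gappy alignments the
  shared site set can shrink substantially (the site count used is always
  reported).
* The NG86 estimator saturates: pN or pS ≥ 3/4 leaves Ka or Ks undefined.
* Fst uses pooled pairs; strongly unbalanced category sizes weight large
  categories more heavily.
* The generator's clades are monophyletic by construction; paraphyletic
  groupings of real data can only enter via the metadata/tree inputs.
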