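---
title: "Footprint analysis of nuclease-induced DSB repair: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprint analysis of nuclease-induced DSB repair: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbfootprints)
```

## The experimental design this package models

A site-specific nuclease (CRISPR/Cas9) is expressed in plants, inducing a
double-strand break (DSB) at a chosen protospacer. Erroneous end-joining
repair leaves a *footprint* — a deletion, insertion, combined
deletion–insertion (delins) or substitution — at the cut. To enrich for
mutated molecules, the target region is PCR-amplified and digested with a
restriction enzyme whose recognition site lies near the cut: a clone whose
footprint destroyed the site resists digestion, is cloned and
Sanger-sequenced. Comparing footprint spectra between wild-type plants and
end-joining mutants (*ku80*, *parp1 parp2*, the triple mutant) separates the
contributions of KU-dependent classical NHEJ, PARP-dependent backup joining,
and alternative pathways with polymerase-theta hallmarks (junction
microhomology, templated insertions).

`dsbfootprints` implements every computational stage of that design: an
in-silico digest model, an end-anchored footprint caller with per-line
deduplication, junction annotation (microhomology, template matches, primer
identity), nonparametric genotype contrasts, and a calibrated simulator so
the entire chain can be exercised and validated without any sequencing data.

## Footprint calling

Each clone read is assumed to carry **one contiguous repair event**: the
read must equal `reference[0,a) + ins + reference[b,len)` for some interval
`[a,b)` and inserted word `ins`. The caller computes the longest common
prefix `p` and suffix `s` of read and reference (with `p + s` capped at the
shorter length), which pins `del_len = len(ref) − p − s` and
`ins_len = len(read) − p − s`. All coordinates are 0-based half-open; the
cut position is a between-base coordinate, so deletion intervals spanning
the cut need no special cases.

When the sequence flanking the junction is locally repeated, several
placements `(a, b)` explain the same read; the set of valid placements is a
contiguous range, reported as `shift_min..shift_max`. The **canonical
placement is the leftmost** — an arbitrary but deterministic choice that
makes deduplication keys stable. For a pure deletion the width of this range
*is* the junction microhomology length, and the shared word may be longer
than the deletion itself when the junction sits in a tandem repeat, so the
flank-extension that measures it is deliberately not capped at the deletion
length.

Policy decisions the sequencing design left open:

* **Substitutions** are any delins with equal deleted and inserted length.
  They are called and reported, but excluded from deletion- and
  insertion-length statistics, since isolated substitutions in this assay
  are plausibly PCR artifacts.
* **Scattered mismatches** (sequencing noise) stop the prefix/suffix
  anchors early and inflate the called event. Clones whose event extends
  more than `max_radius` (default 250 bp) from the cut are flagged
  `complex` and excluded from statistics; reads carrying neither primer
  anchor are flagged `unalignable`. Both remain in the footprint table and
  the manifest counts. This flagging policy is this package's own; the
  original assay did not state one.
* **Deduplication**: identical canonical footprints within one plant line
  count as a single mutagenesis event (PCR siblings); identical footprints
  in different lines are independent events and are kept.
* A delins contributes its *deleted reference length* to deletion-length
  analyses; its insertion is tallied separately in insertion-length
  analyses.

## Digest detectability

`is_detectable()` declares a read detectable when no recognition site
remains on either strand (non-palindromic sites are matched via the reverse
complement; degenerate IUPAC recognition codes are not supported, as both
enzymes modelled here are exact). The `predigest` switch of `run_analyze()`
keeps only detectable events, emulating enrichment by predigestion. Because
the recognition site is near but not overlapping the cut, 1–2 bp events at
the cut never destroy it: the assay is structurally blind to them.
`detection_bias()` quantifies this per event class and deletion-length bin
by brute-force re-digestion of every read. Partial digestion and gel
fragment sizes are not modelled.

## Junction annotation

For insertion-bearing events the ±100 bp neighbourhood of the cut (clipped
at the amplicon ends) and its reverse complement are searched for the
insertion:

* full direct occurrence → `perfect`; full reverse-complement occurrence →
  `reverse`;
* otherwise a greedy decomposition into maximal matched substrings of at
  least `min_seed = 4` bp (longest first, leftmost tie-break, direct
  preferred over reverse) gives `partial` when any base is covered, else
  `none`. Insertions shorter than `min_search_len = 3` bp are not searched.

The greedy scheme is deterministic and mirrors the observed "multiple
stretches of identity" without introducing an optimisation model. The
defaults are configurable and echoed into the run manifest; the window of
100 bp is the distance within which template donors were reported.

**Primer identity** is the exact match length between the 3' terminal bases
of the retained left flank (the strand end that primed repair synthesis)
and the bases immediately upstream of the template start, read in template
orientation (for reverse templates, upstream means downstream on the plus
strand, complemented). A junction is called *primed* at ≥ 2 bp identity:
1 bp matches by chance in 25% of junctions, so a 1 bp threshold would be
dominated by noise; the threshold is configurable and the identity length
is always reported so users can apply their own cutoff. The reported
"about 50%" primed fraction in the source data implies some threshold that
was never stated; sensitivity to this choice should be checked with the
reported lengths rather than assumed.

Microhomology is annotated for pure deletions only; junction ambiguity of a
delins is attributed to the insertion placement instead, and reported as 0.

## Statistics

Deletion lengths are binned into `[1,9]`, `[10,19]`, `[20,49]`, `[50,∞)`
bp. Genotype contrasts use the **two-tailed Mann–Whitney U test**:

* exact p-values by enumeration of rank assignments (a rank-sum counting
  recursion) when `n1 + n2 ≤ 12` and the samples are tie-free;
* otherwise the normal approximation with tie-corrected variance and a 0.5
  continuity correction. Deletion lengths are heavily tied, so real
  contrasts essentially always take this route. Near p = 0.05, exact and
  approximate conventions can disagree slightly; the method used is
  recorded in every result row.

Raw p-values are flagged at α = 0.05 without multiple-testing correction,
matching the presentation style of the assay this models; a `holm = TRUE`
switch adds Holm-adjusted columns. The relative mutation frequency from
band intensities is the digest-resistant band intensity divided by the
total lane intensity.

## The simulator and its calibration

`simulate_clones()` draws, per clone, an event class from
`{intact, small_indel, mmej_deletion, templated_insertion}` and renders the
read by exact concatenation, keeping a truth record of everything planted.

* **Deletion lengths** for scored (≥ 3 bp) deletions follow a mixture of
  two shifted geometric distributions — a short-mean component for
  classical-NHEJ-like nibbling and a long-shift component for
  resection-like loss. For each genotype × nuclease preset the three free
  parameters plus the two shifts were fitted once (grid search plus
  Nelder–Mead on the closed-form bin probabilities) to the published bin
  fractions, and frozen in `inst/extdata/del_len_presets.json`. The
  largest residual across presets is 0.0025. Where only aggregate
  fractions were published (the CRU mutants' split below 20 bp; the full
  split of the ~75%/~73% > 20 bp PPO aggregates), the remaining split is a
  package choice fixed before any validation was run, slightly longer than
  wild type for the *parp1 parp2* background and strongly long-shifted for
  the *ku80* backgrounds.
* **small_indel** events are 1–2 bp deletions or 1 bp insertions at the
  cut — the class the digest assay cannot see. They are modelled separately
  from the scored-deletion distribution precisely because the published
  bin fractions describe only detectable deletions.
* **mmej_deletion** events draw a target microhomology length m from
  `{0..6}` and search local endpoints (length jitter up to ±3 bp) whose
  flank-agreement width is exactly m; when no endpoints achieve m the
  closest achievable width is used and counted as a logged fallback. The
  planted width equals what the caller will report, by construction.
* **templated_insertion** events copy a window substring (reverse
  complement with probability 0.3, matching roughly one third of
  orientation calls in the published junction examples), aim for ≥ 2 bp of
  planted primer identity with probability 0.5 (the reported "about half"),
  and carry an accompanying deletion drawn from the preset model scaled by
  `delins_del_multiplier = 2`, reflecting the observation that junctions
  with insertions carry distinctly larger deletions. Insertion lengths
  follow a truncated geometric on 1–60 bp (more than half below 10 bp,
  matching the reported spectrum and its 60 bp maximum).
* Deletions always overlap or abut the cut, with the left/right split
  uniform over feasible splits; both primer anchors are always retained.
* There is **no sequencing-error model by default** (Sanger clone consensus
  is near-noiseless); a `noise_rate` knob plants uniform substitutions to
  exercise the complex-clone policy.
* All randomness flows from one recorded seed; identical configuration and
  seed give byte-identical FASTA/TSV outputs.

The example locus is **synthetic**: the published amplicons live in a
supplement that is not redistributed, so `synthetic_locus()` builds a
480 bp amplicon with the same geometry (20 nt protospacer, NGG PAM, blunt
cut 3 nt 5' of the PAM — the canonical SpCas9 placement, configurable per
locus — and a single PstI- or FauI-type site 8 bp downstream of the cut).

## What the validation shows — and what it cannot

The test suite and `scripts/acceptance.R` verify, on simulated data:
byte-exact round trips of every called footprint; exact agreement of
microhomology lengths with brute-force placement enumeration; exact
Mann–Whitney p-values against an independent full-enumeration oracle and a
null rejection rate within [0.04, 0.06] at α = 0.05 (10,000 simulations);
structural invisibility of 1–2 bp deletions outside the recognition site;
preset bin probabilities within 0.01 of the published fractions and their
recovery from 2,000 simulated clones within 3 binomial SE; ≥ 90% power for
the wild-type versus *ku80* contrast at 40 events per group against a
near-nominal rate for wild-type versus *parp1 parp2*; and exact recovery of
planted template orientation, position and primer-identity length wherever
the planted word is unique in the window. Problem sizes (2,000 clones for
round-trip checks, 500 oracle cases, 10,000 null replicates, 500 power
replicates, 200 planted insertions) were chosen as the smallest giving
stable rates.

These checks validate the *software* against its own generative model.
The simulator does not reproduce PCR amplification bias, pooled-seedling
mosaicism, chromatogram noise, multi-event clones, or incomplete digestion,
so passing tests demonstrate correctness of the computational chain, not
fidelity of any particular biological dataset. Real analyses should treat
the complex/unalignable flags, the fallback counts, and the primed-fraction
threshold sensitivity as diagnostics to inspect, not guarantees.
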