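---
title: "Clade-specific qPCR primer screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-specific qPCR primer screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeqpcr)
```

`cladeqpcr` screens and evaluates clade-specific qPCR primer sets
against a clade-annotated marker-gene reference database. This vignette
documents the models the package implements, the defaults it ships,
and the choices made where the design was genuinely open.

## Mismatch-allowance matching

The elementary operation is primer–template matching under a
*mismatch-allowance* (MAM) pattern `(k, w)`: a template window is an
admissible binding site when it carries at most `k` mismatches against
the primer and none of them falls within the `w` positions closest to
the primer 3′ end. The 3′-protected window models polymerase
sensitivity to terminal mispairing: a mismatch at or near the 3′
terminus blocks extension far more reliably than one in the middle or
at the 5′ end of the primer, which is why 3′-positional information is
the third selection criterion below.

Conventions, fixed throughout the package:

* Coordinates are 1-based, inclusive, on the reference (plus) strand.
  A forward primer's coordinate is its 5′ (leftmost) template
  position; a reverse primer's coordinate is its rightmost template
  position, i.e. the right edge of the amplicon. A name such as
  `Acc-ppk1-372f` parses to orientation and coordinate, but the parsed
  coordinate is advisory: matching never trusts it.
* Mismatch positions are reported as distances from the primer 3′ end
  (1 = the terminus itself). For a reverse primer laid on the
  reference strand, the 3′ end faces left.
* Base compatibility is IUPAC set intersection. A degenerate template
  base therefore never creates a mismatch it could not truly have
  (`N` matches everything). This is deliberately conservative for
  coverage; reports retain the offending matches so degenerate-rich
  references can be inspected.
* Amplicon length is `end − start + 1` with `start` the forward 5′
  coordinate and `end` the reverse rightmost coordinate; a pair is
  convergent when that length is at least the longer primer (primers
  may overlap) and at most `max_len` (default 450 bp).

The shipped presets are `0MAM` = (0, 0), `1MAM` = (1, 1),
`1MAM*` = (1, 0), `3MAM` = (3, 0). The source screening tool for this
family of patterns does not publish closed-form definitions, so these
are this package's documented interpretation; they are chosen so that
the `1MAM` vs `1MAM*` contrast isolates exactly the terminal 3′
position, and they are fully configurable (`mam_pattern()`, inline
`"k<INT>w<INT>"` syntax). Under this parameterization the match sets
are nested, `0MAM ⊆ 1MAM ⊆ 1MAM* ⊆ 3MAM`, and reported percentages are
monotone along the ladder — a property the test suite checks on every
generated fixture.

## Selection criteria and ranking

`rank_candidates()` enumerates candidate pairs from windows conserved
across all target sequences (exact, IUPAC-aware scanning on an
unaligned reference set; no multiple alignment is constructed) and
applies, in order:

1. geometric and thermodynamic screens (defaults in
   `design_constraints()`: primer length 17–25 nt, amplicon 70–450 bp,
   no degenerate primer bases, |ΔTm| ≤ 3 °C, longest
   inter/intra-primer complementary run ≤ 8, 3′-anchored run ≤ 4);
2. **criterion (i)**: 100 % of targets and 0 % of non-targets
   amplifiable at the stringent pattern (`0MAM`). This is evaluated at
   pair level — a non-target escapes amplification if *either* primer
   fails to bind — matching what perfect-match qPCR specificity means;
3. **criterion (ii)**: the total number of non-target records
   amplifiable under the flexible patterns, ascending;
4. **criterion (iii)**: among flexible-pattern non-target matches, the
   distance from the 3′ end of the closest-to-3′ mismatch, ascending
   (mismatches near the 3′ terminus are the discriminating ones), with
   ties broken by the mean distance, then amplicon length, then pair
   name. The published criterion is prose ("as far away from the 5′
   end as possible"); this total order is the package's
   operationalization of it.

The Tm model is the unified nearest-neighbour table (SantaLucia 1998)
with terminal initiation terms and the entropic salt correction
`0.368·(N−1)·ln[Na⁺]`, at 50 mM monovalent salt and 400 nM total
primer — standard qPCR-like conditions. The wet-lab step of
re-optimizing annealing temperature on the instrument cannot be
simulated; |ΔTm| between the two primers is the in-silico proxy.

Degenerate and degenerate-adjacent inputs: candidate primers containing
degeneracy codes are excluded by default (`allow_degenerate = FALSE`),
and `melting_temperature()` refuses degenerate sequences rather than
silently averaging.

## qPCR standard curves and interference

`fit_standard_curve()` regresses Ct on log10 template copies over all
replicate points (replicates are not collapsed to level means, so
replicate variance enters R²). Efficiency is
`E = (10^(−1/slope) − 1) × 100`; a perfectly doubling reaction has
slope `−1/log10 2 ≈ −3.3219` and `E = 100 %`. A curve is valid only
when `R² > 0.96` and `85 ≤ E ≤ 115` — the acceptance band for
quantitative use. A non-negative slope leaves the efficiency undefined
(`NA`) with a diagnostic rather than a fabricated number. Copy numbers
from mass use the conventional 660 g·mol⁻¹ per double-stranded base
pair and Avogadro's number.

Cross-amplification is quantified by the *relative efficiency*
`RE = 2^(−ΔCt)`, where ΔCt is the delay of a primer set on a
non-target amplicon relative to its own target at equal copies,
assuming 100 % per-cycle efficiency. A ten-cycle delay is `2^(−10)`
(0.0977 %, i.e. 0.1 % at one decimal) and is the classification
boundary: undetected → `none`; detected with `RE < 2^(−10)` →
`negligible`; `RE ≥ 2^(−10)` → `interfering`. Undetected reactions are
encoded as absent (`NA`), never as an arbitrary cycle-40 value, so no
pseudo-RE enters the per-primer sums of non-specific relative
efficiencies. The reference Ct is taken to be the measured own-target
Ct at equal template copies (the natural reading; a theoretical
reference Ct would only shift all REs of a primer set by a common
factor).

## Abundance normalization

With taxon fractions `f_i` measured in 16S gene copies and per-cell
rrn operon copy numbers `n_i`, the community average is the harmonic
form `n̄ = 1/Σ(f_i/n_i)` (total gene copies over total cells), bounded
by the extreme `n_i`. A clade's share of bacterial cells is then
`100 · m / (S/n̄)` for `m` marker-gene copies and `S` 16S copies
measured on the same template mass, under the assumption of one marker
gene per cell (configurable via `gene_copies_per_cell`). Taxa with
unknown `n_i` inherit the known-taxa average; a sample with no usable
profile falls back to a constant 2.04 copies per cell, a typical
activated-sludge community average. The unclassified remainder of a
lineage is `max(0, total − Σ clades)`; a negative raw difference
(possible because the assays are independent) is clipped to zero and
flagged.

## Clade assignment

Cloned amplicons are assigned by nearest reference under optimal
*global* alignment (match +1, mismatch −1, linear gap −2, end gaps
penalized), identity = matched columns / alignment columns × 100.
Global rather than local alignment because amplicons are
primer-bounded fragments of the reference region; local alignment
would reward spurious short perfect stretches. Ties go to the
lexicographically smaller reference id, making assignment
deterministic. The default assignment threshold of 93 % reflects the
lower end of identities typically observed between cloned amplicons
and their clade's references; it is a configurable interpretation, not
a published rule.

## Synthetic fixtures

`generate_clade_db()` emulates a multi-clade marker-gene database:
clade consensuses diverge from a common ancestor at disjoint
clade-specific positions (guaranteeing a minimum pairwise consensus
divergence), individual sequences mutate their consensus independently
at the intra-clade substitution rate, and planted primer sites are
written verbatim into every target-clade sequence and corrupted with a
configurable minimum number of substitutions (optionally one forced
onto each primer's 3′-terminal position) in every non-target sequence.
Planted regions are excluded from background mutation, so the
coverage/specificity guarantees hold *exactly*, not just with high
probability. All randomness is fixed by an integer seed through R's
own RNG, and generation restores the caller's RNG state.

What the generator does **not** emulate: insertions/deletions (the
matching engine's contract is window-based; indel realism is
deferred), tree-structured evolution (divergence is star-shaped from
the ancestor), composition bias, and chimeras. Passing tests on these
fixtures therefore demonstrate the correctness of the screening
arithmetic — not that any particular wet-lab primer set will behave on
environmental DNA, where the published evidence is cloning, sequencing
and standard curves.

`simulate_ct()` inverts the standard-curve model:
`Ct = intercept − log10(copies)/log10(1 + E) + N(0, σ)`, with a
detection limit (default cycle 40) above which reactions are emitted
as undetected. Its defaults mirror the published calibration design:
six ten-fold levels, 10³–10⁸ copies, six replicates.

## Problem sizes and numerical tolerances

The test suite exercises the matcher against a brute-force
sliding-window oracle on 10⁴ random primer/template/pattern instances
(primers 10–20 nt, templates 50–100 nt, both orientations, degenerate
codes included), verifies amplicon arithmetic against the published
primer-set coordinates, recovers simulated efficiencies over 200
seeded curves at σ(Ct) = 0.15, and checks the pattern-monotonicity and
strand-symmetry invariants on generated databases (2–14 clades, 260–
1000 bp sequences). These sizes were chosen so the whole suite runs in
about a minute on a single core while covering every code path;
scaling any of them up is a matter of editing the loops. Exact
identities (slope ↔ efficiency, RE boundary) are asserted to machine
precision; simulation-based recoveries to one percentage point.

## Known limitations

* No thermodynamic (ΔG) off-target model: specificity is purely
  mismatch-count/position based, as in the screening strategy it
  implements.
* No probe (hydrolysis) design; SYBR-style two-primer assays only.
* `conserved_windows()` anchors on the first target sequence; a target
  set whose first member carries a deletion inside an otherwise
  conserved site would hide that window (substitution-only references
  are the intended input).
* Global-alignment assignment scales as O(n·m) per reference; for the
  hundreds-of-references databases this package targets that is
  seconds, but it is not a metagenome-scale classifier.
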