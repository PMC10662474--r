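---
title: "Profile-based evolutionary distances for remote protein homologues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based evolutionary distances for remote protein homologues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protsd)
```

## Model and assumptions

`protsd` estimates the evolutionary distance between two protein
sequences from per-site feature profiles rather than from residue
identities. The underlying assumptions are:

1. **Site context carries evolutionary signal.** The admissible residues
   at a site, summarized by a PSSM-derived occurrence-probability vector,
   and the joint behaviour of *adjacent* sites are better conserved
   across remote homologues than the observed residues themselves.
2. **Local structure is more conserved than sequence.** A three-state
   secondary-structure label and a two-state burial label (rASA < 20%
   strictly means buried) add alignment signal at identity levels where
   residues are uninformative.
3. **Global alignability.** Homologous domains are alignable end to end;
   we therefore use a global alignment with end gaps penalized like
   internal gaps.

Each site i contributes a 640-dimensional vector: the flattened outer
product of the probability vectors at sites i and i+1 (400 dims,
row-major over (residue at i, residue at i+1)), concatenated with the
tensor product of a 4-state indicator of the pair's joint accessibility
(BB, BE, EB, EE), a 3-state indicator of the site's secondary structure
and the site's probability vector (240 dims). Both blocks sum to one per
site, so every site vector sums to two and site scores are bounded.

Two interpretive choices here were genuinely open and are our own
reading. First, the 4 × 3 × 20 intersection block does not dictate which
of the two paired sites contributes each factor; we use the joint
accessibility of the *pair*, the secondary structure of site *i*, and the
probability vector of site *i* — the only reading that uses all three raw
feature classes and both sites' accessibility. Second, a length-L
sequence yields L profile sites by pairing the terminal site with itself;
the alternative (L−1 sites) would decouple alignment coordinates from
residue numbering. Both choices are mechanical to change and are
localized in `build_profile()`.

## Scoring and alignment

The site-pair score is the dot product of the two 640-dim vectors plus
`omega1` when secondary-structure labels match and `omega2` when burial
labels match. The weights were characterized over 1.0–2.0; we default
both to the midpoint 1.5 and treat values outside the range as allowed
with a warning.

Alignment is the three-matrix Gotoh recursion (match, gap-in-A,
gap-in-B) with affine cost `d + (k−1)e`. The gap parameters are not
fixed by the method's description; we default to `d = −1`, `e = −0.2`,
chosen so that one gap opening costs about half a typical good site
match (site scores live in `[0, 2 + omega1 + omega2]`). All four
parameters are recorded in every run's metadata sidecar. Two numerical
conventions matter for reproducibility and are fixed: the terminal and
traceback state preference is match > gap-in-A > gap-in-B (with opening
preferred over extension on ties), and the gap-state recursions carry no
cross transitions between the two gap states. The latter matches the
printed recursion of the original description (whose second gap matrix
contains an evident typo — an extension term written against the other
gap matrix — which we resolve to the standard Gotoh form); because all
site scores are non-negative here, an alignment with adjacent opposite
gaps is never strictly better than one that matches those sites, so the
restriction does not change optimal scores. The test suite verifies this
against exhaustive enumeration over *all* global alignments, including
the adjacent-opposite-gap ones.

## Distance mapping

The raw optimal score is normalized by the geometric mean of the two
gapless self-alignment scores (a Scoredist-style normalization; the
self-score upper-bounds any global score when pair scores are
non-negative, so the normalized score lies in (0, 1] up to clamping),
clamped to `(1e-4, 1]`, and mapped through `D = (1/sqrt(S) − 1)/2`. The
clamp caps distances at 49.5 and guards the map's singularity at 0; the
normalization itself is not dictated by the method's published
description and is recorded as our design choice. Distances are
symmetric by construction (each unordered pair is aligned once).

## Trees and tree comparison

`bionj_tree()` implements variance-weighted neighbor joining (BioNJ):
NJ's Q-criterion and branch-length estimates, with the post-join matrix
reduction weighted by the lambda that minimizes the variance of the
reduced distances, taking pair variances proportional to distances. We
wrote this in R rather than delegating to an external implementation
because the consistency contract we test — exact recovery of additive
matrices to 1e-9 in path length — exceeds the numeric precision of the
commonly wrapped C implementation, and because tie behaviour must be
pinned: ties in the Q-criterion are broken by the lexicographically
smallest involved leaf ids, and negative branch-length estimates are
clamped to zero with the deficit moved to the sister edge, the standard
practice that keeps path lengths through the joined node unchanged.
`ape::bionj` serves as an independent topology cross-check in the test
suite. Robinson–Foulds distances count non-trivial bipartitions present
in exactly one tree; the normalized form divides by the total non-trivial
split count of both trees, which is 2(N−3) for two fully resolved
unrooted trees and correspondingly smaller when a tree (such as the
generator's star-shaped truth trees) is multifurcating.

## Benchmark statistics

For each superfamily with at least one within-family and one
between-family pair distance, a two-sided Mann–Whitney U test compares
the two samples. We use exact enumeration when both samples have at most
8 tie-free observations and otherwise the tie-corrected normal
approximation without continuity correction; the published description
names the test but not the variant. The recognition rate RR is the
fraction of evaluable superfamilies with p below alpha = 0.001, and the
relative distance RD averages `(d_diff − d_same)/d_diff` over those
superfamilies, using per-superfamily means. Pair distances are treated
as independent observations although pairs share proteins — the pooled
test the statistic implies — which makes the p-values approximate; the
null-calibration test (label shuffles) bounds the practical consequence.
The between-family standard deviation (`sfsd()`) uses the population
(N-denominator) form; it is reported per superfamily but not used as a
filter, since its published role is descriptive. A practical consequence
of the alpha = 0.001 screen worth knowing: with fewer than about 10
pair distances per sample the normal-approximation p-value cannot fall
below 0.001 even under complete separation, so very small superfamilies
are structurally unable to enter Q.

TM-scores enter as data (computing them from coordinates is out of
scope). `combine_tm()` averages the two per-chain normalizations with
length weights, making the combined score independent of chain order;
`tm_d0()` provides the length-normalization scale factor
`1.24·(N−15)^{1/3} − 1.8`, floored at 0.5 Å since the expression goes
negative for short chains. `correlate_with_structure()` pools pairs,
reports the Pearson correlation between distance and TM-score, and bins
pairs into equal-width TM bins with per-bin mean and standard deviation
of distance.

## Synthetic benchmark generator

`make_superfamily()` generates the study conditions used throughout the
tests: 10 superfamilies, 3 families per superfamily, 4 proteins per
family, ancestor lengths uniform on 60–120 residues (inside the method's
50–500 working range), with family founders derived from the superfamily
ancestor at 0.5 expected substitutions per site and members from their
founder at 0.05 — an order-of-magnitude within/between contrast typical
of family versus superfamily divergence. Substitutions are i.i.d. per
site with uniform target among the 19 alternatives; no rate matrix, no
indels, no rate heterogeneity. Pseudo-PSSM rows mix a one-hot on the
observed residue with the uniform distribution (weight 0.9), emulating a
sharp but non-degenerate profile. Secondary structure is drawn as
geometric runs (mean run length 5) at the ancestor; labels are
independent of sequence content but *inherited* along the derivation,
relabelling per site at the same rate as the substitutions, so structure
drifts more slowly within families than between them — the qualitative
behaviour real superfamilies show. rASA is uniform on [0, 1] (redrawn at
the same per-site rate) and thresholded strictly at 0.20.

What passing tests on this generator do show: the full pipeline
(profiles → affine-gap alignment → normalized distances → Mann–Whitney
screen → BioNJ) recovers a within/between contrast and family clades
from sequence-level signal it was not handed directly. What they do not
show: performance on real PSSMs (whose column correlations reflect
actual substitution processes), on proteins with indels or domain
rearrangements, or at the scale of curated structural classifications —
those require the external search and prediction tools whose outputs
this package consumes.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately small
instances — 36-record all-vs-all runs (630 alignments), 50 additive
matrices of 5–12 leaves, 200 null superfamilies, exhaustive alignment
enumeration up to length 4 — sizes at which every oracle (enumeration,
closed forms, additivity) is exact while the whole suite stays fast on a
single CPU. Readers of degenerate inputs fail loudly: per-site arrays
disagreeing with sequence length, malformed PSSM rows, residue
mismatches, asymmetric matrices and duplicate ids are all errors, not
warnings. All-zero PSSM percentage rows fall back to a one-hot on the
observed residue to stay valid probability vectors. PHYLIP output uses a
relaxed dialect (whitespace-delimited names up to 50 characters) because
structural-classification identifiers exceed the strict 10-character
limit; values are written with 10 significant digits so round-trips hold
to 1e-9.

## Known limitations

* Only adjacent-site correlation is modelled; wider windows and
  position-specific gap costs are out of scope.
* The gap parameters, match weights and score normalization are
  defensible defaults, not fitted values; conclusions sensitive to them
  should sweep `alignment_params()`.
* Distances saturate at 49.5 by the clamp; beyond-saturation divergence
  is not resolved.
* The Mann–Whitney screen treats shared-protein pair distances as
  independent, and small superfamilies cannot reach the 0.001 threshold
  (see above).
* The generator's simplifications (no indels, structure independent of
  sequence content) mean gap handling is exercised by construction-level
  tests, not by realistic indel processes.
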