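---
title: "ptmladder: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ptmladder: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmladder)
```

## Scope and data model

`ptmladder` analyses *deconvoluted* top-down ETD/ECD fragmentation spectra
of an intact, modified protein: the input is a neutral monoisotopic
mass/intensity peak list per technical replicate (the output of upstream
deisotoping such as XTRACT), a protein sequence, one modification
definition (name, monoisotopic delta mass Δ, acceptor residues), and the
observed precursor mass. Raw-file processing, charge deconvolution and
isotope modelling are explicitly upstream of this package. Only a single
modification type per precursor is supported; the number of modifications
n is inferred from the precursor mass as the rounded multiple of Δ above
the unmodified sequence mass, with a ppm check on the residual.

All masses are neutral and monoisotopic. Ion types are defined by offsets
added to the summed residue masses of the fragment's own side: b = ΣN,
a = b − CO, c = b + NH₃, and on the C side y = ΣC + H₂O, x = y + CO − 2H,
z = y − NH₃, with `c-1` and `z+1` one hydrogen atom below c and above z.
The `z+1` species is the ETD z-dot radical; we fix this convention
explicitly (and test the complementarity identities b+y = c+z = M) because
top-down tools are inconsistent about whether "z" means the radical or the
even-electron species. Neutral losses (water, ammonia, hydrogen) are
applied as global search options to every fragment, not gated by fragment
composition; the decoy-based FDR absorbs the cost of the extra search
space. Residue indexing is 1-based; cleavage i on the N side means the
first i residues, cleavage j on the C side the last j residues.
Nonstandard residue codes (B, Z, X, U, O) are rejected outright: a silently
approximated mass would corrupt the ppm calibration.

## Assignment and fragment-level FDR

Matching assigns each theoretical fragment to its single nearest peak
within the tolerance; one peak may serve several theoretical fragments,
because spectra of positional-isomer mixtures are intrinsically
multiplexed. No intensity threshold is applied at any stage — false
matches are empirically intensity-independent, so an intensity cutoff
would cost real signal without buying specificity.

Calibration is data-driven: a broad first pass (default 10 ppm) yields a
ppm-error population; the systematic shift is its median, and the accepted
tolerance is 3 standard deviations after discarding points more than four
robust sigmas (MAD) from the median. When the MAD is zero — error-free
synthetic data — the filter collapses onto the median rather than
switching off, so the tolerance shrinks to its floor (0.001 ppm) instead
of being inflated by accidental isobars from the broad pass. The final
tolerance is `min(3σ, first-pass)`. Decoy searches reuse the target's
calibration: calibration is a property of the instrument, not the
sequence.

Ion types are chosen by a "frequent flyer" test: per candidate type, the
assignment count against the target is compared with the count population
formed by the target counts plus the counts of the same types against
scrambled sequences (default 20), using a percentile-based robust z
(median and the 15.87/84.13 percentiles, right tail only) and a normal
p-value at α = 0.01. The test the original method names is defined for
outlier detection on ratio distributions and its exact inputs are not
specified for this application; anchoring the null distribution on decoy
counts is our documented choice. An empty selection falls back to all
candidates with a warning.

Majority voting accepts a fragment key (terminus, ion type, loss,
cleavage, modification count) iff it was assigned in at least k of n
replicates (default 2 of 3); the accepted intensity is the median across
supporting replicates (median rather than mean: one more robustness
decision the source material leaves open).

The fragment-level FDR runs the identical pipeline against 200 scrambled
(composition-preserving, Fisher–Yates, seed + decoy index) sequences and
reports the *median* decoy coverage, where coverage counts covered
backbone cleavages (an N fragment at cleavage i covers i; a C fragment at
j covers L − j) out of L − 1. Counting cleavages rather than residues is a
deliberate reading of an ambiguous phrase ("percentage of the sequence"):
fragments localize cleavages, and the ladder logic downstream needs
per-cleavage accounting. Note that even noise-free spectra yield a nonzero
decoy floor (a few percent at 3 ppm for a ubiquitin-sized protein):
composition coincidences such as GG = N and G+A = Q exactly, plus shared
terminal residues, let a scramble legitimately "explain" a few cleavages.
This is real chance-match behaviour, not an artefact.

## PTM ladders and the localization score

Accepted fragments are arranged per terminus into a ladder indexed by
cleavage position × modification count; intensities of fragments sharing a
cell are summed. For a candidate site set s₁ < … < sₙ the N-terminal
ladder tiles into stretches of constant expected count: level m covers
cleavages sₘ to sₘ₊₁ − 1 (level 0 from cleavage 1, level n to L − 1); the
C-terminal ladder is the mirror image in its own indexing. Empty stretches
(a site at the terminus) contribute probability 1.

Each stretch is scored by the upper-tail binomial probability
P(X ≥ k | N, q) of its k matched among N theoretical fragments
(N = cleavages × ion kinds), computed in log space, with p = 1 when
nothing matched. The chance-match probability q = X/100 comes from the
average number of peaks X per 100 Da over the observed mass range of the
spectrum (computed once per spectrum, averaged over replicates, clamped to
(10⁻⁶, 0.99); ranges under 100 Da are floored at 100 Da). Matched-peak
counting uses only accepted fragments at the stretch's *expected* level —
fragments at other levels in the span belong to other isomers and are
ignored by the score.

Two combined scores are reported in log10: the plain product of stretch
p-values, and the corrected product in which each stretch's p-value is
divided by the previous stretch's before multiplication (first stretch
uncorrected), a correction intended to stop short in-between stretches
from skewing the result. Applied literally the correction telescopes: per
ladder the corrected product reduces to the final stretch's p-value, so
candidates that differ only in interior sites tie exactly. We therefore
rank by the corrected score but break ties by the plain score, then by
fewer stretch boundaries, then lexicographically. Both scores are stored
per candidate so the discrepancy stays auditable; `score_combination`
also retains every raw stretch p-value.

## Quantifying positional isomers

Within a stretch, every (cleavage, ion kind) present at both levels m and
m+1 contributes one intensity ratio I(m+1)/I(m). Ratios are formed only
within an ion kind — ETD type efficiencies cancel within a type, never
across types — and N- and C-terminal evidence enter the system as separate
rows rather than pooled, which adds an internal consistency check. A
stretch's summary is the median ratio with SEM = SD/√n over its pairs;
stretches with fewer than `min_pairs` (default 3) pairs are flagged
unreliable and excluded from solving. SEM is computed over pair ratios
(not per-replicate medians): that granularity matches sub-0.1% SEMs on
well-populated stretches.

The boundary t-test between two adjacent stretches' ratio samples
(two-sided, equal variance) detects whether the acceptor at the boundary
is modified in some isomer (p < 0.05); identical constant samples return
p = 1 by convention.

For solving, the union of candidate sites partitions each ladder into
regions; each candidate implies exactly one modification level per region,
giving a 0/1 design matrix whose columns sum to 1 within a region.
Observed per-level intensity fractions come from chained adjacent-level
median ratios normalized within the region (for two levels this is the
familiar r ↦ (1/(1+r), r/(1+r)) map); their SEMs propagate by the delta
method, with the base level inheriting its neighbour's SEM since a pair
ratio moves both ends. Abundances are solved by weighted (1/SEM²)
active-set non-negative least squares with an appended sum-to-one row,
then renormalized so Σα = 1 exactly; candidate columns that are identical
are first merged into groups (grouped quantification for rank-deficient
systems), and per-abundance SEMs come from first-order propagation on the
positive support. Estimates with SEM above 10% are flagged "treat with
caution". Before solving, candidates that require a (region, level)
fragment class with zero accepted fragments — while the region holds at
least `min_evidence` (default 3) fragments at competing levels — are
pruned; this operationalizes occupancy/exclusivity deductions of the form
"only fragments with m modifications are observed past this site".

Occupancy calls at a site compare the modification levels supported by at
least `min_evidence` fragments on the two flanks of its cleavage boundary:
an unchanged level set is "unmodified", a clean replacement of the base
level by base+1 is "full", co-occurrence of both is "partial", and
anything else (including thin flanks) "undetermined".

## The simulator: what a green test does and does not establish

`simulate_spectrum_set` emulates the data model the quantification rests
on. Per cleavage one base intensity is drawn log-normally (median 10⁴,
σ_log10 = 0.4 — the dynamic range typical of deconvoluted top-down
spectra; the source material states no values, so these were fixed once)
and *shared across isomers and replicates*; per ion type a fixed
efficiency (defaults c = 1, z+1 = 0.9, y = 0.35, z = 0.3, c-1 = 0.25,
c/z-dot dominance typical of ETD) multiplies it, and each isomer
contributes in proportion to its abundance, summing when isomers share a
(cleavage, type, level) class. Replicates then apply multiplicative
log-normal intensity noise (default CV 10%), Gaussian ppm error (default
bias 0, SD 1 ppm), i.i.d. fragment dropout (default 10%) and uniform decoy
peaks (default 2 per 100 Da, intensities from the low quantile of the base
distribution so that false matches span intensities). Everything is
seeded and byte-reproducible, and every emitted peak is traceable to a
fragment or the decoy registry.

The shared-efficiency assumption *is* the central modelling assumption of
the method — that ETD fragment intensities are unbiased by modification
position. The simulator therefore cannot test that assumption, only
everything downstream of it: a green recovery test establishes that the
pipeline inverts the stated generative model correctly at the stated noise
levels, not that real ETD obeys the model. Real phosphoproteins are known
to suppress fragment intensity close to the modified site; the
`site_suppression_factor`/`site_suppression_width` options inject exactly
that distortion to probe robustness, and quantification stretches within a
few residues of a site should be treated with suspicion (the package warns
rather than excludes by default). Also not emulated: deisotoping artefacts
(wrong monoisotope picks, peak splitting), charge-state effects,
modification losses during fragmentation, and chromatography.

## Numerical choices and degenerate inputs

* Binomial tails via `pbinom(..., log.p = TRUE)`; the test suite holds it
  to an independent summation oracle at 10⁻¹² log-relative accuracy.
* Peak lists are sorted on read and peaks closer than 10⁻⁴ Da merged
  (intensity-summed, intensity-weighted mean mass).
* Matching ties (equidistant peaks) resolve to the higher-intensity peak;
  localization ties as described above; NNLS degeneracy resolves to the
  minimum-norm solution via the pseudoinverse.
* Calibration requires ≥ 20 assignments and errors out otherwise, advising
  a wider first pass; its tolerance has a 0.001 ppm floor.
* Candidate enumeration refuses more than 10⁶ combinations without
  constraints or a site short-list.
* Zero-theoretical stretches score p = 1; empty spectra localize all
  candidates at equal score; all-zero abundance systems error out.

## Known limitations

Single modification type per precursor; no internal fragments; no
spectrum- or proteoform-level FDR (fragment-level only, by design); the
number of independent observations grows with the number of informative
stretches, so systems with many candidates and few stretches are solvable
only as groups — exactly what grouped quantification reports. Ratio
compression at extreme mixing ratios (beyond ~32:1) is expected on real
data for reasons (detection limits, deisotoping artefacts) the simulator
reproduces only via dropout, so treat extreme-ratio recoveries in
simulation as optimistic.
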