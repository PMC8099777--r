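# ptmladder

Fragment assignment, PTM site localization and positional-isomer
quantification for top-down ETD mass spectrometry of intact proteins.

## The problem

When an intact, modified protein is mass-selected and fragmented, all
co-isolated **positional isomers** — proteoforms carrying the same number of
a modification at different sites, hence the same intact mass — fragment
together. The resulting deconvoluted MS2 spectrum is highly multiplexed:
specific backbone fragments appear simultaneously with and without the
modification mass. `ptmladder` turns that multiplexing from a nuisance into
a measurement. It is aimed at top-down proteomics users who have deisotoped
ETD/ECD spectra (neutral monoisotopic mass/intensity lists, e.g. XTRACT
exports) of a single co-isolated proteoform family and want to know *where*
the modifications sit and *how much* of each positional isomer is present.

## What it computes

1. **Fragment assignment with fragment-level FDR.** Theoretical neutral
   c/z-type (and related) fragment masses on a modification-count grid are
   matched to peaks; a data-driven calibration removes the systematic ppm
   shift and sets the tolerance to 3σ of the matched-error distribution;
   ion types are selected by a "frequent flyer" outlier test against
   scrambled-sequence counts; fragments must appear in ≥ k of n technical
   replicates (majority voting). The FDR is the median fraction of backbone
   cleavages explainable by 200 composition-preserving scrambles of the
   sequence.
2. **PTM ladders and site localization.** Accepted fragments are arranged
   per terminus on a cleavage-position × modification-count grid. For a
   candidate site combination with sites s₁ < … < sₙ, the ladder tiles into
   *stretches* of constant expected count m, and each stretch is scored by
   the binomial chance probability P(X ≥ k | N, q) of its k matches among N
   theoretical fragments, with q = X/100 taken from the average number of
   peaks X per 100 Da in the spectrum. Stretch p-values are combined across
   both ladders (plain product, and the previous-stretch-corrected product)
   and candidates ranked.
3. **Positional-isomer stoichiometry.** Within a stretch, each (cleavage,
   ion type) present at modification levels m and m+1 yields an intensity
   ratio I(m+1)/I(m); the median ratio and its SEM feed a weighted
   non-negative least-squares system (columns = candidate isomers, rows =
   per-stretch intensity fractions, Σα = 1). A two-sample t-test between
   adjacent stretches' ratio samples detects hidden isomers at the boundary
   site; rank-deficient systems are reported as grouped abundances.
4. **A ground-truth simulator** that emulates deconvoluted ETD spectra of
   proteoform mixtures — shared per-cleavage fragmentation efficiency,
   multiplicative intensity noise, ppm error, dropout and decoy peaks — so
   the whole pipeline is testable without instrument data.

## Worked example

A heavy-valine (+6.013810 Da on V) labelled ubiquitin benchmark. First,
localize the sites of a single doubly-labelled proteoform from simulated
replicate spectra:

```r
library(ptmladder)
ubi <- read_fasta(system.file("extdata", "ubiquitin.fasta",
                              package = "ptmladder"))[[1]]
hv  <- modification_preset("heavy-val")

sim1 <- simulate_spectrum_set(sim_config(ubi, hv, list(c(17L, 70L)), 1,
                                         seed = 7L))
asg1 <- assign_spectra(sim1$spectra, ubi, mod = hv, max_mods = 2)
lad1 <- list(N = build_ladder(asg1$accepted, "N", 76, 2),
             C = build_ladder(asg1$accepted, "C", 76, 2))
loc  <- localize(lad1, ubi, n_mods = 2, mod = hv, q = asg1$q)
head(loc, 3)
#>   sites log10_corrected log10_plain rank
#> 1 17+70       -73.53325   -425.3421    1
#> 2 17+26       -61.01897   -155.1169    2
#> 3 26+70       -53.97335   -340.0240    3
```

The true combination V17+V70 ranks first, 12.5 log10 units ahead of the
runner-up. Now quantify a 1:3 mixture of the V17 and V70 singly-labelled
positional isomers:

```r
sim <- simulate_spectrum_set(sim_config(ubi, hv, list(17L, 70L), c(1, 3),
                                        seed = 42L))
asg <- assign_spectra(sim$spectra, ubi, mod = hv, max_mods = 1, vote_k = 2)
#> accepted fragments: 618 | coverage: 100.0% | tolerance: 3.07 ppm

ladders <- list(N = build_ladder(asg$accepted, "N", 76, 1),
                C = build_ladder(asg$accepted, "C", 76, 1))
sr <- stretch_ratio(collect_pairs(ladders$N, 17, 69, 0))
#> inter-site stretch: median ratio 0.336 (SEM 0.0035, 99/106 pairs)

quantify_isomers(list(17L, 70L), ladders)$abundances
#>   label abundance          sem n_members flag
#> 1    17 0.2500919 0.0009493317         1
#> 2    70 0.7499081 0.0009493317         1
```

The modified/unmodified intensity ratio on the stretch between the two
sites is α₁₇/α₇₀ ≈ 1/3, and the solved abundances recover the 25%/75% mix.
`estimate_fdr()` on the same data reports a fragment-level FDR of 4% at
100% cleavage coverage (50 scrambles, 3 ppm).

## Command line

```sh
Rscript inst/cli/ptmladder.R simulate --config sim.json --out out/
Rscript inst/cli/ptmladder.R full     --config run.json --out out/ --seed 1
```

Configs are JSON; see `?run_config` and `?sim_config`.

## Documentation

The methods vignette (`vignettes/ptmladder-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default, what
the simulator does and does not emulate, and known limitations.
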