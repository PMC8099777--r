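# shared fixtures: a ubiquitin-like 76-residue benchmark protein carrying a
# heavy-valine label at V17/V26/V70, and small helpers used across tests

UBI <- paste0("MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYN",
              "IQKESTLHLVLRLRGG")
HEAVY_VAL <- modification_preset("heavy-val")
PHOSPHO <- modification_preset("phospho")

# standard noisy simulation of a labelled ubiquitin isomer mixture
ubi_sim <- function(isomer_sites, abundances, seed, ...) {
  simulate_spectrum_set(sim_config(UBI, HEAVY_VAL, isomer_sites, abundances,
                                   seed = seed, ...))
}

# noise-free variant: exact masses/intensities, no dropout, no decoys
ubi_sim_clean <- function(isomer_sites, abundances, seed = 1L, ...) {
  ubi_sim(isomer_sites, abundances, seed = seed, intensity_cv = 0,
          ppm_sd = 0, dropout = 0, decoy_per_100da = 0, ...)
}

# assignment + ladders for a simulated set
sim_ladders <- function(sim, vote_k = 2L) {
  n_mods <- sim$truth$n_mods
  asg <- assign_spectra(sim$spectra, sim$config$sequence,
                        mod = sim$config$mod, max_mods = n_mods,
                        vote_k = vote_k)
  L <- nchar(sim$config$sequence)
  list(asg = asg,
       ladders = list(N = build_ladder(asg$accepted, "N", L, n_mods),
                      C = build_ladder(asg$accepted, "C", L, n_mods)))
}

# independent oracle: log10 upper-tail binomial probability by direct
# summation of the mass function (no pbinom). Sums whichever tail avoids
# cancellation: the upper tail directly via log-sum-exp, or (when the upper
# tail is close to 1) the lower tail linearly followed by log1p.
log10_binom_tail_oracle <- function(k, n, q) {
  if (k <= 0) return(0)
  lterm <- function(x) lchoose(n, x) + x * log(q) + (n - x) * log1p(-q)
  if (k - 1 < n * q) {
    s <- sum(exp(vapply(0:(k - 1), lterm, numeric(1))))
    log1p(-s) / log(10)
  } else {
    terms <- vapply(k:n, lterm, numeric(1))
    m <- max(terms)
    (m + log(sum(exp(terms - m)))) / log(10)
  }
}

# independent oracle: nearest-peak matching by brute force over all pairs
match_oracle <- function(spectrum, table, tolerance_ppm) {
  hits <- lapply(seq_len(nrow(table)), function(i) {
    tm <- table$mass[i]
    ppm <- (spectrum$mass - tm) / tm * 1e6
    ok <- which(abs(ppm) <= tolerance_ppm)
    if (!length(ok)) return(NULL)
    best <- ok[abs(ppm[ok]) == min(abs(ppm[ok]))]
    if (length(best) > 1L)
      best <- best[which.max(spectrum$intensity[best])]
    data.frame(row = i, peak = best, ppm = ppm[best])
  })
  do.call(rbind, hits)
}

# monoisotopic atomic masses for the elemental-composition mass oracle
ATOM <- c(C = 12, H = 1.00782503, N = 14.0030740, O = 15.9949146,
          S = 31.97207117, P = 30.97376200)
elem_mass <- function(counts) sum(ATOM[names(counts)] * counts)
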