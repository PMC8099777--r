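#' Match theoretical fragments to deconvoluted peaks
#'
#' Every theoretical fragment is matched to its single nearest peak within
#' the ppm tolerance (ties broken by smaller absolute ppm error, then higher
#' intensity). One peak may serve several theoretical fragments: spectra of
#' positional-isomer mixtures are highly multiplexed, and no intensity
#' threshold is applied (false matches were found intensity-independent).
#'
#' @param spectrum A `decon_spectrum`.
#' @param table A `fragment_table`.
#' @param tolerance_ppm Match tolerance in ppm (> 0).
#' @return data.table of assignments: the fragment key columns plus
#'   `theo_mass`, `obs_mass`, `intensity`, `ppm_error`, `replicate_id`.
#' @export
match_fragments <- function(spectrum, table, tolerance_ppm) {
  stopifnot(tolerance_ppm > 0, nrow(table) > 0L)
  pm <- spectrum$mass
  tm <- table$mass
  n <- length(pm)
  empty <- data.table::data.table(
    terminus = character(), ion_type = character(), loss = character(),
    cleavage = integer(), mod_count = integer(), theo_mass = numeric(),
    obs_mass = numeric(), intensity = numeric(), ppm_error = numeric(),
    replicate_id = character())
  if (n == 0L) return(empty)
  idx <- findInterval(tm, pm)
  c1 <- pmax(idx, 1L)                      # peak at or below
  c2 <- pmin(idx + 1L, n)                  # peak above
  d1 <- abs(tm - pm[c1]); d1[idx == 0L] <- Inf
  d2 <- abs(tm - pm[c2]); d2[idx >= n] <- Inf
  d2[idx == 0L] <- abs(tm - pm[1L])[idx == 0L]
  pick <- ifelse(d1 < d2, c1,
          ifelse(d2 < d1, c2,
                 ifelse(spectrum$intensity[c1] >= spectrum$intensity[c2],
                        c1, c2)))
  ppm <- (pm[pick] - tm) / tm * 1e6
  keep <- abs(ppm) <= tolerance_ppm
  if (!any(keep)) return(empty)
  out <- data.table::data.table(
    terminus = table$terminus[keep], ion_type = table$ion_type[keep],
    loss = table$loss[keep], cleavage = table$cleavage[keep],
    mod_count = table$mod_count[keep], theo_mass = tm[keep],
    obs_mass = pm[pick[keep]], intensity = spectrum$intensity[pick[keep]],
    ppm_error = ppm[keep],
    replicate_id = attr(spectrum, "replicate_id") %||% "rep1")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Data-driven mass calibration
#'
#' From a broad-tolerance first matching pass, the systematic mass deviation
#' is the median ppm error; the accepted tolerance is three standard
#' deviations of the ppm errors after discarding points more than four
#' robust sigmas (MAD) from the median.
#'
#' @param assignments data.table from [match_fragments()] (possibly pooled
#'   over replicates) with a `ppm_error` column.
#' @param min_n Minimum number of assignments required (default 20).
#' @return Object of class `calibration_model` with `shift_ppm`,
#'   `sigma_ppm`, `tolerance_ppm` and `n_used`.
#' @export
calibrate <- function(assignments, min_n = 20L) {
  ppm <- assignments$ppm_error
  if (length(ppm) < min_n)
    stop("only ", length(ppm), " assignments; widen the first-pass tolerance")
  med <- stats::median(ppm)
  rsig <- stats::mad(ppm)
  # a zero MAD (error-free synthetic data) collapses the filter onto the
  # median rather than disabling it
  keep <- abs(ppm - med) <= 4 * rsig + 1e-9
  sigma <- stats::sd(ppm[keep])
  if (!is.finite(sigma)) sigma <- 0
  structure(
    list(shift_ppm = med, sigma_ppm = sigma,
         tolerance_ppm = max(3 * sigma, 1e-3), n_used = sum(keep)),
    class = "calibration_model"
  )
}

#' Apply a calibration model to a spectrum
#'
#' Corrects every peak mass by the systematic shift:
#' `mass * (1 - shift_ppm * 1e-6)`.
#'
#' @param spectrum A `decon_spectrum`.
#' @param model A `calibration_model`.
#' @return The corrected `decon_spectrum`.
#' @export
apply_calibration <- function(spectrum, model) {
  spectrum$mass <- spectrum$mass * (1 - model$shift_ppm * 1e-6)
  spectrum
}

#' Fraction of backbone cleavages covered by assignments
#'
#' An N-terminal fragment at cleavage i covers cleavage i; a C-terminal
#' fragment at cleavage j covers cleavage L-j. Coverage is the fraction of
#' the L-1 cleavage positions with at least one assignment.
#'
#' @param assignments data.table with `terminus` and `cleavage` columns.
#' @param sequence_length Protein length L.
#' @return Fraction in \[0, 1\].
#' @export
sequence_coverage <- function(assignments, sequence_length) {
  L <- as.integer(sequence_length)
  if (is.null(assignments) || nrow(assignments) == 0L) return(0)
  pos <- ifelse(assignments$terminus == "N", assignments$cleavage,
                L - assignments$cleavage)
  length(unique(pos[pos >= 1L & pos <= L - 1L])) / (L - 1L)
}

#' Majority voting across technical replicates
#'
#' A fragment (keyed by terminus, ion type, loss, cleavage and modification
#' count) is accepted iff it was assigned in at least `k` of the replicates;
#' its intensity (and observed mass) is the median over the replicates where
#' it was seen. `k = 1` is the union, `k = n` the intersection.
#'
#' @param replicate_assignments List of assignment tables, one per replicate.
#' @param k Minimum number of replicates (1 <= k <= n).
#' @return data.table of accepted fragments with `n_replicates` support
#'   column; attribute `k` records the rule.
#' @export
majority_vote <- function(replicate_assignments, k) {
  n <- length(replicate_assignments)
  stopifnot(k >= 1L, k <= n)
  all <- data.table::rbindlist(replicate_assignments)
  if (nrow(all) == 0L) {
    out <- all
  } else {
    # one vote per replicate per key even if a replicate matched twice
    intensity <- obs_mass <- theo_mass <- ppm_error <- replicate_id <- NULL
    per_rep <- all[, list(intensity = max(intensity),
                          obs_mass = obs_mass[which.max(intensity)],
                          theo_mass = theo_mass[1],
                          ppm_error = ppm_error[which.max(intensity)]),
                   by = c("terminus", "ion_type", "loss", "cleavage",
                          "mod_count", "replicate_id")]
    out <- per_rep[, list(n_replicates = .N,
                          intensity = stats::median(intensity),
                          obs_mass = stats::median(obs_mass),
                          theo_mass = theo_mass[1],
                          ppm_error = stats::median(ppm_error)),
                   by = c("terminus", "ion_type", "loss", "cleavage",
                          "mod_count")]
    out <- out[out$n_replicates >= k, ]
  }
  data.table::setattr(out, "k", k)
  data.table::setattr(out, "n_input_replicates", n)
  out[]
}

#' Data-driven ion-type selection ("frequent flyer" test)
#'
#' Counts assignments per candidate ion type against the target sequence and
#' against a set of scrambled decoy sequences, then flags the types whose
#' target count is a significant right-tail outlier of the count population
#' (target counts augmented with all decoy counts), using a percentile-based
#' robust z (median and the 15.87/84.13 percentiles) and a one-sided normal
#' p-value (Significance A style). If nothing is significant, all candidates
#' are returned with a warning.
#'
#' @param spectra A `spectrum_set` (or list of `decon_spectrum`).
#' @param sequence Target residue string.
#' @param candidates Candidate ion types (default: all 8).
#' @param losses Neutral losses searched (default "none").
#' @param tolerance_ppm Match tolerance for the counting pass (default 10).
#' @param alpha Significance threshold (default 0.01).
#' @param n_decoys Number of scrambled sequences (default 20).
#' @param seed Seed for decoy scrambling.
#' @param max_mods,mod Modification grid, as in [generate_fragments()].
#' @return List with `counts`, `decoy_counts` (matrix type x decoy), `p`
#'   (named), `selected` (character vector) and `fallback` (logical).
#' @export
select_ion_types <- function(spectra, sequence,
                             candidates = ion_types()$ion_type,
                             losses = "none", tolerance_ppm = 10,
                             alpha = 0.01, n_decoys = 20L, seed = 1L,
                             max_mods = 0L, mod = NULL) {
  stopifnot(length(candidates) > 0L)
  count_types <- function(seq_) {
    tab <- generate_fragments(seq_, ion_type = candidates, losses = losses,
                              max_mods = max_mods, mod = mod)
    cnt <- stats::setNames(numeric(length(candidates)), candidates)
    for (sp in spectra) {
      a <- match_fragments(sp, tab, tolerance_ppm)
      if (nrow(a)) {
        t <- table(a$ion_type)
        cnt[names(t)] <- cnt[names(t)] + as.numeric(t)
      }
    }
    cnt
  }
  target <- count_types(sequence)
  decoy <- vapply(seq_len(n_decoys), function(d)
    count_types(scramble_sequence(sequence, as.integer(seed) + d)),
    numeric(length(candidates)))
  pop <- c(target, as.numeric(decoy))
  med <- stats::median(pop)
  p84 <- stats::quantile(pop, 0.8413, names = FALSE)
  scale <- max(p84 - med, 1)
  z <- (target - med) / scale
  p <- stats::pnorm(z, lower.tail = FALSE)
  selected <- candidates[p < alpha]
  fallback <- length(selected) == 0L
  if (fallback) {
    warning("no ion type significantly present; falling back to all candidates")
    selected <- candidates
  }
  list(counts = target, decoy_counts = decoy, p = p, selected = selected,
       fallback = fallback)
}

#' Fragment-level FDR from scrambled decoy sequences
#'
#' The identical search pipeline (same ion types, losses, tolerance and
#' majority-vote rule) is run against `n_scrambles` composition-preserving
#' scrambles of the target sequence; the fragment-level FDR is the median
#' decoy sequence coverage. Decoy searches reuse the target's calibration
#' (calibration is a property of the instrument, not of the sequence).
#'
#' @param spectra A `spectrum_set` (already calibrated if applicable).
#' @param sequence Target residue string.
#' @param ion_type,losses,max_mods,mod Search grid, as in
#'   [generate_fragments()].
#' @param tolerance_ppm Match tolerance in ppm.
#' @param vote_k Majority-vote threshold (default 2).
#' @param n_scrambles Number of decoys (default 200).
#' @param seed Base seed; decoy d uses `seed + d`.
#' @return List with `target_coverage`, `decoy_coverages`, `fdr` (median
#'   decoy coverage, fraction of cleavages) and the parameters used.
#' @export
estimate_fdr <- function(spectra, sequence, ion_type = etd_ion_types(),
                         losses = "none", tolerance_ppm = 3, vote_k = 2L,
                         n_scrambles = 200L, seed = 1L,
                         max_mods = 0L, mod = NULL) {
  stopifnot(n_scrambles >= 2L)
  L <- nchar(sequence)
  run <- function(seq_) {
    tab <- generate_fragments(seq_, ion_type = ion_type, losses = losses,
                              max_mods = max_mods, mod = mod)
    per_rep <- lapply(spectra, match_fragments, table = tab,
                      tolerance_ppm = tolerance_ppm)
    acc <- majority_vote(per_rep, k = min(vote_k, length(per_rep)))
    sequence_coverage(acc, L)
  }
  target_coverage <- run(sequence)
  decoy_coverages <- vapply(seq_len(n_scrambles), function(d)
    run(scramble_sequence(sequence, as.integer(seed) + d)), numeric(1))
  list(target_coverage = target_coverage,
       decoy_coverages = decoy_coverages,
       fdr = stats::median(decoy_coverages),
       n_scrambles = n_scrambles, tolerance_ppm = tolerance_ppm,
       ion_type = ion_type, vote_k = vote_k)
}

#' Standard assignment pipeline: broad match, calibrate, tight match, vote
#'
#' Runs the broad-tolerance first pass, fits the calibration model on the
#' pooled assignments, corrects the spectra, re-matches at the calibrated
#' tolerance `min(3 * sigma, first_pass_ppm)` and applies majority voting.
#'
#' @param spectra A `spectrum_set`.
#' @param sequence Residue string.
#' @param mod A `ptm_mod` (or NULL for an unmodified search).
#' @param max_mods Maximum modification count on the precursor.
#' @param ion_type,losses Search grid.
#' @param first_pass_ppm Broad first-pass tolerance (default 10).
#' @param do_calibrate Fit and apply the calibration model (default TRUE).
#' @param vote_k Majority-vote threshold (default 2; capped at the number of
#'   replicates).
#' @param min_calib_n Minimum assignments required to calibrate.
#' @return List with `accepted` (voted fragment table), `per_replicate`
#'   assignment tables, `calibration`, `tolerance_ppm`, `coverage`,
#'   `spectra` (calibrated), `q` (mean chance-match probability over
#'   replicates) and `table` (the theoretical grid).
#' @export
assign_spectra <- function(spectra, sequence, mod = NULL, max_mods = 0L,
                           ion_type = etd_ion_types(), losses = "none",
                           first_pass_ppm = 10, do_calibrate = TRUE,
                           vote_k = 2L, min_calib_n = 20L) {
  if (inherits(spectra, "decon_spectrum")) spectra <- spectrum_set(list(spectra))
  tab <- generate_fragments(sequence, ion_type = ion_type, losses = losses,
                            max_mods = max_mods, mod = mod)
  broad <- lapply(spectra, match_fragments, table = tab,
                  tolerance_ppm = first_pass_ppm)
  model <- NULL
  tol <- first_pass_ppm
  if (do_calibrate) {
    pooled <- data.table::rbindlist(broad)
    if (nrow(pooled) >= min_calib_n) {
      model <- calibrate(pooled, min_n = min_calib_n)
      tol <- min(model$tolerance_ppm, first_pass_ppm)
      spectra <- spectrum_set(lapply(spectra, apply_calibration, model = model))
    }
  }
  per_rep <- lapply(spectra, match_fragments, table = tab, tolerance_ppm = tol)
  vote_k <- min(vote_k, length(per_rep))
  accepted <- majority_vote(per_rep, k = vote_k)
  q <- mean(vapply(spectra, function(s) compute_spectrum_stats(s)$q, 0))
  list(accepted = accepted, per_replicate = per_rep, calibration = model,
       tolerance_ppm = tol, coverage = sequence_coverage(accepted,
                                                         nchar(sequence)),
       spectra = spectra, q = q, table = tab,
       params = list(ion_type = ion_type, losses = losses, vote_k = vote_k,
                     first_pass_ppm = first_pass_ppm, max_mods = max_mods))
}
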