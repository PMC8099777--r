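#' Simulation configuration for deconvoluted ETD spectrum sets
#'
#' The generator emulates the data model of deisotoped top-down ETD spectra
#' of a co-isolated positional-isomer mixture. Its central assumption -- the
#' one the quantification rests on -- is that the per-cleavage fragmentation
#' efficiency is SHARED across isomers: a single base intensity per cleavage
#' times a per-ion-type efficiency, scaled by each isomer's abundance.
#' Replicates differ by multiplicative log-normal intensity noise, ppm mass
#' error, i.i.d. fragment dropout and random decoy peaks.
#'
#' @param sequence Residue string.
#' @param mod A `ptm_mod`.
#' @param isomer_sites List of site vectors, one per proteoform (all the
#'   same length: positional isomers share the modification count).
#' @param abundances Positive abundances, normalized to sum 1.
#' @param ion_type Ion types emitted (default ETD set).
#' @param efficiencies Named per-type efficiencies in (0, 1]; defaults give
#'   c/z-dot dominance typical of ETD.
#' @param base_median,base_sigma_log10 Log-normal per-cleavage base
#'   intensity model (defaults 1e4 and 0.4: the dynamic range of
#'   deconvoluted top-down spectra).
#' @param intensity_cv Multiplicative intensity noise CV per replicate
#'   (default 0.1).
#' @param ppm_bias,ppm_sd Systematic and random mass error in ppm (defaults
#'   0 and 1).
#' @param dropout Per-fragment per-replicate dropout probability (default
#'   0.1).
#' @param decoy_per_100da Random decoy peak density (default 2).
#' @param decoy_median,decoy_sigma_log10 Decoy intensity distribution
#'   (default median 1e3: the low quantile of the base distribution, so
#'   false matches span intensities).
#' @param n_replicates Number of technical replicates (default 3).
#' @param site_suppression_factor,site_suppression_width Optional intensity
#'   suppression of fragments cleaved within `width` residues of a modified
#'   site (default: none), to probe robustness to modification-proximal
#'   intensity distortion.
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(sequence, mod, isomer_sites, abundances,
                       ion_type = etd_ion_types(),
                       efficiencies = c("c" = 1, "c-1" = 0.25, "y" = 0.35,
                                        "z" = 0.3, "z+1" = 0.9),
                       base_median = 1e4, base_sigma_log10 = 0.4,
                       intensity_cv = 0.1, ppm_bias = 0, ppm_sd = 1,
                       dropout = 0.1, decoy_per_100da = 2,
                       decoy_median = 1e3, decoy_sigma_log10 = 0.4,
                       n_replicates = 3L, site_suppression_factor = 1,
                       site_suppression_width = 0L, seed = 1L) {
  abundances <- abundances / sum(abundances)
  stopifnot(all(abundances > 0), length(abundances) == length(isomer_sites),
            intensity_cv >= 0, dropout >= 0, dropout < 1,
            decoy_per_100da >= 0, n_replicates >= 1L)
  n_mods <- unique(lengths(isomer_sites))
  if (length(n_mods) != 1L)
    stop("positional isomers must share one modification count")
  missing_eff <- setdiff(ion_type, names(efficiencies))
  if (length(missing_eff))
    stop("no efficiency for ion type(s): ", paste(missing_eff, collapse = ", "))
  proteoforms <- lapply(seq_along(isomer_sites), function(i)
    proteoform(sequence, mod, isomer_sites[[i]],
               label = paste0("isomer_", i)))
  structure(
    list(sequence = sequence, mod = mod, proteoforms = proteoforms,
         abundances = abundances, ion_type = ion_type,
         efficiencies = efficiencies[ion_type], base_median = base_median,
         base_sigma_log10 = base_sigma_log10, intensity_cv = intensity_cv,
         ppm_bias = ppm_bias, ppm_sd = ppm_sd, dropout = dropout,
         decoy_per_100da = decoy_per_100da, decoy_median = decoy_median,
         decoy_sigma_log10 = decoy_sigma_log10,
         n_replicates = as.integer(n_replicates),
         site_suppression_factor = site_suppression_factor,
         site_suppression_width = as.integer(site_suppression_width),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a deconvoluted ETD spectrum set with ground truth
#'
#' @param config A `sim_config`.
#' @return List of class `sim_result` with `spectra` (a `spectrum_set`),
#'   `truth` (true fragments with noiseless intensities, per-replicate decoy
#'   registries, proteoforms and abundances) and `config`.
#' @export
simulate_spectrum_set <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  seq_ <- config$sequence
  L <- nchar(seq_)
  n_mods <- length(config$proteoforms[[1]]$sites)
  tab <- generate_fragments(seq_, ion_type = config$ion_type, losses = "none",
                            max_mods = n_mods, mod = config$mod)
  base <- 10^(log10(config$base_median) +
                stats::rnorm(L - 1L, 0, config$base_sigma_log10))

  # noiseless fragment intensities: isomers sharing a (terminus, cleavage,
  # type, level) class sum
  frags <- list()
  for (k in seq_along(config$proteoforms)) {
    sites <- config$proteoforms[[k]]$sites
    alpha <- config$abundances[k]
    for (term in c("N", "C")) {
      cl <- seq_len(L - 1L)
      m <- if (term == "N") vapply(cl, function(i) sum(sites <= i), 0L)
           else vapply(cl, function(j) sum(sites > L - j), 0L)
      for (t in config$ion_type) {
        t_term <- ion_types()$terminus[match(t, ion_types()$ion_type)]
        if (t_term != term) next
        supp <- rep(1, L - 1L)
        if (config$site_suppression_factor != 1 &&
            config$site_suppression_width > 0L && length(sites)) {
          pos <- if (term == "N") cl else L - cl
          near <- vapply(pos, function(p)
            any(abs(p - sites) <= config$site_suppression_width), TRUE)
          supp[near] <- config$site_suppression_factor
        }
        frags[[length(frags) + 1L]] <- data.table::data.table(
          terminus = term, ion_type = t, loss = "none", cleavage = cl,
          mod_count = m,
          intensity = alpha * base[cl] * config$efficiencies[[t]] * supp)
      }
    }
  }
  intensity <- NULL
  truth_frags <- data.table::rbindlist(frags)[
    , list(intensity = sum(intensity)),
    by = c("terminus", "ion_type", "loss", "cleavage", "mod_count")]
  key <- c("terminus", "ion_type", "loss", "cleavage", "mod_count")
  truth_frags <- merge(truth_frags,
                       tab[, c(key, "mass"), with = FALSE], by = key)

  M <- protein_neutral_mass(seq_, n_mods, config$mod)
  decoy_registry <- list()
  spectra <- vector("list", config$n_replicates)
  sd_log <- sqrt(log(1 + config$intensity_cv^2))
  for (r in seq_len(config$n_replicates)) {
    nf <- nrow(truth_frags)
    keep <- stats::runif(nf) >= config$dropout
    inten <- truth_frags$intensity * exp(stats::rnorm(nf, -sd_log^2 / 2,
                                                      sd_log))
    ppm <- config$ppm_bias + stats::rnorm(nf, 0, config$ppm_sd)
    mass <- truth_frags$mass * (1 + ppm * 1e-6)
    n_decoy <- stats::rpois(1, config$decoy_per_100da * (M - 150) / 100)
    d_mass <- stats::runif(n_decoy, 150, M)
    d_int <- 10^(log10(config$decoy_median) +
                   stats::rnorm(n_decoy, 0, config$decoy_sigma_log10))
    decoy_registry[[r]] <- data.table::data.table(mass = d_mass,
                                                  intensity = d_int)
    spectra[[r]] <- decon_spectrum(
      c(mass[keep], d_mass), c(inten[keep], d_int),
      replicate_id = paste0("rep", r), precursor_mass = M)
  }
  structure(
    list(spectra = spectrum_set(spectra),
         truth = list(proteoforms = config$proteoforms,
                      abundances = config$abundances,
                      fragments = truth_frags,
                      decoys = decoy_registry,
                      precursor_mass = M, n_mods = n_mods),
         config = config),
    class = "sim_result"
  )
}

#' Write a simulated spectrum set as plain-text fixtures
#'
#' Peak lists are written in the delimited dialect read by
#' [read_peaklist()]; ground truth goes to `ground_truth.json` (marked
#' synthetic).
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sp in sim$spectra) {
    p <- file.path(dir, paste0("synthetic_", attr(sp, "replicate_id"),
                               ".csv"))
    utils::write.table(
      data.frame(mass = formatC(sp$mass, digits = 12, format = "g"),
                 intensity = formatC(sp$intensity, digits = 12,
                                     format = "g")),
      p, sep = ",", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  gt <- file.path(dir, "synthetic_ground_truth.json")
  jsonlite::write_json(
    list(synthetic = TRUE,
         sequence = sim$config$sequence,
         modification = unclass(sim$config$mod),
         sites = lapply(sim$truth$proteoforms, `[[`, "sites"),
         abundances = sim$truth$abundances,
         precursor_mass = sim$truth$precursor_mass,
         seed = sim$config$seed),
    gt, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, gt))
}
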