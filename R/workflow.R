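#' Run configuration for the full pipeline
#'
#' @param fasta Path to the protein FASTA (first record used).
#' @param peaklists Character vector of replicate peak-list paths.
#' @param mod A `ptm_mod` (or preset name understood by
#'   [modification_preset()]).
#' @param precursor_mass Observed neutral precursor mass (Da); the
#'   modification count is inferred from it.
#' @param first_pass_ppm Broad first-pass tolerance (default 10).
#' @param ion_policy `"auto"` (frequent-flyer selection) or an explicit
#'   character vector of ion types.
#' @param losses Neutral losses searched (default "none").
#' @param vote_k Majority-vote threshold (default 2).
#' @param n_scrambles Decoys for the FDR estimate (default 200).
#' @param do_calibrate Apply data-driven mass calibration (default TRUE).
#' @param score Localization score variant reported first, `"corrected"` or
#'   `"plain"` (both are always computed).
#' @param constraints A `constraint_set` for candidate enumeration.
#' @param min_pairs Quantification reliability floor (default 3).
#' @param seed Integer seed.
#' @param out_dir Output directory (NULL: nothing written).
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta, peaklists, mod, precursor_mass,
                       first_pass_ppm = 10, ion_policy = "auto",
                       losses = "none", vote_k = 2L, n_scrambles = 200L,
                       do_calibrate = TRUE, score = c("corrected", "plain"),
                       constraints = constraint_set(), min_pairs = 3L,
                       seed = 1L, out_dir = NULL) {
  if (is.character(mod) && length(mod) == 1L) mod <- modification_preset(mod)
  stopifnot(inherits(mod, "ptm_mod"))
  missing <- c(fasta, peaklists)[!file.exists(c(fasta, peaklists))]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "))
  structure(
    list(fasta = fasta, peaklists = peaklists, mod = mod,
         precursor_mass = precursor_mass, first_pass_ppm = first_pass_ppm,
         ion_policy = ion_policy, losses = losses, vote_k = as.integer(vote_k),
         n_scrambles = as.integer(n_scrambles), do_calibrate = do_calibrate,
         score = match.arg(score), constraints = constraints,
         min_pairs = as.integer(min_pairs), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from JSON
#'
#' Relative paths are resolved against the config file's directory.
#'
#' @param path JSON file with the [run_config()] fields; `mod` may be a
#'   preset name or an object with `name`/`delta_mass`/`acceptor_residues`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  mod <- raw$mod
  if (is.list(mod))
    mod <- modification(mod$name, mod$delta_mass,
                        unlist(mod$acceptor_residues))
  args <- raw[setdiff(names(raw), c("fasta", "peaklists", "mod"))]
  if (!is.null(args$constraints))
    args$constraints <- constraint_set(
      unlist(args$constraints$fixed_sites),
      args$constraints$exclusive_pairs %||% list())
  do.call(run_config, c(list(fasta = resolve(raw$fasta),
                             peaklists = resolve(unlist(raw$peaklists)),
                             mod = mod), args))
}

#' Run the full pipeline
#'
#' Stages: broad match, calibration, ion-type selection, tight match,
#' majority voting, decoy FDR, ladder construction, localization,
#' quantification. Intermediate and final tables are written under
#' `config$out_dir` when set, together with a provenance JSON (parameters,
#' seed, package version).
#'
#' @param config A `run_config`.
#' @param stage Last stage to run: `"assign"`, `"localize"` or `"full"`.
#' @return List with `assignment`, `ion_selection`, `fdr`, `ladders`,
#'   `localization`, `quantification` (stages beyond `stage` are NULL) and
#'   `provenance`.
#' @export
run_full <- function(config, stage = c("full", "assign", "localize")) {
  stage <- match.arg(stage)
  seqs <- read_fasta(config$fasta)
  sequence <- seqs[[1]]
  L <- nchar(sequence)
  spectra <- spectrum_set(lapply(config$peaklists, read_peaklist))
  n_mods <- infer_mod_count(config$precursor_mass, sequence, config$mod)

  ion_sel <- NULL
  ion_type <- config$ion_policy
  if (identical(config$ion_policy, "auto")) {
    ion_sel <- select_ion_types(spectra, sequence, losses = config$losses,
                                tolerance_ppm = config$first_pass_ppm,
                                seed = config$seed, max_mods = n_mods,
                                mod = config$mod)
    ion_type <- ion_sel$selected
  }

  asg <- assign_spectra(spectra, sequence, mod = config$mod,
                        max_mods = n_mods, ion_type = ion_type,
                        losses = config$losses,
                        first_pass_ppm = config$first_pass_ppm,
                        do_calibrate = config$do_calibrate,
                        vote_k = config$vote_k)
  message(sprintf(
    "assignment: %d accepted fragments, coverage %.1f%%, tolerance %.2f ppm",
    nrow(asg$accepted), 100 * asg$coverage, asg$tolerance_ppm))

  fdr <- estimate_fdr(asg$spectra, sequence, ion_type = ion_type,
                      losses = config$losses,
                      tolerance_ppm = asg$tolerance_ppm,
                      vote_k = config$vote_k,
                      n_scrambles = config$n_scrambles, seed = config$seed,
                      max_mods = n_mods, mod = config$mod)
  message(sprintf("fragment-level FDR: %.2f%% (median of %d decoys)",
                  100 * fdr$fdr, fdr$n_scrambles))

  out <- list(assignment = asg, ion_selection = ion_sel, fdr = fdr,
              ladders = NULL, localization = NULL, quantification = NULL)
  it <- ion_types()
  kinds_n <- data.frame(ion_type = intersect(ion_type,
                                             it$ion_type[it$terminus == "N"]),
                        loss = config$losses[1])
  kinds_c <- data.frame(ion_type = intersect(ion_type,
                                             it$ion_type[it$terminus == "C"]),
                        loss = config$losses[1])
  ladders <- list(
    N = build_ladder(asg$accepted, "N", L, n_mods, ion_kinds = kinds_n),
    C = build_ladder(asg$accepted, "C", L, n_mods, ion_kinds = kinds_c))
  out$ladders <- ladders

  if (stage != "assign" && n_mods >= 1L) {
    loc <- localize(ladders, sequence, n_mods, config$mod, asg$q,
                    constraints = config$constraints)
    out$localization <- loc
    if (stage == "full") {
      pool <- sort(unique(unlist(
        strsplit(loc$sites[seq_len(min(nrow(loc), 25L))], "+",
                 fixed = TRUE))))
      pool <- as.integer(pool)
      candidates <- enumerate_isomers(pool, n_mods, config$constraints)
      out$quantification <- tryCatch(
        quantify_isomers(candidates, ladders, min_pairs = config$min_pairs),
        error = function(e) {
          message("quantification not possible: ", conditionMessage(e))
          NULL
        })
    }
  }

  out$provenance <- list(
    package = "ptmladder",
    version = as.character(utils::packageVersion("ptmladder")),
    seed = config$seed,
    n_mods = n_mods,
    ion_type = ion_type,
    tolerance_ppm = asg$tolerance_ppm,
    vote_k = config$vote_k,
    n_scrambles = config$n_scrambles,
    score = config$score)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(as.data.frame(asg$accepted),
                 file.path(config$out_dir, "assignments.tsv"))
    write_report(data.frame(target_coverage = fdr$target_coverage,
                            fdr = fdr$fdr),
                 file.path(config$out_dir, "fdr.tsv"))
    write_ladder_tsv(ladders$N, file.path(config$out_dir, "ladder_N.tsv"))
    write_ladder_tsv(ladders$C, file.path(config$out_dir, "ladder_C.tsv"))
    if (!is.null(out$localization))
      write_report(out$localization,
                   file.path(config$out_dir, "combinations.tsv"))
    if (!is.null(out$quantification))
      write_report(out$quantification$abundances,
                   file.path(config$out_dir, "quantification.tsv"))
    jsonlite::write_json(out$provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
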