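#' Monoisotopic residue masses and mass constants
#'
#' Residue masses are the standard monoisotopic masses of the 20 amino acid
#' residues (the mass contributed to a peptide chain, i.e. the free amino acid
#' minus water). Leucine and isoleucine are isobaric.
#'
#' @return Named numeric vector of residue masses in Da, names are the
#'   one-letter residue codes.
#' @export
#' @examples
#' amino_acid_masses()[["G"]]
amino_acid_masses <- function() {
  c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  )
}

#' Monoisotopic mass constants (Da)
#'
#' @return Named list with `water`, `ammonia`, `co` (carbon monoxide),
#'   `hydrogen` (H atom) and `proton` masses in Da.
#' @export
mass_constants <- function() {
  list(
    water    = 18.010565,
    ammonia  = 17.026549,
    co       = 27.994915,
    hydrogen = 1.007825,
    proton   = 1.007276
  )
}

#' Define a modification
#'
#' A single modification type is considered per precursor: a name, its
#' monoisotopic delta mass and the residues that can carry it.
#'
#' @param name Character scalar.
#' @param delta_mass Monoisotopic mass shift in Da; must be non-zero.
#' @param acceptor_residues Character vector of one-letter residue codes that
#'   can accept the modification.
#' @return Object of class `ptm_mod`.
#' @export
#' @examples
#' modification("phospho", 79.96633, c("S", "T", "Y"))
modification <- function(name, delta_mass, acceptor_residues) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(delta_mass) || length(delta_mass) != 1L || delta_mass == 0)
    stop("delta_mass must be a single non-zero number")
  acceptor_residues <- toupper(as.character(acceptor_residues))
  if (length(acceptor_residues) == 0L)
    stop("acceptor_residues must be nonempty")
  bad <- setdiff(acceptor_residues, names(amino_acid_masses()))
  if (length(bad))
    stop("unknown acceptor residue(s): ", paste(bad, collapse = ", "))
  structure(
    list(name = name, delta_mass = delta_mass,
         acceptor_residues = sort(unique(acceptor_residues))),
    class = "ptm_mod"
  )
}

#' Built-in modification presets
#'
#' `phospho` is +79.96633 Da on S/T/Y. `heavy-val` is the +6.013810 Da
#' 13C5,15N valine isotope label, expressed as a modification on V so the
#' whole PTM machinery applies unchanged to labelled benchmark proteins.
#'
#' @param name One of `"phospho"`, `"heavy-val"`.
#' @return A `ptm_mod`.
#' @export
modification_preset <- function(name = c("phospho", "heavy-val")) {
  name <- match.arg(name)
  switch(name,
    "phospho"   = modification("phospho", 79.96633, c("S", "T", "Y")),
    "heavy-val" = modification("heavy-val", 6.013810, "V")
  )
}

#' Read modification definitions from a JSON config file
#'
#' The file holds one object or a list of objects with fields `name`,
#' `delta_mass` and `acceptor_residues`.
#'
#' @param path Path to a JSON file.
#' @return A list of `ptm_mod` objects.
#' @export
read_modifications <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(raw$name)) raw <- list(raw)
  lapply(raw, function(x) {
    modification(x$name, x$delta_mass, unlist(x$acceptor_residues))
  })
}

# split a sequence string into residue letters, validating against the table
.residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string")
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(amino_acid_masses()))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1]], bad[1]))
  res
}

#' Proteoform: a sequence plus modified site indices
#'
#' @param sequence Residue string.
#' @param mod A `ptm_mod`.
#' @param sites Integer vector of 1-based residue indices carrying the
#'   modification; must be strictly increasing acceptor positions.
#' @param label Optional text label (e.g. an abundance tag).
#' @return Object of class `proteoform`.
#' @export
proteoform <- function(sequence, mod, sites = integer(), label = NULL) {
  res <- .residues(sequence)
  stopifnot(inherits(mod, "ptm_mod"))
  sites <- as.integer(sites)
  if (is.unsorted(sites, strictly = TRUE))
    stop("sites must be strictly increasing")
  if (length(sites) && (min(sites) < 1L || max(sites) > length(res)))
    stop("site index out of range 1..", length(res))
  off <- sites[!res[sites] %in% mod$acceptor_residues]
  if (length(off))
    stop("site ", off[1], " (", res[off[1]], ") is not an acceptor residue for ",
         mod$name)
  structure(
    list(sequence = paste(res, collapse = ""), modification = mod,
         sites = sites, label = label),
    class = "proteoform"
  )
}

#' Occupancy / exclusivity constraints on candidate modification sites
#'
#' @param fixed_sites Integer vector of residue indices that are modified in
#'   every candidate (100% occupancy).
#' @param exclusive_pairs List of length-2 integer vectors; no candidate may
#'   contain both members of a pair.
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(fixed_sites = integer(), exclusive_pairs = list()) {
  fixed_sites <- sort(unique(as.integer(fixed_sites)))
  if (is.matrix(exclusive_pairs))
    exclusive_pairs <- lapply(seq_len(nrow(exclusive_pairs)),
                              function(i) exclusive_pairs[i, ])
  exclusive_pairs <- lapply(exclusive_pairs, function(p) {
    p <- sort(unique(as.integer(unlist(p))))
    if (length(p) != 2L) stop("each exclusive pair must hold two distinct sites")
    p
  })
  structure(list(fixed_sites = fixed_sites, exclusive_pairs = exclusive_pairs),
            class = "constraint_set")
}

#' Neutral monoisotopic mass of a (modified) protein
#'
#' Sum of residue masses plus one water plus `n_mods` times the modification
#' delta mass.
#'
#' @param sequence Residue string.
#' @param n_mods Number of modifications carried (default 0).
#' @param mod A `ptm_mod`; required when `n_mods > 0`.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' protein_neutral_mass("G") # glycine: 75.032029 Da
protein_neutral_mass <- function(sequence, n_mods = 0L, mod = NULL) {
  res <- .residues(sequence)
  n_mods <- as.integer(n_mods)
  stopifnot(n_mods >= 0L)
  delta <- 0
  if (n_mods > 0L) {
    if (is.null(mod)) stop("mod required when n_mods > 0")
    delta <- n_mods * mod$delta_mass
  }
  sum(amino_acid_masses()[res]) + mass_constants()$water + delta
}

#' Infer the modification count from the precursor mass
#'
#' The number of modifications is the rounded multiple of the delta mass
#' separating the observed precursor from the unmodified sequence mass; the
#' residual after rounding must fall within the ppm tolerance.
#'
#' @param observed_mass Observed neutral monoisotopic precursor mass (Da).
#' @param sequence Residue string.
#' @param mod A `ptm_mod`.
#' @param tolerance_ppm Tolerance on the residual, in ppm of the observed
#'   mass (default 5).
#' @return Non-negative integer modification count.
#' @export
infer_mod_count <- function(observed_mass, sequence, mod, tolerance_ppm = 5) {
  stopifnot(tolerance_ppm > 0, inherits(mod, "ptm_mod"))
  m0 <- protein_neutral_mass(sequence)
  n <- round((observed_mass - m0) / mod$delta_mass)
  if (n < 0)
    stop("observed precursor lighter than the unmodified sequence")
  residual <- observed_mass - (m0 + n * mod$delta_mass)
  if (abs(residual) / observed_mass * 1e6 > tolerance_ppm)
    stop(sprintf(
      "precursor inconsistent with modification count: residual %.5f Da at n=%d",
      residual, n))
  as.integer(n)
}

#' Scramble a sequence (composition-preserving decoy)
#'
#' Fisher-Yates shuffle with an explicit seed; the decoy is a permutation of
#' the input, so residue composition and intact mass are preserved exactly.
#' The caller's RNG state is untouched.
#'
#' @param sequence Residue string of length >= 2.
#' @param seed Integer seed; the same seed always yields the same decoy.
#' @return Scrambled residue string.
#' @export
scramble_sequence <- function(sequence, seed) {
  res <- .residues(sequence)
  if (length(res) < 2L) stop("sequence must have length >= 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  paste(res[sample.int(length(res))], collapse = "")
}

#' Enumerate candidate positional isomers
#'
#' All size-`n_mods` subsets of the site pool that contain every fixed site
#' and violate no mutual-exclusion pair, in lexicographic order.
#'
#' @param site_pool Sorted integer vector of candidate site indices.
#' @param n_mods Number of modifications per candidate.
#' @param constraints A `constraint_set` (default empty).
#' @return List of sorted integer vectors.
#' @export
#' @examples
#' length(enumerate_isomers(c(48, 64, 91, 120, 128, 149), 2)) # 15
enumerate_isomers <- function(site_pool, n_mods,
                              constraints = constraint_set()) {
  site_pool <- sort(unique(as.integer(site_pool)))
  n_mods <- as.integer(n_mods)
  stopifnot(n_mods >= 0L, n_mods <= length(site_pool))
  fixed <- constraints$fixed_sites
  if (length(setdiff(fixed, site_pool)))
    stop("fixed sites must be members of the site pool")
  if (length(fixed) > n_mods)
    stop("more fixed sites than modifications")
  free <- setdiff(site_pool, fixed)
  k <- n_mods - length(fixed)
  combos <- if (k == 0L) list(integer()) else
    utils::combn(free, k, simplify = FALSE)
  out <- lapply(combos, function(s) sort(c(fixed, s)))
  if (length(constraints$exclusive_pairs)) {
    keep <- vapply(out, function(s) {
      !any(vapply(constraints$exclusive_pairs,
                  function(p) all(p %in% s), logical(1)))
    }, logical(1))
    out <- out[keep]
  }
  # lexicographic order over the site vectors
  if (length(out) > 1L) {
    key <- vapply(out, function(s) paste(sprintf("%06d", s), collapse = ","),
                  character(1))
    out <- out[order(key)]
  }
  out
}

#' Count unordered pairs of modifiable residues in a sequence
#'
#' @param sequence Residue string.
#' @param mod A `ptm_mod`.
#' @return `choose(k, 2)` where `k` is the number of acceptor residues.
#' @export
count_modifiable_pairs <- function(sequence, mod) {
  res <- .residues(sequence)
  k <- sum(res %in% mod$acceptor_residues)
  choose(k, 2)
}

#' Positions of acceptor residues in a sequence
#'
#' @inheritParams count_modifiable_pairs
#' @return Integer vector of 1-based acceptor positions.
#' @export
acceptor_positions <- function(sequence, mod) {
  which(.residues(sequence) %in% mod$acceptor_residues)
}
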