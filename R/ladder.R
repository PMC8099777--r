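#' Build a per-terminus PTM ladder
#'
#' The ladder arranges accepted fragment evidence on a cleavage-position by
#' modification-count grid for one terminus. Cell (i, m) holds the summed
#' intensity of accepted fragments at cleavage i carrying m modifications;
#' steps in the occupied modification count along the cleavage axis localize
#' modification sites.
#'
#' @param accepted Accepted fragment table (from [majority_vote()]).
#' @param terminus `"N"` or `"C"`.
#' @param L Protein length.
#' @param n_max Maximum modification count (precursor count).
#' @param ion_kinds Optional data.frame of `ion_type`/`loss` combinations
#'   considered by the search for this terminus; defaults to the kinds
#'   present in `accepted` for this terminus. Used for the theoretical
#'   fragment counts in scoring.
#' @return Object of class `ptm_ladder`: list with `terminus`, `L`, `n_max`,
#'   `fragments` (per-fragment rows) and `ion_kinds`.
#' @export
build_ladder <- function(accepted, terminus = c("N", "C"), L, n_max,
                         ion_kinds = NULL) {
  terminus <- match.arg(terminus)
  L <- as.integer(L); n_max <- as.integer(n_max)
  fr <- data.table::as.data.table(as.data.frame(accepted))
  keep_rows <- which(fr[["terminus"]] == terminus)
  fr <- fr[keep_rows, ]
  if (nrow(fr) && max(fr$mod_count) > n_max)
    stop("fragment modification count exceeds the precursor count")
  if (is.null(ion_kinds)) {
    ion_kinds <- unique(fr[, c("ion_type", "loss"), with = FALSE])
  }
  structure(
    list(terminus = terminus, L = L, n_max = n_max,
         fragments = fr[, c("ion_type", "loss", "cleavage", "mod_count",
                            "intensity"), with = FALSE],
         ion_kinds = as.data.frame(ion_kinds)),
    class = "ptm_ladder"
  )
}

#' Ladder matrix view
#'
#' @param ladder A `ptm_ladder`.
#' @return Numeric matrix (L-1 cleavages x n_max+1 modification counts) of
#'   summed intensities, 0 where no fragment matched.
#' @export
ladder_matrix <- function(ladder) {
  m <- matrix(0, nrow = ladder$L - 1L, ncol = ladder$n_max + 1L,
              dimnames = list(NULL, paste0("m", 0:ladder$n_max)))
  fr <- ladder$fragments
  if (nrow(fr)) {
    agg <- fr[, list(intensity = sum(intensity)),
              by = c("cleavage", "mod_count")]
    m[cbind(agg$cleavage, agg$mod_count + 1L)] <- agg$intensity
  }
  m
}

#' Stretches implied by a site combination
#'
#' For sites s_1 < ... < s_n, the N-terminal ladder is tiled into stretches
#' of constant expected modification count: level m covers cleavages s_m to
#' s_(m+1) - 1 (level 0 starts at cleavage 1, level n ends at L-1), because
#' an N-terminal fragment at cleavage i contains site s iff s <= i. The
#' C-terminal ladder is the mirror image in its own cleavage indexing
#' (cleavage j = number of C-side residues). Empty stretches (from > to) can
#' occur at the termini and contribute probability 1 to scores.
#'
#' @param sites Sorted integer vector of modified sites (may be empty).
#' @param terminus `"N"` or `"C"`.
#' @param L Protein length.
#' @return data.frame with columns `terminus`, `m` (expected count), `from`,
#'   `to` (terminus-local cleavage indices, inclusive) and `n_cleavages`.
#' @export
stretches_for <- function(sites, terminus = c("N", "C"), L) {
  terminus <- match.arg(terminus)
  L <- as.integer(L)
  sites <- sort(as.integer(sites))
  n <- length(sites)
  if (terminus == "N") {
    from <- c(1L, sites)
    to <- c(sites - 1L, L - 1L)
  } else {
    # level m needs exactly m sites above L - j
    from <- c(1L, L - rev(sites) + 1L)
    to <- c(L - rev(sites), L - 1L)
  }
  data.frame(terminus = terminus, m = 0:n, from = from, to = to,
             n_cleavages = pmax(to - from + 1L, 0L))
}

#' Binomial chance probability of a stretch's matches
#'
#' Upper-tail binomial probability of observing at least `n_matched` of
#' `n_theoretical` fragments by chance when each theoretical fragment
#' matches a random peak with probability q (= X/100 from
#' [compute_spectrum_stats()]). Computed in log space; by convention p = 1
#' when nothing matched.
#'
#' @param n_matched Number of matched fragments (0..n_theoretical).
#' @param n_theoretical Number of theoretical fragments in the stretch.
#' @param q Chance-match probability in (0, 1).
#' @param log10p Return log10(p) instead of p (default FALSE).
#' @return Probability (or its log10).
#' @export
#' @examples
#' stretch_probability(10, 10, 0.2)  # 0.2^10
stretch_probability <- function(n_matched, n_theoretical, q, log10p = FALSE) {
  stopifnot(n_matched >= 0, n_matched <= n_theoretical, q > 0, q < 1)
  if (n_matched == 0)
    return(if (log10p) 0 else 1)
  lp <- stats::pbinom(n_matched - 1, n_theoretical, q, lower.tail = FALSE,
                      log.p = TRUE) / log(10)
  if (log10p) lp else 10^lp
}

# per-stretch matched/theoretical counts and probabilities for one ladder
.ladder_stretch_pvalues <- function(ladder, sites, q) {
  st <- stretches_for(sites, ladder$terminus, ladder$L)
  kinds <- max(nrow(ladder$ion_kinds), 1L)
  fr <- ladder$fragments
  st$n_theoretical <- st$n_cleavages * kinds
  st$n_matched <- vapply(seq_len(nrow(st)), function(i) {
    if (st$n_cleavages[i] == 0L || nrow(fr) == 0L) return(0L)
    sel <- fr$cleavage >= st$from[i] & fr$cleavage <= st$to[i] &
      fr$mod_count == st$m[i]
    nrow(unique(fr[sel, c("cleavage", "ion_type", "loss"), with = FALSE]))
  }, integer(1))
  st$n_matched <- pmin(st$n_matched, st$n_theoretical)
  st$log10_p <- vapply(seq_len(nrow(st)), function(i) {
    if (st$n_theoretical[i] == 0L) return(0)
    stretch_probability(st$n_matched[i], st$n_theoretical[i], q, log10p = TRUE)
  }, numeric(1))
  st
}

#' Score one candidate site combination against the PTM ladders
#'
#' Per ladder, each stretch contributes the binomial chance probability of
#' its matches at the stretch's expected modification count. Two scores are
#' reported (both as log10): the plain product of the stretch p-values, and
#' the corrected product in which each stretch's p-value is first divided by
#' the previous stretch's p-value (first stretch uncorrected) to guard
#' against short in-between stretches dominating. The two ladders' products
#' are combined by multiplication. Note the corrected product telescopes to
#' the final stretch's p-value per ladder, so combinations differing only in
#' interior sites tie on it; ranking therefore uses the plain score as a
#' tie-break (see [localize()]).
#'
#' @param ladders List with elements `N` and `C` (`ptm_ladder` objects).
#' @param sites Sorted integer site combination.
#' @param q Chance-match probability.
#' @return List of class `combination_score` with `sites`,
#'   `log10_corrected`, `log10_plain` and `stretches` (per-stretch detail).
#' @export
score_combination <- function(ladders, sites, q) {
  detail <- list()
  log10_plain <- 0
  log10_corrected <- 0
  for (term in c("N", "C")) {
    st <- .ladder_stretch_pvalues(ladders[[term]], sites, q)
    lp <- st$log10_p
    log10_plain <- log10_plain + sum(lp)
    corr <- lp - c(0, lp[-length(lp)])  # divide by previous stretch's p
    st$log10_p_corrected <- corr
    log10_corrected <- log10_corrected + sum(corr)
    detail[[term]] <- st
  }
  structure(
    list(sites = sites, log10_corrected = log10_corrected,
         log10_plain = log10_plain,
         stretches = data.table::rbindlist(detail)),
    class = "combination_score"
  )
}

#' Localize modification sites from the PTM ladders
#'
#' Enumerates candidate site combinations over the acceptor positions
#' (honouring constraints), scores each against both ladders and returns
#' them ranked best-first (ascending corrected score; ties broken by plain
#' score, then by fewer stretch boundaries, then lexicographic sites).
#'
#' @param ladders List with `N` and `C` `ptm_ladder` objects.
#' @param sequence Residue string.
#' @param n_mods Modification count of the precursor (>= 1).
#' @param mod A `ptm_mod`.
#' @param q Chance-match probability.
#' @param constraints A `constraint_set`.
#' @param site_pool Optional explicit candidate site vector; default: all
#'   acceptor positions in the sequence.
#' @return data.frame ranked best-first with `sites` (text, "+"-joined),
#'   `log10_corrected`, `log10_plain` and `rank`; the full
#'   `combination_score` list is attached as attribute `scores`, and the
#'   log10 gap between ranks 1 and 2 as attribute `gap`.
#' @export
localize <- function(ladders, sequence, n_mods, mod, q,
                     constraints = constraint_set(), site_pool = NULL) {
  stopifnot(n_mods >= 1L)
  if (is.null(site_pool)) site_pool <- acceptor_positions(sequence, mod)
  if (choose(length(site_pool), n_mods) > 1e6)
    stop("more than 1e6 candidate combinations; supply constraints or a ",
         "site short-list")
  combos <- enumerate_isomers(site_pool, n_mods, constraints)
  scores <- lapply(combos, function(s) score_combination(ladders, s, q))
  df <- data.frame(
    sites = vapply(combos, paste, "", collapse = "+"),
    log10_corrected = vapply(scores, `[[`, 0, "log10_corrected"),
    log10_plain = vapply(scores, `[[`, 0, "log10_plain"),
    n_boundaries = lengths(combos)
  )
  key <- vapply(combos, function(s) paste(sprintf("%06d", s), collapse = ","),
                character(1))
  o <- order(df$log10_corrected, df$log10_plain, df$n_boundaries, key)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "scores") <- scores[o]
  attr(df, "gap") <- if (nrow(df) >= 2L)
    df$log10_corrected[2] - df$log10_corrected[1] else NA_real_
  df
}
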