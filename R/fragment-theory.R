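#' Ion type definitions
#'
#' Neutral monoisotopic mass offsets added to the summed residue masses of
#' the fragment's own side. ETD produces predominantly c and z-type ions;
#' `c-1` and `z+1` are the +/- one hydrogen radical partners (z+1 is the
#' z-dot species).
#'
#' @return data.frame with columns `ion_type`, `terminus` ("N"/"C") and
#'   `offset` (Da).
#' @export
ion_types <- function() {
  k <- mass_constants()
  data.frame(
    ion_type = c("a", "b", "c", "c-1", "x", "y", "z", "z+1"),
    terminus = c("N", "N", "N", "N", "C", "C", "C", "C"),
    offset = c(
      -k$co,                               # a
      0,                                   # b
      k$ammonia,                           # c
      k$ammonia - k$hydrogen,              # c-1
      k$water + k$co - 2 * k$hydrogen,     # x
      k$water,                             # y
      k$water - k$ammonia,                 # z
      k$water - k$ammonia + k$hydrogen     # z+1
    ),
    stringsAsFactors = FALSE
  )
}

#' Neutral loss definitions
#'
#' @return data.frame with columns `loss` and `delta` (Da, <= 0).
#' @export
neutral_losses <- function() {
  k <- mass_constants()
  data.frame(
    loss = c("none", "water", "ammonia", "hydrogen"),
    delta = c(0, -k$water, -k$ammonia, -k$hydrogen),
    stringsAsFactors = FALSE
  )
}

#' Default ETD ion-type set
#'
#' @return Character vector `c("c", "c-1", "y", "z", "z+1")`.
#' @export
etd_ion_types <- function() c("c", "c-1", "y", "z", "z+1")

#' Generate the theoretical fragment mass grid
#'
#' For every backbone cleavage, selected ion type, neutral loss, and
#' modification count 0..`max_mods`, one neutral monoisotopic fragment mass.
#' Modifications enter as `m` times the delta mass added to the unmodified
#' fragment ("PTM mass grid"): localisation is done downstream by the
#' ladders, so the grid is position-agnostic.
#'
#' The cleavage index counts residues on the fragment's own terminus side:
#' an N-terminal ion at cleavage i holds residues 1..i, a C-terminal ion at
#' cleavage j holds the last j residues.
#'
#' @param sequence Residue string (length L >= 2).
#' @param ion_type Character vector of ion types (subset of
#'   `ion_types()$ion_type`).
#' @param losses Character vector of neutral losses (subset of
#'   `neutral_losses()$loss`).
#' @param max_mods Maximum modification count on a fragment.
#' @param mod A `ptm_mod`; required when `max_mods > 0`.
#' @return A `fragment_table`: data.table with columns `terminus`,
#'   `ion_type`, `loss`, `cleavage`, `mod_count`, `mass`, sorted by mass,
#'   with the sequence and modification kept as attributes.
#' @export
generate_fragments <- function(sequence, ion_type = etd_ion_types(),
                               losses = "none", max_mods = 0L, mod = NULL) {
  res <- .residues(sequence)
  L <- length(res)
  if (L < 2L) stop("sequence must have length >= 2")
  max_mods <- as.integer(max_mods)
  stopifnot(max_mods >= 0L)
  if (max_mods > 0L && is.null(mod)) stop("mod required when max_mods > 0")
  it <- ion_types()
  unknown <- setdiff(ion_type, it$ion_type)
  if (length(unknown)) stop("unknown ion type(s): ", paste(unknown, collapse = ", "))
  if (length(ion_type) == 0L) stop("ion_type must be nonempty")
  nl <- neutral_losses()
  unknown <- setdiff(losses, nl$loss)
  if (length(unknown)) stop("unknown loss(es): ", paste(unknown, collapse = ", "))

  masses <- amino_acid_masses()[res]
  csum_n <- cumsum(masses)[seq_len(L - 1L)]        # residues 1..i
  csum_c <- cumsum(rev(masses))[seq_len(L - 1L)]   # last j residues

  it <- it[match(ion_type, it$ion_type), , drop = FALSE]
  nl <- nl[match(losses, nl$loss), , drop = FALSE]
  delta <- if (max_mods > 0L) mod$delta_mass else 0

  grids <- vector("list", nrow(it))
  for (r in seq_len(nrow(it))) {
    base <- if (it$terminus[r] == "N") csum_n else csum_c
    g <- data.table::CJ(cleavage = seq_len(L - 1L), loss = nl$loss,
                        mod_count = 0:max_mods, sorted = FALSE)
    g[, `:=`(
      terminus = it$terminus[r],
      ion_type = it$ion_type[r],
      mass = base[cleavage] + it$offset[r] +
        nl$delta[match(loss, nl$loss)] + mod_count * delta
    )]
    grids[[r]] <- g
  }
  tab <- data.table::rbindlist(grids)
  data.table::setcolorder(tab, c("terminus", "ion_type", "loss", "cleavage",
                                 "mod_count", "mass"))
  data.table::setkey(tab, mass)
  data.table::setattr(tab, "sequence", paste(res, collapse = ""))
  data.table::setattr(tab, "modification", mod)
  data.table::setattr(tab, "max_mods", max_mods)
  data.table::setattr(tab, "class", c("fragment_table", class(tab)))
  tab[]
}

#' Check the complementary-fragment mass identity
#'
#' For a correctly generated table, an N-terminal fragment at cleavage i with
#' m modifications and its C-terminal complement at cleavage L-i with n-m
#' modifications sum to the intact proteoform mass: b_i + y_{L-i} = M and
#' c_i + z_{L-i} = M (no-loss species).
#'
#' @param table A `fragment_table`.
#' @param sequence The sequence the table was generated from.
#' @param mod_count Total modification count n of the proteoform.
#' @param mod A `ptm_mod` (needed when `mod_count > 0`).
#' @param tol Absolute tolerance in Da (default 1e-6).
#' @return TRUE iff the identity holds for every checkable pair (vacuously
#'   TRUE if neither complementary ion pair is present in the table).
#' @export
complement_mass_check <- function(table, sequence, mod_count = 0L, mod = NULL,
                                  tol = 1e-6) {
  L <- nchar(sequence)
  M <- protein_neutral_mass(sequence, mod_count, mod)
  pairs <- list(c("b", "y"), c("c", "z"))
  for (pr in pairs) {
    n_side <- table[table$ion_type == pr[1] & table$loss == "none", ]
    c_side <- table[table$ion_type == pr[2] & table$loss == "none", ]
    if (!nrow(n_side) || !nrow(c_side)) next
    for (m in unique(n_side$mod_count)) {
      mm <- mod_count - m
      if (mm < 0 || !mm %in% c_side$mod_count) next
      a <- n_side[n_side$mod_count == m, ]
      b <- c_side[c_side$mod_count == mm, ]
      j <- L - a$cleavage
      idx <- match(j, b$cleavage)
      ok <- !is.na(idx)
      if (any(abs(a$mass[ok] + b$mass[idx[ok]] - M) > tol)) return(FALSE)
    }
  }
  TRUE
}
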