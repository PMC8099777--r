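#' Collect modified/unmodified fragment-intensity pairs on a stretch
#'
#' For each cleavage position in the span and each ion kind (ion type +
#' loss) observed at BOTH modification levels m and m+1, one pair with the
#' ratio I(m+1)/I(m). Pairs are formed within an ion kind only: ETD ion-type
#' efficiencies cancel within a type but not across types. Positions where
#' only one level is present are skipped but counted in `n_possible`.
#'
#' @param ladder A `ptm_ladder`.
#' @param from,to Cleavage span (terminus-local, inclusive).
#' @param m Lower modification level.
#' @return data.table with columns `cleavage`, `ion_type`, `loss`,
#'   `intensity_lo`, `intensity_hi`, `ratio`; attribute `n_possible` is the
#'   number of (cleavage, kind) slots with at least one level present.
#' @export
collect_pairs <- function(ladder, from, to, m) {
  fr <- ladder$fragments
  sel <- fr[fr$cleavage >= from & fr$cleavage <= to &
              fr$mod_count %in% c(m, m + 1L), ]
  if (nrow(sel) == 0L) {
    out <- data.table::data.table(cleavage = integer(), ion_type = character(),
                                  loss = character(), intensity_lo = numeric(),
                                  intensity_hi = numeric(), ratio = numeric())
    data.table::setattr(out, "n_possible", 0L)
    return(out)
  }
  intensity <- mod_count <- NULL
  w <- data.table::dcast(sel, cleavage + ion_type + loss ~ mod_count,
                         value.var = "intensity", fun.aggregate = sum,
                         fill = NA_real_)
  lo <- as.character(m); hi <- as.character(m + 1L)
  if (!lo %in% names(w)) w[[lo]] <- NA_real_
  if (!hi %in% names(w)) w[[hi]] <- NA_real_
  n_possible <- nrow(w)
  w <- w[!is.na(w[[lo]]) & !is.na(w[[hi]]), ]
  out <- data.table::data.table(
    cleavage = w$cleavage, ion_type = w$ion_type, loss = w$loss,
    intensity_lo = w[[lo]], intensity_hi = w[[hi]],
    ratio = w[[hi]] / w[[lo]])
  data.table::setattr(out, "n_possible", n_possible)
  out[]
}

#' Median ratio and SEM of a stretch's fragment pairs
#'
#' @param pairs data.table from [collect_pairs()].
#' @param min_pairs Reliability floor (default 3); below it the stretch is
#'   flagged unreliable and should not enter the abundance system unless
#'   forced.
#' @return List of class `stretch_ratios` with `median_ratio`, `sem`
#'   (SD of pair ratios / sqrt(n)), `n_pairs`, `n_possible`, `reliable` and
#'   the pair table.
#' @export
stretch_ratio <- function(pairs, min_pairs = 3L) {
  n <- nrow(pairs)
  med <- if (n) stats::median(pairs$ratio) else NA_real_
  sem <- if (n >= 2L) stats::sd(pairs$ratio) / sqrt(n) else
    if (n == 1L) 0 else NA_real_
  structure(
    list(median_ratio = med, sem = sem, n_pairs = n,
         n_possible = attr(pairs, "n_possible") %||% n,
         reliable = n >= min_pairs, pairs = pairs),
    class = "stretch_ratios"
  )
}

#' Compare two stretches' pair-ratio samples
#'
#' Two-sample equal-variance two-sided Student's t-test on the pair ratios.
#' A significant difference (p < 0.05) indicates that the boundary site
#' between the two stretches is modified in some positional isomer. With
#' zero variance in both samples, p is 1 for equal means and 0 otherwise.
#'
#' @param a,b `stretch_ratios` objects (or pair tables), each with >= 2
#'   pairs.
#' @return p-value.
#' @export
compare_stretches <- function(a, b) {
  ra <- if (inherits(a, "stretch_ratios")) a$pairs$ratio else a$ratio
  rb <- if (inherits(b, "stretch_ratios")) b$pairs$ratio else b$ratio
  stopifnot(length(ra) >= 2L, length(rb) >= 2L)
  if (stats::sd(ra) == 0 && stats::sd(rb) == 0)
    return(if (isTRUE(all.equal(mean(ra), mean(rb)))) 1 else 0)
  stats::t.test(ra, rb, var.equal = TRUE)$p.value
}

#' Occupancy status of a site from a PTM ladder
#'
#' Looks at the fragments flanking the site's cleavage boundary (bounded by
#' the neighbouring candidate sites, if given). Full occupancy shows as a
#' clean ladder step: the pre-boundary level disappears entirely past the
#' site. Partial occupancy shows both levels co-occurring past the site; no
#' step at all means the site is unmodified.
#'
#' @param ladder An N-terminal `ptm_ladder`.
#' @param site Residue index of the candidate site.
#' @param min_evidence Minimum fragments required on each flank (default 3).
#' @param flank_left,flank_right Optional flank bounds (cleavage indices);
#'   default: the whole side up to the ladder edge.
#' @return One of `"full"`, `"partial"`, `"unmodified"`, `"undetermined"`.
#' @export
detect_occupancy <- function(ladder, site, min_evidence = 3L,
                             flank_left = NULL, flank_right = NULL) {
  stopifnot(ladder$terminus == "N")
  fr <- ladder$fragments
  lo_from <- flank_left %||% 1L
  hi_to <- flank_right %||% (ladder$L - 1L)
  left <- fr[fr$cleavage >= lo_from & fr$cleavage <= site - 1L, ]
  right <- fr[fr$cleavage >= site & fr$cleavage <= hi_to, ]
  if (nrow(left) < min_evidence || nrow(right) < min_evidence)
    return("undetermined")
  # levels supported by at least min_evidence fragments on a flank
  present <- function(x) {
    tab <- table(x$mod_count)
    as.integer(names(tab)[tab >= min_evidence])
  }
  pl <- present(left); pr <- present(right)
  if (!length(pl) || !length(pr)) return("undetermined")
  base <- min(pl)
  if (setequal(pl, pr)) return("unmodified")
  if (!(base %in% pr) && (base + 1L) %in% pr) return("full")
  if (base %in% pr && (base + 1L) %in% pr) return("partial")
  "undetermined"
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0
.nnls <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(abs(crossprod(A, b)), 1)
  if (is.null(max_iter)) max_iter <- 3L * n
  x <- rep(0, n)
  P <- rep(FALSE, n)
  w <- as.numeric(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!P) && any(w[!P] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      Ap <- A[, P, drop = FALSE]
      s <- rep(0, n)
      s[P] <- as.numeric(MASS::ginv(Ap) %*% b)
      if (all(s[P] > tol)) break
      neg <- P & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      if (!is.finite(alpha) || alpha <= 0) { s[s < 0] <- 0; break }
      x <- x + alpha * (s - x)
      P <- P & x > tol
      x[!P] <- 0
    }
    x <- s
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

#' Build the isomer abundance system from ladders
#'
#' The union of candidate sites partitions each ladder into regions of
#' constant expected modification count per candidate. For every region and
#' terminus, per-level intensity fractions are derived from the fragment
#' pairs (chained adjacent-level median ratios, normalized to sum 1 within
#' the region); each candidate isomer implies exactly one level per region,
#' giving a 0/1 design matrix whose columns sum to 1 within a region. Rows
#' from unreliable regions (< `min_pairs` pairs at some needed level
#' boundary) are dropped.
#'
#' @param candidates List of sorted site vectors (from
#'   [enumerate_isomers()] after occupancy/exclusivity pruning).
#' @param ladders List with `N` and `C` `ptm_ladder` objects.
#' @param min_pairs Reliability floor per level boundary (default 3).
#' @return Object of class `isomer_system`: list with design matrix `A`
#'   (rows = (terminus, region, level) fractions, columns = candidates),
#'   observation vector `b`, `sem` per row, `weights`, `rows` (bookkeeping
#'   data.frame) and `candidates`.
#' @export
build_system <- function(candidates, ladders, min_pairs = 3L) {
  stopifnot(length(candidates) >= 1L)
  site_union <- sort(unique(unlist(candidates)))
  n_cand <- length(candidates)
  rows <- list(); Arows <- list(); b <- c(); sem <- c()
  for (term in c("N", "C")) {
    ladder <- ladders[[term]]
    st <- stretches_for(site_union, term, ladder$L)
    for (r in seq_len(nrow(st))) {
      if (st$n_cleavages[r] <= 0L) next
      # level implied by each candidate over this region
      lev <- vapply(candidates, function(s) {
        if (term == "N") sum(s <= st$from[r])
        else sum(s > ladder$L - st$from[r])
      }, integer(1))
      ulev <- sort(unique(lev))
      if (length(ulev) < 2L) next  # region separates nothing
      # chained adjacent-level median ratios across the observed levels
      wgt <- rep(NA_real_, length(ulev)); wgt[1] <- 1
      sems <- rep(0, length(ulev))
      ok <- TRUE
      for (i in seq_len(length(ulev) - 1L)) {
        if (ulev[i + 1L] != ulev[i] + 1L) { ok <- FALSE; break }
        pr <- collect_pairs(ladder, st$from[r], st$to[r], ulev[i])
        sr <- stretch_ratio(pr, min_pairs = min_pairs)
        if (!sr$reliable || !is.finite(sr$median_ratio)) { ok <- FALSE; break }
        wgt[i + 1L] <- wgt[i] * sr$median_ratio
        sems[i + 1L] <- sr$sem
      }
      if (!ok) next
      frac <- wgt / sum(wgt)
      # delta-method SEM of the fractions from the ratio SEMs (two-level
      # case: d(r/(1+r))/dr = 1/(1+r)^2); chained levels use the same local
      # scale as an approximation; the base level inherits its neighbour's
      # sem (the ratio uncertainty moves both ends of the pair)
      sem_frac <- sems / (1 + wgt)^2
      if (length(sem_frac) > 1L) sem_frac[1] <- sem_frac[2]
      for (i in seq_along(ulev)) {
        Arows[[length(Arows) + 1L]] <- as.numeric(lev == ulev[i])
        b <- c(b, frac[i])
        sem <- c(sem, sem_frac[i])
        rows[[length(rows) + 1L]] <- data.frame(
          terminus = term, from = st$from[r], to = st$to[r],
          level = ulev[i], fraction = frac[i], sem = sem_frac[i])
      }
    }
  }
  if (!length(Arows)) stop("no usable stretches: cannot build a system")
  A <- do.call(rbind, Arows)
  colnames(A) <- vapply(candidates, paste, "", collapse = "+")
  weights <- 1 / pmax(sem, 1e-6)^2
  structure(
    list(A = A, b = b, sem = sem, weights = weights,
         rows = do.call(rbind, rows), candidates = candidates),
    class = "isomer_system"
  )
}

#' Group candidates the data cannot distinguish
#'
#' Candidates with identical design-matrix columns are observationally
#' equivalent and are merged into groups for reporting (rank-deficient
#' systems).
#'
#' @param system An `isomer_system`.
#' @return List with `groups` (list of member index vectors), `labels`
#'   (text: shared sites plus alternatives) and `rank_deficient` (logical).
#' @export
group_isomers <- function(system) {
  A <- system$A
  if (ncol(A) == 0L)
    return(list(groups = list(), labels = character(),
                rank_deficient = FALSE))
  key <- apply(A, 2, paste, collapse = "|")
  groups <- split(seq_len(ncol(A)), factor(key, levels = unique(key)))
  names(groups) <- NULL
  labels <- vapply(groups, function(idx) {
    members <- system$candidates[idx]
    shared <- Reduce(intersect, members)
    alt <- lapply(members, setdiff, y = shared)
    if (length(idx) == 1L) paste(members[[1]], collapse = "+")
    else paste0(paste(shared, collapse = "+"), " + one of {",
                paste(vapply(alt, paste, "", collapse = "+"), collapse = "; "),
                "}")
  }, character(1))
  list(groups = groups, labels = labels,
       rank_deficient = length(groups) < ncol(A))
}

#' Solve for isomer abundances
#'
#' Weighted non-negative least squares on the simplex: candidates with
#' identical design columns are first merged into groups
#' ([group_isomers()]); the grouped system is solved by active-set NNLS with
#' a sum-to-one row appended, and the solution renormalized to sum exactly
#' 1. Per-abundance SEMs come from first-order propagation of the stretch
#' SEMs through the positive-support weighted least-squares solution.
#'
#' @param system An `isomer_system`.
#' @return Object of class `quant_result`: data.frame `abundances` with
#'   `label`, `abundance`, `sem`, `n_members`, `flag` (SEM > 10% is flagged
#'   "treat with caution"); plus `residual_norm`, `grouping` and
#'   `rank_deficient`.
#' @export
solve_abundances <- function(system) {
  grouping <- group_isomers(system)
  idx1 <- vapply(grouping$groups, `[`, 0L, 1L)
  Ag <- system$A[, idx1, drop = FALSE]
  if (all(rowSums(system$A) == 0)) stop("infeasible system: all-zero rows")
  w <- sqrt(system$weights)
  w_sum <- mean(w)
  Aw <- rbind(Ag * w, rep(w_sum, ncol(Ag)))
  bw <- c(system$b * w, w_sum)
  alpha <- .nnls(Aw, bw)
  if (sum(alpha) <= 0) stop("degenerate solution: all abundances zero")
  alpha <- alpha / sum(alpha)
  resid <- sqrt(sum((system$A[, idx1, drop = FALSE] %*% alpha - system$b)^2))
  # first-order SEM propagation on the positive support
  sem_a <- rep(NA_real_, length(alpha))
  P <- alpha > 1e-12
  if (any(P)) {
    Ap <- Aw[, P, drop = FALSE]
    J <- tryCatch(solve(crossprod(Ap), t(Ap)), error = function(e)
      MASS::ginv(Ap))
    # rows of Aw carry weights w; observation sd in the weighted system is
    # w * sem, so Var = J diag((w*sem)^2) J'
    s2 <- c(system$sem * w, 0)^2
    V <- J %*% (s2 * t(J))
    sem_a[P] <- sqrt(pmax(diag(V), 0))
  }
  df <- data.frame(
    label = grouping$labels,
    abundance = alpha,
    sem = sem_a,
    n_members = lengths(grouping$groups),
    flag = ifelse(!is.na(sem_a) & sem_a > 0.10, "treat with caution", ""),
    stringsAsFactors = FALSE
  )
  structure(
    list(abundances = df, residual_norm = resid, grouping = grouping,
         rank_deficient = grouping$rank_deficient),
    class = "quant_result"
  )
}

#' Prune candidates contradicted by missing fragment classes
#'
#' An isomer is excluded when it requires a (region, level) fragment class
#' with zero accepted fragments while that region holds at least
#' `min_evidence` fragments at the other implied levels: the isomer's
#' signature fragments should have been seen. This operationalizes
#' mutual-exclusivity deductions of the form "only fragments with m
#' modifications are detected past this site".
#'
#' @inheritParams build_system
#' @param min_evidence Minimum fragments at competing levels before absence
#'   counts as evidence (default 3).
#' @return The surviving subset of `candidates`.
#' @export
prune_candidates <- function(candidates, ladders, min_evidence = 3L) {
  site_union <- sort(unique(unlist(candidates)))
  alive <- rep(TRUE, length(candidates))
  for (term in c("N", "C")) {
    ladder <- ladders[[term]]
    fr <- ladder$fragments
    st <- stretches_for(site_union, term, ladder$L)
    for (r in seq_len(nrow(st))) {
      if (st$n_cleavages[r] <= 0L) next
      lev <- vapply(candidates, function(s) {
        if (term == "N") sum(s <= st$from[r])
        else sum(s > ladder$L - st$from[r])
      }, integer(1))
      in_span <- fr$cleavage >= st$from[r] & fr$cleavage <= st$to[r]
      n_at <- vapply(sort(unique(lev)), function(l)
        sum(in_span & fr$mod_count == l), integer(1))
      names(n_at) <- sort(unique(lev))
      for (k in which(alive)) {
        mine <- n_at[[as.character(lev[k])]]
        others <- sum(n_at) - mine
        if (mine == 0L && others >= min_evidence) alive[k] <- FALSE
      }
    }
  }
  candidates[alive]
}

#' One-call quantification from ladders
#'
#' Convenience wrapper: optionally prunes candidates contradicted by absent
#' fragment classes, then builds and solves the abundance system. A single
#' surviving candidate short-circuits to abundance 1.
#'
#' @inheritParams build_system
#' @param prune Apply [prune_candidates()] first (default TRUE).
#' @param min_evidence Passed to [prune_candidates()].
#' @return A `quant_result`.
#' @export
quantify_isomers <- function(candidates, ladders, min_pairs = 3L,
                             prune = TRUE, min_evidence = 3L) {
  if (prune)
    candidates <- prune_candidates(candidates, ladders,
                                   min_evidence = min_evidence)
  if (length(candidates) == 0L)
    stop("no candidate isomer is consistent with the ladders")
  if (length(candidates) == 1L) {
    df <- data.frame(label = paste(candidates[[1]], collapse = "+"),
                     abundance = 1, sem = 0, n_members = 1L, flag = "",
                     stringsAsFactors = FALSE)
    return(structure(list(abundances = df, residual_norm = 0,
                          grouping = list(groups = list(1L),
                                          labels = df$label,
                                          rank_deficient = FALSE),
                          rank_deficient = FALSE),
                     class = "quant_result"))
  }
  solve_abundances(build_system(candidates, ladders, min_pairs = min_pairs))
}
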