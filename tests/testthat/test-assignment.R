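test_that("match_fragments equals the brute-force nearest-match oracle", {
  set.seed(11)
  tab0 <- generate_fragments(UBI, max_mods = 1, mod = HEAVY_VAL)
  for (rep in 1:25) {
    n_pk <- sample(20:200, 1)
    idx <- sample(nrow(tab0), sample(20:200, 1), replace = TRUE)
    jitter_ppm <- rnorm(length(idx), 0, 6)
    sp <- decon_spectrum(
      unique(tab0$mass[idx] * (1 + jitter_ppm * 1e-6)),
      runif(length(unique(tab0$mass[idx] * (1 + jitter_ppm * 1e-6))),
            1, 1e4))
    tol <- runif(1, 2, 12)
    got <- match_fragments(sp, tab0, tol)
    want <- match_oracle(sp, tab0, tol)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_equal(got$theo_mass, tab0$mass[want$row])
      expect_equal(got$obs_mass, sp$mass[want$peak])
      expect_equal(got$ppm_error, want$ppm, tolerance = 1e-9)
    }
  }
})

test_that("matching edge cases: exact hit, out-of-tolerance, nearer peak", {
  tab <- generate_fragments("GASGASK", "c", "none")
  m <- tab$mass[3]
  sp <- decon_spectrum(m, 100)
  got <- match_fragments(sp, tab, 5)
  expect_equal(got$ppm_error[got$theo_mass == m], 0)
  sp10 <- decon_spectrum(m * (1 + 10e-6), 100)
  expect_equal(nrow(match_fragments(sp10, tab[3, ], 5)), 0L)
  sp2 <- decon_spectrum(c(m * (1 - 4e-6), m * (1 + 2e-6)), c(900, 100))
  got2 <- match_fragments(sp2, tab[3, ], 5)
  expect_equal(got2$ppm_error, 2, tolerance = 1e-6)
})

test_that("calibration recovers shift and tolerance from known error models", {
  mk <- function(ppm) data.table::data.table(ppm_error = ppm)
  expect_equal(calibrate(mk(rep(4, 30)))$shift_ppm, 4)
  m <- calibrate(mk(rep(c(-1, 0, 1), 10)))
  expect_equal(m$shift_ppm, 0)
  expect_equal(m$tolerance_ppm, 3 * sd(rep(c(-1, 0, 1), 10)),
               tolerance = 1e-9)
  set.seed(42)
  m2 <- calibrate(mk(rnorm(500, 2.5, 0.8)))
  expect_lt(abs(m2$shift_ppm - 2.5), 0.15)
  expect_lt(abs(m2$tolerance_ppm - 2.4) / 2.4, 0.15)
  expect_error(calibrate(mk(rnorm(10))), "widen")
})

test_that("calibration application zeroes the median residual (idempotence)", {
  sim <- ubi_sim(list(c(17L, 70L)), 1, seed = 21L, ppm_bias = 2.5)
  tab <- generate_fragments(UBI, max_mods = 2, mod = HEAVY_VAL)
  broad <- data.table::rbindlist(
    lapply(sim$spectra, match_fragments, table = tab, tolerance_ppm = 10))
  model <- calibrate(broad)
  expect_lt(abs(model$shift_ppm - 2.5), 0.15)
  cal <- lapply(sim$spectra, apply_calibration, model = model)
  recal <- data.table::rbindlist(
    lapply(cal, match_fragments, table = tab,
           tolerance_ppm = model$tolerance_ppm))
  expect_lt(abs(median(recal$ppm_error)), 0.05)
  expect_lt(abs(calibrate(recal)$shift_ppm), 0.05)
})

test_that("sequence_coverage counts cleavage sites from both termini", {
  L <- 10L
  a <- data.table::data.table(terminus = "N", cleavage = 3L)
  expect_equal(sequence_coverage(a, L), 1 / 9)
  # C-terminal fragment at cleavage j covers position L - j
  b <- data.table::data.table(terminus = "C", cleavage = 7L)
  expect_equal(sequence_coverage(b, L), 1 / 9)
  expect_equal(sequence_coverage(rbind(a, b), L), 1 / 9) # same position
  full <- data.table::data.table(terminus = "N", cleavage = 1:9)
  expect_equal(sequence_coverage(full, L), 1)
  expect_equal(sequence_coverage(full[0, ], L), 0)
})

test_that("majority voting implements the k-of-n set algebra", {
  key <- function(cl) data.table::data.table(
    terminus = "N", ion_type = "c", loss = "none", cleavage = cl,
    mod_count = 0L, theo_mass = 100 + cl, obs_mass = 100 + cl,
    intensity = 10 * cl, ppm_error = 0, replicate_id = "x")
  r1 <- key(c(1L, 2L, 3L)); r1$replicate_id <- "r1"
  r2 <- key(c(2L, 3L));     r2$replicate_id <- "r2"
  r3 <- key(c(3L));         r3$replicate_id <- "r3"
  reps <- list(r1, r2, r3)
  v1 <- majority_vote(reps, 1)
  v2 <- majority_vote(reps, 2)
  v3 <- majority_vote(reps, 3)
  expect_setequal(v1$cleavage, 1:3)          # union
  expect_setequal(v2$cleavage, 2:3)          # 2-of-3
  expect_setequal(v3$cleavage, 3L)           # intersection
  # monotone shrinkage
  expect_true(all(v3$cleavage %in% v2$cleavage))
  expect_true(all(v2$cleavage %in% v1$cleavage))
  # median intensity across supporting replicates
  expect_equal(v2[v2$cleavage == 3L, ]$intensity, 30)
})

test_that("2-of-3 voting strips decoy-only hits, keeps replicated truth", {
  sim <- ubi_sim(list(c(17L, 70L)), 1, seed = 31L, dropout = 0.3,
                 decoy_per_100da = 20)
  tab <- generate_fragments(UBI, max_mods = 2, mod = HEAVY_VAL)
  per_rep <- lapply(sim$spectra, match_fragments, table = tab,
                    tolerance_ppm = 10)
  keyof <- function(a) paste(a$terminus, a$ion_type, a$loss, a$cleavage,
                             a$mod_count)
  # label each assignment by whether its peak came from the decoy registry
  is_decoy <- lapply(seq_along(per_rep), function(r) {
    dm <- sim$truth$decoys[[r]]$mass
    vapply(per_rep[[r]]$obs_mass,
           function(m) any(abs(dm - m) < 1e-9), TRUE)
  })
  tagged <- data.table::data.table(
    frag_key = unlist(lapply(per_rep, keyof)), decoy = unlist(is_decoy),
    rep = rep(seq_along(per_rep), vapply(per_rep, nrow, 0L)))
  decoy_only <- tagged[, .(all_decoy = all(decoy), n = length(unique(rep))),
                       by = "frag_key"]
  voted <- majority_vote(per_rep, 2)
  voted_keys <- keyof(voted)
  bad <- decoy_only$frag_key[decoy_only$all_decoy]
  expect_gt(length(bad), 5)  # the fixture must actually plant decoy hits
  expect_gte(mean(!bad %in% voted_keys), 0.9)
  true_2plus <- decoy_only$frag_key[!decoy_only$all_decoy &
                                    decoy_only$n >= 2]
  expect_true(all(true_2plus %in% voted_keys))
})

test_that("frequent-flyer selection recovers the generating ion types", {
  # ETD-type spectrum with decoys: exactly the 5 ETD types are flagged
  sim <- ubi_sim(list(c(17L, 70L)), 1, seed = 41L, decoy_per_100da = 1)
  sel <- select_ion_types(sim$spectra, UBI, max_mods = 2, mod = HEAVY_VAL,
                          seed = 7)
  expect_setequal(sel$selected, etd_ion_types())
  expect_false(sel$fallback)

  # b/y-only spectrum
  simby <- ubi_sim(list(c(17L, 70L)), 1, seed = 43L,
                   ion_type = c("b", "y"),
                   efficiencies = c(b = 1, y = 0.8), decoy_per_100da = 1)
  selby <- select_ion_types(simby$spectra, UBI, max_mods = 2,
                            mod = HEAVY_VAL, seed = 7)
  expect_setequal(selby$selected, c("b", "y"))

  # pure noise: nothing significant, fallback fires
  set.seed(17)
  noise <- spectrum_set(lapply(1:3, function(r)
    decon_spectrum(runif(150, 150, 8000), runif(150, 10, 1e4),
                   replicate_id = paste0("rep", r))))
  expect_warning(seln <- select_ion_types(noise, UBI, seed = 7),
                 "falling back")
  expect_true(seln$fallback)
})

test_that("FDR is near zero on clean data and decreases with stringency", {
  sim <- ubi_sim_clean(list(c(17L, 70L)), 1, seed = 51L)
  fdr0 <- estimate_fdr(sim$spectra, UBI, tolerance_ppm = 3,
                       n_scrambles = 20, seed = 3, max_mods = 2,
                       mod = HEAVY_VAL)
  # compositional isobars (GG = N, G+A = Q, shared terminal residues) let
  # scrambles explain a few cleavages even in noise-free spectra; the decoy
  # background stays far below the target coverage
  expect_lt(fdr0$fdr, 0.05)
  expect_gt(fdr0$target_coverage, 0.99)

  simn <- ubi_sim(list(c(17L, 70L)), 1, seed = 53L, decoy_per_100da = 8)
  f10 <- estimate_fdr(simn$spectra, UBI, tolerance_ppm = 10,
                      n_scrambles = 25, seed = 3, max_mods = 2,
                      mod = HEAVY_VAL)
  f3 <- estimate_fdr(simn$spectra, UBI, tolerance_ppm = 3,
                     n_scrambles = 25, seed = 3, max_mods = 2,
                     mod = HEAVY_VAL)
  expect_lte(f3$fdr, f10$fdr)
  f8types <- estimate_fdr(simn$spectra, UBI, ion_type = ion_types()$ion_type,
                          tolerance_ppm = 10, n_scrambles = 25, seed = 3,
                          max_mods = 2, mod = HEAVY_VAL)
  expect_lte(f10$fdr, f8types$fdr)
})
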