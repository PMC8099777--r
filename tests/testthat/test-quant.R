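test_that("collect_pairs forms within-kind pairs and counts slots", {
  acc <- data.table::data.table(
    terminus = "N",
    ion_type = c("c", "c", "c-1", "c-1", "c", "c"),
    loss = "none",
    cleavage = c(4L, 4L, 4L, 4L, 5L, 6L),
    mod_count = c(0L, 1L, 0L, 1L, 0L, 1L),
    intensity = c(10, 30, 8, 24, 5, 9))
  lad <- build_ladder(acc, "N", 10, 1)
  pr <- collect_pairs(lad, 1, 9, 0)
  # cleavage 4 pairs for both kinds; cleavages 5 and 6 have only one level
  expect_equal(nrow(pr), 2L)
  expect_equal(attr(pr, "n_possible"), 4L)
  expect_equal(sort(pr$ratio), c(3, 3))
  # never cross ion types
  expect_true(all(pr$intensity_hi / pr$intensity_lo == pr$ratio))
  # one level entirely absent -> zero pairs
  lo_only <- acc[acc$mod_count == 0L, ]
  pr0 <- collect_pairs(build_ladder(lo_only, "N", 10, 1), 1, 9, 0)
  expect_equal(nrow(pr0), 0L)
})

test_that("stretch_ratio median and SEM are exact arithmetic", {
  mk <- function(r) {
    dt <- data.table::data.table(
      cleavage = seq_along(r), ion_type = "c", loss = "none",
      intensity_lo = 1, intensity_hi = r, ratio = r)
    data.table::setattr(dt, "n_possible", length(r))
    dt
  }
  s1 <- stretch_ratio(mk(rep(1, 5)))
  expect_equal(s1$median_ratio, 1)
  expect_equal(s1$sem, 0)
  r <- c(0.9, 1.0, 1.1, 1.0, 1.0)
  s2 <- stretch_ratio(mk(r))
  expect_equal(s2$median_ratio, 1)
  expect_equal(s2$sem, sd(r) / sqrt(5))
  expect_true(s2$reliable)
  s3 <- stretch_ratio(mk(c(2, 2)))
  expect_false(s3$reliable)
})

test_that("compare_stretches is a symmetric equal-variance t-test", {
  mk <- function(r) stretch_ratio(data.table::data.table(
    cleavage = seq_along(r), ion_type = "c", loss = "none",
    intensity_lo = 1, intensity_hi = r, ratio = r), min_pairs = 2)
  a <- mk(c(1.02, 0.98, 1.01, 0.99))
  b <- mk(c(3.01, 2.99, 3.02, 2.98))
  p <- compare_stretches(a, b)
  expect_lt(p, 1e-6)
  expect_equal(p, compare_stretches(b, a))
  expect_equal(compare_stretches(a, a), 1)
  # matches stats::t.test directly
  expect_equal(p, t.test(a$pairs$ratio, b$pairs$ratio,
                         var.equal = TRUE)$p.value)
  # degenerate zero-variance samples
  expect_equal(compare_stretches(mk(c(1, 1)), mk(c(1, 1))), 1)
  expect_equal(compare_stretches(mk(c(1, 1)), mk(c(2, 2))), 0)
})

test_that("boundary t-test finds the middle isomer iff it is present", {
  # A(17) + B(26) + C(70) at 1:1:1 -> stretches 17-25 and 26-69 differ
  sim3 <- ubi_sim(list(17L, 26L, 70L), c(1, 1, 1), seed = 61L)
  sl3 <- sim_ladders(sim3)
  a <- stretch_ratio(collect_pairs(sl3$ladders$N, 17, 25, 0))
  b <- stretch_ratio(collect_pairs(sl3$ladders$N, 26, 69, 0))
  expect_lt(compare_stretches(a, b), 0.05)
  # A(17) + C(70) only -> V26 not modified, stretches agree
  sim2 <- ubi_sim(list(17L, 70L), c(1, 1), seed = 63L)
  sl2 <- sim_ladders(sim2)
  a2 <- stretch_ratio(collect_pairs(sl2$ladders$N, 17, 25, 0))
  b2 <- stretch_ratio(collect_pairs(sl2$ladders$N, 26, 69, 0))
  expect_gt(compare_stretches(a2, b2), 0.05)
})

test_that("occupancy detection distinguishes full, partial, unmodified", {
  single <- sim_ladders(ubi_sim_clean(list(c(17L, 70L)), 1))
  expect_identical(detect_occupancy(single$ladders$N, 17), "full")
  expect_identical(detect_occupancy(single$ladders$N, 70, flank_left = 18L),
                   "full")
  mix <- sim_ladders(ubi_sim_clean(list(17L, 70L), c(1, 1)))
  expect_identical(detect_occupancy(mix$ladders$N, 17), "partial")
  expect_identical(detect_occupancy(mix$ladders$N, 26,
                                    flank_left = 18L, flank_right = 69L),
                   "unmodified")
  empty <- data.table::data.table(
    terminus = character(), ion_type = character(), loss = character(),
    cleavage = integer(), mod_count = integer(), intensity = numeric())
  expect_identical(detect_occupancy(build_ladder(empty, "N", 76, 1), 17),
                   "undetermined")
})

test_that("noise-free abundances are recovered to 1e-9 (exact oracle)", {
  truth <- c(1, 4, 8) / 13
  sim <- ubi_sim_clean(list(17L, 26L, 70L), truth)
  sl <- sim_ladders(sim)
  sys <- build_system(list(17L, 26L, 70L), sl$ladders)
  res <- solve_abundances(sys)
  expect_false(res$rank_deficient)
  got <- res$abundances$abundance[match(c("17", "26", "70"),
                                        res$abundances$label)]
  expect_equal(got, truth, tolerance = 1e-9)
  expect_equal(sum(res$abundances$abundance), 1, tolerance = 1e-12)
  expect_lt(res$residual_norm, 1e-9)
  # independent exact linear-algebra oracle on the same system
  oracle <- qr.solve(sys$A, sys$b)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
})

test_that("pruning drops contradicted candidates; single survivor is exact", {
  sim1 <- ubi_sim_clean(list(c(17L, 70L)), 1)
  sl1 <- sim_ladders(sim1)
  # {26,70} needs unmodified fragments over 17..25, but every fragment
  # there carries one modification: pruned
  kept <- prune_candidates(list(c(17L, 70L), c(26L, 70L)), sl1$ladders)
  expect_identical(kept, list(c(17L, 70L)))
  res1 <- quantify_isomers(list(c(17L, 70L), c(26L, 70L)), sl1$ladders)
  expect_identical(res1$abundances$label, "17+70")
  expect_equal(res1$abundances$abundance, 1)
})

test_that("grouped sums equal summed ground truth on rank-deficient input", {
  # truth: isomers at 17 (0.4) and 26 (0.6); phantom candidate at 70.
  # Without pruning, {26} and {70} are observationally identical on the
  # usable regions and must be grouped; the group sum is the truth sum.
  sim <- ubi_sim_clean(list(17L, 26L), c(0.4, 0.6))
  sl <- sim_ladders(sim)
  sys <- build_system(list(17L, 26L, 70L), sl$ladders)
  grp <- group_isomers(sys)
  expect_true(grp$rank_deficient)
  res <- solve_abundances(sys)
  lab <- res$abundances$label
  expect_equal(res$abundances$abundance[match("17", lab)], 0.4,
               tolerance = 1e-9)
  gi <- grep("one of", lab)
  expect_length(gi, 1L)
  expect_equal(res$abundances$abundance[gi], 0.6, tolerance = 1e-9)
  expect_equal(res$abundances$n_members[gi], 2L)
  expect_equal(sum(res$abundances$abundance), 1, tolerance = 1e-12)
  # with pruning, the phantom is removed and the system becomes full rank
  res2 <- quantify_isomers(list(17L, 26L, 70L), sl$ladders)
  expect_false(res2$rank_deficient)
  lab2 <- res2$abundances$label
  expect_setequal(lab2, c("17", "26"))
  expect_equal(res2$abundances$abundance[match("26", lab2)], 0.6,
               tolerance = 1e-9)
})

test_that("recovery across mixing ratios 1..32 within 10% relative", {
  for (r in c(2, 16)) {  # light sweep here; full sweep in acceptance tests
    sim <- ubi_sim(list(17L, 70L), c(r, 1), seed = 70L + r)
    sl <- sim_ladders(sim)
    res <- quantify_isomers(list(17L, 70L), sl$ladders)
    ab <- res$abundances
    got <- ab$abundance[match("17", ab$label)] /
      ab$abundance[match("70", ab$label)]
    expect_lt(abs(got - r) / r, 0.10)
  }
})

test_that("flags: SEM above 10% is marked treat-with-caution", {
  sys <- structure(list(
    A = rbind(c(1, 0), c(0, 1)), b = c(0.5, 0.5), sem = c(0.2, 0.2),
    weights = 1 / c(0.2, 0.2)^2, rows = NULL,
    candidates = list(1L, 2L)), class = "isomer_system")
  res <- solve_abundances(sys)
  expect_true(all(res$abundances$flag == "treat with caution"))
})
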