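test_that("incidence frequency statistics match hand counts", {
  f <- incidence_freq(m1_incidence())
  expect_equal(f$T, 4L)
  expect_equal(f$S_obs, 5L)
  expect_equal(f$U, 9L)
  expect_equal(f$Q1, 3L)
  expect_equal(f$Q2, 1L)

  single <- matrix(1L, nrow = 3, ncol = 1,
                   dimnames = list(paste0("sp", 1:3), "t1"))
  fs <- incidence_freq(single)
  expect_equal(c(fs$T, fs$Q1, fs$Q2, fs$U), c(1L, 3L, 0L, 3L))

  ubiq <- matrix(1L, nrow = 1, ncol = 6,
                 dimnames = list("sp1", paste0("t", 1:6)))
  fu <- incidence_freq(ubiq)
  expect_equal(c(fu$Q1, fu$Q2, fu$U), c(0L, 0L, 6L))

  expect_error(incidence_freq(rbind(c(0, 0), c(1, 0))), "all-zero")
})

test_that("Chao2 evaluates both branches and respects its lower-bound role", {
  expect_equal(chao2(m1_incidence()), 8.375)  # 5 + (3/4) * 9/2

  # bias-corrected branch: S_obs 4, Q1 = 2, Q2 = 0, T = 5 -> 4.8
  f0 <- structure(list(T = 5L, S_obs = 4L, Y = c(3L, 3L, 1L, 1L), U = 8L,
                       Q1 = 2L, Q2 = 0L), class = "incidence_freq")
  expect_equal(chao2(f0), 4.8)

  # no uniques -> estimate equals observed richness exactly
  f1 <- incidence_freq(rbind(sp1 = c(1, 1), sp2 = c(1, 1)))
  expect_equal(chao2(f1), 2)
  expect_equal(sample_completeness(f1), 1)

  expect_equal(sample_completeness(m1_incidence()), 5 / 8.375)

  set.seed(21)
  for (i in 1:25) {
    m <- random_incidence(sample(3:12, 1), sample(2:8, 1))
    est <- chao2(m)
    expect_gte(est, nrow(m))
    expect_gt(sample_completeness(m), 0)
    expect_lte(sample_completeness(m), 1)
  }
})

test_that("coverage estimators match closed forms on the worked fixture", {
  m <- m1_incidence()
  expect_equal(coverage_observed(m), 1 - (3 / 9) * (9 / 11))  # 8/11
  expect_equal(coverage_rarefied(m, 3), 2 / 3)
  expect_equal(coverage_extrapolated(m, 1), 1 - (1 / 3) * (9 / 11)^2)
  expect_equal(coverage_extrapolated(m, 0), coverage_observed(m))

  # no uniques -> full coverage at any effort
  full <- rbind(sp1 = c(1, 1, 1), sp2 = c(1, 1, 1))
  expect_equal(coverage_observed(full), 1)
  expect_equal(coverage_rarefied(full, 2), 1)
  expect_equal(coverage_extrapolated(full, 5), 1)
})

test_that("rarefied coverage at t = T-1 equals 1 - Q1/U on random fixtures", {
  set.seed(31)
  for (i in 1:50) {
    m <- random_incidence(sample(3:15, 1), sample(3:9, 1))
    f <- incidence_freq(m)
    expect_equal(coverage_rarefied(f, f$T - 1), 1 - f$Q1 / f$U)
  }
})

test_that("stitched coverage profiles are nondecreasing and within [0, 1]", {
  set.seed(41)
  for (i in 1:100) {
    m <- random_incidence(sample(3:15, 1), sample(2:9, 1))
    prof <- coverage_profile(m)
    expect_true(all(prof$coverage >= 0 & prof$coverage <= 1))
    expect_true(all(diff(prof$coverage) >= -1e-12))
    expect_equal(prof$method[prof$t == ncol(m)], "observed")
  }
})

test_that("rarefied richness equals exhaustive subset enumeration", {
  m <- m1_incidence()
  expect_equal(rarefied_richness(m, 2), 20 / 6)  # mean over all 6 trap pairs
  expect_equal(rarefied_richness(m, 4), 5)
  expect_equal(rarefied_richness(m, 1), 9 / 4)   # U / T

  set.seed(51)
  for (i in 1:20) {
    m <- random_incidence(sample(3:10, 1), sample(2:8, 1))
    for (t in seq_len(ncol(m))) {
      expect_equal(rarefied_richness(m, t), enumerated_rarefied_richness(m, t))
    }
  }
})

test_that("rarefied richness agrees with vegan's exact accumulation curve", {
  skip_if_not_installed("vegan")
  set.seed(61)
  m <- random_incidence(12, 7)
  acc <- vegan::specaccum(t(m), method = "exact")
  ours <- vapply(seq_len(ncol(m)), function(t) rarefied_richness(m, t),
                 numeric(1))
  expect_equal(ours, as.numeric(acc$richness), tolerance = 1e-10)
  # and Chao2 against vegan::specpool (small-sample corrected form)
  expect_equal(chao2(m), vegan::specpool(t(m))$chao, tolerance = 1e-10)
})

test_that("pairwise replacement handles identity, disjointness and overlap", {
  expect_equal(pairwise_replacement(c("a", "b"), c("a", "b"))$beta_repl, 0)
  expect_equal(pairwise_replacement(c("a", "b"), c("c", "d"))$beta_repl, 1)
  pr <- pairwise_replacement(c("sp1", "sp2", "sp3"), c("sp1", "sp2", "sp4"))
  expect_equal(c(pr$a, pr$b, pr$c, pr$beta_repl), c(2, 1, 1, 0.5))
  # nested sets: no replacement
  expect_equal(pairwise_replacement(c("a", "b", "c"), c("a"))$beta_repl, 0)
  # symmetry
  set.seed(71)
  for (i in 1:20) {
    A <- sample(letters, sample(1:10, 1))
    B <- sample(letters, sample(1:10, 1))
    expect_equal(pairwise_replacement(A, B)$beta_repl,
                 pairwise_replacement(B, A)$beta_repl)
  }
  expect_error(pairwise_replacement(character(0), character(0)), "empty")
})

test_that("mean turnover matches brute force over all trap pairs", {
  # M1 pairs evaluate to 0.5, 0.5, 0, 0.5, 0, 0 -> mean 0.25
  tv <- mean_turnover(m1_incidence())
  expect_equal(tv$mean_turnover, 0.25)
  expect_equal(tv$n_pairs, 6L)

  ident <- matrix(1L, 3, 4, dimnames = list(paste0("sp", 1:3), paste0("t", 1:4)))
  expect_equal(mean_turnover(ident)$mean_turnover, 0)

  # empty-vs-empty pairs are skipped, not counted as zero
  m <- cbind(m1_incidence(), t5 = 0L, t6 = 0L)
  tv2 <- mean_turnover(m)
  expect_equal(tv2$n_empty_pairs, 1L)
  expect_equal(tv2$n_pairs, 14L)
})

test_that("diversity table assembles the per-landscape battery", {
  st <- generate_study(synthetic_config(n_landscapes = 3), seed = 99)
  dt <- diversity_table(st$traps, st$captures)
  expect_equal(nrow(dt), 3L)
  expect_true(all(c("chao2", "completeness", "coverage_observed",
                    "coverage_t4", "coverage_t32", "mean_turnover")
                  %in% names(dt)))
  expect_true(all(dt$chao2 >= dt$S_obs))
  expect_true(all(dt$coverage_t4 <= dt$coverage_t32))
})
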