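test_that("removal order follows the urbanization policy with stable ties", {
  traps <- data.frame(trap_id = c("a", "b", "c"), landscape_id = "L1",
                      tree_cover_250m = 50, barrier_free_angle = 50,
                      urbanization_index = c(10, 50, 30))
  expect_equal(removal_order(traps, "most_urbanized_first"), c("b", "c", "a"))
  expect_equal(removal_order(traps, "least_urbanized_first"), c("a", "c", "b"))
  # distinct indices: the two orders are exact reverses
  expect_equal(removal_order(traps, "least_urbanized_first"),
               rev(removal_order(traps, "most_urbanized_first")))
  # equal indices: lexicographic trap_id tie-break
  traps$urbanization_index <- 42
  expect_equal(removal_order(traps, "most_urbanized_first"), c("a", "b", "c"))
  traps$urbanization_index <- NULL
  expect_error(removal_order(traps, "most_urbanized_first"), "urbanization_index")
})

test_that("species loss along a removal sequence matches hand unions", {
  m <- m1_incidence()
  sl <- species_loss(m, c("t3", "t4", "t1", "t2"))  # retain last k
  expect_equal(sl$loss_pct[sl$k == 2], 20)  # {t1,t2} holds 4 of 5 species
  expect_equal(sl$loss_pct[sl$k == 4], 0)
  sl2 <- species_loss(m, c("t1", "t2", "t3", "t4"))
  expect_equal(sl2$loss_pct[sl2$k == 1], 80)  # {t4} holds only sp1
  expect_error(species_loss(m, c("t1", "t2")), "permutation")
  # loss curves are monotone: fewer retained traps never lose fewer species
  set.seed(81)
  for (i in 1:20) {
    mm <- random_incidence(sample(3:10, 1), sample(2:7, 1))
    seqn <- sample(colnames(mm))
    expect_true(all(diff(species_loss(mm, seqn)$loss_pct) <= 1e-12))
  }
})

test_that("random mean loss is seed-reproducible and matches the analytic identity", {
  m <- m1_incidence()
  expect_identical(random_mean_loss(m, 5, seed = 3),
                   random_mean_loss(m, 5, seed = 3))
  expect_error(random_mean_loss(m, 5), "seed")

  # Monte-Carlo convergence to 100 * (1 - S(k)/S_obs)
  set.seed(91)
  for (fixture in list(m1_incidence(), random_incidence(10, 8),
                       random_incidence(6, 5))) {
    rml <- random_mean_loss(fixture, 1000, seed = 17)
    for (k in seq_len(ncol(fixture))) {
      expected <- 100 * (1 - rarefied_richness(fixture, k) / nrow(fixture))
      expect_lt(abs(rml$mean_loss_pct[rml$k == k] - expected), 1.5)
    }
  }
})

test_that("scenario table covers every landscape-policy-k cell and flags k > T", {
  st <- generate_study(synthetic_config(n_landscapes = 3,
                                        traps_per_landscape = 6), seed = 23)
  tab <- scenario_table(st$traps, st$captures, k_values = c(4, 2, 8),
                        n_randomizations = 10, seed = 5)
  expect_equal(nrow(tab), 3 * 3 * 3)
  expect_true(all(!tab$feasible[tab$k == 8]))
  expect_true(all(is.na(tab$mean_loss_pct[tab$k == 8])))
  ok <- tab[tab$feasible, ]
  expect_true(all(ok$mean_loss_pct >= 0 & ok$mean_loss_pct <= 100))
  # reproducible under the same seed
  tab2 <- scenario_table(st$traps, st$captures, k_values = c(4, 2, 8),
                         n_randomizations = 10, seed = 5)
  expect_identical(tab, tab2)
})

test_that("scenario comparison detects no difference between identical policies", {
  tab <- expand.grid(landscape_id = paste0("L", 1:5),
                     policy = c("most_urbanized_first", "least_urbanized_first"),
                     k = 4, stringsAsFactors = FALSE)
  tab$mean_loss_pct <- rep(c(10, 20, 30, 25, 15), 2)
  tab$feasible <- TRUE
  cmp <- compare_scenarios(tab, 4)
  expect_equal(cmp$chisq, 0, tolerance = 1e-10)
  expect_equal(cmp$p_value, 1, tolerance = 1e-10)
  expect_equal(cmp$contrasts$mean_diff, 0)
  expect_equal(cmp$contrasts$p, 1)
})

test_that("scenario comparison is invariant to landscape relabeling", {
  set.seed(101)
  tab <- expand.grid(landscape_id = paste0("L", 1:6),
                     policy = c("random", "most_urbanized_first",
                                "least_urbanized_first"),
                     k = 8, stringsAsFactors = FALSE)
  tab$mean_loss_pct <- runif(nrow(tab), 10, 40)
  tab$feasible <- TRUE
  cmp1 <- compare_scenarios(tab, 8)
  relabeled <- tab
  relabeled$landscape_id <- chartr("123456", "641325", relabeled$landscape_id)
  cmp2 <- compare_scenarios(relabeled, 8)
  expect_equal(cmp1$chisq, cmp2$chisq)
  expect_equal(cmp1$contrasts$p, cmp2$contrasts$p)
})

test_that("ordered policies bracket random removal on a graded community", {
  gf <- graded_fixture(6)
  most <- species_loss(gf$incidence,
                       removal_order(gf$traps, "most_urbanized_first"))
  least <- species_loss(gf$incidence,
                        removal_order(gf$traps, "least_urbanized_first"))
  rnd <- random_mean_loss(gf$incidence, 500, seed = 13)
  for (k in 1:5) {
    expect_lte(most$loss_pct[most$k == k], rnd$mean_loss_pct[rnd$k == k] + 1e-9)
    expect_lte(rnd$mean_loss_pct[rnd$k == k], least$loss_pct[least$k == k] + 1e-9)
  }
})

test_that("landscape regression recovers exact and degenerate fits", {
  # an exact fit triggers summary.lm's perfect-fit warning by design
  r <- suppressWarnings(landscape_regression(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)

  rc <- landscape_regression(c(10, 40, 70, 90), rep(0.9, 4))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  expect_equal(rc$p_value, 1)

  expect_error(landscape_regression(rep(5, 4), 1:4), "zero variance")
  expect_error(landscape_regression(1:2, 1:2), "at least 3")
})

test_that("regression p-values are calibrated under the null", {
  set.seed(111)
  n_rep <- 1000
  rejections <- 0
  for (i in seq_len(n_rep)) {
    x <- runif(13, 10, 80)
    y <- rnorm(13)
    if (landscape_regression(x, y)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.015)
})
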