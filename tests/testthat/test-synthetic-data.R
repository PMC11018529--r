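test_that("simulation config validates proportions and design", {
  expect_error(simulation_config(category_proportions = c(balanced = 0.5)),
               "sum")
  expect_error(simulation_config(category_proportions =
                                   c(balanced = 1.2, A_dominant = -0.2)),
               "nonnegative")
  expect_error(simulation_config(category_proportions = c(weird = 1)),
               "unknown category")
  expect_error(simulation_config(ratio_class = "pair",
                                 subgenome_labels = c("A", "B", "C")),
               "2 subgenome labels")
  expect_error(simulation_config(dominance_fold = 1), "dominance_fold")
  expect_error(simulation_config(nb_dispersion = -1), "nb_dispersion")
})

test_that("identical config and seed give bit-identical simulations", {
  cfg <- simulation_config(n_groups = 30, seed = 42)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$lengths, s2$lengths)
  s3 <- simulate_expression(simulation_config(n_groups = 30, seed = 43))
  expect_false(identical(s1$counts$values, s3$counts$values))

  m1 <- simulate_modules(n_genes = 60, n_modules = 2, seed = 7)
  m2 <- simulate_modules(n_genes = 60, n_modules = 2, seed = 7)
  expect_identical(m1$expr$values, m2$expr$values)
  expect_identical(m1$truth, m2$truth)

  r1 <- simulate_retention(500, c(A = 0.2, B = 0.4), seed = 9)
  r2 <- simulate_retention(500, c(A = 0.2, B = 0.4), seed = 9)
  expect_identical(as.data.frame(r1$track), as.data.frame(r2$track))
})

test_that("simulators leave the caller's RNG stream untouched", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_expression(simulation_config(n_groups = 5)))
  invisible(simulate_retention(100, c(A = 0.5), seed = 1))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("balanced zero-noise groups have equal expected member counts", {
  cfg <- simulation_config(n_groups = 20, nb_dispersion = 0,
                           library_size_cv = 0,
                           category_proportions = c(balanced = 1), seed = 5)
  sim <- simulate_expression(cfg)
  # members of a group occupy consecutive rows (A, B, C)
  for (j in seq_len(ncol(sim$mu))) {
    mu <- matrix(sim$mu[, j], nrow = 3)
    expect_equal(mu[1, ], mu[2, ])
    expect_equal(mu[1, ], mu[3, ])
  }
})

test_that("planted dominant and suppressed folds shape the expected means", {
  cfg <- simulation_config(
    n_groups = 40, nb_dispersion = 0, library_size_cv = 0,
    dominance_fold = 8,
    category_proportions = c(A_dominant = 0.5, B_suppressed = 0.5), seed = 8)
  sim <- simulate_expression(cfg)
  by_group <- split(seq_len(nrow(sim$mu)), sub("_[ABC]$", "", rownames(sim$mu)))
  truth1 <- sim$truth[sim$truth$tissue == sim$truth$tissue[1], ]
  for (g in names(by_group)) {
    rows <- unname(sim$mu[by_group[[g]], 1])  # A, B, C order within group
    cat <- truth1$category[truth1$group_id == g]
    if (cat == "A_dominant") {
      expect_equal(rows[1] / rows[2], 8, tolerance = 1e-9)
      expect_equal(rows[2], rows[3])
    } else {
      expect_equal(rows[1] / rows[2], 8, tolerance = 1e-9) # B = A/8
      expect_equal(rows[1], rows[3])
    }
  }
})

test_that("empirical mean counts converge to configured expectations", {
  # many replicates of one tissue: mean count within 3 standard errors of mu
  cfg <- simulation_config(n_groups = 10, tissues = "leaf",
                           replicates_per_tissue = 300,
                           nb_dispersion = 0.05, library_size_cv = 0,
                           category_proportions = c(balanced = 1), seed = 31)
  sim <- simulate_expression(cfg)
  mu <- sim$mu[, 1]
  emp <- rowMeans(sim$counts$values)
  se <- sqrt((mu + 0.05 * mu^2) / 300)
  expect_true(all(abs(emp - mu) <= 3 * se + 1e-9))
})

test_that("category recovery does not improve with higher dispersion", {
  acc <- vapply(c(0.01, 0.3, 2), function(phi) {
    cfg <- simulation_config(n_groups = 200, nb_dispersion = phi, seed = 77)
    sim <- simulate_expression(cfg)
    avg <- average_replicates(counts_to_tpm(sim$counts, sim$lengths))
    res <- categorize_species(avg, sim$map)
    mrg <- merge(res$triads[res$triads$expressed,
                            c("group_id", "tissue", "category")],
                 sim$truth, by = c("group_id", "tissue"))
    mean(mrg$category.x == mrg$category.y)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.02))   # monotone non-increasing up to noise
  expect_gt(acc[1], acc[3])
})

test_that("noiseless modules are perfectly correlated latent factors", {
  ms <- simulate_modules(n_genes = 90, n_modules = 3, noise_sd = 0,
                         min_module_size = 30, seed = 3)
  for (mod in 1:3) {
    idx <- ms$truth$gene_id[ms$truth$module == mod]
    cc <- cor(t(ms$expr$values[idx, ]))
    expect_equal(abs(unname(cc)), matrix(1, length(idx), length(idx)),
                 tolerance = 1e-12)
  }
  expect_error(simulate_modules(n_genes = 50, n_modules = 2,
                                min_module_size = 30), "cannot host")
})

test_that("hub labels follow the hub subgenome weights", {
  ms <- simulate_modules(n_genes = 300, n_modules = 2,
                         hub_subgenome_weights = c(A = 0.05, B = 0.05, C = 0.9),
                         seed = 11)
  hubs <- ms$truth[ms$truth$hub, ]
  expect_gte(mean(hubs$subgenome == "C"), 0.8)
  expect_gte(nrow(hubs), 0.08 * 300)    # ~10% planted hubs per module
})

test_that("retention simulation matches its loss probabilities", {
  r0 <- simulate_retention(200, c(A = 0, B = 0), seed = 1)
  expect_true(all(r0$track$present == 1))
  r1 <- simulate_retention(200, c(A = 1), seed = 1)
  expect_true(all(r1$track$present == 0))
  expect_error(simulate_retention(10, c(A = 1.5)), "\\[0, 1\\]")
  # binomial expectation: retention 0.70 +- 3 sigma at n = 10000
  rb <- simulate_retention(10000, c(B = 0.3), seed = 4)
  p <- mean(rb$track$present[rb$track$subgenome == "B"])
  expect_lt(abs(p - 0.7), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("planted shift profiles carry their exact truth", {
  s <- simulate_shift_profiles(n_pairs = 50, shifted_fraction = 0.4, seed = 2)
  expect_equal(sum(s$truth$shifted), 20)
  expect_equal(nrow(s$profiles), 100)
  s2 <- simulate_shift_profiles(n_pairs = 50, shifted_fraction = 0.4, seed = 2)
  expect_identical(s$profiles, s2$profiles)
})
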