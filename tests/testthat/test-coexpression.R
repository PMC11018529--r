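test_that("bicor matches a naive scalar-loop implementation", {
  set.seed(91)
  for (i in 1:50) {
    x <- rnorm(50); y <- rnorm(50)
    expect_equal(bicor(x, y, max_p_outliers = 0.5), naive_bicor(x, y),
                 tolerance = 1e-12)
  }
  # self-correlation and affine invariance
  x <- rnorm(30)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(3 * x + 2, x), bicor(x, x), tolerance = 1e-12)
  # close to Pearson on clean Gaussian data
  set.seed(92)
  d <- sapply(1:20, function(i) {
    x <- rnorm(100); y <- x + rnorm(100)
    abs(bicor(x, y) - cor(x, y))
  })
  expect_lt(max(d), 0.1)
  expect_error(bicor(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(suppressWarnings(
    bicor(rep(1, 10), 1:10, fallback_pearson = TRUE))))
})

test_that("the outlier cap tames a single wild observation", {
  set.seed(93)
  x <- rnorm(50); y <- x + rnorm(50, sd = 0.1)
  x2 <- x; x2[1] <- 100               # one gross outlier
  expect_gt(bicor(x2, y), 0.9)        # robust: outlier down-weighted
  expect_lt(cor(x2, y), 0.5)          # Pearson is destroyed
})

test_that("bicor matrix agrees with pairwise bicor and Pearson mode", {
  set.seed(94)
  x <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(letters[1:8], NULL))
  bm <- bicor_matrix(x)
  expect_equal(bm, t(bm))
  for (i in 1:7) expect_equal(bm[i, i + 1],
                              bicor(x[i, ], x[i + 1, ]), tolerance = 1e-12)
  expect_equal(bicor_matrix(x, robust = FALSE), cor(t(x)), tolerance = 1e-12)
})

test_that("signed-hybrid adjacency zeroes negatives and powers positives", {
  cc <- matrix(c(1, 0.5, -0.9, 0.5, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  a1 <- adjacency_signed_hybrid(cc, 1)
  expect_equal(a1[1, 3], 0)
  expect_equal(a1[1, 2], 0.5)
  expect_equal(adjacency_signed_hybrid(cc, 2)[2, 3], 0.81)
  expect_equal(unname(diag(a1)), rep(0, 3))
  expect_error(adjacency_signed_hybrid(cc, 0), "positive")
})

test_that("TOM matches a brute-force triple loop on random instances", {
  set.seed(95)
  for (i in 1:3) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tom_unsigned(a)
    expect_lt(max(abs(tom - naive_tom(a))), 1e-10)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1))
  }
  # two genes adjacent only to each other with weight 1
  a2 <- matrix(0, 4, 4); a2[1, 2] <- a2[2, 1] <- 1
  expect_equal(tom_unsigned(a2)[1, 2], 1)
  # empty network: off-diagonal TOM is zero
  z <- tom_unsigned(matrix(0, 5, 5))
  expect_true(all(z[upper.tri(z)] == 0))
})

test_that("soft-power choice equals an exhaustive independent scan", {
  set.seed(96)
  ms <- simulate_modules(n_genes = 120, n_modules = 4, noise_sd = 0.6,
                         min_module_size = 30, seed = 41)
  cc <- bicor_matrix(ms$expr$values)
  target <- 0.8
  p <- suppressWarnings(pick_soft_power(cc, powers = 1:12, target_fit = target))
  # oracle: rebuild the rule from scratch over all powers
  fits <- vapply(1:12, function(pw) {
    a <- ifelse(cc > 0, cc^pw, 0); diag(a) <- 0
    scale_free_fit(rowSums(a))$fit
  }, numeric(1))
  qualifying <- which(!is.na(fits) & fits >= target)
  expected <- if (length(qualifying)) qualifying[1] else which.max(fits)
  expect_equal(as.integer(p), as.integer(expected))
  expect_equal(attr(p, "fit_table")$fit, fits, tolerance = 1e-12)
  # determinism
  p2 <- suppressWarnings(pick_soft_power(cc, powers = 1:12, target_fit = target))
  expect_identical(as.integer(p), as.integer(p2))
})

test_that("module detection recovers planted modules and merge is idempotent", {
  ms <- simulate_modules(n_genes = 120, n_modules = 2, noise_sd = 0,
                         min_module_size = 30, seed = 42)
  cc <- bicor_matrix(ms$expr$values, robust = FALSE)
  tom <- tom_unsigned(adjacency_signed_hybrid(cc, 6))
  lab <- detect_modules(tom, expr = ms$expr$values)
  expect_equal(rand_index(unname(lab), ms$truth$module), 1)
  # min_size larger than any cluster -> all unassigned, with warning
  expect_warning(lab0 <- detect_modules(tom, min_size = 200), "unassigned")
  expect_true(all(lab0 == 0))
  # rerunning the merge step changes nothing (fixed point)
  lab2 <- detect_modules(tom, expr = ms$expr$values)
  expect_identical(lab, lab2)
})

test_that("eigengenes behave like oriented unit-variance first PCs", {
  set.seed(97)
  prof <- rnorm(20)
  x <- matrix(rep(prof, each = 6), 6, 20,
              dimnames = list(letters[1:6], NULL))   # identical genes
  me <- module_eigengene(x, letters[1:6])
  expect_equal(abs(cor(me, prof)), 1, tolerance = 1e-12)
  expect_equal(sd(me), 1, tolerance = 1e-12)
  expect_gte(mean(cor(me, t(x))), 0)
  # PC1 explained variance matches a direct eigendecomposition oracle
  y <- matrix(rnorm(10 * 25), 10, 25, dimnames = list(letters[1:10], NULL))
  me2 <- module_eigengene(y, letters[1:10])
  z <- t(scale(t(y)))
  ev <- eigen(crossprod(t(z)) )$values     # gene-space Gram eigenvalues
  sv <- svd(t(z))$d^2
  expect_equal(sort(sv, decreasing = TRUE)[1], sort(ev, decreasing = TRUE)[1],
               tolerance = 1e-8)
  expect_equal(abs(cor(me2, svd(t(z))$u[, 1])), 1, tolerance = 1e-8)
  # single-gene module: the standardized profile itself
  me1 <- module_eigengene(y, "a")
  expect_equal(unname(me1), unname(as.vector(scale(y["a", ]))),
               tolerance = 1e-12)
})

test_that("KME hubs are detected and planted hubs recovered", {
  ms <- simulate_modules(n_genes = 150, n_modules = 3, noise_sd = 0.05,
                         min_module_size = 30, seed = 43)
  cc <- bicor_matrix(ms$expr$values, robust = FALSE)
  tom <- tom_unsigned(adjacency_signed_hybrid(cc, 6))
  lab <- detect_modules(tom, expr = ms$expr$values)
  hubs <- hub_genes(ms$expr$values, lab, kme_threshold = 0.9)
  planted <- ms$truth$gene_id[ms$truth$hub]
  sens <- mean(planted %in% hubs$gene_id[hubs$hub])
  expect_gte(sens, 0.9)
  # an identical-profile member has KME 1; threshold 1 admits (almost) none
  hubs1 <- hub_genes(ms$expr$values, lab, kme_threshold = 1)
  expect_equal(sum(hubs1$hub), 0)
})

test_that("neighbor composition ranks weights with deterministic ties", {
  w <- matrix(0.5, 5, 5)
  diag(w) <- 1
  dimnames(w) <- list(letters[1:5], letters[1:5])
  subg <- setNames(c("A", "A", "B", "B", "B"), letters[1:5])
  comp <- neighbor_composition(w, subg, k = 2)
  # all weights tied: neighbors are the 2 alphabetically first others
  expect_equal(comp$intra[comp$gene_id == "a"], 1)  # neighbors b, c -> one A
  expect_equal(comp$inter[comp$gene_id == "e"], 2)  # neighbors a, b -> both A
  expect_true(all(comp$intra + comp$inter == comp$k_used))
  # single-subgenome network: intra = k everywhere
  subg1 <- setNames(rep("A", 5), letters[1:5])
  comp1 <- neighbor_composition(w, subg1, k = 3)
  expect_true(all(comp1$intra == 3))
  # k larger than network uses all others with a note
  expect_message(compk <- neighbor_composition(w, subg, k = 100), "reduced")
  expect_true(all(compk$k_used == 4))
})

test_that("hub-weighted subgenomes are overrepresented among neighbors", {
  ms <- simulate_modules(n_genes = 150, n_modules = 3,
                         hub_subgenome_weights = c(A = 0.1, B = 0.1, C = 0.8),
                         noise_sd = 0.3, min_module_size = 30, seed = 44)
  subg <- setNames(ms$truth$subgenome, ms$truth$gene_id)
  cc <- bicor_matrix(ms$expr$values, robust = FALSE)
  tom <- tom_unsigned(adjacency_signed_hybrid(cc, 6))
  comp <- neighbor_composition(tom, subg, k = 10)
  # planted hubs sit at module cores and are 80% C-labelled, so C genes
  # should be overrepresented among top neighbors vs the label base rate
  c_rate <- mean(subg == "C")
  c_among_neighbors <- sum(comp$n_C) / sum(comp$k_used)
  expect_gt(c_among_neighbors, c_rate)
  expect_true(all(comp$intra + comp$inter == comp$k_used))
  # the full pipeline runs end to end and keeps its invariants
  net <- suppressWarnings(build_network(ms$expr, subg, power = 6,
                                        k_neighbors = 30))
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  expect_equal(net$tom, t(net$tom))
  expect_true(all(abs(apply(net$eigengenes, 2, sd) - 1) < 1e-8))
})
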