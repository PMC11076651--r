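test_that("position binarization thresholds at 0.5 with an argmax guard", {
  expect_equal(binarize_position(c(0.9, 0.1, 0.6)), c(1L, 0L, 1L))
  expect_equal(binarize_position(rep(0.2, 4)), c(1L, 0L, 0L, 0L))
  expect_equal(binarize_position(c(0.2, 0.3, 0.25)), c(0L, 1L, 0L))
  expect_equal(binarize_position(c(0.2, 0.3), threshold = 0), c(1L, 1L))
})

test_that("fitness is the CV misclassification MSE and is deterministic", {
  d <- separable_xy(n = 15)
  feats <- cbind(d$x, matrix(rnorm(30 * 3), 30, 3))
  spec <- classifier_spec("CENTROID")
  # mask covering the separating features -> 0
  f0 <- evaluate_fitness(c(1L, 1L, 0L, 0L, 0L), feats, d$y, spec, folds = 3)
  expect_equal(f0, 0)
  mask <- c(1L, 0L, 1L, 1L, 0L)
  f1 <- evaluate_fitness(mask, feats, d$y, spec, folds = 3, seed = 5)
  f2 <- evaluate_fitness(mask, feats, d$y, spec, folds = 3, seed = 5)
  expect_identical(f1, f2)
  expect_error(evaluate_fitness(c(1L, 0L), feats, d$y, spec), "mask length")
  expect_error(evaluate_fitness(rep(0L, 5), feats, d$y, spec), "at least one")
})

test_that("memoization never changes fitness values", {
  d <- separable_xy(n = 12)
  feats <- cbind(d$x, matrix(rnorm(24 * 4), 24, 4))
  spec <- classifier_spec("DECISION_TREE")
  cache <- new.env(parent = emptyenv())
  set.seed(1)
  masks <- replicate(10, binarize_position(runif(6)), simplify = FALSE)
  cached <- vapply(masks, evaluate_fitness, numeric(1), feats, d$y, spec,
                   folds = 3, seed = 2, cache = cache)
  again <- vapply(masks, evaluate_fitness, numeric(1), feats, d$y, spec,
                  folds = 3, seed = 2, cache = cache)
  uncached <- vapply(masks, evaluate_fitness, numeric(1), feats, d$y, spec,
                     folds = 3, seed = 2)
  expect_identical(cached, uncached)
  expect_identical(cached, again)
})

test_that("fitness of label-independent features matches the majority baseline", {
  # Monte-Carlo oracle: a majority-class predictor errs exactly on the
  # minority class, so the expected MSE is the minority proportion
  spec <- classifier_spec("MAJORITY")
  fits <- vapply(1:50, function(s) {
    set.seed(s)
    feats <- matrix(rnorm(40 * 5), 40, 5)
    y <- factor(rep(c("healthy", "malignant"), c(16, 24)),
                levels = c("healthy", "malignant"))
    evaluate_fitness(rep(1L, 5), feats, y, spec, folds = 4, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(fits) - 0.4), 0.05)
})

test_that("degenerate harmony rates reduce improvisation to memory recall", {
  # HMCR = 1, PAR = 0: every improvised coordinate must equal some memory
  # value; with a constant fitness the memory never changes
  seen <- new.env(parent = emptyenv())
  fn <- function(x) { seen$last <- x; 1 }
  cfg <- hs_config(shm = 4, hmcr = 1, par = 0, max_iter = 30)
  set.seed(99)
  hm0 <- matrix(runif(4 * 5), 4, 5)   # replay the initializer draw
  tr <- harmony_search(fn, 5, cfg, seed = 99)
  expect_true(all(vapply(seen$last, function(v)
    any(abs(hm0 - v) < 1e-12), logical(1))))
  expect_length(tr$best_fitness, 30)
})

test_that("optimizer traces are monotone, in bounds, and within budget", {
  rosen_like <- function(x) sum((x - 0.3)^2)
  runs <- list(
    hs = harmony_search(rosen_like, 5, hs_config(max_iter = 100), seed = 1),
    ff = firefly_search(rosen_like, 5, ff_config(population = 8,
                                                 max_iter = 40), seed = 1),
    eho = eho_search(rosen_like, 5, eho_config(population = 12, n_clans = 3,
                                               max_iter = 40), seed = 1))
  budgets <- c(hs = 10 + 100, ff = 8 * 41, eho = 12 * 41)
  for (nm in names(runs)) {
    tr <- runs[[nm]]
    expect_true(all(diff(tr$best_fitness) <= 1e-12), label = nm)
    expect_true(all(tr$best_position >= 0 & tr$best_position <= 1),
                label = nm)
    expect_lte(tr$evaluations, budgets[[nm]])
  }
})

test_that("attractiveness follows the inverse-exponential law", {
  expect_equal(firefly_attractiveness(0.8, 0.1, 0), 0.8)
  expect_equal(firefly_attractiveness(1, 0.1, 2), exp(-0.4))
  # distance of identical positions is zero -> full attractiveness
  x <- runif(6)
  expect_equal(sqrt(sum((x - x)^2)), 0)
})

test_that("optimizers find the sphere minimum from a handful of seeds", {
  for (s in 1:3) {
    expect_lt(tail(harmony_search(sphere_fn, 10, seed = s)$best_fitness, 1),
              1e-2)
    expect_lt(tail(firefly_search(sphere_fn, 10, seed = s)$best_fitness, 1),
              1e-2)
    expect_lt(tail(eho_search(sphere_fn, 10, seed = s)$best_fitness, 1),
              1e-2)
  }
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(hs_config(max_iter = 0), "max_iter")
  expect_error(hs_config(shm = 1), "memory size")
  expect_error(hs_config(hmcr = 1.2), "HMCR")
  expect_error(hs_config(bw = 0), "bandwidth")
  expect_error(ff_config(population = 1), "population")
  expect_error(ff_config(gamma = -1), "gamma")
  expect_error(eho_config(alpha = 2), "alpha")
  expect_error(eho_config(population = 10, n_clans = 3), "divisible")
})

test_that("wrapper selection recovers planted features and is reproducible", {
  set.seed(77)
  make_data <- function(seed) {
    set.seed(seed)
    n <- 40
    y <- factor(rep(c("healthy", "malignant"), each = n / 2),
                levels = c("healthy", "malignant"))
    feats <- matrix(rnorm(n * 20), n, 20)
    feats[y == "malignant", 1:2] <- feats[y == "malignant", 1:2] + 3
    list(feats = feats, y = y)
  }
  cfg <- eho_config(population = 9, n_clans = 3, max_iter = 8)
  hits <- vapply(1:10, function(s) {
    d <- make_data(s)
    sel <- select_features(d$feats, d$y, algorithm = "EHO",
                           clf_spec = classifier_spec("CENTROID"),
                           config = cfg, folds = 3, seed = s)
    all(c(1, 2) %in% sel$selected)
  }, logical(1))
  expect_gte(sum(hits), 8)

  d <- make_data(1)
  s1 <- select_features(d$feats, d$y, algorithm = "HS",
                        clf_spec = classifier_spec("CENTROID"),
                        config = hs_config(max_iter = 25), folds = 3, seed = 4)
  s2 <- select_features(d$feats, d$y, algorithm = "HS",
                        clf_spec = classifier_spec("CENTROID"),
                        config = hs_config(max_iter = 25), folds = 3, seed = 4)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$trace$best_fitness, s2$trace$best_fitness)

  # a budget of one iteration still yields a length-1 monotone trace
  s3 <- select_features(d$feats, d$y, algorithm = "FF",
                        clf_spec = classifier_spec("CENTROID"),
                        config = ff_config(population = 6, max_iter = 1),
                        folds = 3, seed = 1)
  expect_length(s3$trace$best_fitness, 1)
})
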