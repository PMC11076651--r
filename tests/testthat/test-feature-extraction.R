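test_that("single-component GMM reduces to the closed-form MLE", {
  set.seed(1)
  v <- rnorm(200, 3, 2)
  fit <- gmm_em_fit(v, n_components = 1)
  expect_equal(fit$pi, 1)
  expect_equal(fit$mu, mean(v), tolerance = 1e-9)
  expect_equal(fit$sigma2, mean((v - mean(v))^2), tolerance = 1e-9)
})

test_that("EM recovers well-separated component means", {
  set.seed(2)
  v <- c(rnorm(1000, 0), rnorm(1000, 10))
  fit <- gmm_em_fit(v, n_components = 2, seed = 7)
  # oracle: per-cluster sample means after thresholding at the midpoint
  oracle <- c(mean(v[v < 5]), mean(v[v >= 5]))
  expect_equal(sort(fit$mu), sort(oracle), tolerance = 0.1)
  expect_equal(sort(fit$mu), c(0, 10), tolerance = 0.1)
})

test_that("EM invariants hold across fits: responsibilities and likelihood", {
  set.seed(3)
  for (s in 1:5) {
    v <- rnorm(60) + sample(c(0, 4), 60, replace = TRUE)
    fit <- gmm_em_fit(v, n_components = 2, seed = s)
    expect_equal(rowSums(fit$responsibilities), rep(1, 60), tolerance = 1e-12)
    expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
    expect_true(all(diff(fit$log_likelihood_trace) > -1e-9))
  }
})

test_that("NLR recovers exponential-decay parameters on noise-free data", {
  n <- 0:49
  y <- 2 * exp(-0.5 * n) + 1
  fit <- nlr_fit(y)
  expect_equal(unname(fit$theta), c(2, 0.5, 1), tolerance = 1e-6)
  expect_lt(fit$residual_ss, 1e-18)
  expect_true(fit$converged)
  expect_false(fit$singular_jacobian)
  # recovery from perturbed inits within +/- 50% of truth
  for (f in c(0.5, 1.5)) {
    fit2 <- nlr_fit(y, init = c(2, 0.5, 1) * f)
    expect_equal(unname(fit2$theta), c(2, 0.5, 1), tolerance = 1e-4)
  }
})

test_that("constant signal leaves NLR parameters unidentifiable and flagged", {
  fit <- nlr_fit(rep(3, 30))
  expect_true(fit$singular_jacobian)
  expect_lt(fit$residual_ss, 1e-12)
})

test_that("k-means with K = 1 returns the grand mean and total scatter", {
  set.seed(4)
  pts <- matrix(rnorm(40), 20, 2)
  km <- kmeans_fit(pts, K = 1)
  expect_equal(km$centroids[1, ], colMeans(pts), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(km$inertia, sum(sweep(pts, 2, colMeans(pts))^2),
               tolerance = 1e-9)
})

test_that("k-means separates distant blobs and matches stats::kmeans inertia", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(60), ncol = 2),
               matrix(rnorm(60) + 100, ncol = 2))
  km <- kmeans_fit(pts, K = 2, seed = 1)
  truth <- rep(1:2, each = 30)
  purity <- max(mean(km$assignments == truth),
                mean(km$assignments == 3 - truth))
  expect_equal(purity, 1)
  ref <- kmeans(pts, centers = 2, nstart = 5)
  expect_equal(km$inertia, ref$tot.withinss, tolerance = 1e-6)
  expect_true(all(diff(km$inertia_trace) <= 1e-9))
})

test_that("PCA eigenpairs satisfy the spectral identities", {
  set.seed(6)
  x <- matrix(rnorm(80), 20, 4) %*% matrix(rnorm(16), 4, 4)
  p <- pca_decompose(x)
  cv <- cov(x) * (nrow(x) - 1) / nrow(x)
  expect_equal(sum(p$eigenvalues), sum(diag(cv)), tolerance = 1e-9)
  expect_equal(crossprod(p$eigenvectors), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in 1:4)
    expect_equal(cv %*% p$eigenvectors[, j],
                 p$eigenvalues[j] * p$eigenvectors[, j],
                 tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(p$eigenvectors %*% diag(p$eigenvalues) %*% t(p$eigenvectors),
               cv, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PCA eigenvalues agree with a characteristic-polynomial solve on 3x3", {
  set.seed(7)
  x <- matrix(rnorm(30), 10, 3)
  p <- pca_decompose(x)
  cv <- cov(x) * (nrow(x) - 1) / nrow(x)
  # brute-force oracle: roots of det(C - lambda I) via polyroot
  cpoly <- c(-det(cv),
             cv[1,1]*cv[2,2] - cv[1,2]^2 + cv[1,1]*cv[3,3] - cv[1,3]^2 +
               cv[2,2]*cv[3,3] - cv[2,3]^2,
             -sum(diag(cv)), 1)
  roots <- sort(Re(polyroot(cpoly)), decreasing = TRUE)
  expect_equal(p$eigenvalues, roots, tolerance = 1e-9)
})

test_that("rank-1 data concentrates the spectrum on one axis", {
  x <- cbind(1:50, 2 * (1:50))
  p <- pca_decompose(x)
  expect_gte(p$eigenvalues[1] / sum(p$eigenvalues), 0.99999)
})

test_that("PCA projection is an isometry at full rank and centers correctly", {
  set.seed(8)
  x <- matrix(rnorm(60), 20, 3)
  p <- pca_decompose(x)
  y <- pca_project(p, x, 3)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(norm(y, "F"), norm(xc, "F"), tolerance = 1e-9)
  expect_equal(pca_project(p, matrix(p$mean, 1), 3), matrix(0, 1, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  # 1-D construction oracle: data on a known direction in 3-D
  t <- rnorm(40)
  x1 <- outer(t, c(1, 2, 2) / 3)
  p1 <- pca_decompose(x1)
  y1 <- pca_project(p1, x1, 1)[, 1]
  ctr <- t - mean(t)
  expect_equal(abs(cor(y1, ctr)), 1, tolerance = 1e-9)
  expect_error(pca_project(p, x, 10), "maximum usable k")
})

test_that("wide-matrix PCA (SVD route) matches the covariance route", {
  set.seed(9)
  x <- matrix(rnorm(20 * 600), 20, 600)
  p <- pca_decompose(x)   # wide: SVD path
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  expect_equal(p$eigenvalues[1:19], (sv$d^2 / nrow(x))[1:19], tolerance = 1e-9)
})

test_that("DCT matches direct summation and is orthonormal", {
  # closed forms
  expect_equal(dct_1d(rep(2, 4))$coefficients, c(4, 0, 0, 0),
               tolerance = 1e-12)
  N <- 16
  xx <- cos(pi / N * ((0:(N - 1)) + 0.5) * 3)
  sp <- dct_1d(xx)$coefficients
  expect_equal(sp[4], sqrt(N / 2), tolerance = 1e-9)
  expect_lt(max(abs(sp[-4])), 1e-9)
  # direct-summation oracle and Parseval on random input
  set.seed(10)
  x <- rnorm(64)
  direct <- sapply(0:63, function(k) {
    a <- if (k == 0) 1 / sqrt(64) else sqrt(2 / 64)
    a * sum(x * cos(pi / 64 * ((0:63) + 0.5) * k))
  })
  expect_equal(dct_1d(x)$coefficients, direct, tolerance = 1e-9)
  expect_equal(sum(x^2), sum(direct^2), tolerance = 1e-9)
  expect_equal(idct_1d(dct_1d(x)), x, tolerance = 1e-9)
  expect_error(dct_1d(numeric(0)), "empty")
})

test_that("extraction produces the requested shape for every method", {
  ds <- tiny_dataset(n_per_class = 15, n_genes = 40, n_informative = 6)
  for (m in c("EM", "NLR", "KMEANS", "PCA", "DCT")) {
    ex <- extract_features(ds, method = m, k = 12, seed = 1)
    expect_equal(dim(ex$features), c(30, 12))
    expect_false(anyNA(ex$features))
  }
  expect_error(extract_features(ds, method = "DCT", k = 100), "k must not")
  expect_error(extract_features(ds, method = "FOO", k = 5))
})

test_that("full-scale DCT extraction keeps the cohort geometry and energy", {
  ds <- generate_dataset(synth_config(n_genes = 12600, n_informative = 600,
                                      seed = 1))
  ex <- extract_features(ds, method = "DCT", k = 6000, seed = 1)
  expect_equal(dim(ex$features), c(136, 6000))
  # k = n_genes conserves per-sample energy (orthonormal transform)
  ds2 <- tiny_dataset(n_per_class = 4, n_genes = 32)
  full <- extract_features(ds2, method = "DCT", k = 32, seed = 1)
  expect_equal(rowSums(full$features^2), rowSums(ds2$matrix^2),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("extractors are per-sample maps: permuting samples permutes rows", {
  ds <- tiny_dataset(n_per_class = 10, n_genes = 25, n_informative = 4)
  perm <- sample(nrow(ds$matrix))
  for (m in c("DCT", "PCA", "KMEANS")) {
    ex <- extractor_fit(ds$matrix, ds$labels, method = m, k = 10, seed = 1)
    a <- extractor_transform(ex, ds$matrix)
    b <- extractor_transform(ex, ds$matrix[perm, ])
    expect_equal(unname(b), unname(a[perm, ]), tolerance = 1e-12)
  }
})

test_that("k-means retention is enriched for a planted tight cluster", {
  # informative genes share the class-shift structure, so their profiles
  # form a coherent cluster; retention should beat the random baseline
  ds <- tiny_dataset(n_per_class = 25, n_genes = 60, n_informative = 12,
                     effect = 3, seed = 13)
  ex <- extractor_fit(ds$matrix, ds$labels, method = "KMEANS", k = 20,
                      params = list(kmeans_K = 4), seed = 1)
  hits <- length(intersect(ex$retained, ds$informative))
  # hypergeometric oracle: P(X >= hits) under random retention
  pval <- phyper(hits - 1, 12, 48, 20, lower.tail = FALSE)
  expect_lt(pval, 0.01)
})
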