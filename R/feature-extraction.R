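# Five per-sample dimensionality-reduction methods for expression data:
# Gaussian mixture (EM) responsibilities, exponential-decay nonlinear
# regression, k-means gene clustering, PCA, and the 1-D DCT. Each comes
# with a documented retention rule mapping n_genes -> k features.

GW_METHODS <- c("EM", "NLR", "KMEANS", "PCA", "DCT")

## ---------------------------------------------------------------- EM / GMM

#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Alternates the E-step (posterior responsibilities via Bayes' theorem)
#' and the M-step (mixing weights, means and variances as
#' responsibility-weighted moments) until the log-likelihood change drops
#' below `tol`. Variances are floored at `1e-6` times the data variance to
#' prevent component collapse; a triggered floor is flagged.
#'
#' @param values numeric vector, length >= `n_components`.
#' @param n_components number of mixture components.
#' @param tol absolute log-likelihood convergence threshold.
#' @param max_iter iteration cap.
#' @param seed RNG seed (initialization draws means from the data).
#' @return a `gw_gmm`: list with `n_components`, `pi`, `mu`, `sigma2`,
#'   `responsibilities` (n x J, rows sum to 1), `log_likelihood_trace`,
#'   `converged`, `floored`.
#' @export
gmm_em_fit <- function(values, n_components = 2L, tol = 1e-8,
                       max_iter = 200L, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < n_components) stop("need at least n_components data points", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  set.seed(seed)
  J <- as.integer(n_components)
  v <- stats::var(values) * (n - 1) / n
  floor2 <- max(1e-6 * v, .Machine$double.eps)
  # quantile-spread initialization: robust against the overlapping-means
  # local optimum that random starts fall into on well-separated data
  mu <- unname(stats::quantile(values, (seq_len(J) - 0.5) / J)) +
    1e-6 * max(1e-12, sqrt(v)) * rnorm(J)
  sigma2 <- rep(max(v, floor2), J)
  pi_j <- rep(1 / J, J)
  ll_trace <- numeric(0)
  floored <- FALSE
  w <- matrix(1 / J, n, J)
  for (it in seq_len(max_iter)) {
    # E-step: responsibilities w_ij = pi_j N(x_i; mu_j, sigma2_j) / sum_j
    dens <- vapply(seq_len(J), function(j)
      pi_j[j] * stats::dnorm(values, mu[j], sqrt(sigma2[j])), numeric(n))
    dens <- matrix(dens, n, J)
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    w <- dens / rs
    ll <- sum(log(rs))
    ll_trace <- c(ll_trace, ll)
    # M-step
    nk <- colSums(w)
    pi_j <- nk / n
    mu <- colSums(w * values) / nk
    sigma2 <- colSums(w * (outer(values, mu, "-"))^2) / nk
    if (any(sigma2 < floor2)) {
      sigma2 <- pmax(sigma2, floor2)
      floored <- TRUE
    }
    if (it > 1 && abs(ll_trace[it] - ll_trace[it - 1]) < tol) break
  }
  structure(list(n_components = J, pi = pi_j, mu = mu, sigma2 = sigma2,
                 responsibilities = w, log_likelihood_trace = ll_trace,
                 converged = length(ll_trace) < max_iter, floored = floored),
            class = "gw_gmm")
}

## ------------------------------------------------------ nonlinear regression

#' Fit the exponential-decay model m = theta1 * exp(-theta2 * n) + theta3
#'
#' Damped least squares (Levenberg-Marquardt, via \pkg{minpack.lm}) from
#' `init`, over the index n = 0..N-1. A near-singular Jacobian at the
#' solution (condition number > 1e8), as arises when the decay rate is 0
#' and theta1/theta3 are unidentifiable, is flagged.
#'
#' @param y numeric response vector, length >= 3.
#' @param init optional length-3 start; default `(range(y), 0.1, min(y))`.
#' @param max_iter iteration budget.
#' @return a `gw_nlr`: `theta` (named length-3), `residual_ss`,
#'   `converged`, `singular_jacobian`.
#' @export
nlr_fit <- function(y, init = NULL, max_iter = 200L) {
  y <- as.numeric(y)
  N <- length(y)
  if (N < 3) stop("need at least 3 points", call. = FALSE)
  n <- seq_len(N) - 1
  if (is.null(init)) init <- c(diff(range(y)), 0.1, min(y))
  resid_fn <- function(th) y - (th[1] * exp(-th[2] * n) + th[3])
  jac_fn <- function(th) {
    e <- exp(-th[2] * n)
    -cbind(e, -th[1] * n * e, 1)
  }
  # iteration-budget exhaustion is an expected outcome (converged = FALSE
  # below), not a user-facing warning
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = init, fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = 1e-15,
                         ptol = 1e-15, gtol = 0)))
  th <- unname(fit$par)
  J <- jac_fn(th)
  sv <- svd(J, nu = 0, nv = 0)$d
  singular <- sv[1] / max(sv[length(sv)], .Machine$double.xmin) > 1e8
  structure(list(theta = stats::setNames(th, c("theta1", "theta2", "theta3")),
                 residual_ss = sum(resid_fn(th)^2),
                 converged = fit$info %in% 1:4,
                 singular_jacobian = singular),
            class = "gw_nlr")
}

## -------------------------------------------------------------------- kmeans

#' Lloyd's k-means with deterministic seeding
#'
#' Seeded uniform sampling of K distinct points as initial centroids;
#' nearest-centroid assignment with ties broken toward the lowest cluster
#' index; an emptied cluster is re-seeded at the point farthest from its
#' centroid (recorded in `reseeded`). Iterates until assignments are
#' stable or `max_iter`.
#'
#' @param points numeric matrix, points in rows; `nrow(points) >= K`.
#' @param K number of clusters.
#' @param seed RNG seed for initialization.
#' @param max_iter iteration cap.
#' @return a `gw_kmeans`: `K`, `centroids` (K x d), `assignments`,
#'   `inertia`, `inertia_trace` (non-increasing), `reseeded`.
#' @export
kmeans_fit <- function(points, K, seed = 1L, max_iter = 100L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < K) stop("need at least K points", call. = FALSE)
  set.seed(seed)
  centroids <- points[sample.int(n, K), , drop = FALSE]
  assign_old <- rep(0L, n)
  inertia_trace <- numeric(0)
  reseeded <- 0L
  sq <- rowSums(points^2)
  for (it in seq_len(max_iter)) {
    # squared Euclidean distances n x K; max.col with ties.method "first"
    # on the negated matrix picks the lowest index among ties
    d2 <- outer(sq, rowSums(centroids^2), "+") - 2 * points %*% t(centroids)
    assignment <- max.col(-d2, ties.method = "first")
    inertia_trace <- c(inertia_trace,
                       sum(d2[cbind(seq_len(n), assignment)]))
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
    for (k in seq_len(K)) {
      members <- assignment == k
      if (!any(members)) {
        far <- which.max(d2[cbind(seq_len(n), assignment)])
        centroids[k, ] <- points[far, ]
        reseeded <- reseeded + 1L
      } else {
        centroids[k, ] <- colMeans(points[members, , drop = FALSE])
      }
    }
  }
  d2 <- outer(sq, rowSums(centroids^2), "+") - 2 * points %*% t(centroids)
  assignment <- max.col(-d2, ties.method = "first")
  structure(list(K = K, centroids = centroids, assignments = assignment,
                 inertia = sum(d2[cbind(seq_len(n), assignment)]),
                 inertia_trace = inertia_trace, reseeded = reseeded),
            class = "gw_kmeans")
}

## ----------------------------------------------------------------------- PCA

#' Eigendecomposition of the (1/n) covariance of centered data
#'
#' The covariance uses the maximum-likelihood 1/n scaling. For wide
#' matrices (more features than samples) the eigenpairs are obtained
#' through the thin SVD of the centered matrix, which yields the same
#' nonzero eigenvalues and eigenvectors without forming the full
#' covariance.
#'
#' @param x numeric matrix, samples in rows (>= 2 rows).
#' @return a `gw_pca`: `mean`, `eigenvalues` (descending), `eigenvectors`
#'   (columns, orthonormal), `constant` flag (all-zero spectrum).
#' @export
pca_decompose <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 2) stop("need at least 2 rows", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (m <= n || m <= 512) {
    cv <- crossprod(xc) / n
    eg <- eigen(cv, symmetric = TRUE)
    lambda <- eg$values
    vecs <- eg$vectors
  } else {
    sv <- svd(xc, nu = 0)
    lambda <- c(sv$d^2 / n, rep(0, 0))
    vecs <- sv$v
  }
  lambda[lambda < 0 & lambda > -1e-12] <- 0
  constant <- all(lambda < .Machine$double.eps * max(1, lambda[1]))
  if (constant) warning("constant matrix: all eigenvalues are zero")
  structure(list(mean = mu, eigenvalues = lambda, eigenvectors = vecs,
                 constant = constant),
            class = "gw_pca")
}

#' Project centered data onto the first k principal axes
#'
#' @param model a [pca_decompose()] fit.
#' @param x matrix with the model's feature dimension.
#' @param k number of components; must not exceed the available rank.
#' @return samples x k score matrix `Y = X_centered V[, 1:k]`.
#' @export
pca_project <- function(model, x, k) {
  stopifnot(inherits(model, "gw_pca"))
  x <- matrix(as.numeric(x), ncol = length(model$mean))
  kmax <- ncol(model$eigenvectors)
  if (k > kmax)
    stop("k exceeds available rank; maximum usable k is ", kmax, call. = FALSE)
  sweep(x, 2, model$mean) %*% model$eigenvectors[, seq_len(k), drop = FALSE]
}

## ----------------------------------------------------------------------- DCT

#' Orthonormal 1-D DCT-II
#'
#' `X(k) = a(k) sum_n x(n) cos(pi/N (n + 0.5) k)` with `a(0) = 1/sqrt(N)`
#' and `a(k>0) = sqrt(2/N)`, computed through a length-2N FFT of the
#' mirrored sequence so that long gene vectors transform in O(N log N).
#' The transform is orthonormal (Parseval: `sum x^2 = sum X^2`).
#'
#' @param x numeric vector, length >= 1.
#' @return a `gw_dct`: `coefficients` (length N), `n`.
#' @export
dct_1d <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  if (N == 0) stop("empty input", call. = FALSE)
  if (N == 1) return(structure(list(coefficients = x, n = 1L), class = "gw_dct"))
  y <- stats::fft(c(x, rev(x)))[seq_len(N)]
  k <- seq_len(N) - 1
  cc <- Re(exp(-1i * pi * k / (2 * N)) * y) / 2
  alpha <- c(1 / sqrt(N), rep(sqrt(2 / N), N - 1))
  structure(list(coefficients = alpha * cc, n = N), class = "gw_dct")
}

#' Inverse of [dct_1d()]
#'
#' @param spectrum a `gw_dct` or a plain coefficient vector.
#' @return the reconstructed signal.
#' @export
idct_1d <- function(spectrum) {
  cc <- if (inherits(spectrum, "gw_dct")) spectrum$coefficients else as.numeric(spectrum)
  N <- length(cc)
  if (N == 1) return(cc)
  # orthonormal transform: inverse = transpose; direct O(N^2) synthesis
  n <- seq_len(N) - 1
  alpha <- c(1 / sqrt(N), rep(sqrt(2 / N), N - 1))
  basis <- cos(pi / N * outer(n + 0.5, n))  # [n, k]
  as.numeric(basis %*% (alpha * cc))
}

# Full DCT spectra for all rows of a samples x genes matrix.
dct_rows <- function(x) {
  t(apply(x, 1, function(r) dct_1d(r)$coefficients))
}

## ------------------------------------------------------------- extractors

# Each extractor is fit(train data, labels) -> rule, then transform(rule,
# newdata) -> features, so retention can be learned on training folds only.

#' Fit a feature-extraction rule on training data
#'
#' The retention rules reducing `n_genes` columns to `k` features use only
#' each method's own outputs:
#' \describe{
#'   \item{EM}{per gene, fit a 2-component Gaussian mixture to the training
#'     values; rank genes by the between-class difference in mean
#'     first-component responsibility, keep the top k genes.}
#'   \item{NLR}{per gene, fit the exponential-decay model across training
#'     samples; rank genes by residual sum of squares (worst fit = most
#'     structure), keep the top k genes.}
#'   \item{KMEANS}{cluster standardized gene profiles (genes as points in
#'     sample space); rank genes by the ratio of distance-to-nearest-other
#'     centroid over distance-to-own centroid, keep the top k genes.}
#'   \item{PCA}{default retention is gene selection by aggregate absolute
#'     loading (eigenvalue-weighted) on the leading components; score-mode
#'     projection onto the first k axes is available when `k <= rank`.}
#'   \item{DCT}{keep the k coefficient indices with the largest mean
#'     absolute value across training samples.}
#' }
#'
#' @param x training samples x genes matrix.
#' @param y training labels (factor healthy/malignant); used only by EM.
#' @param method one of `"EM"`, `"NLR"`, `"KMEANS"`, `"PCA"`, `"DCT"`.
#' @param k number of features to retain.
#' @param params optional per-method settings: `em_components` (2),
#'   `kmeans_K` (8), `pca_mode` (`"loadings"` or `"projection"`),
#'   `pca_components` (leading components scored, default `min(rank, 10)`).
#' @param seed RNG seed.
#' @return a `gw_extractor` with the fitted retention rule.
#' @export
extractor_fit <- function(x, y = NULL, method, k, params = list(), seed = 1L) {
  method <- match.arg(method, GW_METHODS)
  x <- as.matrix(x)
  m <- ncol(x)
  if (k > m) stop("k must not exceed the number of genes", call. = FALSE)
  rule <- switch(method,
    EM = {
      if (is.null(y)) stop("EM extraction needs training labels", call. = FALSE)
      nc <- params$em_components %||% 2L
      pos <- y == GW_POSITIVE
      score <- vapply(seq_len(m), function(j) {
        fit <- gmm_em_fit(x[, j], n_components = nc, max_iter = 50L,
                          seed = seed + j)
        w1 <- fit$responsibilities[, which.min(fit$mu)]
        abs(mean(w1[pos]) - mean(w1[!pos]))
      }, numeric(1))
      list(retained = order(score, decreasing = TRUE)[seq_len(k)])
    },
    NLR = {
      score <- vapply(seq_len(m), function(j)
        nlr_fit(x[, j], max_iter = 50L)$residual_ss, numeric(1))
      list(retained = order(score, decreasing = TRUE)[seq_len(k)])
    },
    KMEANS = {
      K <- params$kmeans_K %||% 8L
      prof <- scale(t(x))          # genes x samples, standardized profiles
      prof[is.na(prof)] <- 0
      km <- kmeans_fit(prof, K = min(K, m), seed = seed)
      d2 <- outer(rowSums(prof^2), rowSums(km$centroids^2), "+") -
        2 * prof %*% t(km$centroids)
      d2[d2 < 0] <- 0
      own <- d2[cbind(seq_len(m), km$assignments)]
      d2[cbind(seq_len(m), km$assignments)] <- Inf
      other <- apply(d2, 1, min)
      score <- sqrt(other) / (sqrt(own) + 1e-12)   # high = tight & distinctive
      list(retained = order(score, decreasing = TRUE)[seq_len(k)])
    },
    PCA = {
      fit <- pca_decompose(x)
      mode <- params$pca_mode %||% "loadings"
      rank <- sum(fit$eigenvalues > 1e-12 * max(fit$eigenvalues, 1))
      if (mode == "projection") {
        if (k > rank)
          stop("k exceeds data rank ", rank, " for PCA projection", call. = FALSE)
        list(pca = fit)
      } else {
        ncomp <- min(params$pca_components %||% 10L, max(rank, 1L))
        V <- fit$eigenvectors[, seq_len(ncomp), drop = FALSE]
        lam <- fit$eigenvalues[seq_len(ncomp)]
        score <- as.numeric(abs(V) %*% lam)
        list(retained = order(score, decreasing = TRUE)[seq_len(k)])
      }
    },
    DCT = {
      spec <- dct_rows(x)
      score <- colMeans(abs(spec))
      list(retained = order(score, decreasing = TRUE)[seq_len(k)])
    })
  structure(c(list(method = method, k = as.integer(k), seed = seed), rule),
            class = "gw_extractor")
}

#' Apply a fitted extraction rule to new samples
#'
#' @param extractor a [extractor_fit()] result.
#' @param x samples x genes matrix with the training gene dimension.
#' @return samples x k feature matrix.
#' @export
extractor_transform <- function(extractor, x) {
  stopifnot(inherits(extractor, "gw_extractor"))
  x <- as.matrix(x)
  out <- switch(extractor$method,
    DCT = dct_rows(x)[, extractor$retained, drop = FALSE],
    PCA = if (!is.null(extractor$pca))
      pca_project(extractor$pca, x, extractor$k)
    else x[, extractor$retained, drop = FALSE],
    x[, extractor$retained, drop = FALSE])
  if (anyNA(out) || any(!is.finite(out)))
    stop("extraction produced non-finite features", call. = FALSE)
  out
}

#' One-shot feature extraction on a whole dataset
#'
#' Convenience wrapper fitting the retention rule on all samples and
#' transforming them; inside cross-validation use [extractor_fit()] /
#' [extractor_transform()] on training folds only.
#'
#' @inheritParams extractor_fit
#' @param dataset a `gw_dataset`.
#' @param method extraction method name.
#' @return a `gw_extraction`: `method`, `k`, `features` (samples x k),
#'   `retained` (indices, or NULL for PCA projection), `extractor`.
#' @export
extract_features <- function(dataset, method, k = 6000L, params = list(),
                             seed = 1L) {
  stopifnot(inherits(dataset, "gw_dataset"))
  ex <- extractor_fit(dataset$matrix, dataset$labels, method = method,
                      k = k, params = params, seed = seed)
  feat <- extractor_transform(ex, dataset$matrix)
  rownames(feat) <- dataset$sample_ids
  structure(list(method = ex$method, k = ex$k, features = feat,
                 retained = ex$retained, extractor = ex),
            class = "gw_extraction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
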