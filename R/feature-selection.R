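# Metaheuristic wrapper feature selection over binary masks encoded as
# continuous positions in [lower, upper]^d. Three search algorithms are
# provided -- harmony search, the firefly algorithm and elephant herding
# optimization -- all minimizing a cross-validated MSE fitness.

#' Threshold a continuous position into a binary feature mask
#'
#' `mask[i] = 1` iff `position[i] > threshold`. An all-zero mask is
#' guarded: the single largest coordinate is selected instead, so a mask
#' always keeps at least one feature.
#'
#' @param position numeric vector with coordinates in `[0, 1]`.
#' @param threshold scalar cut point (default 0.5).
#' @return integer 0/1 vector of the same length.
#' @export
binarize_position <- function(position, threshold = 0.5) {
  mask <- as.integer(position > threshold)
  if (!any(mask == 1L)) mask[which.max(position)] <- 1L
  mask
}

#' Cross-validated MSE fitness of a feature mask
#'
#' Trains `clf_spec` on the masked feature columns under stratified
#' k-fold cross-validation and returns the mean squared error between the
#' 0/1-coded true labels and pooled predicted labels (for hard labels this
#' equals the misclassification rate). Results are memoized by mask when a
#' cache environment is supplied.
#'
#' @param mask 0/1 vector over feature columns (>= 1 selected).
#' @param features samples x d feature matrix.
#' @param labels factor of class labels.
#' @param clf_spec a [classifier_spec()].
#' @param folds number of CV folds (>= 2).
#' @param seed RNG seed controlling fold assignment and training.
#' @param cache optional environment used to memoize fitness by mask.
#' @param sparsity optional penalty weight `lambda`; adds
#'   `lambda * sum(mask) / d` (default 0, no penalty).
#' @return scalar fitness (lower is better).
#' @export
evaluate_fitness <- function(mask, features, labels, clf_spec,
                             folds = 5L, seed = 1L, cache = NULL,
                             sparsity = 0) {
  if (length(mask) != ncol(features))
    stop("mask length must equal feature dimension", call. = FALSE)
  if (!any(mask == 1L)) stop("mask must select at least one feature", call. = FALSE)
  key <- paste(which(mask == 1L), collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  x <- features[, mask == 1L, drop = FALSE]
  scheme <- stratified_folds(labels, k = folds, seed = seed)
  pred <- cross_val_predict(clf_spec, x, labels, scheme)
  y01 <- as.integer(labels == GW_POSITIVE)
  p01 <- as.integer(pred == GW_POSITIVE)
  fit <- mean((y01 - p01)^2) + sparsity * sum(mask) / length(mask)
  if (!is.null(cache)) cache[[key]] <- fit
  fit
}

new_trace <- function(best_fitness, best_position, evaluations, seed) {
  structure(list(best_fitness = best_fitness,
                 best_position = best_position,
                 evaluations = evaluations, seed = seed),
            class = "gw_trace")
}

# Shared stopping rule: fitness target reached or iteration cap.
GW_FITNESS_TARGET <- 1e-5

#' Harmony search configuration
#'
#' @param shm harmony memory size.
#' @param hmcr harmony memory consideration rate.
#' @param par pitch adjusting rate.
#' @param bw pitch-adjustment bandwidth (absolute, in coordinate units).
#' @param max_iter improvisation cap.
#' @export
hs_config <- function(shm = 10L, hmcr = 0.95, par = 0.3, bw = 0.1,
                      max_iter = 1000L) {
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (shm < 2) stop("harmony memory size must be >= 2", call. = FALSE)
  if (hmcr < 0 || hmcr > 1 || par < 0 || par > 1)
    stop("HMCR and PAR must lie in [0, 1]", call. = FALSE)
  if (bw <= 0) stop("bandwidth must be > 0", call. = FALSE)
  list(shm = as.integer(shm), hmcr = hmcr, par = par, bw = bw,
       max_iter = as.integer(max_iter))
}

#' Harmony search minimizer
#'
#' Memory of `shm` harmonies initialized uniformly in the bounds; each
#' iteration improvises one harmony coordinate-wise: with probability
#' `hmcr` copy a random memory member's value and, with probability `par`,
#' perturb it by `bw * U(-1, 1)`; otherwise draw uniformly in the bounds.
#' The improvisation replaces the worst memory member when better. Stops
#' at `max_iter` improvisations or when the best fitness falls below the
#' `1e-5` target.
#'
#' @param fitness_fn function(position) -> scalar to minimize.
#' @param d search dimension.
#' @param config a [hs_config()].
#' @param seed RNG seed.
#' @param lower,upper box bounds.
#' @return a `gw_trace`: monotone `best_fitness` per iteration,
#'   `best_position`, `evaluations`, `seed`.
#' @export
harmony_search <- function(fitness_fn, d, config = hs_config(), seed = 1L,
                           lower = 0, upper = 1) {
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  set.seed(seed)
  hm <- matrix(runif(config$shm * d, lower, upper), config$shm, d)
  hf <- apply(hm, 1, fitness_fn)
  evals <- config$shm
  best <- numeric(0)
  for (it in seq_len(config$max_iter)) {
    use_mem <- runif(d) < config$hmcr
    src <- sample.int(config$shm, d, replace = TRUE)
    new <- ifelse(use_mem, hm[cbind(src, seq_len(d))], runif(d, lower, upper))
    adj <- use_mem & runif(d) < config$par
    new[adj] <- new[adj] + config$bw * runif(sum(adj), -1, 1)
    new <- pmin(pmax(new, lower), upper)
    f <- fitness_fn(new)
    evals <- evals + 1L
    worst <- which.max(hf)
    if (f < hf[worst]) {
      hm[worst, ] <- new
      hf[worst] <- f
    }
    best <- c(best, min(hf))
    if (min(hf) <= GW_FITNESS_TARGET) break
  }
  i <- which.min(hf)
  new_trace(best, hm[i, ], evals, seed)
}

#' Firefly algorithm configuration
#'
#' @param gamma light absorption coefficient.
#' @param beta0 attractiveness at distance 0.
#' @param alpha0 initial randomization scale (decays geometrically by
#'   `alpha_decay` each iteration).
#' @param alpha_decay per-iteration decay of the randomization scale.
#' @param population number of fireflies.
#' @param max_iter iteration cap.
#' @export
ff_config <- function(gamma = 0.1, beta0 = 1, alpha0 = 0.65,
                      alpha_decay = 0.97, population = 25L,
                      max_iter = 1000L) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (population < 2) stop("population must be >= 2", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  list(gamma = gamma, beta0 = beta0, alpha0 = alpha0,
       alpha_decay = alpha_decay, population = as.integer(population),
       max_iter = as.integer(max_iter))
}

#' Attractiveness of a firefly seen at distance r
#'
#' `beta(r) = beta0 * exp(-gamma r^2)`: full attractiveness at r = 0,
#' decaying with the squared Euclidean distance.
#'
#' @param beta0 attractiveness at r = 0.
#' @param gamma light absorption coefficient.
#' @param r Euclidean distance.
#' @export
firefly_attractiveness <- function(beta0, gamma, r) beta0 * exp(-gamma * r^2)

#' Firefly algorithm minimizer
#'
#' Brightness is the negated fitness. Each iteration every firefly moves
#' toward every brighter one by `beta0 exp(-gamma r^2) (x_j - x_i)` plus a
#' uniform perturbation `alpha (rand - 0.5)` per coordinate (positions
#' compared against the iteration-start snapshot; moves are clipped to the
#' bounds). The randomization scale starts at `alpha0` and decays
#' geometrically so the swarm settles. Stops at `max_iter` or at the
#' `1e-5` fitness target.
#'
#' @inheritParams harmony_search
#' @param config a [ff_config()].
#' @return a `gw_trace`.
#' @export
firefly_search <- function(fitness_fn, d, config = ff_config(), seed = 1L,
                           lower = 0, upper = 1) {
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  set.seed(seed)
  p <- config$population
  pos <- matrix(runif(p * d, lower, upper), p, d)
  fit <- apply(pos, 1, fitness_fn)
  evals <- p
  alpha <- config$alpha0
  best <- numeric(0)
  gbest_f <- min(fit)
  gbest_x <- pos[which.min(fit), ]
  for (it in seq_len(config$max_iter)) {
    snap <- pos
    snapf <- fit
    for (i in seq_len(p)) {
      brighter <- which(snapf < snapf[i])
      xi <- pos[i, ]
      for (j in brighter) {
        r <- sqrt(sum((xi - snap[j, ])^2))
        beta <- firefly_attractiveness(config$beta0, config$gamma, r)
        xi <- xi + beta * (snap[j, ] - xi) + alpha * (runif(d) - 0.5)
      }
      if (length(brighter)) {
        pos[i, ] <- pmin(pmax(xi, lower), upper)
        fit[i] <- fitness_fn(pos[i, ])
        evals <- evals + 1L
      }
    }
    if (min(fit) < gbest_f) {
      gbest_f <- min(fit)
      gbest_x <- pos[which.min(fit), ]
    }
    alpha <- alpha * config$alpha_decay
    best <- c(best, gbest_f)
    if (gbest_f <= GW_FITNESS_TARGET) break
  }
  new_trace(best, gbest_x, evals, seed)
}

#' Elephant herding optimization configuration
#'
#' @param alpha movement factor toward the clan best.
#' @param beta attraction of the clan best toward the clan center.
#' @param n_clans number of clans; must divide `population`.
#' @param population herd size.
#' @param max_iter iteration cap.
#' @export
eho_config <- function(alpha = 0.6, beta = 0.6, n_clans = 3L,
                       population = 30L, max_iter = 1000L) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (population %% n_clans != 0)
    stop("population must be divisible by n_clans", call. = FALSE)
  list(alpha = alpha, beta = beta, n_clans = as.integer(n_clans),
       population = as.integer(population), max_iter = as.integer(max_iter))
}

#' Elephant herding optimization minimizer
#'
#' The herd is split into clans. Each iteration, clan members move toward
#' the clan best by `alpha * (x_best - x_old) * r` with `r ~ U(0, 1)`;
#' the clan best itself is replaced by `beta * x_centre` (the scaled clan
#' mean); the clan worst is re-drawn as
#' `lower + (upper - lower + 1) * rand`, clipped to the bounds. Elitism
#' keeps the global best ever seen. Stops at `max_iter` or at the `1e-5`
#' fitness target.
#'
#' @inheritParams harmony_search
#' @param config an [eho_config()].
#' @return a `gw_trace`.
#' @export
eho_search <- function(fitness_fn, d, config = eho_config(), seed = 1L,
                       lower = 0, upper = 1) {
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  set.seed(seed)
  p <- config$population
  clans <- rep(seq_len(config$n_clans), each = p / config$n_clans)
  pos <- matrix(runif(p * d, lower, upper), p, d)
  fit <- apply(pos, 1, fitness_fn)
  evals <- p
  gbest_f <- min(fit)
  gbest_x <- pos[which.min(fit), ]
  best <- numeric(0)
  for (it in seq_len(config$max_iter)) {
    for (c_id in seq_len(config$n_clans)) {
      members <- which(clans == c_id)
      cb <- members[which.min(fit[members])]
      cw <- members[which.max(fit[members])]
      centre <- colMeans(pos[members, , drop = FALSE])
      xb <- pos[cb, ]
      for (i in members) {
        cand <- if (i == cb) {
          config$beta * centre
        } else if (i == cw) {
          # the clan worst is re-drawn at random; the +1 stretch follows
          # the update rule as published and the draw is clipped to bounds
          lower + (upper - lower + 1) * runif(d)
        } else {
          pos[i, ] + config$alpha * (xb - pos[i, ]) * runif(d)
        }
        pos[i, ] <- pmin(pmax(cand, lower), upper)
      }
      fit[members] <- apply(pos[members, , drop = FALSE], 1, fitness_fn)
      evals <- evals + length(members)
    }
    if (min(fit) < gbest_f) {
      gbest_f <- min(fit)
      gbest_x <- pos[which.min(fit), ]
    } else {
      # elitism: re-insert the global best over the current worst
      w <- which.max(fit)
      pos[w, ] <- gbest_x
      fit[w] <- gbest_f
    }
    best <- c(best, gbest_f)
    if (gbest_f <= GW_FITNESS_TARGET) break
  }
  new_trace(best, gbest_x, evals, seed)
}

#' Wrapper feature selection by a metaheuristic
#'
#' Runs the chosen search algorithm over continuous positions in
#' `[0, 1]^d`, scoring each candidate by the cross-validated MSE of
#' `clf_spec` on the binarized mask ([binarize_position()] at 0.5 with the
#' argmax guard). Fitness values are memoized by mask, so re-visited masks
#' cost nothing.
#'
#' @param features samples x d feature matrix.
#' @param labels factor of class labels.
#' @param algorithm `"HS"`, `"FF"` or `"EHO"`.
#' @param clf_spec [classifier_spec()] used inside the fitness wrapper
#'   (wrapper semantics: default it to the downstream classifier; pass
#'   `classifier_spec("CENTROID")` as a cheap surrogate).
#' @param config per-algorithm config ([hs_config()], [ff_config()],
#'   [eho_config()]); defaults to the algorithm's defaults.
#' @param folds internal CV folds for the fitness.
#' @param seed RNG seed.
#' @param sparsity optional sparsity penalty weight (default 0).
#' @return list with `mask` (0/1 over features), `selected` (indices),
#'   `trace` (a `gw_trace`), `algorithm`.
#' @export
select_features <- function(features, labels, algorithm = c("HS", "FF", "EHO"),
                            clf_spec, config = NULL, folds = 5L, seed = 1L,
                            sparsity = 0) {
  algorithm <- match.arg(algorithm)
  d <- ncol(features)
  if (d < 1) stop("need at least one candidate feature", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  fitness_fn <- function(position) {
    mask <- binarize_position(position)
    evaluate_fitness(mask, features, labels, clf_spec, folds = folds,
                     seed = seed, cache = cache, sparsity = sparsity)
  }
  trace <- switch(algorithm,
    HS = harmony_search(fitness_fn, d, config %||% hs_config(), seed = seed),
    FF = firefly_search(fitness_fn, d, config %||% ff_config(), seed = seed),
    EHO = eho_search(fitness_fn, d, config %||% eho_config(), seed = seed))
  mask <- binarize_position(trace$best_position)
  list(mask = mask, selected = which(mask == 1L), trace = trace,
       algorithm = algorithm)
}

#' Serialize a selection result to JSON
#'
#' @param selection a [select_features()] result.
#' @param path output path.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(
    list(algorithm = selection$algorithm,
         selected = selection$selected,
         final_fitness = utils::tail(selection$trace$best_fitness, 1),
         evaluations = selection$trace$evaluations,
         seed = selection$trace$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
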