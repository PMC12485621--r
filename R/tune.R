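#' Hyperparameter search spaces
#'
#' A search space is a named list of parameter definitions made with
#' [param_numeric()] / [param_integer()]. `default_search_space()` returns
#' the space used when tuning each base-classifier family.
#'
#' @param lower,upper bounds (inclusive).
#' @param log search on a log10 scale (bounds still on the natural scale).
#' @return a parameter definition (internal list).
#' @export
param_numeric <- function(lower, upper, log = FALSE) {
  if (upper < lower) stop("upper < lower")
  list(type = "numeric", lower = lower, upper = upper, log = log)
}

#' @rdname param_numeric
#' @export
param_integer <- function(lower, upper) {
  list(type = "integer", lower = lower, upper = upper, log = FALSE)
}

#' @rdname param_numeric
#' @param algorithm a base-classifier family name.
#' @export
default_search_space <- function(algorithm = c("logistic", "random_forest", "xgboost")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    logistic = list(lambda = param_numeric(1e-4, 10, log = TRUE)),
    random_forest = list(
      num_trees = param_integer(100, 500),
      mtry_frac = param_numeric(0.05, 1),
      min_node_size = param_integer(1, 10)
    ),
    xgboost = list(
      eta = param_numeric(0.01, 0.3, log = TRUE),
      max_depth = param_integer(2, 8),
      nrounds = param_integer(50, 300),
      subsample = param_numeric(0.5, 1)
    )
  )
}

# ---- unit-cube transforms ---------------------------------------------------

space_dim <- function(space) length(space)

unit_to_params <- function(u, space) {
  out <- list()
  for (j in seq_along(space)) {
    p <- space[[j]]
    lo <- p$lower; hi <- p$upper
    v <- if (isTRUE(p$log)) 10^(log10(lo) + u[j] * (log10(hi) - log10(lo)))
         else lo + u[j] * (hi - lo)
    if (p$type == "integer") v <- as.integer(round(v))
    out[[names(space)[j]]] <- v
  }
  out
}

space_is_point <- function(space) {
  all(vapply(space, function(p) p$upper == p$lower, logical(1)))
}

# ---- Gaussian-process surrogate --------------------------------------------

rbf_kernel <- function(A, B, lengthscale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-0.5 * pmax(d2, 0) / lengthscale^2)
}

gp_fit <- function(U, y, lengthscale, nugget = 1e-6) {
  mu <- mean(y); sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  z <- (y - mu) / sdv
  K <- rbf_kernel(U, U, lengthscale) + diag(nugget, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, z, transpose = TRUE))
  list(U = U, L = L, alpha = alpha, mu = mu, sdv = sdv, ls = lengthscale,
       nugget = nugget)
}

gp_predict <- function(gp, Unew) {
  Ks <- rbf_kernel(Unew, gp$U, gp$ls)
  mean_z <- Ks %*% gp$alpha
  v <- backsolve(gp$L, t(Ks), transpose = TRUE)
  var_z <- pmax(1 + gp$nugget - colSums(v^2), 1e-12)
  list(mean = as.numeric(mean_z) * gp$sdv + gp$mu,
       sd = sqrt(var_z) * gp$sdv)
}

expected_improvement <- function(mean, sd, best) {
  imp <- mean - best
  z <- imp / sd
  ei <- imp * stats::pnorm(z) + sd * stats::dnorm(z)
  ei[sd < 1e-12] <- 0
  ei
}

#' Sequential model-based optimization (maximization)
#'
#' A compact Bayesian optimizer: a maximin Latin-hypercube initial design,
#' then a Gaussian-process surrogate (RBF kernel on the unit cube, fixed
#' lengthscale, standardized responses) with expected-improvement
#' acquisition over a random candidate set. Deterministic given `seed`.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar to maximize.
#' @param space a search space (named list of [param_numeric()] /
#'   [param_integer()]).
#' @param budget total number of objective evaluations (>= 1).
#' @param seed integer seed.
#' @param n_init size of the initial design (default `max(4, budget %/% 3)`,
#'   capped at `budget`).
#' @param n_candidates random candidates scored by EI per iteration.
#' @return list with `best_params`, `best_value` and a `history` data.frame
#'   (unit-cube coordinates and objective values in evaluation order).
#' @export
smbo_optimize <- function(objective, space, budget, seed,
                          n_init = NULL, n_candidates = 256L) {
  if (budget < 1) stop("budget must be >= 1")
  d <- space_dim(space)
  if (space_is_point(space)) {
    par <- unit_to_params(rep(0.5, d), space)
    return(list(best_params = par, best_value = objective(par),
                history = NULL))
  }
  if (is.null(n_init)) n_init <- min(budget, max(4L, budget %/% 3L))
  n_init <- min(n_init, budget)
  withr::with_seed(as.integer(seed), {
    U <- as.matrix(lhs::maximinLHS(n_init, d))
    vals <- vapply(seq_len(n_init), function(i) {
      objective(unit_to_params(U[i, ], space))
    }, numeric(1))
    lengthscale <- 0.3 * sqrt(d)
    while (length(vals) < budget) {
      gp <- tryCatch(gp_fit(U, vals, lengthscale), error = function(e) NULL)
      if (is.null(gp)) {
        cand_best <- stats::runif(d)
      } else {
        cand <- matrix(stats::runif(n_candidates * d), ncol = d)
        pr <- gp_predict(gp, cand)
        ei <- expected_improvement(pr$mean, pr$sd, max(vals))
        cand_best <- cand[which.max(ei), ]
      }
      U <- rbind(U, cand_best)
      vals <- c(vals, objective(unit_to_params(cand_best, space)))
    }
    best <- which.max(vals)
    list(best_params = unit_to_params(U[best, ], space),
         best_value = vals[best],
         history = data.frame(U, value = vals))
  })
}

#' Tune a base classifier by Bayesian optimization
#'
#' Selects hyperparameters maximizing the mean stratified k-fold
#' cross-validated balanced accuracy, using [smbo_optimize()] over the
#' family's search space. Deterministic given `seed`.
#'
#' @param X feature matrix.
#' @param y binary labels (0/1); both classes must be present.
#' @param algorithm base-classifier family.
#' @param space search space (default [default_search_space()] for the
#'   family).
#' @param n_folds stratified CV folds (>= 2).
#' @param budget number of hyperparameter points evaluated (>= 1).
#' @param seed integer seed.
#' @return a [classifier_spec()] carrying the selected hyperparameters,
#'   with attributes `"cv_score"` (best mean CV balanced accuracy) and
#'   `"history"`.
#' @export
tune_hyperparameters <- function(X, y, algorithm = "logistic", space = NULL,
                                 n_folds = 3L, budget = 10L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present to tune")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (is.null(space)) space <- default_search_space(algorithm)
  folds <- stratified_folds(y, n_folds, seed = seed)
  objective <- function(params) {
    spec <- classifier_spec(algorithm, hyperparameters = params, seed = seed)
    accs <- vapply(seq_len(n_folds), function(f) {
      hold <- folds == f
      if (!any(hold) || length(unique(y[!hold])) < 2L) return(NA_real_)
      m <- fit_binary(X[!hold, , drop = FALSE], y[!hold], spec)
      pred <- as.integer(predict_score(m, X[hold, , drop = FALSE]) >= 0.5)
      balanced_accuracy(y[hold], pred)
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }
  res <- smbo_optimize(objective, space, budget = budget, seed = seed)
  spec <- classifier_spec(algorithm, hyperparameters = res$best_params,
                         seed = seed)
  attr(spec, "cv_score") <- res$best_value
  attr(spec, "history") <- res$history
  spec
}
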