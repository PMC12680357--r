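#' Default hyperparameter search spaces
#'
#' The tunable domains for the four families that survive screening in the
#' reference pipeline. Numeric parameters are uniform over the stated
#' range (integers rounded), categorical parameters uniform over their
#' levels: random forest `n_estimators` [10, 150], `max_depth` [5, 20],
#' `min_samples_split` [2, 10], `min_samples_leaf` [1, 5]; XGBoost
#' `booster` {gbtree, gblinear, dart}, `eta` [0.01, 1], `gamma` [0, 0.6],
#' `max_depth` [1, 100], `sampling_method` {uniform, subsample,
#' gradient_based}; gradient boosting `n_estimators` [10, 500],
#' `learning_rate` [0.01, 1], `loss` {squared_error, absolute_error,
#' huber, quantile}, `criterion` {friedman_mse, squared_error} (the
#' criterion is accepted for interface parity but the rpart base learner
#' always splits on anova deviance); SVR `degree` [1, 9], `gamma` {scale,
#' auto}, `epsilon` [0, 5], `kernel` {linear, poly, rbf, sigmoid},
#' `C` [0.01, 5].
#'
#' @param kind model family.
#' @return a list of parameter definitions, each
#'   `list(name, type, range | values)` with `type` one of `"uniform"`,
#'   `"int"`, `"categorical"`.
#' @export
default_search_space <- function(kind) {
  switch(match.arg(kind, supported_kinds()),
    rf = list(
      list(name = "n_estimators", type = "int", range = c(10, 150)),
      list(name = "max_depth", type = "int", range = c(5, 20)),
      list(name = "min_samples_split", type = "int", range = c(2, 10)),
      list(name = "min_samples_leaf", type = "int", range = c(1, 5))),
    xgb = list(
      list(name = "booster", type = "categorical",
           values = c("gbtree", "gblinear", "dart")),
      list(name = "eta", type = "uniform", range = c(0.01, 1)),
      list(name = "gamma", type = "uniform", range = c(0, 0.6)),
      list(name = "max_depth", type = "int", range = c(1, 100)),
      list(name = "sampling_method", type = "categorical",
           values = c("uniform", "subsample", "gradient_based"))),
    gb = list(
      list(name = "n_estimators", type = "int", range = c(10, 500)),
      list(name = "learning_rate", type = "uniform", range = c(0.01, 1)),
      list(name = "loss", type = "categorical",
           values = c("squared_error", "absolute_error", "huber", "quantile")),
      list(name = "criterion", type = "categorical",
           values = c("friedman_mse", "squared_error"))),
    svm = list(
      list(name = "degree", type = "int", range = c(1, 9)),
      list(name = "gamma", type = "categorical", values = c("scale", "auto")),
      list(name = "epsilon", type = "uniform", range = c(0, 5)),
      list(name = "kernel", type = "categorical",
           values = c("linear", "poly", "rbf", "sigmoid")),
      list(name = "C", type = "uniform", range = c(0.01, 5))),
    stop("no default search space for kind ", kind, call. = FALSE))
}

space_is_degenerate <- function(space) {
  all(vapply(space, function(p) {
    if (p$type == "categorical") length(p$values) == 1L else diff(p$range) == 0
  }, logical(1)))
}

draw_point <- function(space, u = NULL) {
  out <- list()
  for (i in seq_along(space)) {
    p <- space[[i]]
    ui <- if (is.null(u)) stats::runif(1) else u[i]
    out[[p$name]] <- switch(p$type,
      uniform = p$range[1] + ui * diff(p$range),
      int = as.integer(round(p$range[1] + ui * diff(p$range))),
      categorical = p$values[1 + floor(ui * length(p$values) * 0.999999)])
  }
  out
}

encode_point <- function(space, params) {
  unlist(lapply(space, function(p) {
    x <- params[[p$name]]
    if (p$type == "categorical") {
      as.numeric(p$values == x)
    } else if (diff(p$range) == 0) 0 else {
      (as.numeric(x) - p$range[1]) / diff(p$range)
    }
  }))
}

# GP posterior (RBF kernel, median-heuristic length scale) + expected
# improvement over a candidate pool
propose_ei <- function(Xe, y, cand_enc) {
  d2 <- as.matrix(stats::dist(Xe))^2
  ell2 <- stats::median(d2[d2 > 0])
  if (!is.finite(ell2) || ell2 <= 0) ell2 <- 1
  K <- exp(-d2 / (2 * ell2))
  ys <- (y - mean(y)) / max(stats::sd(y), 1e-9)
  A <- K + diag(1e-4, nrow(K))
  alpha <- solve(A, ys)
  cd2 <- outer(rowSums(cand_enc^2), rowSums(Xe^2), `+`) - 2 * cand_enc %*% t(Xe)
  Kc <- exp(-pmax(cd2, 0) / (2 * ell2))
  mu <- drop(Kc %*% alpha)
  v <- pmax(1 - rowSums((Kc %*% solve(A)) * Kc), 1e-12)
  s <- sqrt(v)
  best <- max(ys)
  z <- (mu - best) / s
  ei <- (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
  which.max(ei)
}

#' Bayesian hyperparameter search
#'
#' Sequential model-based optimisation of the mean 5-fold CV R-squared: an
#' initial Latin-hypercube design, then a Gaussian-process surrogate (RBF
#' kernel) with expected-improvement acquisition over a random candidate
#' pool, for a total budget of `n_iter` objective evaluations. Folds are
#' seeded once and shared by every evaluation. The best configuration is
#' refit on the full training partition and evaluated on the test
#' partition.
#'
#' @param split a `sac_split`.
#' @param kind model family (one with a [default_search_space()]).
#' @param space search space (defaults to the family's standard space).
#' @param n_iter total number of objective evaluations (default 50).
#' @param folds CV folds per evaluation (default 5).
#' @param seed integer seed controlling folds, design and candidates.
#' @param n_init size of the initial design.
#' @return a `sac_search`: `best_params`, `best_cv_r2`, `history`
#'   (tibble of evaluated points and scores), `report`
#'   (the [evaluate_model()] report of the refit best model), `model`.
#' @export
bayes_search <- function(split, kind, space = default_search_space(kind),
                         n_iter = 50, folds = 5, seed = 1L,
                         n_init = min(10, n_iter)) {
  if (length(space) == 0L) stop("empty search space", call. = FALSE)
  objective <- function(params) {
    mean(cv_r2(split, kind, params, folds = folds, seed = seed))
  }
  history <- list()
  evaluated_keys <- character(0)
  eval_point <- function(params) {
    key <- paste(vapply(params, as.character, character(1)), collapse = "|")
    if (key %in% evaluated_keys) return(FALSE)
    score <- objective(params)
    history[[length(history) + 1L]] <<- c(params, list(.score = score))
    evaluated_keys <<- c(evaluated_keys, key)
    TRUE
  }

  if (space_is_degenerate(space)) {
    with_seed(seed, eval_point(draw_point(space)))
  } else {
    with_seed(seed, {
      U <- lhs::randomLHS(n_init, length(space))
      for (i in seq_len(n_init)) eval_point(draw_point(space, U[i, ]))
      tries <- 0L
      while (length(history) < n_iter && tries < 10L * n_iter) {
        tries <- tries + 1L
        cand <- replicate(256, draw_point(space), simplify = FALSE)
        Xe <- t(vapply(history, function(h) {
          encode_point(space, h)
        }, encode_point(space, cand[[1]])))
        y <- vapply(history, function(h) h$.score, numeric(1))
        cand_enc <- t(vapply(cand, function(p) encode_point(space, p),
                             encode_point(space, cand[[1]])))
        pick <- propose_ei(Xe, y, cand_enc)
        if (!eval_point(cand[[pick]])) {
          eval_point(draw_point(space))   # duplicate: fall back to a fresh draw
        }
      }
    })
  }

  scores <- vapply(history, function(h) h$.score, numeric(1))
  best_i <- which.max(scores)
  best_params <- history[[best_i]]
  best_params$.score <- NULL
  hist_tbl <- dplyr::bind_rows(lapply(seq_along(history), function(i) {
    h <- history[[i]]
    tibble::as_tibble(c(list(iteration = i), h[names(h) != ".score"],
                        list(cv_r2 = h$.score)))
  }))
  model <- train_model(split, kind, best_params, seed = seed)
  report <- evaluate_model(model, split,
                           cv_r2 = cv_r2(split, kind, best_params,
                                         folds = folds, seed = seed))
  structure(list(best_params = best_params, best_cv_r2 = scores[best_i],
                 history = hist_tbl, report = report, model = model,
                 kind = kind, seed = as.integer(seed)),
            class = "sac_search")
}

#' @export
print.sac_search <- function(x, ...) {
  cat(sprintf("<sac_search> %s | %d evaluations | best CV R2 %.3f | test R2 %.3f\n",
              x$kind, nrow(x$history), x$best_cv_r2, x$report$r2))
  invisible(x)
}

#' @export
tidy.sac_search <- function(x, ...) x$history

#' @export
glance.sac_search <- function(object, ...) {
  dplyr::bind_cols(tibble::tibble(n_evaluations = nrow(object$history),
                                  best_cv_r2 = object$best_cv_r2),
                   glance.sac_model_report(object$report))
}
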