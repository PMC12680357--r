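#' Assemble the surrogate regression dataset
#'
#' One row per simulation: patient age (days), osteotomy ratios, the two
#' springs' stiffness and free length (8 features), the pre-operative shape
#' coefficients `b_in` (projection of the patient's pre-op shape on the
#' input shape model) and the post-operative coefficients `b_out`
#' (projection of the simulated outcome on the output shape model). With 11
#' input and 11 output modes this is the classic 30-column layout.
#'
#' @param ssm_in,ssm_out `sac_ssm` models for the pre-op and outcome sets.
#' @param plans a `sac_doe_plan` (rows for all patients).
#' @param sim_results named list, `config_id` -> post-op `sac_mesh` (or
#'   shape vector, or `sac_sim_result`).
#' @param population the [sample_population()] tibble (for ages).
#' @param preop_shapes named list, `patient_id` -> pre-op `sac_mesh` or
#'   shape vector.
#' @return a `sac_dataset` tibble: `patient_id`, `config_id`, 8 feature
#'   columns, `b_in_*`, `b_out_*`.
#' @export
assemble_dataset <- function(ssm_in, ssm_out, plans, sim_results,
                             population, preop_shapes) {
  stopifnot(inherits(ssm_in, "sac_ssm"), inherits(ssm_out, "sac_ssm"))
  if (anyDuplicated(plans$config_id)) {
    stop("duplicate config ids: ",
         paste(unique(plans$config_id[duplicated(plans$config_id)]), collapse = ", "),
         call. = FALSE)
  }
  missing_sims <- setdiff(plans$config_id, names(sim_results))
  if (length(missing_sims) > 0L) {
    stop("no simulation result for: ", paste(utils::head(missing_sims, 10), collapse = ", "),
         call. = FALSE)
  }
  missing_pre <- setdiff(unique(plans$patient_id), names(preop_shapes))
  if (length(missing_pre) > 0L) {
    stop("no pre-op shape for: ", paste(missing_pre, collapse = ", "), call. = FALSE)
  }
  as_vec <- function(s) {
    if (inherits(s, "sac_sim_result")) s <- s$postop_mesh
    if (inherits(s, "sac_mesh")) flatten_shape(s) else as.numeric(s)
  }
  b_in_by_patient <- lapply(preop_shapes, function(s) project_shape(ssm_in, as_vec(s)))
  B_out <- vapply(plans$config_id,
                  function(id) project_shape(ssm_out, as_vec(sim_results[[id]])),
                  numeric(ssm_out$k))
  B_out <- t(matrix(B_out, nrow = ssm_out$k))
  B_in <- t(matrix(vapply(plans$patient_id, function(p) b_in_by_patient[[p]],
                          numeric(ssm_in$k)), nrow = ssm_in$k))
  age <- population$age_days[match(plans$patient_id, population$patient_id)]
  if (anyNA(age)) stop("plan patients missing from population table", call. = FALSE)
  colnames(B_in) <- paste0("b_in_", seq_len(ssm_in$k))
  colnames(B_out) <- paste0("b_out_", seq_len(ssm_out$k))
  ds <- dplyr::bind_cols(
    tibble::tibble(patient_id = plans$patient_id, config_id = plans$config_id,
                   age_days = as.numeric(age),
                   A = plans$A, AP = plans$AP, LAT = plans$LAT,
                   ant_k = plans$ant_k, ant_L0 = plans$ant_L0,
                   post_k = plans$post_k, post_L0 = plans$post_L0),
    tibble::as_tibble(B_in), tibble::as_tibble(B_out))
  class(ds) <- c("sac_dataset", class(ds))
  ds
}

dataset_feature_cols <- function(ds) {
  c("age_days", "A", "AP", "LAT", "ant_k", "ant_L0", "post_k", "post_L0",
    grep("^b_in_", names(ds), value = TRUE))
}

dataset_output_cols <- function(ds) grep("^b_out_", names(ds), value = TRUE)

#' Train/test split with standard scaling
#'
#' Random row split (`ceiling(test_fraction * n)` rows held out), then
#' per-column standardisation (zero mean, unit variance) of features and
#' output modes, fit on the training rows only and applied to both
#' partitions. Zero-variance columns are left centred and flagged.
#'
#' @param ds a `sac_dataset`.
#' @param test_fraction fraction in (0, 1); default 0.33.
#' @param seed integer seed.
#' @return a `sac_split`: `train`, `test` (scaled tibbles), `scaler`
#'   (`center`, `scale`, `flagged`), `feature_cols`, `output_cols`,
#'   `test_idx`, `seed`.
#' @export
split_and_scale <- function(ds, test_fraction = 0.33, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(ds)
  n_test <- ceiling(test_fraction * n)
  fc <- dataset_feature_cols(ds)
  oc <- dataset_output_cols(ds)
  test_idx <- with_seed(seed, sort(sample.int(n, n_test)))
  train <- ds[-test_idx, , drop = FALSE]
  test <- ds[test_idx, , drop = FALSE]
  cols <- c(fc, oc)
  center <- vapply(cols, function(cn) mean(train[[cn]]), numeric(1))
  scl <- vapply(cols, function(cn) stats::sd(train[[cn]]), numeric(1))
  flagged <- names(scl)[scl < 1e-12]
  scl[scl < 1e-12] <- 1
  apply_scale <- function(d) {
    for (cn in cols) d[[cn]] <- (d[[cn]] - center[[cn]]) / scl[[cn]]
    d
  }
  structure(list(train = apply_scale(train), test = apply_scale(test),
                 scaler = list(center = center, scale = scl, flagged = flagged),
                 feature_cols = fc, output_cols = oc,
                 test_idx = test_idx, seed = as.integer(seed)),
            class = "sac_split")
}

split_xy <- function(split, part = c("train", "test")) {
  part <- match.arg(part)
  d <- split[[part]]
  list(X = as.matrix(d[, split$feature_cols, drop = FALSE]),
       Y = as.matrix(d[, split$output_cols, drop = FALSE]))
}

supported_kinds <- function() c("lr", "dt", "rf", "xgb", "svm", "gb", "ab")

#' Train a multi-output regression model
#'
#' Fits one of seven model families on the (scaled) training partition:
#' linear regression (`"lr"`, the baseline), decision tree (`"dt"`),
#' random forest (`"rf"`), XGBoost (`"xgb"`), support vector regression
#' (`"svm"`), gradient boosting (`"gb"`) and AdaBoost.R2 (`"ab"`).
#' Linear regression is natively multi-output; the other learners are
#' wrapped per output dimension. Deterministic given `seed`.
#'
#' @param split a `sac_split` (or a list with `X`, `Y` matrices plus
#'   `feature_cols`/`output_cols`).
#' @param kind one of `supported_kinds()`.
#' @param hyperparams named list; see [default_search_space()] for the
#'   tunable names per kind.
#' @param seed integer seed.
#' @return a `sac_surrogate` model object with a `predict()` method.
#' @export
train_model <- function(split, kind, hyperparams = list(), seed = 1L) {
  kind <- match.arg(kind, supported_kinds())
  xy <- split_xy(split, "train")
  fit <- with_seed(seed, fit_kind(kind, xy$X, xy$Y, hyperparams, seed))
  structure(list(kind = kind, fit = fit, hyperparams = hyperparams,
                 feature_cols = split$feature_cols,
                 output_cols = split$output_cols, seed = as.integer(seed)),
            class = "sac_surrogate")
}

fit_kind <- function(kind, X, Y, hp, seed) {
  switch(kind,
    lr = {
      cf <- qr.coef(qr(cbind(1, X)), Y)
      cf[is.na(cf)] <- 0       # rank-deficient (e.g. constant) columns
      list(coef = cf)
    },
    dt = lapply(seq_len(ncol(Y)), function(j) {
      df <- data.frame(.y = Y[, j], X)
      rpart::rpart(.y ~ ., df, method = "anova",
                   control = rpart::rpart.control(
                     maxdepth = min(hp$max_depth %||% 30, 30),
                     minsplit = hp$min_samples_split %||% 2,
                     minbucket = hp$min_samples_leaf %||% 1,
                     cp = hp$cp %||% 0, xval = 0))
    }),
    rf = lapply(seq_len(ncol(Y)), function(j) {
      df <- data.frame(.y = Y[, j], X)
      ranger::ranger(.y ~ ., df,
                     num.trees = hp$n_estimators %||% 100,
                     max.depth = hp$max_depth %||% 0,
                     min.node.size = max(hp$min_samples_leaf %||% 1,
                                         ceiling((hp$min_samples_split %||% 2) / 2)),
                     num.threads = 1, seed = seed + j)
    }),
    xgb = lapply(seq_len(ncol(Y)), function(j) {
      booster <- hp$booster %||% "gbtree"
      params <- list(booster = booster, eta = hp$eta %||% 0.3,
                     objective = "reg:squarederror", nthread = 1)
      if (booster != "gblinear") {
        params$gamma <- hp$gamma %||% 0
        params$max_depth <- min(hp$max_depth %||% 6, 100)
        sm <- hp$sampling_method %||% "uniform"
        if (sm %in% c("subsample", "gradient_based")) params$subsample <- 0.8
      }
      set.seed(seed + j)
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(X, label = Y[, j]),
                         nrounds = hp$nrounds %||% 100, verbose = 0)
    }),
    svm = lapply(seq_len(ncol(Y)), function(j) {
      gamma_mode <- hp$gamma %||% "scale"
      gam <- if (identical(gamma_mode, "scale")) {
        1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
      } else if (identical(gamma_mode, "auto")) {
        1 / ncol(X)
      } else as.numeric(gamma_mode)
      kmap <- c(linear = "linear", poly = "polynomial", rbf = "radial",
                sigmoid = "sigmoid", radial = "radial", polynomial = "polynomial")
      m <- e1071::svm(x = X, y = Y[, j], type = "eps-regression",
                      kernel = unname(kmap[hp$kernel %||% "rbf"]),
                      cost = hp$C %||% 1, epsilon = hp$epsilon %||% 0.1,
                      degree = hp$degree %||% 3, gamma = gam, scale = FALSE,
                      fitted = FALSE, cachesize = 200)
      # a wide epsilon tube can leave no support vectors; keep a constant
      # fallback so prediction stays defined
      attr(m, "y_mean") <- mean(Y[, j])
      m
    }),
    gb = lapply(seq_len(ncol(Y)), function(j) {
      fit_gradient_boost(X, Y[, j],
                         n_estimators = hp$n_estimators %||% 100,
                         learning_rate = hp$learning_rate %||% 0.1,
                         loss = hp$loss %||% "squared_error",
                         max_depth = hp$max_depth %||% 3)
    }),
    ab = lapply(seq_len(ncol(Y)), function(j) {
      fit_adaboost_r2(X, Y[, j],
                      n_estimators = hp$n_estimators %||% 50,
                      max_depth = hp$max_depth %||% 3,
                      seed = seed + j)
    }))
}

#' @export
predict.sac_surrogate <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, object$feature_cols, drop = FALSE])
  out <- switch(object$kind,
    lr = cbind(1, X) %*% object$fit$coef,
    dt = vapply(object$fit, function(m) {
      unname(stats::predict(m, data.frame(X)))
    }, numeric(nrow(X))),
    rf = vapply(object$fit, function(m) {
      stats::predict(m, data.frame(X), num.threads = 1)$predictions
    }, numeric(nrow(X))),
    xgb = vapply(object$fit, function(m) {
      stats::predict(m, xgboost::xgb.DMatrix(X))
    }, numeric(nrow(X))),
    svm = vapply(object$fit, function(m) {
      if (m$tot.nSV == 0) rep(attr(m, "y_mean"), nrow(X)) else
        unname(stats::predict(m, X))
    }, numeric(nrow(X))),
    gb = vapply(object$fit, function(m) predict_gradient_boost(m, X),
                numeric(nrow(X))),
    ab = vapply(object$fit, function(m) predict_adaboost_r2(m, X),
                numeric(nrow(X))))
  out <- matrix(out, nrow = nrow(X))
  colnames(out) <- object$output_cols
  out
}

# least-squares / robust gradient boosting over rpart base learners
fit_gradient_boost <- function(X, y, n_estimators, learning_rate, loss,
                               max_depth) {
  loss <- match.arg(loss, c("squared_error", "absolute_error", "huber", "quantile"))
  f0 <- if (loss == "squared_error") mean(y) else stats::median(y)
  Fx <- rep(f0, length(y))
  trees <- vector("list", n_estimators)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                               minsplit = 5, minbucket = 2)
  df <- data.frame(X)
  for (t in seq_len(n_estimators)) {
    r <- y - Fx
    g <- switch(loss,
      squared_error = r,
      absolute_error = sign(r),
      huber = {
        delta <- stats::quantile(abs(r), 0.9)
        ifelse(abs(r) <= delta, r, delta * sign(r))
      },
      quantile = ifelse(r > 0, 0.5, -0.5))
    df$.g <- g
    tr <- rpart::rpart(.g ~ ., df, method = "anova", control = ctrl)
    Fx <- Fx + learning_rate * unname(stats::predict(tr, df))
    trees[[t]] <- tr
  }
  list(f0 = f0, trees = trees, lr = learning_rate)
}

predict_gradient_boost <- function(model, X) {
  df <- data.frame(X)
  out <- rep(model$f0, nrow(X))
  for (tr in model$trees) out <- out + model$lr * unname(stats::predict(tr, df))
  out
}

# AdaBoost.R2 (linear loss) over rpart base learners
fit_adaboost_r2 <- function(X, y, n_estimators, max_depth, seed) {
  n <- length(y)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                               minsplit = 5, minbucket = 2)
  df <- data.frame(.y = y, X)
  for (t in seq_len(n_estimators)) {
    tr <- rpart::rpart(.y ~ ., df, weights = w, method = "anova", control = ctrl)
    pred <- unname(stats::predict(tr, df))
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) {
      trees <- c(trees, list(tr)); betas <- c(betas, 1e-10)
      break
    }
    L <- err / emax
    Lbar <- sum(w * L)
    if (Lbar >= 0.5) break
    beta <- Lbar / (1 - Lbar)
    trees <- c(trees, list(tr)); betas <- c(betas, beta)
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  if (length(trees) == 0L) {       # fall back to a single unweighted tree
    tr <- rpart::rpart(.y ~ ., df, method = "anova", control = ctrl)
    trees <- list(tr); betas <- 0.5
  }
  list(trees = trees, log_inv_beta = log(1 / betas))
}

predict_adaboost_r2 <- function(model, X) {
  df <- data.frame(X)
  P <- vapply(model$trees, function(tr) unname(stats::predict(tr, df)),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  wts <- model$log_inv_beta
  # weighted median over estimators, per sample
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * sum(wts))[1]]
  })
}

r2_per_output <- function(truth, pred) {
  vapply(seq_len(ncol(truth)), function(j) {
    ss_res <- sum((truth[, j] - pred[, j])^2)
    ss_tot <- sum((truth[, j] - mean(truth[, j]))^2)
    if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)  # constant truth
    1 - ss_res / ss_tot
  }, numeric(1))
}

#' Evaluate a fitted surrogate on the held-out partition
#'
#' R-squared is the uniformly-averaged coefficient of determination over
#' the output columns; MSE and MAE are uniform means over all output
#' entries, on the standardised mode scale.
#'
#' @param model a `sac_surrogate`.
#' @param split the `sac_split` the model was trained on (its `test`
#'   partition is used).
#' @param cv_r2 optional per-fold CV scores to record.
#' @return a `sac_model_report`.
#' @export
evaluate_model <- function(model, split, cv_r2 = NULL) {
  xy <- split_xy(split, "test")
  if (nrow(xy$X) == 0L) stop("empty test partition", call. = FALSE)
  pred <- predict(model, xy$X)
  per_out <- r2_per_output(xy$Y, pred)
  structure(list(
    kind = model$kind, hyperparams = model$hyperparams,
    cv_r2 = cv_r2,
    r2 = mean(per_out), per_output_r2 = per_out,
    mse = mean((xy$Y - pred)^2), mae = mean(abs(xy$Y - pred)),
    n_test = nrow(xy$X), n_outputs = ncol(xy$Y),
    scaler = split$scaler, seed = model$seed,
    truth = xy$Y, predictions = pred),
    class = "sac_model_report")
}

#' @export
print.sac_model_report <- function(x, ...) {
  cat(sprintf("<sac_model_report> %s | test R2 %.3f, MSE %.3f, MAE %.3f (%d rows, %d outputs)\n",
              x$kind, x$r2, x$mse, x$mae, x$n_test, x$n_outputs))
  if (!is.null(x$cv_r2)) {
    cat(sprintf("  CV R2 %.3f +/- %.3f over %d folds\n",
                mean(x$cv_r2), stats::sd(x$cv_r2), length(x$cv_r2)))
  }
  invisible(x)
}

#' @export
tidy.sac_model_report <- function(x, ...) {
  tibble::tibble(output = colnames(x$truth) %||%
                   paste0("b_out_", seq_along(x$per_output_r2)),
                 r2 = x$per_output_r2,
                 mse = colMeans((x$truth - x$predictions)^2),
                 mae = colMeans(abs(x$truth - x$predictions)))
}

#' @export
glance.sac_model_report <- function(object, ...) {
  tibble::tibble(kind = object$kind, r2 = object$r2, mse = object$mse,
                 mae = object$mae,
                 cv_r2_mean = if (is.null(object$cv_r2)) NA_real_ else mean(object$cv_r2),
                 cv_r2_sd = if (is.null(object$cv_r2)) NA_real_ else stats::sd(object$cv_r2),
                 n_test = object$n_test)
}

#' Predicted-vs-actual plot for the leading output modes
#' @param object a `sac_model_report`.
#' @param n_modes number of output modes to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sac_model_report <- function(object, n_modes = 4, ...) {
  k <- min(n_modes, ncol(object$truth))
  df <- purrr::map_dfr(seq_len(k), function(j) {
    tibble::tibble(mode = colnames(object$truth)[j],
                   actual = object$truth[, j], predicted = object$predictions[, j])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~mode, scales = "free") +
    ggplot2::labs(x = "actual (standardised)", y = "predicted (standardised)") +
    ggplot2::theme_minimal()
}

cv_folds_idx <- function(n, folds, seed) {
  with_seed(seed, {
    idx <- sample.int(n)
    split(idx, cut(seq_len(n), folds, labels = FALSE))
  })
}

#' Cross-validated R-squared for one model family
#'
#' @param split a `sac_split`.
#' @param kind model family.
#' @param hyperparams named list.
#' @param folds number of folds (default 5).
#' @param seed fold seed.
#' @return numeric vector of per-fold uniformly-averaged R-squared.
#' @export
cv_r2 <- function(split, kind, hyperparams = list(), folds = 5, seed = 1L) {
  xy <- split_xy(split, "train")
  fidx <- cv_folds_idx(nrow(xy$X), folds, seed)
  vapply(seq_along(fidx), function(f) {
    hold <- fidx[[f]]
    sub <- list(train = NULL, feature_cols = split$feature_cols,
                output_cols = split$output_cols)
    m <- structure(list(kind = kind,
                        fit = with_seed(seed + f,
                          fit_kind(kind, xy$X[-hold, , drop = FALSE],
                                   xy$Y[-hold, , drop = FALSE], hyperparams,
                                   seed + f)),
                        hyperparams = hyperparams,
                        feature_cols = split$feature_cols,
                        output_cols = split$output_cols, seed = seed),
                   class = "sac_surrogate")
    pred <- predict(m, xy$X[hold, , drop = FALSE])
    mean(r2_per_output(xy$Y[hold, , drop = FALSE], pred))
  }, numeric(1))
}

#' Screen model families by cross-validation
#'
#' Runs 5-fold CV with default hyperparameters for every family, then
#' discards families whose mean R-squared falls below the linear-regression
#' baseline and families whose fold-to-fold standard deviation exceeds
#' `sd_threshold` (high variability). The baseline itself is never
#' discarded.
#'
#' @param split a `sac_split`.
#' @param kinds families to screen; must include `"lr"`.
#' @param folds,seed CV controls.
#' @param sd_threshold fold-SD discard threshold.
#' @return a `sac_screening` tibble: `kind`, `cv_r2_mean`, `cv_r2_sd`,
#'   `discarded`, `reason`, plus a `folds` attribute with per-fold scores.
#' @export
screen_models <- function(split, kinds = supported_kinds(), folds = 5,
                          seed = 1L, sd_threshold = 0.10) {
  if (!"lr" %in% kinds) stop("the lr baseline must be included", call. = FALSE)
  scores <- lapply(kinds, function(k) cv_r2(split, k, folds = folds, seed = seed))
  names(scores) <- kinds
  mu <- vapply(scores, mean, numeric(1))
  sdv <- vapply(scores, stats::sd, numeric(1))
  base <- mu[["lr"]]
  discarded <- (mu < base | sdv > sd_threshold) & kinds != "lr"
  reason <- dplyr::case_when(
    !discarded ~ "",
    mu < base & sdv > sd_threshold ~ "below baseline; high fold variance",
    mu < base ~ "below baseline",
    TRUE ~ "high fold variance")
  out <- tibble::tibble(kind = kinds, cv_r2_mean = mu, cv_r2_sd = sdv,
                        discarded = discarded, reason = reason)
  attr(out, "folds") <- scores
  class(out) <- c("sac_screening", class(out))
  out
}

#' @export
autoplot.sac_screening <- function(object, ...) {
  folds <- attr(object, "folds")
  df <- purrr::map_dfr(names(folds), function(k) {
    tibble::tibble(kind = k, fold = seq_along(folds[[k]]), r2 = folds[[k]])
  })
  df$kind <- factor(df$kind, levels = object$kind)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$r2)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey40") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7, size = 1) +
    ggplot2::labs(x = NULL, y = expression(R^2 ~ "(5-fold CV)")) +
    ggplot2::theme_minimal()
}
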