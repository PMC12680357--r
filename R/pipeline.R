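#' Derive a per-entity seed from a master seed
#'
#' Deterministic fan-out: per-patient (and per-stage) seeds are derived by
#' a small modular hash of the master seed and the entity id, so a corpus
#' can be extended with new patients without reshuffling existing ones.
#' The result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param id entity id (string or integer).
#' @param stage optional stage label folded into the hash.
#' @return an integer seed.
#' @export
derive_seed <- function(master, id, stage = "") {
  txt <- paste0(id, "/", stage)
  h <- sum(as.integer(charToRaw(txt)) * (seq_along(charToRaw(txt)) %% 31 + 1))
  s <- ((as.numeric(master) %% 50021) * 40009 + h * 10007 + 12345) %% 2147483646
  as.integer(s) + 1L
}

#' Generate the full synthetic corpus
#'
#' End-to-end data generation: sample a patient population, build each
#' patient's skull, draw its design-of-experiments plan, run every spring
#' simulation, build the input and output shape models, and assemble the
#' surrogate dataset. Fully deterministic given `master_seed`; per-patient
#' seeds come from [derive_seed()]. With default settings this reproduces
#' the reference corpus layout: 30 patients x ~80 configurations
#' (2250-2550 rows).
#'
#' @param n_patients number of patients.
#' @param master_seed master seed.
#' @param spec a [population_spec()].
#' @param resolution skull mesh resolution (approximate vertex count).
#' @param variance_threshold explained-variance threshold for both shape
#'   models (default 0.94).
#' @param opts [solver_options()] for the simulator.
#' @param doe_args named list of extra arguments for [generate_doe()]
#'   (e.g. a smaller `count_mean` for smoke-scale corpora).
#' @param out_dir optional directory: writes `population.csv`, `plan.csv`,
#'   `dataset.csv`, the two serialised shape models and `manifest.json`.
#' @param progress print per-patient progress to stderr.
#' @return a `sac_corpus`: list with `population`, `skulls`, `plan`,
#'   `sim_meta` (openings, iterations per config), `ssm_in`, `ssm_out`,
#'   `dataset`, `master_seed`.
#' @export
run_corpus <- function(n_patients = 30, master_seed = 1L,
                       spec = population_spec(), resolution = 2000,
                       variance_threshold = 0.94,
                       opts = solver_options(), doe_args = list(),
                       out_dir = NULL, progress = FALSE) {
  population <- sample_population(n_patients, derive_seed(master_seed, "population"),
                                  spec = spec)
  skulls <- list()
  plans <- list()
  preop_shapes <- list()
  sim_results <- list()
  sim_meta <- list()
  for (i in seq_len(n_patients)) {
    pat <- population[i, ]
    pid <- pat$patient_id
    if (progress) message(sprintf("[%s] simulating (%d/%d)", pid, i, n_patients))
    skull <- build_skull(pat, resolution = resolution)
    plan <- do.call(generate_doe,
                    c(list(pid, seed = derive_seed(master_seed, pid, "doe")),
                      doe_args))
    skulls[[pid]] <- skull
    preop_shapes[[pid]] <- skull$mesh
    plans[[pid]] <- plan
    for (j in seq_len(nrow(plan))) {
      cfg <- config_from_plan(plan[j, ])
      cut <- apply_osteotomy(skull, cfg)
      sim <- simulate_springs(cut, opts = opts)
      cid <- plan$config_id[j]
      sim_results[[cid]] <- sim$postop_mesh
      sim_meta[[cid]] <- tibble::tibble(
        config_id = cid, patient_id = pid,
        opening_ant = sim$openings[["anterior"]],
        opening_post = sim$openings[["posterior"]],
        iterations = sim$iterations, residual = sim$residual)
    }
  }
  plan_all <- dplyr::bind_rows(plans)
  sim_meta <- dplyr::bind_rows(sim_meta)
  template_faces <- skulls[[1]]$mesh$faces
  ssm_in <- build_ssm(preop_shapes, variance_threshold, faces = template_faces)
  ssm_out <- build_ssm(sim_results[plan_all$config_id], variance_threshold,
                       faces = template_faces)
  dataset <- assemble_dataset(ssm_in, ssm_out, plan_all, sim_results,
                              population, preop_shapes)
  corpus <- structure(list(population = population, skulls = skulls,
                           plan = plan_all, sim_meta = sim_meta,
                           ssm_in = ssm_in, ssm_out = ssm_out,
                           dataset = dataset,
                           master_seed = as.integer(master_seed)),
                      class = "sac_corpus")
  if (!is.null(out_dir)) write_corpus(corpus, out_dir)
  corpus
}

#' @export
print.sac_corpus <- function(x, ...) {
  cat(sprintf("<sac_corpus> %d patients, %d simulations | %d input / %d output modes | seed %d\n",
              nrow(x$population), nrow(x$dataset), x$ssm_in$k, x$ssm_out$k,
              x$master_seed))
  invisible(x)
}

#' @rdname run_corpus
#' @param corpus a `sac_corpus`.
#' @param dir output directory.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(corpus$population),
                   file.path(dir, "population.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(corpus$plan), file.path(dir, "plan.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(corpus$dataset), file.path(dir, "dataset.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(corpus$sim_meta), file.path(dir, "sim_meta.csv"),
                   row.names = FALSE)
  write_ssm(corpus$ssm_in, file.path(dir, "ssm_in"))
  write_ssm(corpus$ssm_out, file.path(dir, "ssm_out"))
  jsonlite::write_json(
    list(n_patients = nrow(corpus$population),
         n_simulations = nrow(corpus$dataset),
         master_seed = corpus$master_seed,
         artifacts = c("population.csv", "plan.csv", "dataset.csv",
                       "sim_meta.csv", "ssm_in/", "ssm_out/")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

# scale a feature row with a stored scaler
scale_features <- function(x, scaler, cols) {
  (x - scaler$center[cols]) / scaler$scale[cols]
}

#' Predict a post-operative head shape
#'
#' The real-time prediction path: register the pre-operative head to the
#' template (identity when the mesh already shares the template topology,
#' non-rigid ICP otherwise), strip the soft tissue (inward offset by
#' `t_skin`), project onto the input shape model, assemble and scale the
#' feature row, predict the output mode coefficients with the trained
#' surrogate, reconstruct the post-operative skull and restore the soft
#' tissue by an external offset of `t_skin`.
#'
#' @param preop_mesh pre-operative head `sac_mesh` (template topology, or
#'   any mesh with `register = TRUE`), or a skull mesh with
#'   `t_skin = 0`.
#' @param age_days patient age at surgery (days).
#' @param config a [surgical_config()].
#' @param corpus a `sac_corpus` (supplies both shape models and the
#'   scaler-bearing split is taken from `model`).
#' @param model a `sac_surrogate` trained on the corpus, plus its
#'   `scaler` via the `split` argument.
#' @param split the `sac_split` the model was trained on (for the scaler).
#' @param t_skin soft-tissue thickness in mm (0 when `preop_mesh` is
#'   already a skull).
#' @param register run [nricp()] registration to the template first.
#' @param reference optional known outcome mesh; when given, a surface
#'   error map against the prediction is included.
#' @return a `sac_prediction`: `predicted_mesh` (head surface),
#'   `predicted_skull`, `b_in`, `b_out`, `preop_ci`, `predicted_ci`,
#'   `config`, `error` (a `sac_distance_map` or `NULL`), `timing_s`.
#' @export
predict_outcome <- function(preop_mesh, age_days, config, corpus, model,
                            split, t_skin = 0, register = FALSE,
                            reference = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(inherits(corpus, "sac_corpus"), inherits(model, "sac_surrogate"))
  config <- validate_config(config)
  mesh <- preop_mesh
  if (register) {
    mesh <- nricp(unflatten_shape(corpus$ssm_in$mean_shape, corpus$ssm_in$faces),
                  mesh)$deformed
  }
  skull_mesh <- if (t_skin > 0) offset_mesh(mesh, t_skin, "inward") else mesh
  b_in <- project_shape(corpus$ssm_in, skull_mesh)
  feat <- c(age_days = as.numeric(age_days),
            A = config$A, AP = config$AP, LAT = config$LAT,
            ant_k = config$anterior$k, ant_L0 = config$anterior$L0,
            post_k = config$posterior$k, post_L0 = config$posterior$L0)
  feat <- c(feat, stats::setNames(b_in, paste0("b_in_", seq_along(b_in))))
  if (!setequal(names(feat), split$feature_cols)) {
    stop("feature dimension mismatch vs training metadata: expected ",
         paste(split$feature_cols, collapse = ", "), call. = FALSE)
  }
  xs <- scale_features(feat[split$feature_cols], split$scaler, split$feature_cols)
  b_out_std <- drop(predict(model, matrix(xs, nrow = 1,
                                          dimnames = list(NULL, split$feature_cols))))
  b_out <- b_out_std * split$scaler$scale[split$output_cols] +
    split$scaler$center[split$output_cols]
  skull_post <- reconstruct_shape(corpus$ssm_out, unname(b_out), as_mesh = TRUE)
  head_post <- if (t_skin > 0) offset_mesh(skull_post, t_skin, "outward") else skull_post
  err <- if (!is.null(reference)) surface_distance(head_post, reference) else NULL
  structure(list(predicted_mesh = head_post, predicted_skull = skull_post,
                 b_in = b_in, b_out = unname(b_out),
                 preop_ci = cranial_index(mesh),
                 predicted_ci = cranial_index(head_post),
                 config = config, error = err,
                 timing_s = proc.time()[["elapsed"]] - t0),
            class = "sac_prediction")
}

#' @export
print.sac_prediction <- function(x, ...) {
  cat(sprintf("<sac_prediction> CI %.1f%% -> %.1f%% | %.2f s\n",
              x$preop_ci, x$predicted_ci, x$timing_s))
  if (!is.null(x$error)) {
    cat(sprintf("  vs reference: mean %.2f mm, max %.2f mm\n",
                attr(x$error, "mean"), attr(x$error, "max")))
  }
  invisible(x)
}

#' Validation-style comparison of a prediction with a reference shape
#'
#' The reference (e.g. a follow-up surface acquired later) is first
#' rescaled to the predicted shape's volume — the unchanged-volume
#' normalisation that removes interval growth — then symmetric surface
#' distances are computed and summarised.
#'
#' @param predicted,reference `sac_mesh` objects.
#' @param volume_match rescale the reference to the predicted volume
#'   first.
#' @return a `sac_validation`: tibble of summary stats (mean, p95, max in
#'   both directions) with the two distance maps as attributes.
#' @export
evaluate_validation <- function(predicted, reference, volume_match = TRUE) {
  ref <- if (volume_match) volume_match_scale(reference, predicted) else reference
  d_pr <- surface_distance(predicted, ref)
  d_rp <- surface_distance(ref, predicted)
  out <- tibble::tibble(
    direction = c("predicted_to_reference", "reference_to_predicted"),
    mean_mm = c(attr(d_pr, "mean"), attr(d_rp, "mean")),
    p95_mm = c(attr(d_pr, "p95"), attr(d_rp, "p95")),
    max_mm = c(attr(d_pr, "max"), attr(d_rp, "max")))
  structure(out, class = c("sac_validation", class(out)),
            map_predicted = d_pr, map_reference = d_rp)
}

#' Correlation of prediction error with clinical covariates
#'
#' Pearson correlation between a per-case error measure and each
#' covariate (typically age, pre-operative cranial index and the two
#' spring stiffnesses), with two-sided p-values reported but not
#' thresholded. Zero-variance covariates are reported as undefined.
#'
#' @param data data frame of per-case records.
#' @param error column name of the error measure.
#' @param covariates character vector of covariate column names.
#' @return a tibble: `term`, `r`, `p_value`, `n`, `defined`.
#' @export
correlation_analysis <- function(data, error = "mean_error",
                                 covariates = c("age_days", "preop_ci",
                                                "ant_k", "post_k")) {
  stopifnot(error %in% names(data))
  purrr::map_dfr(covariates, function(cv) {
    x <- data[[cv]]; y <- data[[error]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("need at least 3 paired observations for ", cv,
                             call. = FALSE)
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      return(tibble::tibble(term = cv, r = NA_real_, p_value = NA_real_,
                            n = length(x), defined = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(term = cv, r = unname(ct$estimate),
                   p_value = ct$p.value, n = length(x), defined = TRUE)
  })
}
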