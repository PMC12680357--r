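#' Design of experiments over surgical configurations
#'
#' For one patient, draws a set of surgical configurations spanning the
#' parameter space: the number of configurations is `round(Normal(80, 2.5))`
#' clipped to [75, 85] (reproducing the 80 +/- 5 per-patient band as a
#' 2-sigma envelope); `A`, `AP` and `LAT` are truncated normals centred
#' mid-range with SD = range/4, truncated to the valid bounds
#' (A [0.18, 0.30], AP [0.47, 0.63], LAT [0.10, 0.25]); spring models are
#' drawn uniformly from the 3-model catalogue independently for the
#' anterior and posterior site. Draws with `AP <= A` are rejected and
#' redrawn. Deterministic given `seed`. A Latin-hypercube option gives a
#' space-filling alternative for the three ratios.
#'
#' @param patient one row of [sample_population()] (needs `patient_id`; a
#'   bare id string is also accepted).
#' @param seed integer seed.
#' @param catalogue a [spring_catalogue()].
#' @param count_mean,count_sd,count_range configuration-count distribution.
#' @param method `"normal"` (default) or `"lhs"` (Latin hypercube on the
#'   three ratios).
#' @return a `sac_doe_plan` tibble, one row per configuration:
#'   `patient_id`, `config_id`, `A`, `AP`, `LAT`, `ant_model`, `ant_k`,
#'   `ant_L0`, `post_model`, `post_k`, `post_L0`, `seed`.
#' @examples
#' plan <- generate_doe("P001", seed = 7)
#' nrow(plan)
#' @export
generate_doe <- function(patient, seed = 1L, catalogue = spring_catalogue(),
                         count_mean = 80, count_sd = 2.5,
                         count_range = c(75, 85),
                         method = c("normal", "lhs")) {
  method <- match.arg(method)
  pid <- if (is.character(patient)) patient else as.list(patient)$patient_id
  if (is.null(pid)) stop("patient needs a patient_id", call. = FALSE)
  b <- config_bounds()
  with_seed(seed, {
    n <- as.integer(min(max(round(stats::rnorm(1, count_mean, count_sd)),
                            count_range[1]), count_range[2]))
    if (method == "lhs") {
      U <- lhs::randomLHS(n, 3)
      ratios <- vapply(1:3, function(j) {
        r <- b[[j]]
        r[1] + U[, j] * (r[2] - r[1])
      }, numeric(n))
      colnames(ratios) <- names(b)
      ratios <- as.data.frame(ratios)
      # enforce AP > A (holds automatically: ranges are disjoint)
    } else {
      draw_ratio <- function(r, m) {
        rtruncnorm(m, mean(r), diff(r) / 4, r[1], r[2])
      }
      ratios <- data.frame(A = draw_ratio(b$A, n), AP = draw_ratio(b$AP, n),
                           LAT = draw_ratio(b$LAT, n))
      bad <- which(ratios$AP <= ratios$A)
      while (length(bad) > 0L) {
        ratios$A[bad] <- draw_ratio(b$A, length(bad))
        ratios$AP[bad] <- draw_ratio(b$AP, length(bad))
        bad <- bad[ratios$AP[bad] <= ratios$A[bad]]
      }
    }
    ant <- catalogue[sample.int(nrow(catalogue), n, replace = TRUE), ]
    post <- catalogue[sample.int(nrow(catalogue), n, replace = TRUE), ]
    plan <- tibble::tibble(
      patient_id = pid,
      config_id = sprintf("%s_C%03d", pid, seq_len(n)),
      A = ratios$A, AP = ratios$AP, LAT = ratios$LAT,
      ant_model = ant$model, ant_k = ant$k, ant_L0 = ant$L0,
      post_model = post$model, post_k = post$k, post_L0 = post$L0,
      seed = as.integer(seed))
    class(plan) <- c("sac_doe_plan", class(plan))
    plan
  })
}

#' Turn a DoE plan row into a surgical configuration
#'
#' @param row one row of a `sac_doe_plan`.
#' @return a [surgical_config()].
#' @export
config_from_plan <- function(row) {
  row <- as.list(row)
  surgical_config(
    A = row$A, AP = row$AP, LAT = row$LAT,
    anterior = spring_spec(row$ant_model, k = row$ant_k, L0 = row$ant_L0),
    posterior = spring_spec(row$post_model, k = row$post_k, L0 = row$post_L0))
}

#' @rdname generate_doe
#' @param plan a `sac_doe_plan`.
#' @param path CSV output path.
#' @export
write_doe_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}
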