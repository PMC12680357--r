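#' Spring distractor catalogue and specifications
#'
#' The distractors are stainless-steel Hookean springs with a free (fully
#' expanded) opening of 60 mm: compressed to an opening `x < L0` they push
#' outward with force `k * (L0 - x)` and exert no force once fully open.
#' Three catalogue models are available. The stiffness values shipped here
#' are configurable placeholders (the clinically measured per-model
#' constants are not published with this package); the free length of 60 mm
#' is the real device value.
#'
#' @param models character vector of model names.
#' @param stiffness numeric vector of stiffnesses (N/mm), same length.
#' @param free_length free length(s) in mm.
#' @return `spring_catalogue()`: a tibble with `model`, `k`, `L0`.
#' @export
spring_catalogue <- function(models = c("S10", "S12", "S14"),
                             stiffness = c(0.5, 1.0, 1.5),
                             free_length = 60) {
  if (length(models) != 3L) stop("catalogue must have exactly 3 models", call. = FALSE)
  tibble::tibble(model = models, k = stiffness,
                 L0 = rep_len(free_length, length(models)))
}

#' @rdname spring_catalogue
#' @param model model name to look up, or `NULL` to build a custom spec.
#' @param k stiffness in N/mm (custom spec).
#' @param L0 free length in mm (custom spec).
#' @param catalogue a [spring_catalogue()].
#' @return `spring_spec()`: list with `model`, `k`, `L0`, class `sac_spring`.
#' @export
spring_spec <- function(model = NULL, k = NULL, L0 = 60,
                        catalogue = spring_catalogue()) {
  if (!is.null(model) && is.null(k)) {
    row <- catalogue[catalogue$model == model, ]
    if (nrow(row) != 1L) stop("unknown spring model: ", model, call. = FALSE)
    k <- row$k; L0 <- row$L0
  }
  if (is.null(k) || k <= 0) stop("spring stiffness must be > 0", call. = FALSE)
  if (L0 <= 0) stop("spring free length must be > 0", call. = FALSE)
  structure(list(model = model %||% "custom", k = k, L0 = L0),
            class = "sac_spring")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hookean push-only spring force
#'
#' `F = k * (L0 - opening)` while compressed; zero at and beyond the free
#' length (the spring pushes, never pulls).
#'
#' @param spec a [spring_spec()].
#' @param opening current opening in mm (>= 0); vectorised.
#' @return force in N.
#' @export
spring_force <- function(spec, opening) {
  stopifnot(inherits(spec, "sac_spring"))
  if (any(opening < 0)) stop("opening must be >= 0", call. = FALSE)
  pmax(spec$k * (spec$L0 - opening), 0)
}

#' Closed-form equilibrium opening against a linear tissue stiffness
#'
#' For a spring of stiffness `k` and free length `L0` working against a
#' linear elastic resistance `c * x`, force balance `k (L0 - x) = c x`
#' gives `x* = k L0 / (k + c)`. Used as the analytic oracle for the
#' simulator's condensed force balance.
#'
#' @param spec a [spring_spec()].
#' @param tissue_stiffness condensed tissue stiffness `c` in N/mm (>= 0).
#' @return equilibrium opening in mm.
#' @export
equilibrium_opening <- function(spec, tissue_stiffness) {
  stopifnot(inherits(spec, "sac_spring"))
  if (tissue_stiffness < 0) stop("tissue stiffness must be >= 0", call. = FALSE)
  if (spec$k + tissue_stiffness == 0) stop("degenerate system", call. = FALSE)
  spec$k * spec$L0 / (spec$k + tissue_stiffness)
}

#' Surgical configuration
#'
#' Osteotomy ratios and the spring pair. `A` (anterior notch distance),
#' `AP` (posterior notch distance) and `LAT` (rectangle width) are ratios
#' of the anteroposterior midline arc length from the coronal-suture
#' reference point to the lambdoid suture. Valid ranges: A in [0.18, 0.30],
#' AP in [0.47, 0.63], LAT in [0.10, 0.25], with AP > A.
#'
#' @param A,AP,LAT osteotomy ratios.
#' @param anterior,posterior [spring_spec()] objects (or model names).
#' @param catalogue the spring catalogue used to resolve model names.
#' @return a list of class `sac_config`.
#' @export
surgical_config <- function(A, AP, LAT, anterior = "S12", posterior = "S12",
                            catalogue = spring_catalogue()) {
  if (is.character(anterior)) anterior <- spring_spec(anterior, catalogue = catalogue)
  if (is.character(posterior)) posterior <- spring_spec(posterior, catalogue = catalogue)
  cfg <- structure(list(A = A, AP = AP, LAT = LAT,
                        anterior = anterior, posterior = posterior),
                   class = "sac_config")
  validate_config(cfg)
}

config_bounds <- function() {
  list(A = c(0.18, 0.30), AP = c(0.47, 0.63), LAT = c(0.10, 0.25))
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sac_config"))
  b <- config_bounds()
  for (nm in names(b)) {
    x <- cfg[[nm]]
    if (!is.numeric(x) || x < b[[nm]][1] - 1e-9 || x > b[[nm]][2] + 1e-9) {
      stop(sprintf("%s = %.3f outside [%.2f, %.2f]", nm, x, b[[nm]][1], b[[nm]][2]),
           call. = FALSE)
    }
  }
  stopifnot(inherits(cfg$anterior, "sac_spring"), inherits(cfg$posterior, "sac_spring"))
  cfg
}

#' @export
print.sac_config <- function(x, ...) {
  cat(sprintf("<sac_config> A=%.3f AP=%.3f LAT=%.3f | ant %s (k=%.2f N/mm, L0=%.0f mm) | post %s (k=%.2f, L0=%.0f)\n",
              x$A, x$AP, x$LAT, x$anterior$model, x$anterior$k, x$anterior$L0,
              x$posterior$model, x$posterior$k, x$posterior$L0))
  invisible(x)
}
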