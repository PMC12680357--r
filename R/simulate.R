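#' Solver options for the spring-distraction simulator
#'
#' The simulator minimises `0.5 u' K u - f' u` with
#' `K = alpha * L + beta * I` on the free vertices, where `L` is the
#' 3D-block graph Laplacian of the mesh edges. Per-region edge weights make
#' sutures and the osteotomy band compliant relative to bone (a soft
#' hinge), the skull base ring is clamped (`u = 0`), and the spring forces
#' are coupled to the notch openings by fixed-point iteration.
#'
#' @param alpha0 bone edge weight (N/mm per unit Laplacian) at the
#'   reference age of 174 days; the effective weight scales linearly with
#'   `age_days / 174` (older bone is stiffer).
#' @param beta_frac Tikhonov weight as a fraction of the effective alpha.
#' @param suture_ratio,osteotomy_ratio edge-weight ratios (relative to
#'   bone) for suture bands and the osteotomy band.
#' @param tol convergence tolerance on the notch openings (mm).
#' @param max_iter maximum fixed-point iterations.
#' @param relax relaxation factor on the displacement update.
#' @param clamp if `FALSE` the push-only clamp on the spring force is
#'   disabled (pure Hookean line; used for linearity diagnostics).
#' @param coupling `"linearised"` (default): each fixed-point iteration
#'   solves the force-opening balance exactly for the current separation
#'   directions via unit-force responses and a 2 x 2 condensed system;
#'   `"naive"`: relaxed fixed point with forces evaluated at the current
#'   openings (slower; kept for diagnostics such as one-step linearity).
#' @return a named list of class `sac_solver_options`.
#' @export
solver_options <- function(alpha0 = 0.7, beta_frac = 1e-3,
                           suture_ratio = 0.1, osteotomy_ratio = 0.02,
                           tol = 1e-4, max_iter = 100, relax = 0.6,
                           clamp = TRUE, coupling = c("linearised", "naive")) {
  structure(list(alpha0 = alpha0, beta_frac = beta_frac,
                 suture_ratio = suture_ratio, osteotomy_ratio = osteotomy_ratio,
                 tol = tol, max_iter = max_iter, relax = relax, clamp = clamp,
                 coupling = match.arg(coupling)),
            class = "sac_solver_options")
}

# unique mesh edges with per-edge weights = min over adjacent face weights
weighted_edges <- function(mesh, face_w) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  w <- rep(face_w, 3)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- lo * (nrow(mesh$vertices) + 1) + hi
  o <- order(key)
  key <- key[o]; lo <- lo[o]; hi <- hi[o]; w <- w[o]
  first <- which(!duplicated(key))
  # manifold surface: each edge borders at most 2 faces, so groups are runs
  # of length 1 or 2 in the sorted key
  wmin <- w[first]
  second <- first + 1L
  ok <- second <= length(key) & key[second] == key[first]
  wmin[ok] <- pmin(wmin[ok], w[second[ok]])
  list(i = lo[first], j = hi[first], w = wmin)
}

# stiffness matrix on free vertices + index maps
assemble_system <- function(skull, opts) {
  mesh <- skull$mesh
  n <- nrow(mesh$vertices)
  face_w <- rep(1, nrow(mesh$faces))
  face_w[skull$regions %in% c("coronal_suture", "lambdoid_suture")] <- opts$suture_ratio
  if (!is.null(skull$osteotomy)) face_w[skull$osteotomy] <- opts$osteotomy_ratio
  ed <- weighted_edges(mesh, face_w)
  age <- skull$params$age_days %||% 174
  alpha <- opts$alpha0 * (age / 174)
  Lap <- Matrix::sparseMatrix(
    i = c(ed$i, ed$j, ed$i, ed$j),
    j = c(ed$j, ed$i, ed$i, ed$j),
    x = alpha * c(-ed$w, -ed$w, ed$w, ed$w),
    dims = c(n, n))
  free <- setdiff(seq_len(n), skull$base_ring)
  K <- Lap[free, free, drop = FALSE] +
    Matrix::Diagonal(length(free), opts$beta_frac * alpha)
  list(K = K, free = free, alpha = alpha,
       full_to_free = match(seq_len(n), free))
}

#' Quasi-static spring-distraction simulation
#'
#' Maps a skull with an applied osteotomy and a surgical configuration to
#' the post-operative skull shape. Equal-and-opposite spring forces act at
#' each notch pair along the current lateral separation direction, with
#' magnitudes from [spring_force()] evaluated self-consistently: the linear
#' elastic system is factorised once and the force-opening coupling solved
#' by relaxed fixed-point iteration until the openings change by less than
#' `tol`. Fully deterministic.
#'
#' @param skull a `sac_skull` with the osteotomy applied
#'   (see [apply_osteotomy()]); if `config` is supplied and no osteotomy is
#'   present, it is applied first.
#' @param config optional [surgical_config()] (defaults to the one stored
#'   on the skull).
#' @param opts [solver_options()].
#' @return a `sac_sim_result`: list with `postop_mesh`, `openings`
#'   (anterior, posterior; mm), `displacement` (n x 3, mm), `iterations`,
#'   `converged`, `residual`, plus the condensing `skull` reference info.
#' @export
simulate_springs <- function(skull, config = NULL, opts = solver_options()) {
  stopifnot(inherits(skull, "sac_skull"))
  if (!is.null(config) && is.null(skull$osteotomy)) {
    skull <- apply_osteotomy(skull, config)
  }
  if (is.null(skull$osteotomy)) stop("apply_osteotomy() first", call. = FALSE)
  config <- config %||% skull$config
  sys <- assemble_system(skull, opts)
  ch <- Matrix::Cholesky(sys$K, LDL = FALSE)
  v0 <- skull$mesh$vertices
  n <- nrow(v0)
  pairs <- notch_pairs(skull, config)
  pair_force <- function(f, pr, Fm, dir) {
    f[pr$left, ] <- f[pr$left, , drop = FALSE] -
      matrix(Fm * dir / length(pr$left), length(pr$left), 3, byrow = TRUE)
    f[pr$right, ] <- f[pr$right, , drop = FALSE] +
      matrix(Fm * dir / length(pr$right), length(pr$right), 3, byrow = TRUE)
    f
  }
  solve_free <- function(f) {
    un <- matrix(0, n, 3)
    un[sys$free, ] <- as.matrix(Matrix::solve(ch, f[sys$free, , drop = FALSE]))
    un
  }
  gap <- function(p, pr) anchor_centroid(p, pr$right) - anchor_centroid(p, pr$left)

  u <- matrix(0, n, 3)
  openings_prev <- c(NA_real_, NA_real_)
  iter <- 0L; converged <- FALSE; f <- matrix(0, n, 3)
  while (iter < opts$max_iter) {
    iter <- iter + 1L
    p <- v0 + u
    if (opts$coupling == "linearised") {
      # exact solve of the linear inner problem under current directions:
      # unit-force responses give the 2x2 compliance D, then
      # (I + K D) F = K (L0 - d0), with the push-only clamp re-imposed
      dirs <- lapply(pairs, function(pr) {
        dv <- gap(p, pr); dv / sqrt(sum(dv^2))
      })
      d0 <- vapply(seq_along(pairs), function(i) {
        sum(gap(v0, pairs[[i]]) * dirs[[i]])
      }, numeric(1))
      uresp <- lapply(seq_along(pairs), function(i) {
        solve_free(pair_force(matrix(0, n, 3), pairs[[i]], 1, dirs[[i]]))
      })
      D <- vapply(seq_along(pairs), function(jf) {
        vapply(seq_along(pairs), function(io) {
          sum(gap(uresp[[jf]], pairs[[io]]) * dirs[[io]])
        }, numeric(1))
      }, numeric(length(pairs)))
      kk <- vapply(pairs, function(pr) pr$spec$k, numeric(1))
      LL <- vapply(pairs, function(pr) pr$spec$L0, numeric(1))
      Fv <- solve(diag(2) + kk * D, kk * (LL - d0))
      if (opts$clamp) {
        for (i in which(Fv < 0)) {
          j <- setdiff(1:2, i)
          Fv[i] <- 0
          Fv[j] <- max(kk[j] * (LL[j] - d0[j]) / (1 + kk[j] * D[j, j]), 0)
        }
      }
      u <- Fv[1] * uresp[[1]] + Fv[2] * uresp[[2]]
      f <- pair_force(pair_force(matrix(0, n, 3), pairs[[1]], Fv[1], dirs[[1]]),
                      pairs[[2]], Fv[2], dirs[[2]])
    } else {
      f[] <- 0
      for (pr in pairs) {
        dv <- gap(p, pr)
        d <- sqrt(sum(dv^2))
        Fm <- pr$spec$k * (pr$spec$L0 - d)
        if (opts$clamp) Fm <- max(Fm, 0)
        f <- pair_force(f, pr, Fm, dv / d)
      }
      u <- (1 - opts$relax) * u + opts$relax * solve_free(f)
    }
    p <- v0 + u
    openings <- vapply(pairs, function(pr) sqrt(sum(gap(p, pr)^2)), numeric(1))
    if (all(!is.na(openings_prev)) &&
        max(abs(openings - openings_prev)) < opts$tol && iter > 1L) {
      converged <- TRUE
      break
    }
    openings_prev <- openings
  }
  p <- v0 + u
  openings <- vapply(pairs, function(pr) {
    sqrt(sum((anchor_centroid(p, pr$right) - anchor_centroid(p, pr$left))^2))
  }, numeric(1))
  if (!converged && opts$max_iter > 2L) {
    stop(sprintf("spring coupling did not converge in %d iterations (last opening change %.3g mm)",
                 opts$max_iter, max(abs(openings - openings_prev))), call. = FALSE)
  }
  resid <- as.numeric(
    sqrt(sum((sys$K %*% u[sys$free, , drop = FALSE] - f[sys$free, , drop = FALSE])^2)) /
      max(sqrt(sum(f[sys$free, ]^2)), .Machine$double.eps))
  postop <- skull$mesh
  postop$vertices <- p
  structure(list(postop_mesh = postop, openings = openings,
                 displacement = u, iterations = iter,
                 converged = converged, residual = resid,
                 config = config), class = "sac_sim_result")
}

#' @export
print.sac_sim_result <- function(x, ...) {
  cat(sprintf("<sac_sim_result> openings ant %.1f / post %.1f mm | %d iterations | residual %.2g\n",
              x$openings[["anterior"]], x$openings[["posterior"]],
              x$iterations, x$residual))
  invisible(x)
}

#' Condensed tissue stiffness at a notch pair
#'
#' Static condensation of the assembled elastic system onto one notch pair:
#' a unit equal-and-opposite force pair is applied along the pair's
#' separation direction and the resulting separation increase `delta`
#' measured; the condensed stiffness is `1 / delta` (N/mm). This is the
#' `c` against which the closed-form [equilibrium_opening()] is exact.
#'
#' @param skull a `sac_skull` with osteotomy applied.
#' @param which `"anterior"` or `"posterior"`.
#' @param opts [solver_options()].
#' @return condensed stiffness in N/mm.
#' @export
condensed_stiffness <- function(skull, which = c("anterior", "posterior"),
                                opts = solver_options()) {
  which <- match.arg(which)
  stopifnot(!is.null(skull$osteotomy))
  sys <- assemble_system(skull, opts)
  pr <- notch_pairs(skull, skull$config %||%
                      surgical_config(0.2, 0.5, 0.15))[[which]]
  v0 <- skull$mesh$vertices
  dvec <- anchor_centroid(v0, pr$right) - anchor_centroid(v0, pr$left)
  dir <- dvec / sqrt(sum(dvec^2))
  f <- matrix(0, nrow(v0), 3)
  f[pr$left, ] <- matrix(-dir / length(pr$left), length(pr$left), 3, byrow = TRUE)
  f[pr$right, ] <- matrix(dir / length(pr$right), length(pr$right), 3, byrow = TRUE)
  u <- matrix(0, nrow(v0), 3)
  u[sys$free, ] <- as.matrix(Matrix::solve(sys$K, f[sys$free, , drop = FALSE]))
  delta <- sum((anchor_centroid(u, pr$right) - anchor_centroid(u, pr$left)) * dir)
  1 / delta
}

anchor_centroid <- function(p, idx) {
  if (length(idx) == 1L) p[idx, ] else colMeans(p[idx, , drop = FALSE])
}

notch_pairs <- function(skull, config) {
  an <- skull$notch_anchors
  if (is.null(an)) {
    nv <- skull$notch_vertices
    an <- lapply(nv, identity)
    names(an) <- names(nv)
  }
  list(anterior = list(left = an[["ant_left"]], right = an[["ant_right"]],
                       spec = config$anterior),
       posterior = list(left = an[["post_left"]], right = an[["post_right"]],
                        spec = config$posterior))
}

#' Fixed-point solution of the spring-tissue force balance
#'
#' Solves `x = w0 + F(x) / c` with `F(x) = k (L0 - x)` clamped at zero,
#' by the same relaxed fixed-point iteration the full simulator uses. With
#' `w0 = 0` the solution is the closed form `k L0 / (k + c)`.
#'
#' @param spec a [spring_spec()].
#' @param tissue_stiffness condensed stiffness `c` (N/mm, > 0).
#' @param w0 force-free opening (mm).
#' @param tol,max_iter,relax iteration controls; the default relaxation
#'   `1 / (1 + k/c)` makes the affine map a contraction for any stiffness
#'   ratio.
#' @return the converged opening (mm).
#' @export
fixed_point_opening <- function(spec, tissue_stiffness, w0 = 0,
                                tol = 1e-10, max_iter = 1000, relax = NULL) {
  relax <- relax %||% (1 / (1 + spec$k / tissue_stiffness))
  x <- w0
  for (i in seq_len(max_iter)) {
    x_new <- w0 + spring_force(spec, max(x, 0)) / tissue_stiffness
    if (abs(x_new - x) < tol) return(x_new)
    x <- (1 - relax) * x + relax * x_new
  }
  stop("fixed point did not converge", call. = FALSE)
}
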