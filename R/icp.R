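#' Rigid (optionally similarity) iterative closest point alignment
#'
#' Classic ICP between two meshes: each template vertex is matched to its
#' nearest target vertex, the least-squares rigid transform (Kabsch, or
#' Umeyama when `allow_scale = TRUE`) is estimated, and the process
#' repeats. The mean residual is monotone non-increasing across
#' iterations; iteration stops when it improves by less than `tol` or
#' after `max_iter` rounds.
#'
#' @param template,target `sac_mesh` objects.
#' @param max_iter maximum iterations.
#' @param tol stopping tolerance on the mean residual (mm).
#' @param allow_scale estimate a uniform scale as well.
#' @return list of class `sac_rigid_icp`: `rotation` (3 x 3),
#'   `translation`, `scale`, `aligned` (transformed template mesh),
#'   `residuals` (mean residual per iteration).
#' @export
rigid_icp <- function(template, target, max_iter = 100, tol = 1e-6,
                      allow_scale = FALSE) {
  stopifnot(inherits(template, "sac_mesh"), inherits(target, "sac_mesh"))
  Y <- target$vertices
  sv_y <- svd(sweep(Y, 2, colMeans(Y)))$d
  if (sv_y[2] < 1e-8 * sv_y[1]) {
    stop("degenerate target: points are collinear, alignment is ill-posed",
         call. = FALSE)
  }
  X0 <- template$vertices
  R <- diag(3); tr <- c(0, 0, 0); s <- 1
  residuals <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    X <- sweep(s * (X0 %*% t(R)), 2, tr, `+`)
    sc <- surface_closest(X, target)
    corr <- sc$points
    res <- mean(sc$distance)
    residuals <- c(residuals, res)
    if (prev - res < tol) break
    prev <- res
    tf <- kabsch(X0, corr, allow_scale)
    R <- tf$R; tr <- tf$t; s <- tf$s
  }
  aligned <- template
  aligned$vertices <- sweep(s * (X0 %*% t(R)), 2, tr, `+`)
  structure(list(rotation = R, translation = tr, scale = s,
                 aligned = aligned, residuals = residuals),
            class = "sac_rigid_icp")
}

nearest_vertex_index <- function(P, V) {
  n <- nrow(P)
  out <- integer(n)
  v2 <- rowSums(V^2)
  step <- max(1L, floor(4e6 / nrow(V)))
  for (st in seq(1L, n, by = step)) {
    e <- min(n, st + step - 1L)
    d2 <- outer(rowSums(P[st:e, , drop = FALSE]^2), v2, `+`) -
      2 * P[st:e, , drop = FALSE] %*% t(V)
    out[st:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

# least-squares rigid/similarity transform mapping X onto Y
kabsch <- function(X, Y, allow_scale = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  s <- if (allow_scale) sum(sv$d * c(1, 1, d)) / sum(Xc^2) else 1
  list(R = R, t = cy - s * drop(R %*% cx), s = s)
}

#' Non-rigid ICP template-to-target correspondence
#'
#' Amberg-style non-rigid ICP: every template vertex carries its own 4 x 3
#' affine transform; the energy is a data term (distance of the deformed
#' vertices to their closest target points) plus a stiffness term
#' penalising differences between the transforms of neighbouring vertices,
#' solved as a sparse linear system per stiffness level, from stiff to
#' soft. The result has exactly the template's topology with the target's
#' geometry — the standardised node count on which the shape model is
#' built.
#'
#' @param template,target `sac_mesh` objects.
#' @param stiffness_schedule strictly decreasing positive sequence.
#' @param inner_iter correspondence/solve rounds per stiffness level.
#' @param gamma weight of the translational part in the transform
#'   difference.
#' @param tol inner stopping tolerance on the mean vertex motion (mm).
#' @param rigid_first run [rigid_icp()] for initial alignment.
#' @return a `sac_correspondence`: `deformed` (template topology, target
#'   geometry), `residuals` (per-vertex distance to the target surface),
#'   `mean_residual`, `rigid` (the rigid pre-alignment, or `NULL`),
#'   `schedule`.
#' @export
nricp <- function(template, target, stiffness_schedule = c(50, 20, 5, 2),
                  inner_iter = 10, gamma = 1, tol = 1e-4,
                  rigid_first = TRUE) {
  stopifnot(inherits(template, "sac_mesh"), inherits(target, "sac_mesh"))
  if (length(stiffness_schedule) == 0L || any(stiffness_schedule <= 0) ||
      any(diff(stiffness_schedule) >= 0)) {
    stop("stiffness_schedule must be a strictly decreasing positive sequence",
         call. = FALSE)
  }
  rigid <- NULL
  src <- template
  if (rigid_first) {
    rigid <- rigid_icp(template, target)
    src <- rigid$aligned
  }
  V <- src$vertices
  n <- nrow(V)
  Y <- target$vertices

  # D: n x 4n, row i = [v_i^T 1] in block i
  Dm <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 4),
    j = c(4 * (seq_len(n) - 1) + 1, 4 * (seq_len(n) - 1) + 2,
          4 * (seq_len(n) - 1) + 3, 4 * (seq_len(n) - 1) + 4),
    x = c(V[, 1], V[, 2], V[, 3], rep(1, n)),
    dims = c(n, 4L * n))
  # M: edge incidence (x) diag(1,1,1,gamma)
  f <- src$faces
  e <- unique(rbind(
    cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
    cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
    cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))))
  ne <- nrow(e)
  rows <- rep(seq_len(4L * ne), 2)
  g <- rep(c(1, 1, 1, gamma), ne)
  cols_i <- as.vector(t(outer(4 * (e[, 1] - 1), 1:4, `+`)))
  cols_j <- as.vector(t(outer(4 * (e[, 2] - 1), 1:4, `+`)))
  Mm <- Matrix::sparseMatrix(
    i = rows, j = c(cols_i, cols_j), x = c(g, -g),
    dims = c(4L * ne, 4L * n))
  MtM <- Matrix::crossprod(Mm)
  DtD <- Matrix::crossprod(Dm)

  # identity initialisation
  X <- do.call(rbind, replicate(n, rbind(diag(3), c(0, 0, 0)), simplify = FALSE))
  Vd <- as.matrix(Dm %*% X)
  for (lev in seq_along(stiffness_schedule)) {
    alpha <- stiffness_schedule[lev]
    for (it in seq_len(inner_iter)) {
      nn <- nearest_vertex_index(Vd, Y)
      U <- Y[nn, , drop = FALSE]
      A <- alpha^2 * MtM + DtD
      rhs <- Matrix::crossprod(Dm, U)
      X_new <- tryCatch(as.matrix(Matrix::solve(A, rhs)),
                        error = function(e) {
                          stop(sprintf("NRICP solve failed at stiffness level %d (alpha=%g): %s",
                                       lev, alpha, conditionMessage(e)), call. = FALSE)
                        })
      Vd_new <- as.matrix(Dm %*% X_new)
      moved <- mean(sqrt(rowSums((Vd_new - Vd)^2)))
      X <- X_new; Vd <- Vd_new
      if (moved < tol) break
    }
  }
  deformed <- template
  deformed$vertices <- Vd
  dmap <- surface_distance(deformed, target)
  structure(list(deformed = deformed,
                 residuals = dmap$distance_mm,
                 mean_residual = attr(dmap, "mean"),
                 rigid = rigid,
                 schedule = stiffness_schedule),
            class = "sac_correspondence")
}

#' @export
print.sac_correspondence <- function(x, ...) {
  cat(sprintf("<sac_correspondence> %d template vertices | mean residual %.4f mm\n",
              nrow(x$deformed$vertices), x$mean_residual))
  invisible(x)
}
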