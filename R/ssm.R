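#' Stack shapes into a shape matrix
#'
#' Columns are shape vectors (`x1,y1,z1,...`) of meshes sharing one
#' topology.
#'
#' @param shapes a list of `sac_mesh` objects (shared topology) or of
#'   numeric shape vectors, or a ready 3N x n matrix.
#' @param ids optional shape ids (defaults to names or indices).
#' @return a 3N x n numeric matrix with column names.
#' @export
shape_matrix <- function(shapes, ids = NULL) {
  if (is.matrix(shapes)) {
    M <- shapes
  } else {
    cols <- lapply(shapes, function(s) {
      if (inherits(s, "sac_mesh")) flatten_shape(s) else as.numeric(s)
    })
    len <- vapply(cols, length, integer(1))
    if (length(unique(len)) != 1L) {
      stop("shape vectors have mismatched lengths", call. = FALSE)
    }
    M <- do.call(cbind, cols)
  }
  ids <- ids %||% colnames(M) %||% as.character(seq_len(ncol(M)))
  colnames(M) <- ids
  M
}

#' Build a statistical shape model
#'
#' PCA on corresponding shape vectors: the mean shape is the column mean,
#' deviations `d_i = m_i - mean` form the deviation matrix, and the
#' eigenpairs of the sample covariance (divisor `n - 1`) are obtained
#' through the thin SVD of the deviation matrix (via its `n x n` Gram
#' matrix when `3N > n` — mathematically identical to the dense
#' eigendecomposition, at a fraction of the cost). The number of retained
#' modes `k` is the smallest count whose cumulative explained-variance
#' fraction reaches `variance_threshold` (default 0.94). Eigenvector signs
#' are fixed so each mode's largest-magnitude entry is positive.
#'
#' @param shapes input for [shape_matrix()].
#' @param variance_threshold fraction in (0, 1].
#' @param faces optional face array of the shared topology (kept for
#'   reconstruction to meshes).
#' @return a `sac_ssm`: `mean_shape` (3N), `modes` (3N x m, all nonzero
#'   modes, orthonormal), `eigenvalues` (length m, descending),
#'   `explained` (fractions summing to 1), `k` (retained count),
#'   `variance_threshold`, `n_shapes`, `n_nodes`, `faces`.
#' @examples
#' m <- mesh_icosphere(10, 1)
#' shapes <- lapply(c(9, 10, 11), function(r) {
#'   s <- m; s$vertices <- s$vertices * (r / 10); s
#' })
#' ssm <- build_ssm(shapes, faces = m$faces)
#' ssm$explained
#' @export
build_ssm <- function(shapes, variance_threshold = 0.94, faces = NULL) {
  M <- shape_matrix(shapes)
  n <- ncol(M)
  if (n < 2L) stop("need at least 2 shapes", call. = FALSE)
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1) {
    stop("variance_threshold must be in (0, 1]", call. = FALSE)
  }
  mbar <- rowMeans(M)
  Dm <- M - mbar
  p <- nrow(M)
  if (p > n) {
    G <- crossprod(Dm) / (n - 1)          # n x n Gram dual
    eg <- eigen(G, symmetric = TRUE)
    lam <- eg$values
    keep <- lam > max(lam[1], 0) * 1e-12
    lam <- lam[keep]
    Phi <- Dm %*% eg$vectors[, keep, drop = FALSE]
    Phi <- sweep(Phi, 2, sqrt(lam * (n - 1)), `/`)
  } else {
    sv <- svd(Dm)
    lam <- sv$d^2 / (n - 1)
    keep <- lam > max(lam[1], 0) * 1e-12
    lam <- lam[keep]
    Phi <- sv$u[, keep, drop = FALSE]
  }
  # reproducible sign: largest-magnitude entry of each mode positive
  for (j in seq_len(ncol(Phi))) {
    if (Phi[which.max(abs(Phi[, j])), j] < 0) Phi[, j] <- -Phi[, j]
  }
  explained <- lam / sum(lam)
  k <- which(cumsum(explained) >= variance_threshold - 1e-12)[1]
  structure(list(mean_shape = mbar, modes = Phi, eigenvalues = lam,
                 explained = explained, k = k,
                 variance_threshold = variance_threshold,
                 n_shapes = n, n_nodes = p / 3, faces = faces,
                 ids = colnames(M)),
            class = "sac_ssm")
}

#' @export
print.sac_ssm <- function(x, ...) {
  cat(sprintf("<sac_ssm> %d shapes, %d nodes | %d/%d modes retained at %.0f%% variance\n",
              x$n_shapes, x$n_nodes, x$k, length(x$eigenvalues),
              100 * x$variance_threshold))
  invisible(x)
}

#' Project a shape onto the model's modes
#'
#' `b = Phi^T (m - mean)`: the low-dimensional mode coefficients of a
#' shape in the model basis.
#'
#' @param model a `sac_ssm`.
#' @param shape a `sac_mesh`, shape vector, or matrix of shape columns.
#' @param n_modes number of coefficients (default: the retained `k`).
#' @return numeric vector of length `n_modes` (or a matrix, one column per
#'   input column).
#' @export
project_shape <- function(model, shape, n_modes = model$k) {
  stopifnot(inherits(model, "sac_ssm"))
  m <- if (inherits(shape, "sac_mesh")) flatten_shape(shape) else shape
  if (is.matrix(m)) {
    if (nrow(m) != length(model$mean_shape)) stop("shape length mismatch", call. = FALSE)
    return(crossprod(model$modes[, seq_len(n_modes), drop = FALSE], m - model$mean_shape))
  }
  if (length(m) != length(model$mean_shape)) stop("shape length mismatch", call. = FALSE)
  drop(crossprod(model$modes[, seq_len(n_modes), drop = FALSE],
                 as.numeric(m) - model$mean_shape))
}

#' Reconstruct a shape from mode coefficients
#'
#' `m = mean + Phi b`. Fewer coefficients than retained modes are allowed
#' (higher modes set to zero); more than the model holds is an error.
#'
#' @param model a `sac_ssm`.
#' @param b coefficient vector.
#' @param as_mesh return a `sac_mesh` (requires `faces` stored on the
#'   model).
#' @return shape vector of length 3N, or a `sac_mesh`.
#' @export
reconstruct_shape <- function(model, b, as_mesh = FALSE) {
  stopifnot(inherits(model, "sac_ssm"))
  if (length(b) > ncol(model$modes)) {
    stop("more coefficients than available modes", call. = FALSE)
  }
  out <- model$mean_shape
  if (length(b) > 0) {
    out <- out + drop(model$modes[, seq_along(b), drop = FALSE] %*% b)
  }
  if (as_mesh) {
    if (is.null(model$faces)) stop("model stores no face array", call. = FALSE)
    return(unflatten_shape(out, model$faces))
  }
  out
}

#' Tidy the mode spectrum of a shape model
#'
#' @param x a `sac_ssm`.
#' @param ... unused.
#' @return tibble with `mode`, `eigenvalue`, `explained`, `cumulative`,
#'   `retained`.
#' @export
tidy.sac_ssm <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    explained = x$explained,
    cumulative = cumsum(x$explained),
    retained = seq_along(x$eigenvalues) <= x$k)
}

#' @rdname tidy.sac_ssm
#' @param object a `sac_ssm`.
#' @export
glance.sac_ssm <- function(object, ...) {
  tibble::tibble(n_shapes = object$n_shapes, n_nodes = object$n_nodes,
                 n_modes = length(object$eigenvalues), k = object$k,
                 variance_threshold = object$variance_threshold,
                 variance_at_k = cumsum(object$explained)[object$k])
}

#' Explained-variance CDF plot for a shape model
#'
#' @param object a `sac_ssm`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sac_ssm <- function(object, ...) {
  df <- tidy.sac_ssm(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$retained), size = 1.5) +
    ggplot2::geom_hline(yintercept = object$variance_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "mode", y = "cumulative explained variance",
                  colour = "retained") +
    ggplot2::theme_minimal()
}

#' Serialise / load a shape model as a plain-text directory
#'
#' Writes `mean.stl` (when a face array is stored), `modes.csv`
#' (eigenvectors), `eigenvalues.csv` and `meta.json`.
#'
#' @param model a `sac_ssm`.
#' @param dir directory path.
#' @return the directory, invisibly (`write_ssm`); a `sac_ssm`
#'   (`read_ssm`).
#' @export
write_ssm <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(model$faces)) {
    write_stl(unflatten_shape(model$mean_shape, model$faces),
              file.path(dir, "mean.stl"))
  }
  utils::write.csv(as.data.frame(model$modes), file.path(dir, "modes.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(eigenvalue = model$eigenvalues),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = model$k, variance_threshold = model$variance_threshold,
         n_shapes = model$n_shapes, n_nodes = model$n_nodes,
         mean_shape = model$mean_shape,
         faces = model$faces),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ssm
#' @export
read_ssm <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  modes <- as.matrix(utils::read.csv(file.path(dir, "modes.csv")))
  dimnames(modes) <- NULL
  lam <- utils::read.csv(file.path(dir, "eigenvalues.csv"))$eigenvalue
  structure(list(mean_shape = as.numeric(meta$mean_shape), modes = modes,
                 eigenvalues = lam, explained = lam / sum(lam),
                 k = meta$k, variance_threshold = meta$variance_threshold,
                 n_shapes = meta$n_shapes, n_nodes = meta$n_nodes,
                 faces = if (!is.null(meta$faces)) matrix(as.integer(meta$faces),
                                                          ncol = 3) else NULL,
                 ids = NULL),
            class = "sac_ssm")
}
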