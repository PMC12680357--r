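#' Population specification for synthetic patients
#'
#' Defines the sampling distributions for a synthetic population of infants
#' with sagittal craniosynostosis. Defaults encode the study conditions:
#' skull thickness 2.02 +/- 0.33 mm, soft-tissue (skin) thickness
#' 3.42 +/- 0.51 mm, age 174 +/- 35 days (about 5.8 +/- 1.15 months,
#' truncated to 90-300 days), and an ellipsoidal neurocranium whose
#' semi-axes and scaphocephalic elongation produce pre-operative cranial
#' indices around 70 percent.
#'
#' Each entry is `c(mean, sd, min, max)` (use `-Inf`/`Inf` for open ends).
#'
#' @param ... named overrides, e.g. `t_skull = c(2.5, 0.2, 0.5, Inf)`.
#' @param json optional path to a JSON file of overrides with the same names.
#' @return a named list of length-4 numeric vectors, class `sac_population_spec`.
#' @export
population_spec <- function(..., json = NULL) {
  spec <- list(
    age_days   = c(174, 35, 90, 300),
    t_skull    = c(2.02, 0.33, 0.5, Inf),
    t_skin     = c(3.42, 0.51, 1.0, Inf),
    width_sa   = c(58, 2.5, 45, 75),
    length_sa  = c(64, 3.0, 50, 85),
    height_sa  = c(55, 2.5, 42, 70),
    elongation = c(1.18, 0.06, 1.05, 1.45))
  if (!is.null(json)) {
    ov <- jsonlite::read_json(json, simplifyVector = TRUE)
    for (nm in names(ov)) spec[[nm]] <- as.numeric(ov[[nm]])
  }
  dots <- list(...)
  for (nm in names(dots)) spec[[nm]] <- as.numeric(dots[[nm]])
  bad <- vapply(spec, function(x) length(x) != 4L || x[2] < 0, logical(1))
  if (any(bad)) stop("spec entries must be c(mean, sd, min, max): ",
                     paste(names(spec)[bad], collapse = ", "), call. = FALSE)
  structure(spec, class = "sac_population_spec")
}

# run code under a seed, restoring RNG state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(out[bad], lo), hi)
  out
}

#' Sample a synthetic patient population
#'
#' Draws `n` patients from the population specification: truncated-normal
#' skull/skin thicknesses, age in days, ellipsoid semi-axes and
#' scaphocephaly elongation. Deterministic given `seed`.
#'
#' @param n number of patients (>= 1).
#' @param seed integer seed.
#' @param spec a [population_spec()].
#' @return a tibble with one row per patient: `patient_id`, `age_days`,
#'   `t_skull`, `t_skin`, `width_sa`, `length_sa`, `height_sa`,
#'   `elongation`, `seed`.
#' @examples
#' pop <- sample_population(5, seed = 1)
#' pop$t_skull
#' @export
sample_population <- function(n, seed = 1L, spec = population_spec()) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  draw <- function(p) rtruncnorm(n, p[1], p[2], p[3], p[4])
  with_seed(seed, {
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      age_days = as.integer(pmin(pmax(round(draw(spec$age_days)),
                                      spec$age_days[3]), spec$age_days[4])),
      t_skull = draw(spec$t_skull),
      t_skin = draw(spec$t_skin),
      width_sa = draw(spec$width_sa),
      length_sa = draw(spec$length_sa),
      height_sa = draw(spec$height_sa),
      elongation = pmax(draw(spec$elongation), 1),
      seed = as.integer(seed))
  })
}

# mesh resolution -> hemisphere grid dimensions (sectors even, for midline
# and midsagittal symmetry)
hemisphere_grid <- function(resolution) {
  n_stacks <- max(8L, as.integer(round(sqrt(resolution / 1.6))))
  # multiple of 4 so the anterior/posterior and both lateral poles are vertices
  n_sectors <- 4L * max(3L, as.integer(round(resolution / (4 * n_stacks))))
  list(n_stacks = n_stacks, n_sectors = n_sectors)
}

#' Build a synthetic scaphocephalic skull model
#'
#' The neurocranium is the upper half of an ellipsoid cut at the
#' nasion-tragion analogue plane z = 0, in the anatomical frame
#' (x lateral, y anteroposterior with anterior positive, z superior).
#' Scaphocephaly is applied as a volume-preserving severity transform:
#' the anteroposterior semi-axis is multiplied by `elongation` and the
#' lateral and vertical semi-axes by `1/sqrt(elongation)`, so the cranial
#' index scales as `1/elongation^1.5` while the enclosed volume is
#' unchanged. Coronal and lambdoid suture bands (2 mm declared width,
#' widened to the local edge length where the mesh is coarser) are placed
#' at fixed fractions of the anteroposterior extent from the anterior pole,
#' and a reference point is set at the centre of the coronal suture on the
#' midline. Mesh topology is identical for every patient at a given
#' resolution, so correspondence across the population holds by
#' construction.
#'
#' @param params one row of [sample_population()] (or a list with the same
#'   fields).
#' @param resolution approximate vertex count (default 2000).
#' @param suture_fractions fractions of the anteroposterior extent, from the
#'   anterior pole, at which the coronal and lambdoid sutures sit.
#' @param suture_width declared suture band width in mm.
#' @return a `sac_skull`: list with `mesh`, `regions` (per-face factor:
#'   frontal, coronal_suture, parietal, lambdoid_suture, occipital),
#'   `reference_point`, `base_ring`, `semi_axes`, `suture_y`, `params`.
#' @export
build_skull <- function(params, resolution = 2000,
                        suture_fractions = c(coronal = 0.30, lambdoid = 0.85),
                        suture_width = 2, base_cut = 0.35) {
  params <- as.list(params)
  e <- params$elongation
  stopifnot(e >= 1, params$t_skull > 0, params$t_skin > 0)
  a <- params$width_sa / sqrt(e)
  b <- params$length_sa * e
  c_ <- params$height_sa / sqrt(e)

  # the base plane sits below the ellipsoid equator (the head is widest
  # above the skull base), at z_ellipsoid = -base_cut * c
  theta_min <- asin(-base_cut)
  z_offset <- -c_ * sin(theta_min)
  g <- hemisphere_grid(resolution)
  ns <- g$n_sectors; nst <- g$n_stacks
  theta <- theta_min + (seq_len(nst) - 1) / nst * (pi / 2 - theta_min)
  phi <- (seq_len(ns) - 1) / ns * 2 * pi
  ct <- rep(cos(theta), each = ns); st <- rep(sin(theta), each = ns)
  sp <- rep(sin(phi), nst); cp <- rep(cos(phi), nst)
  v <- cbind(a * ct * sp, b * ct * cp, c_ * st + z_offset)
  v <- rbind(v, c(0, 0, c_ + z_offset))           # apex
  apex <- nrow(v)

  idx <- function(i, j) (i - 1L) * ns + ((j - 1L) %% ns) + 1L
  i_grid <- rep(seq_len(nst - 1L), each = ns)
  j_grid <- rep(seq_len(ns), nst - 1L)
  q1 <- idx(i_grid, j_grid); q2 <- idx(i_grid, j_grid + 1L)
  q3 <- idx(i_grid + 1L, j_grid + 1L); q4 <- idx(i_grid + 1L, j_grid)
  f <- rbind(cbind(q1, q2, q3), cbind(q1, q3, q4),
             cbind(idx(nst, seq_len(ns)), idx(nst, seq_len(ns) + 1L), apex))
  mesh <- triangle_mesh(v, f)

  # suture bands from face-centroid anteroposterior position
  cent <- face_centroids(mesh)
  y_max <- max(v[, 2]); y_ext <- y_max - min(v[, 2])
  y_cor <- y_max - suture_fractions[["coronal"]] * y_ext
  y_lam <- y_max - suture_fractions[["lambdoid"]] * y_ext
  med_edge <- stats::median(edge_lengths(mesh))
  hw <- max(suture_width / 2, 0.55 * med_edge)
  regions <- rep("parietal", nrow(mesh$faces))
  regions[cent[, 2] > y_cor + hw] <- "frontal"
  regions[cent[, 2] < y_lam - hw] <- "occipital"
  regions[abs(cent[, 2] - y_cor) <= hw] <- "coronal_suture"
  regions[abs(cent[, 2] - y_lam) <= hw] <- "lambdoid_suture"
  regions <- factor(regions, levels = c("frontal", "coronal_suture", "parietal",
                                        "lambdoid_suture", "occipital"))

  ref <- c(0, y_cor, c_ * sqrt(max(0, 1 - (y_cor / b)^2)) + z_offset)
  structure(list(
    mesh = mesh,
    regions = regions,
    reference_point = ref,
    base_ring = seq_len(ns),
    semi_axes = c(x = a, y = b, z = c_),
    z_offset = z_offset,
    base_cut = base_cut,
    suture_y = c(coronal = y_cor, lambdoid = y_lam),
    notch_sites = NULL,
    osteotomy = NULL,
    config = NULL,
    params = params), class = "sac_skull")
}

#' @export
print.sac_skull <- function(x, ...) {
  cat(sprintf("<sac_skull> %d vertices | CI %.1f%% | semi-axes %.1f x %.1f x %.1f mm\n",
              nrow(x$mesh$vertices), cranial_index(x$mesh),
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  if (!is.null(x$config)) {
    cat(sprintf("  osteotomy A=%.2f AP=%.2f LAT=%.2f, springs %s/%s\n",
                x$config$A, x$config$AP, x$config$LAT,
                x$config$anterior$model, x$config$posterior$model))
  }
  invisible(x)
}

face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
     mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

edge_lengths <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  c(sqrt(rowSums((v[f[, 1], ] - v[f[, 2], ])^2)),
    sqrt(rowSums((v[f[, 2], ] - v[f[, 3], ])^2)),
    sqrt(rowSums((v[f[, 3], ] - v[f[, 1], ])^2)))
}

# arc length along the midsagittal midline ellipse y = b cos t, z = c sin t,
# from the anterior pole (t = 0); returns interpolating functions both ways
midline_arc <- function(b, c_, n_grid = 4000) {
  t_grid <- seq(0, pi, length.out = n_grid + 1)
  dy <- -b * sin(t_grid); dz <- c_ * cos(t_grid)
  speed <- sqrt(dy^2 + dz^2)
  s_grid <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2 * diff(t_grid)))
  list(
    s_of_t = stats::approxfun(t_grid, s_grid, rule = 2),
    t_of_s = stats::approxfun(s_grid, t_grid, rule = 2))
}

# arc length along the cross-section ellipse x = Ax sin(psi), z = Az cos(psi)
# from the top (psi = 0); vectorised Simpson over a fixed refinement
lateral_arc <- function(psi, Ax, Az, n_sub = 16L) {
  k <- seq(0, 1, length.out = n_sub + 1)
  P <- outer(psi, k)                     # points x sub-nodes
  speed <- sqrt(Ax^2 * cos(P)^2 + Az^2 * sin(P)^2)
  w <- rep(c(2, 4), length.out = n_sub + 1); w[1] <- 1; w[n_sub + 1] <- 1
  (psi / n_sub / 3) * drop(speed %*% w)
}

# invert lateral_arc: psi such that arc = target
lateral_arc_inverse <- function(target, Ax, Az) {
  quarter <- lateral_arc(pi / 2, Ax, Az)
  if (target > quarter) {
    stop("osteotomy half-width exceeds the lateral quarter-arc", call. = FALSE)
  }
  stats::uniroot(function(p) lateral_arc(p, Ax, Az) - target,
                 c(0, pi / 2), tol = 1e-10)$root
}

#' Mark the parietal osteotomy and spring notch sites
#'
#' Outlines the osteotomy rectangle on the skull: distances are measured as
#' arc length along the midsagittal surface midline from the coronal-suture
#' reference point, in units of `L`, the midline arc length from the
#' reference point to the lambdoid suture. The anterior notch pair sits at
#' `A * L`, the posterior pair at `AP * L`, each pair separated laterally by
#' `LAT * L` of cross-sectional arc (half-width each side of the midline).
#' Faces inside the rectangle are flagged (the simulator softens them; bone
#' is not removed), and four notch marks of 5 mm diameter are recorded at
#' the corners.
#'
#' @param skull a `sac_skull` from [build_skull()].
#' @param config a [surgical_config()].
#' @param notch_diameter notch mark diameter in mm.
#' @param validate enforce the clinical parameter box (disable only for
#'   diagnostic geometries).
#' @return the skull with `osteotomy` (per-face logical), `notch_sites`
#'   (4 x 3 matrix: ant_left, ant_right, post_left, post_right),
#'   `notch_vertices`, `notch_faces`, `osteotomy_L` and `config` filled in.
#' @export
apply_osteotomy <- function(skull, config, notch_diameter = 5, validate = TRUE) {
  stopifnot(inherits(skull, "sac_skull"))
  if (config$AP <= config$A) {
    stop("AP must exceed A: posterior notches cannot sit anterior to the anterior pair",
         call. = FALSE)
  }
  if (validate) config <- validate_config(config)
  b <- skull$semi_axes[["y"]]; c_ <- skull$semi_axes[["z"]]
  a <- skull$semi_axes[["x"]]
  arc <- midline_arc(b, c_)
  t_ref <- acos(min(1, max(-1, skull$suture_y[["coronal"]] / b)))
  t_lam <- acos(min(1, max(-1, skull$suture_y[["lambdoid"]] / b)))
  s_ref <- arc$s_of_t(t_ref)
  L <- arc$s_of_t(t_lam) - s_ref

  notch_at <- function(s_frac, side) {
    t_s <- arc$t_of_s(s_ref + s_frac * L)
    y_s <- b * cos(t_s)
    Ax <- a * sqrt(max(0, 1 - (y_s / b)^2))
    Az <- c_ * sqrt(max(0, 1 - (y_s / b)^2))
    psi <- lateral_arc_inverse(config$LAT * L / 2, Ax, Az)
    c(side * Ax * sin(psi), y_s, Az * cos(psi) + (skull$z_offset %||% 0))
  }
  sites <- rbind(
    ant_left = notch_at(config$A, -1), ant_right = notch_at(config$A, 1),
    post_left = notch_at(config$AP, -1), post_right = notch_at(config$AP, 1))

  v <- skull$mesh$vertices
  notch_vertices <- apply(sites, 1, function(p) {
    which.min(colSums((t(v) - p)^2))
  })

  # per-face (s, lateral-arc) coordinates for rectangle marking
  cent <- face_centroids(skull$mesh)
  t_c <- acos(pmin(1, pmax(-1, cent[, 2] / b)))
  s_c <- arc$s_of_t(t_c) - s_ref
  frac <- sqrt(pmax(1e-9, 1 - (cent[, 2] / b)^2))
  Axc <- a * frac; Azc <- c_ * frac
  psi_c <- atan2(abs(cent[, 1]) / Axc,
                 pmax(cent[, 3] - (skull$z_offset %||% 0), 0) / Azc)
  ell_c <- lateral_arc_varaxes(psi_c, Axc, Azc)
  half <- config$LAT * L / 2
  med_edge <- stats::median(edge_lengths(skull$mesh))
  inside <- s_c >= config$A * L - 0.25 * med_edge &
    s_c <= config$AP * L + 0.25 * med_edge & ell_c <= half + 0.25 * med_edge

  notch_faces <- lapply(seq_len(nrow(sites)), function(k) {
    which(sqrt(colSums((t(cent) - sites[k, ])^2)) <= notch_diameter / 2)
  })
  names(notch_faces) <- rownames(sites)

  # the spring feet anchor in bone: faces at/around the drilled notches stay
  # stiff even where they overlap the rectangle
  for (k in seq_len(nrow(sites))) {
    near <- sqrt(colSums((t(cent) - sites[k, ])^2)) <= notch_diameter
    inside[near] <- FALSE
  }
  # anchor vertex sets: vertices of the notch-mark faces (fallback: nearest
  # vertex when the mark is finer than the mesh)
  notch_anchors <- lapply(seq_len(nrow(sites)), function(k) {
    fa <- which(sqrt(colSums((t(cent) - sites[k, ])^2)) <= notch_diameter / 2)
    vs <- unique(as.vector(skull$mesh$faces[fa, ]))
    if (length(vs) == 0L) vs <- notch_vertices[k]
    vs
  })
  names(notch_anchors) <- rownames(sites)

  skull$notch_anchors <- notch_anchors
  skull$notch_sites <- sites
  skull$notch_vertices <- notch_vertices
  skull$notch_faces <- notch_faces
  skull$osteotomy <- inside
  skull$osteotomy_L <- unname(L)
  skull$config <- config
  skull
}

# lateral arc with per-element axes (Simpson, vectorised over faces)
lateral_arc_varaxes <- function(psi, Ax, Az, n_sub = 16L) {
  k <- seq(0, 1, length.out = n_sub + 1)
  P <- outer(psi, k)
  speed <- sqrt((Ax^2) * cos(P)^2 + (Az^2) * sin(P)^2)
  w <- rep(c(2, 4), length.out = n_sub + 1); w[1] <- 1; w[n_sub + 1] <- 1
  (psi / n_sub / 3) * drop(speed %*% w)
}

#' Export skull region labels
#'
#' @param skull a `sac_skull`.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_region_labels <- function(skull, path) {
  df <- data.frame(face_index = seq_along(skull$regions),
                   label = as.character(skull$regions))
  if (!is.null(skull$osteotomy)) df$osteotomy <- skull$osteotomy
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
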