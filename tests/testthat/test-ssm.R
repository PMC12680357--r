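# shapes with an exactly prescribed sample covariance spectrum: orthonormal
# Helmert contrasts give mean-zero, mutually orthogonal coefficient rows
shapes_with_spectrum <- function(lambdas, p = 30, seed = 1) {
  n <- length(lambdas) + 1L
  H <- stats::contr.helmert(n)                       # n x (n-1), orthogonal cols
  H <- sweep(H, 2, sqrt(colSums(H^2)), `/`)          # unit columns, mean zero
  C <- sweep(H, 2, sqrt(lambdas * (n - 1)), `*`)     # col j has sample var lambda_j
  U <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(p * (n - 1)), p))))
  M <- U %*% t(C) + 5                                # constant mean offset
  M
}

test_that("explained fractions follow the eigenvalue ratios", {
  M <- shapes_with_spectrum(c(3, 1))
  ssm <- build_ssm(M, variance_threshold = 0.94)
  expect_equal(ssm$eigenvalues, c(3, 1), tolerance = 1e-10)
  expect_equal(ssm$explained, c(0.75, 0.25), tolerance = 1e-10)
})

test_that("mode retention is the smallest count crossing the variance threshold", {
  M <- shapes_with_spectrum(c(0.5, 0.3, 0.15, 0.05))
  expect_equal(build_ssm(M, 0.94)$k, 3)
  expect_equal(build_ssm(M, 0.80)$k, 2)
  expect_equal(build_ssm(M, 0.95)$k, 3)
  expect_equal(build_ssm(M, 0.96)$k, 4)
  # threshold 1 retains the full rank
  expect_equal(build_ssm(M, 1.0)$k, 4)
})

test_that("thin-SVD eigenpairs match the dense covariance eigendecomposition", {
  M <- with_seed(33, matrix(stats::rnorm(12 * 5), 12, 5) * 2 + 1)
  ssm <- build_ssm(M, 1.0)
  # dense oracle on the explicit 12 x 12 covariance
  Dm <- M - rowMeans(M)
  Cv <- Dm %*% t(Dm) / (ncol(M) - 1)
  eg <- eigen(Cv, symmetric = TRUE)
  nz <- seq_along(ssm$eigenvalues)
  expect_lt(max(abs(ssm$eigenvalues - eg$values[nz])), 1e-8)
  for (j in nz) {
    expect_lt(abs(abs(sum(ssm$modes[, j] * eg$vectors[, j])) - 1), 1e-8)
  }
  # orthonormality
  expect_lt(max(abs(crossprod(ssm$modes) - diag(length(nz)))), 1e-8)
})

test_that("projection and reconstruction invert each other at full rank", {
  M <- with_seed(7, matrix(stats::rnorm(24 * 6), 24, 6) + 10)
  ssm <- build_ssm(M, 1.0)
  # projecting the mean gives zero
  expect_lt(max(abs(project_shape(ssm, ssm$mean_shape))), 1e-10)
  # mean + 2 phi_1 projects to (2, 0, ...)
  b <- project_shape(ssm, ssm$mean_shape + 2 * ssm$modes[, 1])
  expect_equal(b[1], 2, tolerance = 1e-10)
  expect_lt(max(abs(b[-1])), 1e-10)
  # every training shape reconstructs exactly with all modes
  for (i in seq_len(ncol(M))) {
    rec <- reconstruct_shape(ssm, project_shape(ssm, M[, i]))
    expect_lt(max(abs(rec - M[, i])), 1e-8)
  }
  # b = 0 reconstructs the mean; opposite coefficients mirror about it
  expect_equal(reconstruct_shape(ssm, numeric(0)), ssm$mean_shape)
  up <- reconstruct_shape(ssm, c(sqrt(ssm$eigenvalues[1])))
  dn <- reconstruct_shape(ssm, c(-sqrt(ssm$eigenvalues[1])))
  expect_equal((up + dn) / 2, ssm$mean_shape, tolerance = 1e-10)
})

test_that("training-set mode coefficients have sample variance lambda_i", {
  M <- with_seed(13, matrix(stats::rnorm(30 * 8), 30, 8) * 3)
  ssm <- build_ssm(M, 1.0)
  B <- project_shape(ssm, M, n_modes = length(ssm$eigenvalues))
  v <- apply(B, 1, stats::var)
  expect_equal(v, ssm$eigenvalues, tolerance = 1e-8)
})

test_that("reconstruction error is monotone non-increasing in retained modes", {
  M <- with_seed(99, matrix(stats::rnorm(18 * 7), 18, 7))
  ssm <- build_ssm(M, 1.0)
  errs <- vapply(seq_along(ssm$eigenvalues), function(k) {
    mean(vapply(seq_len(ncol(M)), function(i) {
      b <- project_shape(ssm, M[, i], n_modes = k)
      sqrt(mean((reconstruct_shape(ssm, b) - M[, i])^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("the explained-variance CDF is a proper CDF and input is validated", {
  M <- shapes_with_spectrum(c(2, 1, 0.5))
  ssm <- build_ssm(M)
  cdf <- cumsum(ssm$explained)
  expect_true(all(diff(cdf) >= 0))
  expect_equal(utils::tail(cdf, 1), 1, tolerance = 1e-10)
  expect_error(build_ssm(M[, 1, drop = FALSE]), "at least 2")
  expect_error(build_ssm(M, 0), "in \\(0, 1\\]")
  expect_error(build_ssm(list(rnorm(6), rnorm(9))), "mismatched")
  expect_error(reconstruct_shape(ssm, rep(0, 10)), "more coefficients")
  expect_error(project_shape(ssm, rnorm(5)), "length mismatch")
})

test_that("eigenvector signs are reproducible and meshes roundtrip through SSM", {
  m <- mesh_icosphere(10, 1)
  shapes <- lapply(c(0.9, 1, 1.1, 1.2), function(s) {
    sc <- m; sc$vertices <- sc$vertices * s; sc
  })
  s1 <- build_ssm(shapes, faces = m$faces)
  s2 <- build_ssm(rev(shapes), faces = m$faces)
  # same spectrum regardless of input order; fixed sign convention
  expect_equal(s1$eigenvalues, s2$eigenvalues, tolerance = 1e-10)
  expect_equal(s1$modes[, 1], s2$modes[, 1], tolerance = 1e-8)
  expect_gt(s1$modes[which.max(abs(s1$modes[, 1])), 1], 0)
  rec <- reconstruct_shape(s1, project_shape(s1, shapes[[2]]), as_mesh = TRUE)
  expect_lt(max(abs(rec$vertices - shapes[[2]]$vertices)), 1e-8)
})

test_that("SSM serialisation roundtrips through the plain-text directory", {
  m <- mesh_icosphere(10, 1)
  shapes <- lapply(c(0.9, 1, 1.15), function(s) {
    sc <- m; sc$vertices <- sc$vertices * s; sc
  })
  ssm <- build_ssm(shapes, faces = m$faces)
  d <- withr::local_tempdir()
  write_ssm(ssm, d)
  expect_true(all(file.exists(file.path(d, c("mean.stl", "modes.csv",
                                             "eigenvalues.csv", "meta.json")))))
  back <- read_ssm(d)
  expect_equal(back$k, ssm$k)
  expect_equal(back$mean_shape, ssm$mean_shape, tolerance = 1e-9)
  expect_equal(back$modes, ssm$modes, tolerance = 1e-9)
  expect_equal(back$eigenvalues, ssm$eigenvalues, tolerance = 1e-9)
  expect_identical(back$faces, ssm$faces)
  # tidy/glance/autoplot interfaces
  td <- tidy(ssm)
  expect_equal(nrow(td), length(ssm$eigenvalues))
  expect_s3_class(autoplot(ssm), "ggplot")
  expect_equal(glance(ssm)$k, ssm$k)
})
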