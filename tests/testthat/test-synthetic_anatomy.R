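test_that("population sampling recovers the configured thickness means", {
  pop <- sample_population(1000, seed = 101)
  expect_equal(mean(pop$t_skull), 2.02, tolerance = 0.05 / 2.02)
  expect_equal(mean(pop$t_skin), 3.42, tolerance = 0.08 / 3.42)
  expect_true(all(pop$t_skull > 0.5))
  expect_true(all(pop$t_skin > 1))
  expect_true(all(pop$age_days >= 90 & pop$age_days <= 300))
  expect_true(all(pop$elongation >= 1))
})

test_that("population sampling is deterministic and validates input", {
  expect_identical(sample_population(50, seed = 7), sample_population(50, seed = 7))
  expect_false(identical(sample_population(50, seed = 7),
                         sample_population(50, seed = 8)))
  expect_error(sample_population(0), ">= 1")
  expect_error(population_spec(t_skull = c(2, 0.3)), "mean, sd, min, max")
})

test_that("population spec JSON overrides are honoured", {
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(t_skull = c(2.5, 0.1, 0.5, 10)), p)
  pop <- sample_population(400, seed = 1, spec = population_spec(json = p))
  expect_equal(mean(pop$t_skull), 2.5, tolerance = 0.02)
})

test_that("built skulls have a complete region partition and anatomical landmarks", {
  sk <- test_skull()
  expect_s3_class(sk, "sac_skull")
  expect_setequal(levels(sk$regions),
                  c("frontal", "coronal_suture", "parietal", "lambdoid_suture",
                    "occipital"))
  expect_false(anyNA(sk$regions))                     # every face labelled once
  expect_true(all(table(sk$regions) > 0))             # all five present
  expect_equal(length(sk$regions), nrow(sk$mesh$faces))
  # reference point sits on the coronal band and on the midline
  expect_equal(sk$reference_point[1], 0, tolerance = 1e-9)
  expect_equal(sk$reference_point[2], unname(sk$suture_y["coronal"]),
               tolerance = 1e-9)
  # base ring is at z = 0
  expect_lt(max(abs(sk$mesh$vertices[sk$base_ring, 3])), 1e-9)
})

test_that("skulls are midsagittally symmetric and share topology across patients", {
  pop <- sample_population(2, seed = 3)
  s1 <- build_skull(pop[1, ], resolution = 700)
  s2 <- build_skull(pop[2, ], resolution = 700)
  expect_identical(s1$mesh$faces, s2$mesh$faces)
  # reflection x -> -x maps the vertex set onto itself
  v <- s1$mesh$vertices
  refl <- v; refl[, 1] <- -refl[, 1]
  nn <- sacshape:::nearest_vertex_index(refl, v)
  expect_lt(max(sqrt(rowSums((refl - v[nn, ])^2))), 1e-9)
})

test_that("scaphocephalic elongation follows the CI ~ e^-1.5 law at constant volume", {
  pat <- as.list(test_patient())
  pat$elongation <- 1
  base <- build_skull(pat, resolution = 900)
  ci0 <- cranial_index(base$mesh)
  expect_equal(ci0, 100 * pat$width_sa / pat$length_sa, tolerance = 1e-6)
  pat2 <- pat; pat2$elongation <- 1.25
  elong <- build_skull(pat2, resolution = 900)
  expect_equal(cranial_index(elong$mesh), ci0 / 1.25^1.5,
               tolerance = 0.02 * ci0 / 1.25^1.5)
  suppressWarnings({
    v0 <- as.numeric(mesh_volume(base$mesh))
    v1 <- as.numeric(mesh_volume(elong$mesh))
  })
  expect_equal(v1, v0, tolerance = 0.005 * v0)
  # CI decreases monotonically with severity
  cis <- vapply(c(1, 1.1, 1.2, 1.3, 1.4), function(e) {
    p <- pat; p$elongation <- e
    cranial_index(build_skull(p, resolution = 500)$mesh)
  }, numeric(1))
  expect_true(all(diff(cis) < 0))
})

test_that("osteotomy notches land at the prescribed arc-length ratios", {
  sk <- test_skull(resolution = 1600)
  cfg <- surgical_config(0.18, 0.63, 0.10)
  cut <- apply_osteotomy(sk, cfg)
  L <- cut$osteotomy_L

  # independent oracle: dense polyline arc length along the midline ellipse
  b <- sk$semi_axes[["y"]]; cc <- sk$semi_axes[["z"]]
  t_grid <- seq(0, pi, length.out = 20001)
  pts <- cbind(b * cos(t_grid), cc * sin(t_grid))
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  arc_to <- function(y) {
    t_y <- acos(min(1, max(-1, y / b)))
    cum[which.min(abs(t_grid - t_y))]
  }
  L_oracle <- arc_to(sk$suture_y[["lambdoid"]]) - arc_to(sk$suture_y[["coronal"]])
  expect_equal(L, L_oracle, tolerance = 1e-4 * L_oracle)
  s_ant <- arc_to(cut$notch_sites["ant_left", 2]) - arc_to(sk$suture_y[["coronal"]])
  s_post <- arc_to(cut$notch_sites["post_left", 2]) - arc_to(sk$suture_y[["coronal"]])
  expect_equal(s_ant, 0.18 * L, tolerance = 0.005 * L)
  expect_equal(s_post, 0.63 * L, tolerance = 0.005 * L)

  # lateral width: dense sampling of the cross-section ellipse
  z_off <- sk$z_offset
  y_s <- cut$notch_sites["ant_left", 2]
  fr <- sqrt(1 - (y_s / b)^2)
  Ax <- sk$semi_axes[["x"]] * fr; Az <- cc * fr
  psi <- seq(0, pi / 2, length.out = 20001)
  xs <- Ax * sin(psi); zs <- Az * cos(psi)
  cuml <- c(0, cumsum(sqrt(diff(xs)^2 + diff(zs)^2)))
  psi_notch <- atan2(cut$notch_sites["ant_right", 1] / Ax,
                     (cut$notch_sites["ant_right", 3] - z_off) / Az)
  half_arc <- cuml[which.min(abs(psi - psi_notch))]
  expect_equal(2 * half_arc, cfg$LAT * L, tolerance = 0.005 * L)
})

test_that("osteotomy rejects a posterior pair at or before the anterior pair", {
  sk <- test_skull()
  cfg <- surgical_config(0.25, 0.5, 0.15)
  cfg$AP <- 0.25
  expect_error(apply_osteotomy(sk, cfg), "AP must exceed A")
  cfg$AP <- 0.20
  expect_error(apply_osteotomy(sk, cfg), "AP must exceed A")
})

test_that("notch marks span about 5 mm and osteotomy faces stay on the vault", {
  sk <- test_skull(resolution = 1600)
  cut <- apply_osteotomy(sk, surgical_config(0.22, 0.55, 0.18))
  cent <- sacshape:::face_centroids(sk$mesh)
  for (nm in names(cut$notch_faces)) {
    fa <- cut$notch_faces[[nm]]
    if (length(fa) >= 2) {
      spread <- max(stats::dist(cent[fa, , drop = FALSE]))
      expect_lt(spread, 5 + 2 * stats::median(sacshape:::edge_lengths(sk$mesh)))
    }
  }
  expect_gt(sum(cut$osteotomy), 0)
  # flagged faces lie between the suture bands (parietal territory)
  expect_true(all(cent[cut$osteotomy, 2] < sk$suture_y[["coronal"]] + 5))
  expect_true(all(cent[cut$osteotomy, 2] > sk$suture_y[["lambdoid"]] - 5))
  # region labels are untouched by the overlay
  expect_identical(cut$regions, sk$regions)
})

test_that("surgical config enforces the valid parameter box", {
  expect_error(surgical_config(0.17, 0.5, 0.15), "A = ")
  expect_error(surgical_config(0.2, 0.65, 0.15), "AP = ")
  expect_error(surgical_config(0.2, 0.5, 0.26), "LAT = ")
  cfg <- surgical_config(0.18, 0.63, 0.25)
  expect_s3_class(cfg, "sac_config")
})

test_that("region labels export as CSV", {
  sk <- test_skull()
  p <- withr::local_tempfile(fileext = ".csv")
  write_region_labels(sk, p)
  df <- utils::read.csv(p)
  expect_equal(nrow(df), nrow(sk$mesh$faces))
  expect_setequal(unique(df$label), levels(sk$regions))
})
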