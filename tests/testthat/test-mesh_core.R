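test_that("STL write/read roundtrips preserve geometry and topology", {
  tet <- mesh_tetrahedron()
  pb <- withr::local_tempfile(fileext = ".stl")
  pa <- withr::local_tempfile(fileext = ".stl")
  write_stl(tet, pb, format = "binary")
  write_stl(tet, pa, format = "ascii")
  rb <- read_stl(pb)
  ra <- read_stl(pa)
  expect_equal(nrow(rb$vertices), 4)
  expect_equal(nrow(rb$faces), 4)
  # vertex sets identical up to ordering induced by the triangle soup
  expect_equal(dim(ra$vertices), dim(rb$vertices))
  expect_lt(max(abs(sort(as.vector(ra$vertices)) -
                      sort(as.vector(rb$vertices)))), 1e-6)
  # float32 precision on a larger mesh
  sph <- mesh_icosphere(50, 2)
  write_stl(sph, pb, format = "binary")
  r2 <- read_stl(pb)
  expect_equal(nrow(r2$vertices), nrow(sph$vertices))
  expect_lt(max(abs(sort(as.vector(r2$vertices)) -
                      sort(as.vector(sph$vertices)))), 1e-4)
})

test_that("malformed and degenerate STL input is rejected with a clear error", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid empty", "endsolid empty"), p)
  expect_error(read_stl(p), "0 triangles")
  # truncated binary: header says 10 triangles, file ends early
  con <- file(p, "wb")
  writeBin(charToRaw(sprintf("%-80s", "binary junk")), con)
  writeBin(10L, con, size = 4, endian = "little")
  writeBin(raw(60), con)
  close(con)
  expect_error(read_stl(p), "byte")
})

test_that("flatten/unflatten is an exact bijection with x1,y1,z1 ordering", {
  expect_equal(
    as.numeric(flatten_shape(triangle_mesh(rbind(c(1, 2, 3), c(4, 5, 6), c(0, 0, 1)),
                                           rbind(c(1, 2, 3))))),
    c(1, 2, 3, 4, 5, 6, 0, 0, 1))
  for (s in 1:5) {
    m <- with_seed(s, {
      v <- matrix(stats::rnorm(300), 100)
      triangle_mesh(v, cbind(1:98, 2:99, 3:100))
    })
    back <- unflatten_shape(flatten_shape(m), m$faces)
    expect_identical(back$vertices, m$vertices)
    expect_identical(back$faces, m$faces)
  }
})

test_that("surface distance is exact point-to-triangle, not point-to-vertex", {
  # brute-force oracle: dense barycentric sampling of one triangle
  tri_v <- rbind(c(0, -3, -1), c(0, 4, -2), c(0, 0, 5))
  ref <- triangle_mesh(tri_v, rbind(c(1, 2, 3)))
  set.seed(42)
  g <- expand.grid(u = seq(0, 1, length.out = 400), v = seq(0, 1, length.out = 400))
  g <- g[g$u + g$v <= 1, ]
  dense <- cbind(0, 0, 0) # placeholder
  dense <- t(tri_v[1, ] + outer(tri_v[2, ] - tri_v[1, ], g$u) +
               outer(tri_v[3, ] - tri_v[1, ], g$v))
  for (q in list(c(10, 0, 0), c(5, 5, 5), c(-2, -10, 0), c(1, 0.5, 0.5))) {
    qm <- triangle_mesh(rbind(q, q + c(1e-3, 0, 0), q + c(0, 1e-3, 0)),
                        rbind(c(1, 2, 3)))
    d <- unname(surface_distance(qm, ref)$distance_mm[1])
    oracle <- min(sqrt(rowSums(sweep(dense, 2, q)^2)))
    expect_equal(d, oracle, tolerance = 1e-3)
    expect_lte(d, oracle + 1e-9)   # exact distance can only undercut sampling
  }
})

test_that("surface distance: zero on identical meshes, ~2 mm between concentric spheres", {
  s50 <- mesh_icosphere(50, 3)
  expect_equal(max(surface_distance(s50, s50)$distance_mm), 0, tolerance = 1e-9)
  d <- surface_distance(s50, mesh_icosphere(52, 3))
  expect_equal(attr(d, "mean"), 2, tolerance = 0.01 * 2)
  expect_true(all(d$distance_mm >= 0))
  expect_lte(attr(d, "mean"), attr(d, "max"))
})

test_that("cranial index follows extents, symmetry and scaling laws", {
  ell <- mesh_ellipsoid(c(50, 62.5, 45), 3)
  expect_equal(cranial_index(ell), 80, tolerance = 1e-9)
  expect_equal(cranial_index(mesh_icosphere(10, 2)), 100, tolerance = 1e-9)
  # y-elongation by 1.25 divides CI by 1.25
  ell2 <- ell; ell2$vertices[, 2] <- ell2$vertices[, 2] * 1.25
  expect_equal(cranial_index(ell2), 80 / 1.25, tolerance = 1e-9)
  # invariance under uniform scaling and translation
  ell3 <- ell; ell3$vertices <- ell3$vertices * 3.7 + 11
  expect_equal(cranial_index(ell3), cranial_index(ell), tolerance = 1e-12)
})

test_that("mesh volume: exact on cube, 1% on icosphere, orientation-proof, scales as s^3", {
  cube <- mesh_box()
  expect_equal(as.numeric(mesh_volume(cube)), 1, tolerance = 1e-12)
  inv <- cube; inv$faces <- inv$faces[, c(1, 3, 2)]
  expect_equal(as.numeric(mesh_volume(inv)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(mesh_volume(mesh_icosphere(10, 4))), 4188.79,
               tolerance = 0.01 * 4188.79)
  for (s in c(0.5, 2, 3.3)) {
    sc <- cube; sc$vertices <- sc$vertices * s
    expect_equal(as.numeric(mesh_volume(sc)), s^3, tolerance = 1e-9)
  }
  # open mesh warns and flags the value
  open_m <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_warning(v <- mesh_volume(open_m), "not closed")
  expect_false(attr(v, "reliable"))
})

test_that("normal offset matches the analytic sphere offset and roundtrips", {
  s <- mesh_icosphere(50, 3)
  inward <- offset_mesh(s, 3.42, "inward")
  r <- sqrt(rowSums(inward$vertices^2))
  expect_lt(max(abs(r - 46.58)), 0.02 * 3.42)
  expect_identical(offset_mesh(s, 0, "outward")$vertices, s$vertices)
  back <- offset_mesh(offset_mesh(s, 2.02, "inward"), 2.02, "outward")
  expect_lt(attr(surface_distance(back, s), "mean"), 0.05)
  expect_error(offset_mesh(s, -1), ">= 0")
})

test_that("volume matching rescales by the cube-root law", {
  cube <- mesh_box()
  big <- cube; big$vertices <- big$vertices * 2     # 8x the volume
  out <- volume_match_scale(big, cube)
  expect_equal(as.numeric(mesh_volume(out)), 1, tolerance = 1e-3)
  expect_equal(diff(range(out$vertices[, 1])), 1, tolerance = 1e-9)
  same <- volume_match_scale(cube, cube)
  expect_lt(max(abs(same$vertices - cube$vertices)), 1e-12)
  m <- volume_match_scale(mesh_icosphere(10, 3), mesh_icosphere(12, 3))
  expect_equal(mean(sqrt(rowSums(m$vertices^2))), 12, tolerance = 0.001 * 12)
})

test_that("mesh construction enforces the core invariants", {
  expect_error(triangle_mesh(rbind(c(0, 0, 0)), rbind(c(1, 1, 2))), "out of range|degenerate")
  expect_error(triangle_mesh(rbind(c(0, 0, NA), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 2, 3))), "finite")
  # zero-area faces are dropped at construction
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0)),
                     rbind(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(nrow(m$faces), 1)
})

test_that("distance maps export to CSV and PLY", {
  s <- mesh_icosphere(10, 1)
  d <- surface_distance(s, mesh_icosphere(11, 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  ply <- withr::local_tempfile(fileext = ".ply")
  export_distance_map(d, csv_path = csv, ply_path = ply, mesh = s)
  got <- utils::read.csv(csv)
  expect_equal(got$distance_mm, d$distance_mm, tolerance = 1e-9)
  expect_match(readLines(ply, n = 1), "^ply$")
  expect_s3_class(autoplot(d), "ggplot")
})
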