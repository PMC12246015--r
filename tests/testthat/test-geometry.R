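test_that("build_layout expands the lattice with alternating orientations", {
  layout <- build_layout(scaffold_spec(N_H = 7, N_V = 9, step = 0))
  expect_equal(nrow(layout), 63)                       # 9 layers x 7 strands
  ori <- tapply(layout$orientation, layout$layer, unique)
  expect_equal(as.vector(ori), rep(c(0, 90), length.out = 9))
  expect_equal(as.vector(table(layout$layer)), rep(7L, 9))
  # chord endpoints lie on the envelope circle
  expect_equal(layout$x0^2 + layout$y0^2, rep(25, 63), tolerance = 1e-12)
  # stack is vertically centred: layer heights symmetric about H/2
  expect_equal(sort(unique(layout$z)) + rev(sort(unique(layout$z))),
               rep(4.8, 9))
})

test_that("single-layer and tangent-chord edge cases behave", {
  one <- build_layout(scaffold_spec(N_H = 5, N_V = 1))
  expect_equal(unique(one$layer), 1)
  expect_equal(unique(one$orientation), 0)
  expect_equal(unique(one$z), 4.8 / 2)                # mid-height
  # outermost strands at exactly the envelope radius are excluded
  tang <- suppressWarnings(
    build_layout(scaffold_spec(N_H = 3, N_V = 2, Y = 5, h = 2.4,
                               D_strand = 0.7)))
  expect_equal(nrow(tang), 2)                         # only the axis strands
  expect_true(all(tang$offset == 0))
})

test_that("scaffold_spec rejects invalid geometry", {
  expect_error(scaffold_spec(N_H = 1, N_V = 9), "at least 2")
  expect_error(scaffold_spec(N_H = 20, N_V = 9), "pore window")  # Y <= D
  expect_error(scaffold_spec(N_H = 7, N_V = 9, h = 1), "exceeds H_scaffold")
  expect_error(scaffold_spec(N_H = 7, N_V = 0), "must be > 0")
})

test_that("voxel porosity matches the analytic clipped-cylinder volume", {
  fx <- single_strand_fixture()
  # independent oracle: 2D integral of chord x vertical extent, frozen
  v_exact <- 7.84415184657
  m <- pore_metrics(fx$layout, resolution = 0.025)
  v_voxel <- m$solid_volume
  expect_lt(abs(v_voxel - v_exact) / v_exact, 0.003)
  expect_equal(m$porosity, 1 - v_exact / (pi * 25 * 10), tolerance = 0.003)
  expect_equal(m$porosity, 0.99, tolerance = 0.001)
  # Monte-Carlo estimator agrees within 4 standard errors, reproducibly
  mc <- pore_metrics(fx$layout, method = "montecarlo", n_samples = 2e5,
                     seed = 3)
  mc2 <- pore_metrics(fx$layout, method = "montecarlo", n_samples = 2e5,
                      seed = 3)
  expect_identical(mc$porosity, mc2$porosity)
  expect_lt(abs(mc$porosity - m$porosity), 4 * mc$se + 1e-6)
})

test_that("porosity guards: empty layout and coarse resolution", {
  expect_warning(m <- pore_metrics(empty_layout()), "porosity is 1")
  expect_equal(m$porosity, 1)
  expect_error(pore_metrics(build_layout(original_scaffold()),
                            resolution = 0.1), "too coarse")
})

test_that("porosity converges under refinement and decreases with N_H", {
  specs <- lapply(6:10, function(nh) scaffold_spec(nh, 9, step = 1))
  p50 <- vapply(specs, function(s)
    pore_metrics(build_layout(s), resolution = 0.05)$porosity, numeric(1))
  expect_true(all(diff(p50) < 0))                     # strictly decreasing
  p25 <- pore_metrics(build_layout(specs[[3]]), resolution = 0.025)$porosity
  expect_lt(abs(p25 - p50[3]), 0.005)                 # < 0.5 points
})

test_that("pore diameter follows the window formula and scales linearly", {
  # formula inversion: gap of sqrt(pi)/2 mm gives exactly 1000 um
  s <- scaffold_spec(N_H = 5, N_V = 9, D_strand = 0.7,
                     Y = 0.7 + sqrt(pi) / 2)
  expect_equal(pore_equivalent_diameter(s), 1000)
  base <- scaffold_spec(9, 9)
  for (k in c(0.5, 2, 3.7)) {
    scaled <- suppressWarnings(
      scaffold_spec(9, 9, D_scaffold = k * 10, D_strand = k * 0.7,
                    Y = k * base$Y))
    expect_equal(pore_equivalent_diameter(scaled),
                 k * pore_equivalent_diameter(base), tolerance = 1e-12)
  }
})

test_that("mesh export writes readable STL and VTK tubes", {
  fx <- single_strand_fixture()
  stl <- tempfile(fileext = ".stl")
  vtk <- tempfile(fileext = ".vtk")
  on.exit(unlink(c(stl, vtk)), add = TRUE)
  out <- export_mesh(fx$layout, stl, format = "stl", n_segments = 64)
  # analytic capped-tube area: pi*D*chord + 2 caps
  a_exact <- pi * 1 * 10 + 2 * pi * 0.5^2
  expect_equal(out$area, a_exact, tolerance = 0.01)
  lines <- readLines(stl)
  expect_match(lines[1], "^solid")
  expect_equal(sum(grepl("^facet", lines)), out$n_triangles)

  out2 <- export_mesh(build_layout(scaffold_spec(7, 9, step = 0)), vtk,
                      format = "vtk", n_segments = 8)
  expect_equal(out2$n_strands, 63)
  head <- readLines(vtk, n = 5)
  expect_match(head[4], "POLYDATA")

  expect_error(export_mesh(fx$layout, stl, format = "obj"),
               "supported formats: stl, vtk")
  expect_error(export_mesh(empty_layout(), stl), "empty")
})
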