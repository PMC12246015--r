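test_that("surface mesh: conformal weights, junction scores, guards", {
  mesh <- surface_mesh(build_layout(scaffold_spec(7, 9, step = 0)),
                       n_nodes = 1200, seed = 4)
  expect_equal(length(unique(mesh$id)), 1200)
  expect_true(all(mesh$area > 0))
  expect_equal(sum(mesh$area), attr(mesh, "total_area"))
  expect_true(all(mesh$junction >= 0 & mesh$junction <= 1))
  expect_error(surface_mesh(build_layout(scaffold_spec(7, 9)), n_nodes = 50),
               "resolution error")
})

test_that("junction proximity peaks at strand crossings", {
  # single strand: no intersections anywhere
  fx <- single_strand_fixture()
  m1 <- surface_mesh(fx$layout, n_nodes = 300, seed = 1)
  expect_true(all(m1$junction == 0))
  expect_equal(junction_load_index(fx$layout), 0)
  # two crossed strands: single junction at the origin-axis crossing
  spec <- scaffold_spec(N_H = 2, N_V = 2, D_scaffold = 10, H_scaffold = 1.2,
                        D_strand = 0.7, Y = 6, h = 0.6, name = "cross")
  cross <- manual_layout(spec, c(0, 0), c(0.3, 0.9), c(0, 90))
  jp <- scaffoldmech:::junction_points(cross)
  expect_equal(nrow(jp), 1)
  expect_equal(unlist(jp), c(x = 0, y = 0, z = 0.6))
  m2 <- surface_mesh(cross, n_nodes = 500, seed = 2)
  top <- m2[which.max(m2$junction), ]
  expect_lt(sqrt(top$x^2 + top$y^2 + (top$z - 0.6)^2), 1.0)
  # denser lattices carry more junction-scored nodes at equal density
  m_h6 <- surface_mesh(build_layout(scaffold_spec(6, 9)), 1000, seed = 5)
  m_h10 <- surface_mesh(build_layout(scaffold_spec(10, 9)), 1000, seed = 5)
  expect_gt(nrow(attr(m_h10, "junctions")), nrow(attr(m_h6, "junctions")))
  expect_gt(mean(m_h10$junction), mean(m_h6$junction))
})

test_that("strain field is linear in compression and zero at rest", {
  mesh <- surface_mesh(build_layout(scaffold_spec(7, 9, step = 0)),
                       n_nodes = 600, seed = 3)
  params <- default_surrogate_params()
  expect_equal(sample_strain_field(mesh, 0, params), rep(0, 600))
  noise <- rep(1, 600)
  f1 <- sample_strain_field(mesh, 0.025, params, node_noise = noise)
  f2 <- sample_strain_field(mesh, 0.05, params, node_noise = noise)
  expect_equal(f2, 2 * f1)
  expect_equal(mean(f2), 2 * mean(f1))
  expect_error(sample_strain_field(mesh, -0.01, params), ">= 0")
})

test_that("WSS field: zero at rest, monotone in speed, porosity effect", {
  params <- default_surrogate_params()
  mk <- function(nh) surface_mesh(build_layout(scaffold_spec(nh, 9)),
                                  600, seed = 6)
  m6 <- mk(6); m10 <- mk(10)
  expect_equal(sample_wss_field(m6, 0, params = params, porosity = 0.58),
               rep(0, 600))
  noise <- rep(1, 600)
  w1 <- sample_wss_field(m6, 0.4, params = params, porosity = 0.58,
                         node_noise = noise)
  w2 <- sample_wss_field(m6, 0.8, params = params, porosity = 0.58,
                         node_noise = noise)
  expect_true(all(w2 > w1))
  # exponent 1 makes the mean exactly linear in piston speed
  lin <- surrogate_params(wss_gain = 1, wss_exponent = 1, sigma = 0)
  l1 <- sample_wss_field(m6, 0.4, params = lin, porosity = 0.58,
                         node_noise = noise)
  l2 <- sample_wss_field(m6, 0.8, params = lin, porosity = 0.58,
                         node_noise = noise)
  expect_equal(l2, 2 * l1)
  # at matched speed the lower-porosity design sees higher mean WSS
  hi <- sample_wss_field(m10, 0.4, params = params, porosity = 0.33,
                         node_noise = noise)
  expect_gt(weighted.mean(hi, m10$area), weighted.mean(w1, m6$area))
  # interior nodes are attenuated relative to the rim
  rho <- sqrt(m6$x^2 + m6$y^2)
  expect_lt(mean(w1[rho < 2]), mean(w1[rho > 4]))
})

test_that("generate_cycle emits conformal, reproducible fields", {
  cyc <- quick_cycle(n_nodes = 500, seed = 21)
  expect_identical(cyc$strain$mesh$id, cyc$wss$mesh$id)
  expect_identical(cyc$strain$mesh$area, cyc$wss$mesh$area)
  expect_identical(cyc$strain$times, cyc$wss$times)
  # rest state at t = 0
  expect_equal(cyc$strain$values[, 1], rep(0, 500))
  expect_equal(cyc$wss$values[, 1], rep(0, 500))
  # OSS mean peaks at mid-cycle, WSS mean at the speed peaks
  oss_t <- colMeans(cyc$strain$values)
  expect_equal(cyc$times[which.max(oss_t)], 0.5)
  wss_t <- colMeans(cyc$wss$values)
  expect_true(cyc$times[which.max(wss_t)] %in% c(0.24, 0.26, 0.74, 0.76,
                                                 0.25, 0.75))
  # determinism under a fixed seed; a new seed changes the draw
  cyc2 <- quick_cycle(n_nodes = 500, seed = 21)
  expect_identical(cyc$strain$values, cyc2$strain$values)
  expect_identical(cyc$wss$values, cyc2$wss$values)
  cyc3 <- quick_cycle(n_nodes = 500, seed = 22)
  expect_false(identical(cyc$strain$values, cyc3$strain$values))
})

test_that("field_series validates shape and sign", {
  cyc <- quick_cycle(n_nodes = 500, seed = 21)
  expect_error(field_series(cyc$strain$values[, 1:3], cyc$times,
                            cyc$mesh, "oss"), "nodes x times")
  bad <- cyc$strain$values; bad[1, 2] <- -1
  expect_error(field_series(bad, cyc$times, cyc$mesh, "oss"), ">= 0")
})

test_that("Reynolds number based on the strand diameter", {
  spec <- original_scaffold()
  expect_equal(reynolds_number(0, spec), 0)
  # u ~ 3.1 mm/s with default fluid gives Re ~ 1.5
  expect_equal(reynolds_number(3.1e-3, spec), 1.4966, tolerance = 1e-4)
  thick <- scaffold_spec(7, 9, D_strand = 1.4, Y = 10 / 7)
  expect_equal(reynolds_number(3.1e-3, thick),
               2 * reynolds_number(3.1e-3, spec))
  expect_error(reynolds_number(-1, spec), ">= 0")
})

test_that("nodal field CSV round-trips and is bit-reproducible", {
  cyc <- quick_cycle(n_nodes = 150, seed = 8, timestep = 0.1)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)), add = TRUE)
  write_field_csv(cyc, f1, config_hash = "abc123")
  expect_error(write_field_csv(cyc, f1), "overwrite")
  # identical seed + parameters give a bit-identical file
  write_field_csv(quick_cycle(n_nodes = 150, seed = 8, timestep = 0.1), f2)
  expect_identical(readLines(f1)[-5], readLines(f2)[-5])  # hash line aside
  back <- read_field_csv(f1)
  expect_equal(back$design, cyc$design)
  expect_equal(back$seed, cyc$seed)
  expect_equal(back$config_hash, "abc123")
  expect_equal(back$strain$times, cyc$times)
  expect_equal(back$strain$values, cyc$strain$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$wss$values, cyc$wss$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$strain$mesh$area, cyc$mesh$area, tolerance = 1e-12)
  # schema major-version gate
  txt <- readLines(f1)
  txt[1] <- "# scaffoldmech nodal field schema 2.0"
  writeLines(txt, f2)
  expect_error(read_field_csv(f2), "schema version")
})
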