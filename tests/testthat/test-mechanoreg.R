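test_that("stimulus combines the two channels linearly", {
  expect_equal(stimulus(0, 0), 0)
  expect_equal(stimulus(0.0375, 10), 2)       # both terms equal 1
  expect_equal(stimulus(0.045, 14.76), 2.676) # step-2 peak averages
  set.seed(1)
  for (i in 1:25) {
    oss <- runif(1, 0, 0.1); wss <- runif(1, 0, 30); k <- runif(1, 0, 5)
    expect_equal(stimulus(k * oss, k * wss), k * stimulus(oss, wss))
  }
  expect_error(stimulus(-0.01, 1), ">= 0")
})

test_that("phenotype classification matches the threshold partition", {
  expect_equal(as.character(classify_phenotype(0.005)), "very_low")
  expect_equal(as.character(classify_phenotype(6.5)), "very_high")
  # inclusive upper bounds: the threshold belongs to the lower class
  lv <- phenotype_levels()
  for (i in seq_along(c(0.01, 1, 3, 6))) {
    th <- c(0.01, 1, 3, 6)[i]
    expect_equal(as.character(classify_phenotype(th)), lv[i])
    expect_equal(as.character(classify_phenotype(th + 1e-9)), lv[i + 1])
  }
  expect_error(classify_phenotype(NaN), "classification error")
})

test_that("conformal node matching: identity, tolerance, offenders", {
  nodes <- data.frame(id = 1:20, x = runif(20), y = runif(20),
                      z = runif(20))
  mp <- match_nodes(nodes, nodes)
  expect_equal(mp$fe_id, mp$cfd_id)
  # sub-tolerance perturbation keeps the same pairing
  jig <- nodes
  jig$x <- jig$x + 1e-8
  mp2 <- match_nodes(nodes, jig, tolerance = 1e-6)
  expect_equal(sort(mp2$fe_id), 1:20)
  expect_equal(mp2$fe_id, mp2$cfd_id)
  # an extra node is reported by id
  extra <- rbind(jig, data.frame(id = 99, x = 5, y = 5, z = 5))
  expect_error(match_nodes(nodes, extra, tolerance = 1e-6), "99")
  expect_error(match_nodes(nodes, transform(nodes, x = x + 1)),
               "conformality error")
})

test_that("averaged series: arithmetic OSS mean, area-weighted WSS mean", {
  spec <- scaffold_spec(2, 1, D_scaffold = 10, H_scaffold = 10,
                        D_strand = 1, Y = 5, h = 10, name = "toy")
  mesh <- manual_mesh(spec, areas = c(1, 3))
  times <- c(0, 0.5)
  strain <- field_series(matrix(c(0, 0, 0.02, 0.04), 2), times, mesh, "oss")
  wss <- field_series(matrix(c(0, 0, 4, 0), 2), times, mesh, "wss")
  ser <- averaged_series(strain, wss)
  expect_s3_class(ser, "stimulus_series")
  expect_equal(ser$oss_avg, c(0, 0.03))       # ignores area weights
  expect_equal(ser$wss_avg, c(0, 1))          # (1*4 + 3*0) / 4
  expect_equal(ser$s_avg, ser$oss_avg / 0.0375 + ser$wss_avg / 10)
  # all-zero fields give a flat zero series
  z <- field_series(matrix(0, 2, 2), times, mesh, "oss")
  zw <- field_series(matrix(0, 2, 2), times, mesh, "wss")
  expect_equal(averaged_series(z, zw)$s_avg, c(0, 0))
  # mismatched time grids are rejected
  wss_bad <- field_series(matrix(c(0, 0, 4, 0), 2), c(0, 0.6), mesh, "wss")
  expect_error(averaged_series(strain, wss_bad), "time grids")
})

test_that("S_Max detection splits the cycle and breaks ties late", {
  mk <- function(s, t = seq(0, 1, length.out = length(s))) {
    structure(data.frame(time = t, s_avg = s), class = c("stimulus_series",
                                                         "data.frame"))
  }
  # constant series: both maxima equal the constant
  const <- mk(rep(2, 101))
  sm <- find_smax(const)
  expect_equal(sm$smax1[["value"]], 2)
  expect_equal(sm$smax2[["value"]], 2)
  expect_gte(sm$smax2[["time"]], 0.5)         # tie broken into release phase
  # two bumps at 0.3 and 0.7 s
  t <- seq(0, 1, by = 0.01)
  bump <- exp(-((t - 0.3) / 0.05)^2) + 2 * exp(-((t - 0.7) / 0.05)^2)
  sm2 <- find_smax(mk(bump, t))
  expect_equal(sm2$smax1[["time"]], 0.3)
  expect_equal(sm2$smax2[["time"]], 0.7)
  # monotone increase: S_Max1 sits on the last step before 0.5 s
  sm3 <- find_smax(mk(t, t))
  expect_equal(sm3$smax1[["time"]], 0.49)
  expect_equal(sm3$smax2[["time"]], 0.99)     # [0.5, 1) window
  expect_error(find_smax(mk(1)), "shorter than one cycle")
})

test_that("phenotype map classifies nodes at the evaluation time", {
  spec <- scaffold_spec(2, 1, D_scaffold = 10, H_scaffold = 10,
                        D_strand = 1, Y = 5, h = 10, name = "toy")
  mesh <- manual_mesh(spec, areas = rep(1, 4))
  times <- c(0, 0.5)
  zero <- matrix(0, 4, 2)
  strain <- field_series(cbind(0 * 1:4, rep(0.0375, 4)), times, mesh, "oss")
  wss <- field_series(cbind(0 * 1:4, rep(10, 4)), times, mesh, "wss")
  m0 <- phenotype_map(field_series(zero, times, mesh, "oss"),
                      field_series(zero, times, mesh, "wss"), 0.5)
  expect_true(all(m0$class == "very_low"))
  m1 <- phenotype_map(strain, wss, 0.5)
  expect_true(all(m1$class == "cartilage"))   # S = 2 everywhere
  expect_equal(m1$S, rep(2, 4))
  expect_error(phenotype_map(strain, wss, 0.3), "not on the series")
  # node-wise classification commutes with subsetting
  sub <- phenotype_map(subset_series(strain, 1:2),
                       subset_series(wss, 1:2), 0.5)
  expect_equal(sub$class, m1$class[1:2])
})

test_that("phenotype percentages: weighting, normalisation, oracle", {
  mk_map <- function(cls) data.frame(node_id = seq_along(cls), S = NA,
                                     class = cls)
  uni <- phenotype_percentages(mk_map(rep("bone", 5)), rep(2, 5))
  expect_equal(uni[["bone"]], 100)
  expect_equal(sum(uni), 100)
  half <- phenotype_percentages(mk_map(c("bone", "cartilage")), c(3, 3))
  expect_equal(half[["bone"]], 50)
  expect_equal(half[["cartilage"]], 50)
  expect_error(phenotype_percentages(mk_map(c("bone", "bone")), 1:3),
               "one weight per node")
  expect_error(phenotype_percentages(mk_map(c("bone", "bone")), c(1, 0)),
               "> 0")
  # brute-force oracle on 500 random synthetic maps
  set.seed(42)
  lv <- phenotype_levels()
  for (i in 1:500) {
    n <- sample(3:40, 1)
    cls <- sample(lv, n, replace = TRUE)
    w <- runif(n, 0.1, 2)
    got <- phenotype_percentages(mk_map(cls), w)
    oracle <- vapply(lv, function(l) 100 * sum(w[cls == l]) / sum(w),
                     numeric(1))
    expect_equal(unclass(got), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(got), 100, tolerance = 1e-9)
  }
})

test_that("design comparison deltas and stimulus shares", {
  a <- phenotype_percentages(
    data.frame(node_id = 1:4, S = NA,
               class = c("bone", "bone", "cartilage", "fibrous")),
    rep(1, 4))
  b <- phenotype_percentages(
    data.frame(node_id = 1:4, S = NA,
               class = c("bone", "cartilage", "cartilage", "fibrous")),
    rep(1, 4))
  expect_equal(compare_designs(a, a), setNames(rep(0, 5), names(a)))
  expect_equal(sum(compare_designs(b, a)), 0)
  expect_equal(compare_designs(b, a), -compare_designs(a, b))

  expect_equal(contribution_shares(0.0375, 10), c(oss = 50, wss = 50))
  expect_equal(contribution_shares(0.03, 0), c(oss = 100, wss = 0))
  sh <- contribution_shares(0.041, 13.2)
  expect_equal(sum(sh), 100)
  expect_error(contribution_shares(0, 0), "undefined")
})
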