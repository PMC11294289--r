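cfg12 <- radar_config(property_radius = 12)

test_that("profiles place vertices on the canonical axes", {
  plp <- build_profile(vox_fixture("fig4"), cfg12)
  expect_equal(unname(plp$vertices),
               matrix(c(12, 0, 0, 10, -8, 0, 0, -12), ncol = 2, byrow = TRUE))
  expect_equal(rownames(plp$vertices),
               c("echoic", "mand", "sequelic", "tact"))

  plp2 <- build_profile(axis_values(5, 2, 5, 1))
  expect_equal(unname(plp2$vertices),
               matrix(c(5, 0, 0, 2, -1, 0, 0, -5), ncol = 2, byrow = TRUE))

  zero <- build_profile(axis_values(0, 0, 0, 0))
  expect_true(all(zero$vertices == 0))

  expect_error(axis_values(-1, 0, 0, 0), "non-negative")
  expect_error(build_profile(c(echoic = -1, mand = 0, sequelic = 0, tact = 0)),
               "non-negative")
  expect_warning(build_profile(axis_values(20, 0, 0, 0), cfg12),
                 "property radius")
})

test_that("area matches the worked example and closed forms", {
  expect_identical(polygon_area(build_profile(vox_fixture("fig4"))), 220)
  expect_identical(polygon_area(build_profile(axis_values(12, 12, 12, 12))),
                   288)  # 2 v^2 for an equal-valued rhombus
  expect_identical(polygon_area(build_profile(axis_values(5, 2, 5, 1))), 21)
  expect_identical(polygon_area(build_profile(axis_values(0, 0, 0, 0))), 0)
})

test_that("area equals the shoelace formula on random profiles and axis counts", {
  set.seed(11)
  for (rep in 1:200) {
    plp <- build_profile(random_axis_values())
    expect_equal(polygon_area(plp), oracle_shoelace(plp$vertices))
  }
  for (n in 3:8) {
    config <- radar_config(axis_order = letters[1:n])
    v <- setNames(runif(n, 0, 10), letters[1:n])
    plp <- build_profile(v, config)
    expect_equal(polygon_area(plp), oracle_shoelace(plp$vertices))
  }
})

test_that("quadrant convergence reproduces the worked ranking", {
  qc <- quadrant_convergence(build_profile(vox_fixture("fig4")))
  expect_equal(qc$area, c(60, 40, 48, 72))
  expect_equal(order(qc$area, decreasing = TRUE), c(4, 1, 3, 2))
  expect_equal(qc$operants[1], "echoic&mand")

  equal <- quadrant_convergence(build_profile(axis_values(7, 7, 7, 7)))
  expect_equal(equal$share, rep(0.25, 4))

  small <- quadrant_convergence(build_profile(axis_values(5, 2, 5, 1)))
  expect_equal(small$area, c(5, 1, 2.5, 12.5))
  expect_equal(sum(small$area), 21)
  expect_equal(sum(small$share), 1)

  degen <- quadrant_convergence(build_profile(axis_values(0, 0, 0, 0)))
  expect_true(all(is.na(degen$share)))
})

test_that("maximal-area ordering is exhaustive, deterministic, and optimal", {
  opt <- maximize_area_ordering(vox_fixture("fig4"))
  expect_equal(opt$A_tilde, 220)
  expect_equal(opt$ordering, c("echoic", "mand", "sequelic", "tact"))
  expect_equal(opt$n_orderings, 3)

  tie <- maximize_area_ordering(axis_values(4, 4, 4, 4))
  expect_equal(tie$ordering, c("echoic", "mand", "sequelic", "tact"))

  t2 <- maximize_area_ordering(axis_values(tact = 5, mand = 2,
                                           echoic = 5, sequelic = 1))
  expect_equal(t2$A_tilde, 21)

  set.seed(23)
  for (n in 3:6) {
    v <- setNames(runif(n, 0, 10), letters[1:n])
    opt_n <- maximize_area_ordering(v, axis_order = letters[1:n])
    expect_equal(opt_n$A_tilde, oracle_max_area(v))
  }
})

test_that("centroid matches the worked values and closed forms", {
  ctr <- plp_centroid(build_profile(vox_fixture("fig4")))
  expect_equal(ctr, c(x = 4 / 3, y = -2 / 3))
  expect_equal(round(ctr, 2), c(x = 1.33, y = -0.67))

  balanced <- plp_centroid(build_profile(axis_values(9, 9, 9, 9)))
  expect_equal(balanced, c(x = 0, y = 0))

  # single nonzero quadrant: one triangle, centroid at (sum of its
  # vertices)/3 with signed coordinates
  single <- plp_centroid(build_profile(axis_values(tact = 2, mand = 0,
                                                   echoic = 0, sequelic = 1)))
  expect_equal(single, c(x = -1 / 3, y = -2 / 3))

  degen <- plp_centroid(build_profile(axis_values(0, 0, 0, 0)))
  expect_true(all(is.na(degen)))
  expect_true(attr(degen, "degenerate"))
})

test_that("triangle decomposition conserves area and matches Monte-Carlo centroids", {
  set.seed(31)
  for (rep in 1:5) {
    plp <- build_profile(axis_values(runif(1, 2, 15), runif(1, 2, 15),
                                     runif(1, 2, 15), runif(1, 2, 15)))
    tri <- triangle_decomposition(plp)
    expect_equal(sum(tri$area), polygon_area(plp))
    ctr <- plp_centroid(plp)
    mc <- oracle_mc_centroid(plp$vertices, n = 40000, seed = rep)
    expect_lt(abs(ctr[["x"]] - mc$centroid[["x"]]), 3 * mc$se[["x"]] + 1e-9)
    expect_lt(abs(ctr[["y"]] - mc$centroid[["y"]]), 3 * mc$se[["y"]] + 1e-9)
  }
})

test_that("centroidal distance and first moment follow their definitions", {
  expect_equal(round(centroidal_distance(c(x = 4 / 3, y = -2 / 3)), 2), 1.49)
  expect_identical(centroidal_distance(c(x = 0, y = 0)), 0)
  expect_equal(centroidal_distance(c(x = -1 / 3, y = -2 / 3)), sqrt(5) / 3)
  expect_equal(round(sqrt(5) / 3, 2), 0.75)

  expect_identical(first_moment(288, 0, 12), 3456)
  expect_equal(first_moment(1, 0.75, 12), 11.25)
  expect_identical(first_moment(0, NA_real_, 12), 0)
  expect_error(first_moment(10, 1), "property radius")
  expect_error(first_moment(10, 5, 3), "exceeds")
  expect_warning(q_neg <- first_moment(10, 5, 3, permissive = TRUE),
                 "negative")
  expect_equal(q_neg, -20)
})

test_that("descriptors scale and reflect as the geometry dictates", {
  set.seed(41)
  v <- c(tact = 3, mand = 7, echoic = 2, sequelic = 5)
  base <- build_profile(v)
  for (k in c(0.5, 2, 10)) {
    scaled <- build_profile(k * v)
    expect_equal(polygon_area(scaled), k^2 * polygon_area(base))
    expect_equal(plp_centroid(scaled), k * plp_centroid(base))
  }
  # swapping the two values on one axis pair reflects the centroid
  swapped <- build_profile(c(tact = 3, mand = 7, echoic = 5, sequelic = 2))
  expect_equal(plp_centroid(swapped)[["x"]], -plp_centroid(base)[["x"]])
  expect_equal(plp_centroid(swapped)[["y"]], plp_centroid(base)[["y"]])
  flipped <- build_profile(c(tact = 7, mand = 3, echoic = 2, sequelic = 5))
  expect_equal(plp_centroid(flipped)[["y"]], -plp_centroid(base)[["y"]])
  expect_equal(plp_centroid(flipped)[["x"]], plp_centroid(base)[["x"]])
})

test_that("describe_profile composes the full descriptor pipeline", {
  d <- describe_profile(vox_fixture("fig4"), cfg12)
  expect_equal(d$A, 220)
  expect_equal(d$A_tilde, 220)
  expect_equal(d$R, 2 * sqrt(5) / 3)
  expect_equal(round(d$Q, 2), 2312.04)
  expect_equal(sum(d$quadrants$share), 1)

  zero <- describe_profile(axis_values(0, 0, 0, 0), cfg12)
  expect_equal(zero$A, 0)
  expect_equal(zero$Q, 0)
  expect_true(all(is.na(zero$centroid)))

  # maximize mode can only improve on the canonical area
  v <- axis_values(tact = 9, mand = 1, echoic = 8, sequelic = 7)
  can <- describe_profile(v, radar_config(12, ordering_mode = "canonical"))
  mx <- describe_profile(v, radar_config(12, ordering_mode = "maximize"))
  expect_equal(mx$A, mx$A_tilde)
  expect_gte(mx$A, can$A)
  expect_setequal(mx$ordering, vox_operants)

  expect_true(is.na(describe_profile(v, radar_config())$Q))
})
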