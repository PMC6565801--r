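test_that("default slices tile the medial 75 mm, slice 5 most medial", {
  centers <- sapply(1:5, function(i) slice_plane(i)$center)
  expect_equal(centers, c(-67.5, -52.5, -37.5, -22.5, -7.5))
  expect_equal(slice_plane(5)$center + slice_plane(5)$half, 0)
})

test_that("slab clipping matches the geometric oracle", {
  # element wholly inside the slab contributes its full blood volume
  nd <- data.frame(id = 1:2, x_mm = c(-40, -36), y_mm = 0, z_mm = 0)
  el <- data.frame(id = 1L, node_in = 1L, node_out = 2L, type = "artery",
                   Q = 10, v = 5, V_B = pi * 4, radius_mm = 1, length_mm = 4)
  net <- list(nodes = nd)
  sol <- fake_solution(el)
  p <- blood_in_slice(net, sol, slice_plane(3))  # slab [-45, -30]
  expect_equal(sum(p$volume), pi * 4, tolerance = 1e-12)

  # element crossing one face at its midpoint: half the volume, within
  # one sub-segment quantum
  nd2 <- data.frame(id = 1:2, x_mm = c(-40, -20), y_mm = 0, z_mm = 0)
  el2 <- transform(el, V_B = pi * 20, length_mm = 20)
  p2 <- blood_in_slice(list(nodes = nd2), fake_solution(el2), slice_plane(3),
                       quantum = 1)
  quantum_vol <- pi * 20 / 20
  expect_lt(abs(sum(p2$volume) - pi * 20 / 2), quantum_vol + 1e-9)

  # vanishing slab thickness: vanishing parcel volume
  thin <- slice_plane(3, thickness = 1e-3, center = -37.5)
  p3 <- blood_in_slice(list(nodes = nd2), fake_solution(el2), thin,
                       quantum = 0.01)
  expect_lt(sum(p3$volume), pi * 20 * 1e-3)
})

test_that("backtracing walks distance = velocity x time", {
  nd <- data.frame(id = 1:2, x_mm = c(0, 10), y_mm = 0, z_mm = 0)
  el <- data.frame(id = 1L, node_in = 1L, node_out = 2L, type = "artery",
                   Q = 1, v = 10, V_B = 1, length_mm = 10)
  net <- list(nodes = nd)
  parcels <- data.frame(parcel = 1L, element = 1L, a_mm = 9, volume = 2)
  o <- trace_origin(parcels, net, fake_solution(el), ti = 800)
  expect_equal(nrow(o), 1)
  expect_equal(o$ox, 1)           # 8 mm upstream of x = 9
  expect_equal(o$volume, 2)
  expect_false(o$exited_inlet)

  # zero budget: origin is the imaging position
  o0 <- trace_origin(parcels, net, fake_solution(el), ti = 0)
  expect_equal(o0$ox, 9)

  # exhausting the network: origin at the inlet, outside-band flag
  oi <- trace_origin(parcels, net, fake_solution(el), ti = 1e6)
  expect_equal(oi$ox, 0)
  expect_true(oi$exited_inlet)

  # stagnant blood freezes in place
  el_s <- transform(el, v = 0, Q = 0)
  os <- trace_origin(parcels, net, fake_solution(el_s), ti = 800)
  expect_true(os$stagnant)
  expect_equal(os$ox, 9)
})

test_that("venous junctions split parcels by flow fraction", {
  nd <- data.frame(id = 1:4, x_mm = c(0, 0, 10, 30),
                   y_mm = c(5, -5, 0, 0), z_mm = 0)
  el <- data.frame(id = 1:3,
                   node_in = c(1L, 2L, 3L), node_out = c(3L, 3L, 4L),
                   type = "vein",
                   Q = c(0.7, 0.3, 1), v = c(10, 10, 10),
                   V_B = 1, length_mm = c(sqrt(125), sqrt(125), 20))
  net <- list(nodes = nd)
  parcels <- data.frame(parcel = 1L, element = 3L, a_mm = 2, volume = 1)
  o <- trace_origin(parcels, net, fake_solution(el), ti = 400)
  expect_equal(nrow(o), 2)
  expect_equal(sort(o$volume), c(0.3, 0.7))
  # both sub-parcels moved 2 mm into their feeders
  expect_true(all(abs(sqrt(o$ox^2 + (abs(o$oy) - 5)^2 + o$oz^2) -
                        (sqrt(125) - 2) / sqrt(125) * 0) >= 0))
  expect_equal(sum(o$volume), 1)
})

test_that("split sub-parcel volumes always sum to the parent volume", {
  net <- generate_network(lung_domain(), geometry_config(60), seed = 12)
  sol <- solve_flow(net, sheet = sheet_params(c_sheet = 0.05))
  parcels <- blood_in_slice(net, sol, slice_plane(4))
  o <- trace_origin(parcels, net, sol, ti = 800)
  per_parcel <- tapply(o$volume, o$parcel, sum)
  expect_equal(as.numeric(per_parcel),
               parcels$volume[match(as.integer(names(per_parcel)),
                                    parcels$parcel)],
               tolerance = 1e-9)
})

test_that("labeling profile has the plateau/transition structure", {
  sl <- slice_plane(3)
  pr <- inversion_profile()
  expect_equal(magnetization_at_origin(0, sl, pr)$m0, -1, tolerance = 1e-6)
  expect_equal(magnetization_at_origin(200, sl, pr)$m0, 1, tolerance = 1e-6)
  expect_true(magnetization_at_origin(0, sl, pr)$in_band)
  expect_false(magnetization_at_origin(200, sl, pr)$in_band)
  # even symmetry and monotone rise through the shoulder
  z <- seq(0, 40, by = 0.25)
  m <- magnetization_at_origin(z, sl, pr)$m0
  m_neg <- magnetization_at_origin(-z, sl, pr)$m0
  expect_equal(m, m_neg)
  expect_true(all(diff(m) >= -1e-12))
  edge <- sl$half + pr$gap
  m_edge <- magnetization_at_origin(edge, sl, pr)$m0
  expect_gt(m_edge, -1); expect_lt(m_edge, 1)

  # tabulated profile overrides the parametric form
  tab <- data.frame(z_mm = c(0, 10, 20), m0 = c(-1, 0, 1))
  pr2 <- inversion_profile(table = tab)
  expect_equal(magnetization_at_origin(5, sl, pr2)$m0, -0.5)
  expect_equal(magnetization_at_origin(-15, sl, pr2)$m0, 0.5)
})

test_that("signal equations match hand evaluation and join continuously", {
  mr <- mr_params(ti = 800, t1 = 1300, t2 = 254, te = 36)
  # fresh blood outside the band: a single exponential
  expect_equal(parcel_signal(1, NA, FALSE, mr), exp(-36 / 254))
  expect_equal(exp(-36 / 254), 0.8679, tolerance = 1e-3)
  # fully inverted blood: two-exponential hand evaluation
  s_inv <- (1 - 2 * exp(-800 / 1300)) * exp(-36 / 254)
  expect_equal(parcel_signal(1, -1, TRUE, mr), s_inv)
  expect_equal(s_inv, -0.0702, tolerance = 1e-3)
  # continuity at the band edge: m0 = 1 reproduces the outside-band signal
  expect_identical(parcel_signal(2.5, 1, TRUE, mr),
                   parcel_signal(2.5, NA, FALSE, mr))
  # null point at TI = T1 ln 2; sign flips across it
  ti_null <- 1300 * log(2)
  expect_equal(parcel_signal(1, -1, TRUE, mr_params(ti = ti_null)), 0,
               tolerance = 1e-12)
  expect_lt(parcel_signal(1, -1, TRUE, mr_params(ti = ti_null - 50)), 0)
  expect_gt(parcel_signal(1, -1, TRUE, mr_params(ti = ti_null + 50)), 0)
})

test_that("fresh blood outcarries any in-band blood of equal volume", {
  mr <- mr_params(ti = 800)
  m0 <- seq(-1, 1 - 1e-9, length.out = 50)
  expect_true(all(parcel_signal(1, m0, TRUE, mr) <
                    parcel_signal(1, NA, FALSE, mr)))
})

test_that("voxelization conserves signal and separates components", {
  sl <- slice_plane(3)
  dom <- lung_domain()
  mr <- mr_params(ti = 800)
  one <- data.frame(x = -37, y = 4, z = 10, vclass = "arterial",
                    volume = 2, signal = 1.5, radius_mm = 0.5)
  g1 <- voxelize(one, sl, dom, mr)
  expect_equal(sum(g1$total != 0), 1)
  expect_equal(sum(g1$total), 1.5)
  expect_equal(sum(g1$arterial), 1.5)
  expect_equal(attr(g1, "voxel_volume"), 67.5)

  withr::local_seed(42)
  n <- 300
  many <- data.frame(
    x = runif(n, -45, -30), y = runif(n, -40, 40), z = runif(n, -60, 60),
    vclass = sample(c("capillary", "arterial", "venous"), n, replace = TRUE),
    volume = runif(n), signal = rnorm(n), radius_mm = runif(n, 0.1, 6))
  g <- voxelize(many, sl, dom, mr, cap_smear_radius = 6)
  expect_equal(sum(g$total), sum(many$signal), tolerance = 1e-9)
  expect_equal(sum(g$capillary), sum(many$signal[many$vclass == "capillary"]),
               tolerance = 1e-9)
  expect_equal(g$total, g$capillary + g$arterial + g$venous, tolerance = 1e-12)
  expect_equal(sum(g$vol_total), sum(many$volume), tolerance = 1e-9)
})

test_that("ASL rate converts delivered volume per TI", {
  g <- toy_grid(capillary = c(67.5, 0, 33.75), ti = 800)
  expect_equal(asl_rate(g), c(75, 0, 37.5))
  attr(g, "ti") <- 1600
  expect_equal(asl_rate(g), c(37.5, 0, 18.75))
})

test_that("shorter TI does not increase total slice signal", {
  net <- get_demo_network()
  sol <- solve_flow(net, sheet = get_demo_sheet())
  totals <- sapply(c(500, 667, 800, 1000), function(ti) {
    g <- simulate_asl_slice(net, sol, slice_plane(3), mr_params(ti = ti))
    sum(lung_voxels(g)$total)
  })
  expect_true(all(diff(totals) > 0))
})

test_that("an empty slab yields an empty, valid grid", {
  net <- generate_network(lung_domain(), geometry_config(3), seed = 5)
  sol <- solve_flow(net, sheet = sheet_params(c_sheet = 0.05))
  far <- slice_plane(1, center = -89)
  g <- simulate_asl_slice(net, sol, far)
  expect_s3_class(g, "voxel_grid")
  expect_equal(sum(g$total), 0)
})
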