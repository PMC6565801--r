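test_that("Poiseuille resistance has the right value and scalings", {
  # hand unit conversion: 8 mu L / (pi r^4) with mm and Pa s
  expect_equal(poiseuille_resistance(10, 1, 3.36e-3),
               8 * 3.36e-3 * 10 / pi, tolerance = 1e-12)
  expect_equal(8 * 3.36e-3 * 10 / pi, 8.556e-2, tolerance = 1e-4)
  r0 <- poiseuille_resistance(10, 1, 3.36e-3)
  expect_equal(poiseuille_resistance(10, 2, 3.36e-3), r0 / 16)
  expect_equal(poiseuille_resistance(5, 1, 3.36e-3), r0 / 2)
  expect_error(poiseuille_resistance(0, 1, 1), "must be > 0")
})

test_that("hydrostatic offset follows the gravity projection", {
  g <- gravity_state("supine")  # gravity toward -y
  # element perpendicular to gravity
  expect_equal(hydrostatic_drop(c(0, 0, 0), c(10, 0, 5), g, 1050), 0)
  # 10 mm element pointing down-gravity (from y = 0 to y = -10)
  drop_pa <- hydrostatic_drop(c(0, 0, 0), c(0, -10, 0), g, 1050)
  expect_equal(drop_pa, 1050 * 9.81 * 0.01, tolerance = 1e-12)
  expect_equal(drop_pa, 103.0, tolerance = 1e-3)
  # posture flip negates every offset
  p <- matrix(rnorm(30), ncol = 3)
  q <- matrix(rnorm(30), ncol = 3)
  expect_equal(hydrostatic_drop(p, q, gravity_state("prone"), 1050),
               -hydrostatic_drop(p, q, g, 1050))
})

test_that("distension law is linear with a cap and no collapse", {
  d <- distension_params(alpha_d = 0.02, max_ratio = 1.5)
  expect_equal(distended_radius(2, 0, d), 2)
  expect_equal(distended_radius(1, cmH2O_to_Pa(10), d), 1.2)
  expect_equal(distended_radius(1, 1e6, d), 1.5)
  expect_equal(distended_radius(1, -500, d), 1)
  ptm <- seq(-1000, 5000, by = 100)
  expect_true(all(diff(distended_radius(1, ptm, d)) >= 0))
})

test_that("sheet flow reproduces the thickness-law arithmetic and zone 2", {
  sp <- sheet_params(h0 = 3.5, alpha_c = 0.127, c_sheet = 1)
  # equal transmural pressures: equal fourth powers
  expect_equal(sheet_flow(cmH2O_to_Pa(8), cmH2O_to_Pa(8), sp), 0)
  # hand evaluation at Ptm_a = 10, Ptm_v = 5 cmH2O (f = 1)
  h_a <- 3.5 + 0.127 * 10
  h_v <- 3.5 + 0.127 * 5
  expect_equal(sheet_flow(cmH2O_to_Pa(10), cmH2O_to_Pa(5), sp),
               h_a^4 - h_v^4, tolerance = 1e-12)
  expect_equal(h_a^4 - h_v^4, 225.4, tolerance = 1e-3)
  # zone-2 sluicing: flow independent of venular pressure once it is <= 0
  f0 <- sheet_flow(cmH2O_to_Pa(10), 0, sp)
  expect_equal(sheet_flow(cmH2O_to_Pa(10), -2000, sp), f0)
  # flow is non-negative whenever Ptm_a >= Ptm_v
  grid <- expand.grid(a = seq(-5, 25, by = 5), v = seq(-5, 25, by = 5))
  grid <- grid[grid$a >= grid$v, ]
  expect_true(all(sheet_flow(cmH2O_to_Pa(grid$a), cmH2O_to_Pa(grid$v), sp) >= 0))
})

test_that("series chain obeys the series resistance law", {
  net <- make_chain_network()
  sheet <- sheet_params(c_sheet = 1)
  sol <- solve_flow(net, boundary_conditions(co = 0.06),  # 1000 mm^3/s
                    gravity = gravity_state("supine", magnitude = 0),
                    sheet = sheet, rigid = TRUE)
  el <- sol$elements
  a <- el[el$type == "artery", ]
  q <- Lmin_to_mm3s(0.06)
  expect_equal(a$Q, rep(q, 2), tolerance = 1e-10)
  r_each <- poiseuille_resistance(15, 1, 3.36e-3)
  expect_equal(a$P_in[1] - a$P_out[2], q * 2 * r_each, tolerance = 1e-8)
  expect_equal(a$v[1], a$v[2], tolerance = 1e-12)
  expect_equal(a$v[1], q / pi, tolerance = 1e-8)      # unit-radius disc
  expect_equal(a$V_B, pi * 1^2 * c(15, 15), tolerance = 1e-12)
})

test_that("symmetric bifurcation splits flow in half", {
  net <- make_mirrored_network()
  sol <- solve_flow(net, boundary_conditions(co = 1),
                    gravity = gravity_state("supine", magnitude = 0),
                    sheet = sheet_params(c_sheet = 1), rigid = TRUE)
  el <- sol$elements
  caps <- el$Q[el$type == "capillary"]
  expect_equal(caps[1], caps[2], tolerance = 1e-10)
  expect_equal(sum(caps), Lmin_to_mm3s(1), tolerance = 1e-8)
})

test_that("fixed-point solver matches an independent dense solve on rigid networks", {
  for (seed in 1:6) {
    withr::local_seed(seed)
    n_units <- sample(1:3, 1)           # 7n - 2 <= 19 elements
    net <- generate_network(lung_domain(),
                            geometry_config(n_units, trunk_radius = 5),
                            seed = seed + 100)
    grav <- gravity_state(sample(c("supine", "prone"), 1),
                          magnitude = sample(c(0, 9.81), 1))
    blood <- blood_properties()
    sheet <- sheet_params(c_sheet = 0.05)
    bc <- boundary_conditions(co = runif(1, 2, 8))
    sol <- solve_flow(net, bc, blood, grav, sheet = sheet, rigid = TRUE)

    # independent dense assembly from first principles
    el <- net$elements
    nd <- net$nodes
    n_par <- net$config$n_parallel
    nn <- nrow(nd)
    A <- matrix(0, nn, nn)
    rhs <- numeric(nn)
    pos <- as.matrix(nd[, c("x_mm", "y_mm", "z_mm")])
    for (e in seq_len(nrow(el))) {
      u <- match(el$node_in[e], nd$id); v <- match(el$node_out[e], nd$id)
      G <- switch(el$type[e],
        artery = , vein = 1 / poiseuille_resistance(el$length_mm[e],
                                                    el$radius0_mm[e],
                                                    blood$viscosity),
        arteriole = , venule = n_par / poiseuille_resistance(el$length_mm[e],
                                                             el$radius0_mm[e],
                                                             blood$viscosity),
        capillary = sheet$c_sheet * sheet$h0^4 / cmH2O_to_Pa(1))
      b <- if (el$type[e] %in% c("artery", "vein"))
        hydrostatic_drop(pos[u, ], pos[v, ], grav, blood$density) else 0
      A[u, u] <- A[u, u] + G; A[u, v] <- A[u, v] - G
      A[v, v] <- A[v, v] + G; A[v, u] <- A[v, u] - G
      rhs[u] <- rhs[u] - G * b
      rhs[v] <- rhs[v] + G * b
    }
    inlet_node <- match(el$node_in[el$id == net$inlet_element], nd$id)
    outlet_node <- match(el$node_out[el$id == net$outlet_element], nd$id)
    rhs[inlet_node] <- rhs[inlet_node] + Lmin_to_mm3s(bc$co)
    A[outlet_node, ] <- 0; A[outlet_node, outlet_node] <- 1
    rhs[outlet_node] <- mmHg_to_Pa(bc$p_la)
    p_ref <- solve(A, rhs)
    expect_equal(unname(sol$node_pressure), p_ref, tolerance = 1e-10)
  }
})

test_that("converged solutions conserve mass at every node", {
  net <- generate_network(lung_domain(), geometry_config(80), seed = 31)
  sol <- solve_flow(net)
  el <- sol$elements
  co <- Lmin_to_mm3s(5)
  # net flow at interior nodes
  influx <- tapply(el$Q, el$node_out, sum)
  outflux <- tapply(el$Q, el$node_in, sum)
  nodes <- net$nodes$id
  bal <- sapply(nodes, function(n) {
    f_in <- if (as.character(n) %in% names(influx)) influx[[as.character(n)]] else 0
    f_out <- if (as.character(n) %in% names(outflux)) outflux[[as.character(n)]] else 0
    f_in - f_out
  })
  inlet_node <- el$node_in[el$id == net$inlet_element]
  outlet_node <- el$node_out[el$id == net$outlet_element]
  interior <- !(nodes %in% c(inlet_node, outlet_node))
  expect_lt(max(abs(bal[interior])) / co, 1e-8)
  expect_equal(sum(el$Q[el$type == "capillary"]), co, tolerance = 1e-6)
  expect_equal(el$Q[el$id == net$inlet_element], co, tolerance = 1e-8)
  expect_equal(el$Q[el$id == net$outlet_element], co, tolerance = 1e-6)
  # arterial flows directed root-to-terminal (closed units may carry a
  # numerically negligible residual)
  expect_true(all(el$Q[el$type == "artery"] > -1e-6 * co))
})

test_that("raising cardiac output raises every capillary flow (rigid limit)", {
  net <- generate_network(lung_domain(), geometry_config(40), seed = 17)
  sheet <- sheet_params(c_sheet = 0.05)
  q4 <- solve_flow(net, boundary_conditions(co = 4), sheet = sheet,
                   rigid = TRUE)$elements
  q8 <- solve_flow(net, boundary_conditions(co = 8), sheet = sheet,
                   rigid = TRUE)$elements
  expect_true(all(q8$Q[q8$type == "capillary"] >=
                    q4$Q[q4$type == "capillary"] - 1e-9))
})

test_that("gravity flip mirrors the solution on a symmetric network", {
  net <- make_mirrored_network()
  sheet <- sheet_params(c_sheet = 0.05)
  sup <- solve_flow(net, gravity = gravity_state("supine"), sheet = sheet)
  pro <- solve_flow(net, gravity = gravity_state("prone"), sheet = sheet)
  expect_equal(unname(pro$node_pressure),
               unname(sup$node_pressure[mirror_map]), tolerance = 1e-6)
})

test_that("supine capillary flow is dorsally biased", {
  net <- get_demo_network()
  sol <- solve_flow(net, sheet = get_demo_sheet())
  cap <- sol$elements[sol$elements$type == "capillary", ]
  nd <- net$nodes
  ymid <- (nd$y_mm[match(cap$node_in, nd$id)] +
             nd$y_mm[match(cap$node_out, nd$id)]) / 2
  thirds <- quantile(ymid, c(1 / 3, 2 / 3))
  expect_gt(mean(cap$Q[ymid < thirds[1]]), mean(cap$Q[ymid > thirds[2]]))
})

test_that("non-convergence raises a typed condition with residual history", {
  net <- generate_network(lung_domain(), geometry_config(20), seed = 3)
  err <- tryCatch(
    solve_flow(net, sheet = sheet_params(c_sheet = 0.05), max_iter = 2,
               tol = 1e-14),
    pulmoasl_no_convergence = function(e) e)
  expect_s3_class(err, "pulmoasl_no_convergence")
  expect_true(length(err$residuals) >= 1)
})

test_that("sheet conductance calibration hits a physiological pressure window", {
  net <- get_demo_network()
  cs <- calibrate_sheet_conductance(net, target_drop_mmHg = 10)
  expect_gt(as.numeric(cs), 0)
  cal <- attr(cs, "calibration")
  expect_equal(cal$conduit_drop_mmHg + cal$capillary_drop_mmHg, 10,
               tolerance = 0.1)
  # the calibrated sheets reproduce the per-unit flow at the nominal drop
  sp <- sheet_params(c_sheet = as.numeric(cs))
  q_unit <- sheet_flow(mmHg_to_Pa(5 + cal$capillary_drop_mmHg), mmHg_to_Pa(5), sp)
  expect_equal(q_unit, Lmin_to_mm3s(5) / net$n_terminal_units,
               tolerance = 1e-6)
})
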