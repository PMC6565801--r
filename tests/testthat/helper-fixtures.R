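# Hand-built networks, toy voxel grids and brute-force oracles shared by the
# test files. Oracles are written as plain loops / stats::lm fits so they are
# independent of the package's vectorized code paths.

make_custom_network <- function(nodes, elements, inlet, outlet, n_units,
                                domain = lung_domain(), config = NULL) {
  structure(list(nodes = nodes, elements = elements,
                 inlet_element = inlet, outlet_element = outlet,
                 n_terminal_units = n_units, domain = domain, config = config),
            class = "vascular_network")
}

# artery-artery-arteriole-capillary-venule-vein chain along the x axis
make_chain_network <- function(r_conduit = 1) {
  nodes <- data.frame(
    id = 1:7,
    x_mm = c(-60, -45, -30, -29, -24, -23, 0),
    y_mm = 0, z_mm = 0)
  elements <- data.frame(
    id = 1:6,
    node_in = 1:6, node_out = 2:7,
    type = c("artery", "artery", "arteriole", "capillary", "venule", "vein"),
    radius0_mm = c(r_conduit, r_conduit, 0.1, 0.1, 0.1, r_conduit),
    length_mm = c(15, 15, 1, 5, 1, 23),
    stringsAsFactors = FALSE)
  make_custom_network(nodes, elements, inlet = 1L, outlet = 6L, n_units = 1L,
                      config = geometry_config(n_terminals = 1, n_parallel = 1))
}

# two identical units mirrored in y about the x axis (for gravity-flip tests)
make_mirrored_network <- function() {
  nodes <- data.frame(
    id = 1:14,
    x_mm = c(-50, -40,
             -30, -29, -24, -23, -10,    # upper unit (y > 0)
             -30, -29, -24, -23, -10,    # lower mirror (y < 0)
             -5, 0),
    y_mm = c(0, 0, 20, 20, 20, 20, 10, -20, -20, -20, -20, -10, 0, 0),
    z_mm = 0)
  elements <- data.frame(
    id = 1:14,
    node_in  = c(1, 2, 3, 4, 5, 6, 7, 2, 8, 9, 10, 11, 12, 13),
    node_out = c(2, 3, 4, 5, 6, 7, 13, 8, 9, 10, 11, 12, 13, 14),
    type = c("artery", "artery", "arteriole", "capillary", "venule", "vein",
             "vein", "artery", "arteriole", "capillary", "venule", "vein",
             "vein", "vein"),
    radius0_mm = c(1.5, 1, 0.1, 0.1, 0.1, 1, 1, 1, 0.1, 0.1, 0.1, 1, 1, 1.5),
    length_mm = NA_real_,
    stringsAsFactors = FALSE)
  p <- as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")])
  elements$length_mm <- sqrt(rowSums(
    (p[elements$node_in, ] - p[elements$node_out, ])^2))
  make_custom_network(nodes, elements, inlet = 1L, outlet = 14L, n_units = 2L,
                      config = geometry_config(n_terminals = 2, n_parallel = 1))
}

# map each node to its y-mirror in the mirrored network
mirror_map <- c(1, 2, 8, 9, 10, 11, 12, 3, 4, 5, 6, 7, 13, 14)

# memoized demo network (the seeded ~1000-terminal synthetic lung)
.demo_cache <- new.env()
get_demo_network <- function(seed = 1234L) {
  key <- paste0("net", seed)
  if (is.null(.demo_cache[[key]]))
    .demo_cache[[key]] <- generate_network(lung_domain(),
                                           geometry_config(1000), seed = seed)
  .demo_cache[[key]]
}
get_demo_sheet <- function(seed = 1234L) {
  key <- paste0("sheet", seed)
  if (is.null(.demo_cache[[key]])) {
    cs <- calibrate_sheet_conductance(get_demo_network(seed))
    .demo_cache[[key]] <- sheet_params(c_sheet = as.numeric(cs))
  }
  .demo_cache[[key]]
}

# minimal voxel grid for threshold tests
toy_grid <- function(capillary, arterial = 0, venous = 0, y_mm = NULL,
                     ti = 800, s_full = NULL, voxel_dims = c(15, 3, 1.5)) {
  n <- length(capillary)
  arterial <- rep_len(arterial, n)
  venous <- rep_len(venous, n)
  if (is.null(y_mm)) y_mm <- seq(0, by = voxel_dims[2], length.out = n)
  df <- data.frame(i = seq_len(n), j = 1L, y_mm = y_mm, z_mm = 0,
                   in_lung = TRUE,
                   capillary = capillary, vol_capillary = 0,
                   arterial = arterial, vol_arterial = 0,
                   venous = venous, vol_venous = 0)
  df$total <- df$capillary + df$arterial + df$venous
  df$vol_total <- 0
  structure(df, class = c("voxel_grid", "data.frame"),
            slice_index = 1L, slice_center = 0, ti = ti,
            voxel_dims = voxel_dims, voxel_volume = prod(voxel_dims),
            s_full = if (is.null(s_full)) prod(voxel_dims) else s_full,
            dims = c(n, 1L))
}

# brute-force threshold metrics: explicit loops, lm() for the gradient
brute_threshold_metrics <- function(grid, x, up_sign = 1, n_bins = 10) {
  sf <- attr(grid, "s_full")
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) keep[i] <- grid$total[i] <= (x / 100) * sf
  f <- grid[keep & grid$in_lung, ]
  u <- grid[grid$in_lung, ]
  cap_f <- 0; con_f <- 0; tot_f <- 0
  for (i in seq_len(nrow(f))) {
    cap_f <- cap_f + f$capillary[i]
    con_f <- con_f + f$arterial[i] + f$venous[i]
    tot_f <- tot_f + f$total[i]
  }
  cap_u <- sum(u$capillary); con_u <- sum(u$arterial) + sum(u$venous)
  q_fraction <- if (tot_f == 0) 0 else cap_f / tot_f
  q_remain <- if (cap_u == 0) 1 else cap_f / cap_u
  c_removed <- if (con_u == 0) 1 else 1 - con_f / con_u
  brute_cov <- function(v) {
    m <- sum(v) / length(v)
    sqrt(sum((v - m)^2) / length(v)) / m
  }
  brute_grad <- function(d, values) {
    h <- up_sign * d$y_mm / 10
    br <- seq(min(h), max(h), length.out = n_bins + 1)
    bin <- findInterval(h, br, rightmost.closed = TRUE)
    bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
    mu <- sapply(split(values, bin), mean)
    xs <- sapply(split(h, bin), mean)
    unname(stats::coef(stats::lm(mu ~ xs))[2])
  }
  list(Q_fraction = q_fraction, Q_remain = q_remain, C_removed = c_removed,
       cov_asl = brute_cov(f$total), cov_q = brute_cov(u$capillary),
       grad_asl = brute_grad(f, f$total), grad_q = brute_grad(u, u$capillary))
}

brute_cost <- function(m) {
  (1 - m$Q_fraction) + (1 - m$Q_remain) + (1 - m$C_removed) +
    abs(m$cov_asl - m$cov_q) / m$cov_q +
    abs(m$grad_asl - m$grad_q) / abs(m$grad_q)
}

# minimal hand-assembled solution for backtrace tests
fake_solution <- function(elements) {
  structure(list(elements = elements), class = "flow_solution")
}
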