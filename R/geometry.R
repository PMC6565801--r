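#' Right-lung-like spatial domain
#'
#' The simulation volume is a half-ellipsoid standing in for a right lung:
#' the full ellipsoid is centred on the hilum and cut by the medial plane
#' x = 0, keeping x <= 0. Coordinates are a right-handed mm frame with
#' x = lateral(-) to medial(+), y = dorsal(-) to ventral(+), and
#' z = caudal(-) to cranial(+). The hilum (entry/exit point for the
#' pulmonary trunk and veins) sits at the origin on the medial face.
#'
#' As in the real thorax the hilum sits dorsal of the dorsoventral midline,
#' so the conduit trees rooted there are dorsally biased; this anatomical
#' asymmetry (not gravity alone) is what differentiates supine from prone
#' perfusion heterogeneity.
#'
#' @param semi_axes numeric length-3, semi-axes (mm) along (x, y, z);
#'   defaults 90 x 80 x 110 mm give a lung-like volume of about 1.66 L.
#' @param hilum_y_frac dorsal offset of the hilum as a fraction of the
#'   dorsoventral semi-axis (negative = dorsal)
#' @return object of class `lung_domain`
#' @export
lung_domain <- function(semi_axes = c(90, 80, 110), hilum_y_frac = -0.3) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3 || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("semi_axes must be three positive finite numbers (mm)")
  if (abs(hilum_y_frac) >= 1)
    stop("hilum_y_frac must keep the hilum on the medial face")
  structure(list(
    semi_axes = semi_axes,
    hilum = c(0, hilum_y_frac * semi_axes[2], 0),
    axes = list(
      x = "lateral(-) -> medial(+)",
      y = "dorsal(-) -> ventral(+)",
      z = "caudal(-) -> cranial(+)"
    )
  ), class = "lung_domain")
}

#' Test points for domain membership
#'
#' @param domain a [lung_domain()]
#' @param pts numeric matrix (n x 3) of positions in mm
#' @param tol boundary tolerance on the normalized ellipsoid radius
#' @return logical vector
#' @export
in_domain <- function(domain, pts, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  a <- domain$semi_axes
  r2 <- (pts[, 1] / a[1])^2 + (pts[, 2] / a[2])^2 + (pts[, 3] / a[3])^2
  r2 <= 1 + tol & pts[, 1] <= tol
}

#' Configuration for synthetic network generation
#'
#' @param n_terminals number of terminal capillary units (>= 1)
#' @param murray_exponent exponent k of Murray's law r_parent^k = sum r_child^k;
#'   the 2.33 default matches pulmonary arterial morphometry (the classic
#'   k = 3 under-sizes proximal pulmonary vessels and yields unphysically
#'   slow peripheral conduit velocities)
#' @param terminal_radius radius (mm) of terminal arterioles/venules; 0.1 mm
#'   is an anatomical terminal-arteriole calibre
#' @param terminal_branch_radius radius (mm) of the terminal conduit
#'   branches that feed/drain one terminal unit (the Murray recursion seed);
#'   0.55 mm carries the per-unit flow at ~90 mm/s at desk scale
#' @param trunk_radius radius (mm) forced onto the root artery and root vein
#'   elements (the pulmonary trunk / left-atrial stubs); `NULL` keeps the
#'   Murray-propagated value
#' @param length_fraction branch length as a fraction of the distance from
#'   the parent tip to the sub-cloud centroid
#' @param min_length minimum branch length (mm)
#' @param dorsal_density_bias linear dorsoventral weighting of terminal-unit
#'   density (0 = uniform); 0.3 gives ~30% denser dorsal than mid-lung
#'   vascularization, emulating the structural dorsal bias of real lungs
#' @param n_parallel number of parallel anatomical arteriole (and venule)
#'   channels each terminal unit aggregates; `NULL` picks
#'   `max(1, round(7.5e5 / n_terminals))` so the network represents on the
#'   order of 7.5e5 terminal arterioles regardless of desk-scale resolution,
#'   which gives Murray-consistent conduit velocities (tens of mm/s in
#'   mm-scale arteries) and arteriolar pressure drops well under the
#'   trunk-to-atrium total
#' @return object of class `geometry_config`
#' @export
geometry_config <- function(n_terminals = 1000,
                            murray_exponent = 2.33,
                            terminal_radius = 0.1,
                            terminal_branch_radius = 0.55,
                            trunk_radius = 15,
                            length_fraction = 0.4,
                            min_length = 1,
                            dorsal_density_bias = 0.3,
                            n_parallel = NULL) {
  if (n_terminals < 1) stop("n_terminals must be >= 1")
  if (murray_exponent <= 0) stop("murray_exponent must be > 0")
  if (terminal_radius <= 0) stop("terminal_radius must be > 0")
  if (terminal_branch_radius <= 0) stop("terminal_branch_radius must be > 0")
  if (length_fraction <= 0 || length_fraction > 1)
    stop("length_fraction must be in (0, 1]")
  if (min_length <= 0) stop("min_length must be > 0")
  if (is.null(n_parallel)) n_parallel <- max(1, round(7.5e5 / n_terminals))
  structure(list(
    n_terminals = as.integer(n_terminals),
    murray_exponent = murray_exponent,
    terminal_radius = terminal_radius,
    terminal_branch_radius = terminal_branch_radius,
    trunk_radius = trunk_radius,
    length_fraction = length_fraction,
    min_length = min_length,
    dorsal_density_bias = dorsal_density_bias,
    n_parallel = n_parallel
  ), class = "geometry_config")
}

# Points inside the half-ellipsoid (rejection sampling). Density is linearly
# weighted along the dorsoventral axis: real lungs carry more vascularized
# tissue dorsally, the structural bias that gravity reinforces supine and
# opposes prone.
sample_domain_points <- function(domain, n, dorsal_bias = 0) {
  a <- domain$semi_axes
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(stats::runif(m, -a[1], 0),
                  stats::runif(m, -a[2], a[2]),
                  stats::runif(m, -a[3], a[3]))
    keep <- (cand[, 1] / a[1])^2 + (cand[, 2] / a[2])^2 + (cand[, 3] / a[3])^2 <= 1
    if (dorsal_bias > 0) {
      w <- (1 - dorsal_bias * cand[, 2] / a[2]) / (1 + dorsal_bias)
      keep <- keep & stats::runif(m) < w
    }
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Split a point cloud by the plane through its centre of mass, normal to the
# principal axis of spread. Exact ties (projection zero) go to the first
# group, lowest index first; degenerate splits fall back to index halves.
bisect_cloud <- function(pts, idx) {
  center <- colMeans(pts[idx, , drop = FALSE])
  d <- sweep(pts[idx, , drop = FALSE], 2, center)
  cv <- crossprod(d) / max(1, length(idx) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  u <- ev$vectors[, 1]
  nz <- which(abs(u) > 1e-12)[1]
  if (!is.na(nz) && u[nz] < 0) u <- -u
  proj <- drop(d %*% u)
  left <- idx[proj <= 1e-12]
  right <- idx[proj > 1e-12]
  if (length(left) == 0 || length(right) == 0) {
    half <- ceiling(length(idx) / 2)
    left <- idx[seq_len(half)]
    right <- idx[-seq_len(half)]
  }
  list(left = left, right = right, center = center)
}

# Volume-filling binary tree over `seeds` rooted at `root`.
# Returns nodes (matrix, row 1 = root), edges (parent node, child node), and
# for each seed the id of the node placed at it (terminal nodes).
grow_tree <- function(root, seeds, length_fraction, min_length) {
  n <- nrow(seeds)
  # root node plus one node per cloud (binary splitting creates 2n - 1 clouds)
  nodes <- matrix(NA_real_, 2 * n, 3)
  nodes[1, ] <- root
  edges <- matrix(NA_integer_, 2 * n - 1, 2)
  term_node <- integer(n)
  next_node <- 2L
  next_edge <- 1L
  stack <- list(list(tip = 1L, cloud = seq_len(n)))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    tip <- fr$tip
    cloud <- fr$cloud
    if (length(cloud) == 1L) {
      target <- seeds[cloud, ]
    } else {
      center <- colMeans(seeds[cloud, , drop = FALSE])
      dir <- center - nodes[tip, ]
      len <- sqrt(sum(dir^2))
      if (len < 1e-12) { dir <- c(-1, 0, 0); len <- 1 }
      step <- max(length_fraction * len, min(min_length, len))
      target <- nodes[tip, ] + dir / len * step
    }
    nid <- next_node; next_node <- next_node + 1L
    nodes[nid, ] <- target
    edges[next_edge, ] <- c(tip, nid); next_edge <- next_edge + 1L
    if (length(cloud) == 1L) {
      term_node[cloud] <- nid
    } else {
      sp <- bisect_cloud(seeds, cloud)
      stack[[length(stack) + 1L]] <- list(tip = nid, cloud = sp$right)
      stack[[length(stack) + 1L]] <- list(tip = nid, cloud = sp$left)
    }
  }
  list(nodes = nodes, edges = edges[seq_len(next_edge - 1L), , drop = FALSE],
       term_node = term_node)
}

#' Generate a synthetic pulmonary vascular network
#'
#' Builds paired arterial and venous bifurcating trees by volume-filling
#' branching (uniform seed points in the half-ellipsoid domain, recursive
#' point-cloud bisection through the centre of mass, branches from the
#' parent tip toward the sub-cloud centroid scaled by the length fraction),
#' both rooted at the hilum, then couples each arterial terminal to the
#' spatially nearest venous terminal through an arteriole - capillary -
#' venule unit. Element direction (`node_in` to `node_out`) is the flow
#' direction everywhere, so venous elements point toward the outlet.
#'
#' @param domain a [lung_domain()]
#' @param config a [geometry_config()]
#' @param seed integer; fixes all randomness (same seed, same config give
#'   byte-identical tables)
#' @return object of class `vascular_network`: list with `nodes` (id, x_mm,
#'   y_mm, z_mm), `elements` (id, node_in, node_out, type, radius0_mm,
#'   length_mm), `inlet_element`, `outlet_element`, `n_terminal_units`,
#'   `domain`, `config`
#' @export
generate_network <- function(domain, config = geometry_config(), seed = 1L) {
  if (any(domain$semi_axes <= config$min_length))
    stop("degenerate domain: every semi-axis must exceed min_length (",
         config$min_length, " mm)")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  n <- config$n_terminals
  db <- if (is.null(config$dorsal_density_bias)) 0 else config$dorsal_density_bias
  art_seeds <- sample_domain_points(domain, n, db)
  ven_seeds <- sample_domain_points(domain, n, db)

  art <- grow_tree(domain$hilum, art_seeds, config$length_fraction, config$min_length)
  ven <- grow_tree(domain$hilum, ven_seeds, config$length_fraction, config$min_length)

  na_art <- nrow(art$nodes)
  na_ven <- nrow(ven$nodes)

  # nearest venous terminal for each arterial terminal (many-to-one allowed)
  a_pos <- art$nodes[art$term_node, , drop = FALSE]
  v_pos <- ven$nodes[ven$term_node, , drop = FALSE]
  nearest <- vapply(seq_len(n), function(i) {
    d2 <- (v_pos[, 1] - a_pos[i, 1])^2 + (v_pos[, 2] - a_pos[i, 2])^2 +
      (v_pos[, 3] - a_pos[i, 3])^2
    which.min(d2)
  }, integer(1))

  # arterioles/venules are short (10% of the unit span each); the capillary
  # sheet path spans the remaining 80% between the terminal pair
  pA <- a_pos + 0.1 * (v_pos[nearest, , drop = FALSE] - a_pos)
  pB <- a_pos + 0.9 * (v_pos[nearest, , drop = FALSE] - a_pos)

  nodes <- rbind(art$nodes, ven$nodes, pA, pB)
  node_id <- seq_len(nrow(nodes))
  ven_off <- na_art
  capA_off <- na_art + na_ven
  capB_off <- na_art + na_ven + n

  seg_len <- function(m, i, j) sqrt(rowSums((m[i, , drop = FALSE] - m[j, , drop = FALSE])^2))

  art_edges <- art$edges
  ven_edges <- ven$edges
  art_len <- seg_len(nodes, art_edges[, 1], art_edges[, 2])
  # venous edges flipped: flow runs terminal -> root (outlet)
  ven_in <- ven_edges[, 2] + ven_off
  ven_out <- ven_edges[, 1] + ven_off
  ven_len <- seg_len(nodes, ven_in, ven_out)

  unit_art_node <- art$term_node
  unit_ven_node <- ven$term_node[nearest] + ven_off
  unit_nA <- capA_off + seq_len(n)
  unit_nB <- capB_off + seq_len(n)
  l_arteriole <- pmax(seg_len(nodes, unit_art_node, unit_nA), 1e-6)
  l_capillary <- pmax(seg_len(nodes, unit_nA, unit_nB), 1e-6)
  l_venule <- pmax(seg_len(nodes, unit_nB, unit_ven_node), 1e-6)

  elements <- data.frame(
    id = seq_len(nrow(art_edges) + nrow(ven_edges) + 3L * n),
    node_in = c(art_edges[, 1], ven_in, unit_art_node, unit_nA, unit_nB),
    node_out = c(art_edges[, 2], ven_out, unit_nA, unit_nB, unit_ven_node),
    type = c(rep("artery", nrow(art_edges)), rep("vein", nrow(ven_edges)),
             rep("arteriole", n), rep("capillary", n), rep("venule", n)),
    radius0_mm = NA_real_,
    length_mm = c(art_len, ven_len, l_arteriole, l_capillary, l_venule),
    stringsAsFactors = FALSE
  )

  inlet_element <- which(elements$type == "artery" & elements$node_in == 1L)[1]
  outlet_element <- which(elements$type == "vein" & elements$node_out == 1L + ven_off)[1]

  net <- structure(list(
    nodes = data.frame(id = node_id, x_mm = nodes[, 1], y_mm = nodes[, 2],
                       z_mm = nodes[, 3]),
    elements = elements,
    inlet_element = as.integer(elements$id[inlet_element]),
    outlet_element = as.integer(elements$id[outlet_element]),
    n_terminal_units = n,
    domain = domain,
    config = config
  ), class = "vascular_network")
  net <- assign_radii(net, config)
  validate_network(net)
  net
}

#' Assign vessel radii by Murray's law
#'
#' Terminal arterioles and venules get the configured terminal radius. The
#' terminal conduit branch feeding each unit is seeded with
#' `terminal_branch_radius` and parent radii follow Murray's law
#' r_parent^k = sum r_child^k, propagated root-ward, independently on the
#' arterial and venous trees. If `trunk_radius` is set it overrides the root
#' artery and root vein elements.
#'
#' @param network a `vascular_network` (topology built)
#' @param config a [geometry_config()]
#' @return the network with `radius0_mm` filled in
#' @export
assign_radii <- function(network, config = network$config) {
  el <- network$elements
  k <- config$murray_exponent
  seed_r <- config$terminal_branch_radius

  murray_up <- function(is_tree, root_element) {
    ids <- which(is_tree)
    sub <- el[ids, ]
    # children of element e: tree elements with node_in == e's node_out
    child_of <- split(seq_len(nrow(sub)), sub$node_in)
    r <- rep(NA_real_, nrow(sub))
    # depth-order: process leaves first (reverse BFS from root)
    root_local <- which(sub$id == root_element)
    ord <- integer(0)
    frontier <- root_local
    while (length(frontier) > 0) {
      ord <- c(ord, frontier)
      kids <- unlist(child_of[as.character(sub$node_out[frontier])], use.names = FALSE)
      frontier <- kids
    }
    for (e in rev(ord)) {
      kids <- child_of[[as.character(sub$node_out[e])]]
      r[e] <- if (is.null(kids) || length(kids) == 0) seed_r
      else sum(r[kids]^k)^(1 / k)
    }
    list(ids = ids, r = r)
  }

  a <- murray_up(el$type == "artery", network$inlet_element)
  el$radius0_mm[a$ids] <- a$r

  # venous tree: node_in/node_out follow flow, so Murray children of a vein
  # element are the vein elements draining INTO its node_in
  vid <- which(el$type == "vein")
  vsub <- el[vid, ]
  child_of <- split(seq_len(nrow(vsub)), vsub$node_out)
  rv <- rep(NA_real_, nrow(vsub))
  root_local <- which(vsub$id == network$outlet_element)
  ord <- integer(0)
  frontier <- root_local
  while (length(frontier) > 0) {
    ord <- c(ord, frontier)
    kids <- unlist(child_of[as.character(vsub$node_in[frontier])], use.names = FALSE)
    frontier <- kids
  }
  for (e in rev(ord)) {
    kids <- child_of[[as.character(vsub$node_in[e])]]
    rv[e] <- if (is.null(kids) || length(kids) == 0) seed_r
    else sum(rv[kids]^k)^(1 / k)
  }
  el$radius0_mm[vid] <- rv

  el$radius0_mm[el$type %in% c("arteriole", "venule", "capillary")] <-
    config$terminal_radius
  if (!is.null(config$trunk_radius)) {
    el$radius0_mm[el$id == network$inlet_element] <- config$trunk_radius
    el$radius0_mm[el$id == network$outlet_element] <- config$trunk_radius
  }
  network$elements <- el
  network
}

#' Terminal-unit table
#'
#' One row per capillary unit with the arteriole, capillary and venule
#' element ids, derived from element types and connectivity.
#'
#' @param network a `vascular_network`
#' @return data.frame(unit, arteriole, capillary, venule)
#' @export
terminal_units <- function(network) {
  el <- network$elements
  cap <- el[el$type == "capillary", ]
  art_by_out <- el$id[el$type == "arteriole"][match(cap$node_in, el$node_out[el$type == "arteriole"])]
  ven_by_in <- el$id[el$type == "venule"][match(cap$node_out, el$node_in[el$type == "venule"])]
  data.frame(unit = seq_len(nrow(cap)), arteriole = art_by_out,
             capillary = cap$id, venule = ven_by_in)
}
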