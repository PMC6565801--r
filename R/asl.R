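#' MR acquisition parameters
#'
#' Defaults follow a 1.5 T pulmonary ASL protocol: T1 = 1300 ms,
#' T2 = 254 ms, TE = 36 ms; TI is set per scenario (80% of the R-R
#' interval). The equilibrium longitudinal magnetization M_OB is 1.
#'
#' @param ti inversion time (ms)
#' @param t1 longitudinal relaxation time (ms)
#' @param t2 transverse relaxation time (ms)
#' @param te echo time (ms)
#' @param b0 field strength (T), informational
#' @param m_ob equilibrium longitudinal magnetization
#' @return object of class `mr_params`
#' @export
mr_params <- function(ti = 800, t1 = 1300, t2 = 254, te = 36, b0 = 1.5,
                      m_ob = 1) {
  if (any(c(ti, t1, t2, te) <= 0)) stop("TI, T1, T2 and TE must be > 0")
  structure(list(ti = ti, t1 = t1, t2 = t2, te = te, b0 = b0, m_ob = m_ob),
            class = "mr_params")
}

#' Sagittal slice plane
#'
#' Five 15 mm sagittal slices (index 1 = lateral, 5 = medial) tile the
#' central 75 mm of the lateral-medial extent; slice 5 touches the medial
#' face (x = 0) where the hilum sits.
#'
#' @param index slice index 1..5
#' @param thickness slice thickness (mm)
#' @param center through-plane centre (mm on the x axis); default places the
#'   five default slices edge to edge ending at the medial face
#' @return object of class `slice_plane`
#' @export
slice_plane <- function(index, thickness = 15, center = NULL) {
  if (thickness <= 0) stop("thickness must be > 0")
  if (is.null(center)) {
    if (!(index %in% 1:5)) stop("default slice index must be 1..5")
    center <- -67.5 + 15 * (index - 1)
  }
  structure(list(index = index, thickness = thickness, center = center,
                 half = thickness / 2, normal_axis = "x"),
            class = "slice_plane")
}

#' Inversion (labeling) profile
#'
#' Normalized longitudinal magnetization Mo(0)/M_OB as a function of signed
#' distance z from the slice centre along the slice normal: a plateau at -1
#' across the slice (fully inverted), rising through error-function
#' shoulders across the inversion gap to +1 well outside. A measured
#' profile can be supplied as a two-column table (z_mm, m0) and overrides
#' the parametric form (evaluated even-symmetrically in |z|).
#'
#' @param gap inversion-gap width beyond each slice face (mm); the 7.5 mm
#'   default makes the inversion band exceed the 15 mm imaging plane by
#'   ~15 mm in total
#' @param edge_sigma shoulder width (mm); default `gap / 6` so the
#'   transition spans the gap
#' @param table optional data.frame(z_mm, m0) tabulated profile
#' @return object of class `inversion_profile`
#' @export
inversion_profile <- function(gap = 7.5, edge_sigma = NULL, table = NULL) {
  if (gap < 0) stop("gap must be >= 0")
  if (is.null(edge_sigma)) edge_sigma <- max(gap / 6, 1e-6)
  if (!is.null(table)) {
    stopifnot(all(c("z_mm", "m0") %in% names(table)))
    table <- table[order(table$z_mm), ]
  }
  structure(list(gap = gap, edge_sigma = edge_sigma, table = table),
            class = "inversion_profile")
}

# erf via pnorm
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Evaluate the labeling profile and classify the origin
#'
#' @param z signed distance from slice centre along the slice normal (mm)
#' @param slice a [slice_plane()]
#' @param profile an [inversion_profile()]
#' @return list with `m0` (in `[-1, 1]`) and `in_band` (logical: inside
#'   slice + gap)
#' @export
magnetization_at_origin <- function(z, slice, profile = inversion_profile()) {
  if (!is.null(profile$table)) {
    f <- stats::approxfun(profile$table$z_mm, profile$table$m0, rule = 2)
    m0 <- f(abs(z))
  } else {
    z_edge <- slice$half + profile$gap / 2
    s <- 0.5 * (1 + erf((z_edge - abs(z)) / (sqrt(2) * profile$edge_sigma)))
    m0 <- 1 - 2 * s
  }
  list(m0 = pmin(pmax(m0, -1), 1),
       in_band = abs(z) < slice$half + profile$gap)
}

#' Inversion-recovery signal of a blood parcel
#'
#' Blood tagged inside the inversion band recovers from its initial
#' magnetization `m0 * M_OB`:
#' `S = [M_OB - (M_OB - m0 M_OB) exp(-TI/T1)] exp(-TE/T2) V_B`;
#' blood from outside the band carries full magnetization:
#' `S = M_OB exp(-TE/T2) V_B`. The two agree exactly at `m0 = 1`.
#' Negative (over-nulled) values are retained, not clamped.
#'
#' @param v_b parcel blood volume (mm^3)
#' @param m0 normalized magnetization at tagging, in `[-1, 1]`
#' @param in_band logical, origin inside the inversion band
#' @param mr an [mr_params()]
#' @return signal in volume-equivalent units (same scale as `v_b` up to the
#'   relaxation factors)
#' @export
parcel_signal <- function(v_b, m0, in_band, mr) {
  e2 <- exp(-mr$te / mr$t2)
  e1 <- exp(-mr$ti / mr$t1)
  ifelse(in_band,
         (mr$m_ob - (mr$m_ob - m0 * mr$m_ob) * e1) * e2 * v_b,
         mr$m_ob * e2 * v_b)
}

# vessel class of an element type
vessel_class <- function(type) {
  c(artery = "arterial", arteriole = "arterial", capillary = "capillary",
    venule = "venous", vein = "venous")[type]
}

#' Blood parcels inside a slice
#'
#' Every element intersecting the slab is subdivided into sub-segments of
#' at most `quantum` mm; each sub-segment whose midpoint lies inside the
#' slab becomes a parcel carrying its share of the element's blood volume.
#'
#' @param network a `vascular_network`
#' @param solution a converged `flow_solution`
#' @param slice a [slice_plane()]
#' @param quantum sub-segment length (mm)
#' @return data.frame(parcel, element, type, vclass, a_mm (arc position
#'   from the flow-upstream end), x, y, z (imaging-time position), volume)
#' @export
blood_in_slice <- function(network, solution, slice, quantum = 1) {
  el <- solution$elements
  nd <- network$nodes
  iu <- match(el$node_in, nd$id)
  iv <- match(el$node_out, nd$id)
  p_in <- as.matrix(nd[iu, c("x_mm", "y_mm", "z_mm")])
  p_out <- as.matrix(nd[iv, c("x_mm", "y_mm", "z_mm")])

  # quick slab rejection by element x-extent
  xlo <- pmin(p_in[, 1], p_out[, 1])
  xhi <- pmax(p_in[, 1], p_out[, 1])
  hit <- which(xhi >= slice$center - slice$half & xlo <= slice$center + slice$half)
  if (!length(hit))
    return(data.frame(parcel = integer(0), element = integer(0),
                      type = character(0), vclass = character(0),
                      a_mm = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), radius_mm = numeric(0),
                      volume = numeric(0)))
  ns <- pmax(1L, ceiling(el$length_mm[hit] / quantum))
  rep_i <- rep(hit, ns)
  frac <- (sequence(ns) - 0.5) / rep(ns, ns)
  px <- p_in[rep_i, 1] + frac * (p_out[rep_i, 1] - p_in[rep_i, 1])
  inside <- abs(px - slice$center) <= slice$half
  rep_i <- rep_i[inside]; frac <- frac[inside]; px <- px[inside]
  if (!length(rep_i))
    return(data.frame(parcel = integer(0), element = integer(0),
                      type = character(0), vclass = character(0),
                      a_mm = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), radius_mm = numeric(0),
                      volume = numeric(0)))
  py <- p_in[rep_i, 2] + frac * (p_out[rep_i, 2] - p_in[rep_i, 2])
  pz <- p_in[rep_i, 3] + frac * (p_out[rep_i, 3] - p_in[rep_i, 3])
  ns_rep <- rep(ns, ns)[inside]
  data.frame(
    parcel = seq_along(rep_i),
    element = el$id[rep_i],
    type = el$type[rep_i],
    vclass = unname(vessel_class(el$type[rep_i])),
    a_mm = frac * el$length_mm[rep_i],
    x = px, y = py, z = pz,
    radius_mm = el$radius_mm[rep_i],
    volume = el$V_B[rep_i] / ns_rep,
    stringsAsFactors = FALSE
  )
}

#' Trace parcels back to their tagging-time positions
#'
#' Walks each parcel upstream against the flow, consuming the TI time
#' budget at each element's mean velocity (distance = velocity x time).
#' At a junction fed by several elements (venous side) the parcel splits
#' into sub-parcels weighted by each feeder's flow fraction; sub-parcels
#' below `vol_floor` are merged into their siblings (total volume is
#' preserved exactly). A parcel reaching a node with no feeder (the network
#' inlet) is assigned origin class outside-band at that position; a parcel
#' stuck on a zero-velocity element is frozen in place (stagnant blood).
#'
#' @param parcels output of [blood_in_slice()]
#' @param network the network
#' @param solution the `flow_solution` used
#' @param ti inversion time (ms)
#' @param vol_floor merge threshold for split sub-parcels (mm^3)
#' @return data.frame(parcel, volume, ox, oy, oz, stagnant, exited_inlet):
#'   one row per origin sub-parcel; volumes within a parcel sum to the
#'   parcel volume
#' @export
trace_origin <- function(parcels, network, solution, ti, vol_floor = 1e-6) {
  if (ti < 0) stop("TI must be >= 0")
  el <- solution$elements
  nd <- network$nodes
  n_el <- nrow(el)
  iu0 <- match(el$node_in, nd$id)
  iv0 <- match(el$node_out, nd$id)
  # canonical flow orientation: upstream node carries the inflow
  fwd <- el$Q >= 0
  up_node <- ifelse(fwd, iu0, iv0)
  dn_node <- ifelse(fwd, iv0, iu0)
  speed <- abs(el$v)          # mm/s
  len <- el$length_mm
  pos <- as.matrix(nd[, c("x_mm", "y_mm", "z_mm")])
  q_abs <- abs(el$Q)

  # feeders of node n: elements whose downstream end is n and carry flow
  feeding <- which(q_abs > 1e-12)
  feeders_by_node <- split(feeding, dn_node[feeding])
  inflow <- vapply(feeders_by_node, function(ix) sum(q_abs[ix]), numeric(1))

  eix <- match(parcels$element, el$id)
  a <- ifelse(fwd[eix], parcels$a_mm, len[eix] - parcels$a_mm)
  st_e <- eix
  st_a <- a
  st_t <- rep(ti / 1000, nrow(parcels))  # seconds
  st_v <- parcels$volume
  st_p <- parcels$parcel

  out <- vector("list", 64)
  n_out <- 0L
  emit <- function(e, a, vol, pid, stagnant, exited) {
    frac <- ifelse(fwd[e], a / len[e], 1 - a / len[e])
    o <- pos[iu0[e], , drop = FALSE] +
      frac * (pos[iv0[e], , drop = FALSE] - pos[iu0[e], , drop = FALSE])
    n_out <<- n_out + 1L
    out[[n_out]] <<- data.frame(parcel = pid, volume = vol,
                                ox = o[, 1], oy = o[, 2], oz = o[, 3],
                                stagnant = stagnant, exited_inlet = exited)
  }
  emit_at_node <- function(node, vol, pid) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- data.frame(parcel = pid, volume = vol,
                                ox = pos[node, 1], oy = pos[node, 2],
                                oz = pos[node, 3],
                                stagnant = FALSE, exited_inlet = TRUE)
  }

  iter <- 0L
  while (length(st_e) > 0) {
    iter <- iter + 1L
    if (iter > 100000L) stop("backtrace failed to terminate")
    sp <- speed[st_e]
    stag <- sp <= 1e-9
    if (any(stag)) {
      emit(st_e[stag], st_a[stag], st_v[stag], st_p[stag], TRUE, FALSE)
      keep <- !stag
      st_e <- st_e[keep]; st_a <- st_a[keep]; st_t <- st_t[keep]
      st_v <- st_v[keep]; st_p <- st_p[keep]
      if (!length(st_e)) break
      sp <- speed[st_e]
    }
    travel <- sp * st_t
    done <- travel <= st_a
    if (any(done)) {
      emit(st_e[done], st_a[done] - travel[done], st_v[done], st_p[done],
           FALSE, FALSE)
    }
    not <- !done
    # remaining budget after reaching the upstream node
    st_t <- st_t[not] - st_a[not] / sp[not]
    st_e <- st_e[not]; st_a <- st_a[not]; st_v <- st_v[not]; st_p <- st_p[not]
    if (!length(st_e)) break
    node <- up_node[st_e]
    fb <- feeders_by_node[as.character(node)]
    nf <- lengths(fb)
    no_feed <- nf == 0L
    if (any(no_feed)) {
      emit_at_node(node[no_feed], st_v[no_feed], st_p[no_feed])
    }
    keep <- !no_feed
    node <- node[keep]; fb <- fb[keep]
    st_v <- st_v[keep]; st_p <- st_p[keep]; st_t <- st_t[keep]
    nf <- nf[keep]
    if (!length(node)) break
    parent_row <- rep(seq_along(node), nf)
    fe <- unlist(fb, use.names = FALSE)
    w <- q_abs[fe] / inflow[as.character(node)][parent_row]
    child_v <- st_v[parent_row] * w
    # merge sub-parcels below the floor into their siblings (per parent)
    if (any(nf > 1L)) {
      keep_c <- child_v >= vol_floor
      # always keep the largest child of each parent
      top <- tapply(child_v, parent_row, which.max)
      first_of <- match(unique(parent_row), parent_row)
      keep_c[first_of + unlist(top) - 1L] <- TRUE
      kept_sum <- tapply(child_v * keep_c, parent_row, sum)
      scale <- st_v[unique(parent_row)] / as.numeric(kept_sum)
      child_v <- child_v * scale[match(parent_row, unique(parent_row))]
      fe <- fe[keep_c]
      child_v <- child_v[keep_c]
      parent_row2 <- parent_row[keep_c]
    } else parent_row2 <- parent_row
    st_e <- fe
    st_a <- len[fe]
    st_t <- st_t[parent_row2]
    st_v <- child_v
    st_p <- st_p[parent_row2]
  }
  res <- do.call(rbind, out[seq_len(n_out)])
  if (is.null(res))
    res <- data.frame(parcel = integer(0), volume = numeric(0),
                      ox = numeric(0), oy = numeric(0), oz = numeric(0),
                      stagnant = logical(0), exited_inlet = logical(0))
  res[order(res$parcel), , drop = FALSE]
}

#' Voxelize parcel signals into the slice grid
#'
#' Builds the in-plane grid of 3 mm x 1.5 mm voxels (one 15 mm cell
#' through-plane) spanning the lung cross-section at the slice centre and
#' accumulates each parcel's signal and blood volume into the voxel
#' containing its imaging-time position, keeping capillary, arterial and
#' venous components separate. Signal is stored in volume-equivalent units
#' (raw inversion-recovery signal divided by `exp(-TE/T2)`), so a voxel
#' completely filled with fresh blood scores exactly the voxel volume
#' (67.5 at default dimensions) -- the 100% anchor of the threshold sweep.
#'
#' Capillary (acinar) blood, unlike conduit blood, fills tissue territories
#' rather than discrete tubes: with `cap_smear_radius > 0` each capillary
#' parcel's signal and volume are spread uniformly over the lung voxels
#' within that in-plane radius of its position (total exactly conserved),
#' emulating the sub-voxel capillary bed of the acinus the terminal unit
#' aggregates. Conduit (arterial/venous) parcels always deposit into the
#' single voxel containing them.
#'
#' @param parcels parcels with columns x, y, z, vclass, volume, signal
#'   (volume-equivalent)
#' @param slice a [slice_plane()]
#' @param domain the [lung_domain()] (for the lung mask)
#' @param mr the [mr_params()] used (TI recorded in the grid)
#' @param voxel_dims c(through-plane, y, z) voxel dimensions (mm)
#' @param cap_smear_radius in-plane radius (mm) over which capillary parcels
#'   are spread; 0 disables smearing
#' @return object of class `voxel_grid`: data.frame with voxel indices,
#'   centres, lung mask, per-component signal and blood volume, and totals;
#'   attributes record TI, voxel dimensions/volume and the full-voxel
#'   reference
#' @export
voxelize <- function(parcels, slice, domain, mr,
                     voxel_dims = c(15, 3, 1.5), cap_smear_radius = 0) {
  a <- domain$semi_axes
  xc <- slice$center
  # widest lung cross-section inside the slab (slab faces or x = 0)
  x_near <- if (xc - slice$half <= 0 && xc + slice$half >= 0) 0
  else min(abs(xc - slice$half), abs(xc + slice$half))
  s2 <- 1 - (x_near / a[1])^2
  s <- sqrt(max(s2, 0))
  y_ext <- a[2] * s
  z_ext <- a[3] * s
  ny <- max(1L, ceiling(2 * y_ext / voxel_dims[2]))
  nz <- max(1L, ceiling(2 * z_ext / voxel_dims[3]))
  y0 <- -ny * voxel_dims[2] / 2
  z0 <- -nz * voxel_dims[3] / 2
  yc <- y0 + (seq_len(ny) - 0.5) * voxel_dims[2]
  zc <- z0 + (seq_len(nz) - 0.5) * voxel_dims[3]
  vox <- expand.grid(i = seq_len(ny), j = seq_len(nz))
  vox$y_mm <- yc[vox$i]
  vox$z_mm <- zc[vox$j]
  # lung mask at the slice-centre cross-section; voxels that actually
  # receive blood are added to the mask after accumulation
  vox$in_lung <- in_domain(domain, cbind(xc, vox$y_mm, vox$z_mm))
  if (abs(xc) > domain$semi_axes[1]) vox$in_lung <- rep(FALSE, nrow(vox))
  for (cl in c("capillary", "arterial", "venous")) {
    vox[[cl]] <- 0
    vox[[paste0("vol_", cl)]] <- 0
  }
  if (nrow(parcels) > 0) {
    pi_ <- findInterval(parcels$y, y0 + (0:ny) * voxel_dims[2],
                        rightmost.closed = TRUE)
    pj <- findInterval(parcels$z, z0 + (0:nz) * voxel_dims[3],
                       rightmost.closed = TRUE)
    bad <- which(pi_ < 1 | pi_ > ny | pj < 1 | pj > nz)
    if (length(bad))
      stop("parcel(s) outside the voxel grid, e.g. parcel row ", bad[1],
           " at y = ", round(parcels$y[bad[1]], 2), ", z = ",
           round(parcels$z[bad[1]], 2), " mm (bounding-box bug)")
    cell <- (pj - 1L) * ny + pi_
    deposit <- function(cl, cells, sig, volb) {
      s <- rowsum(sig, cells)
      b <- rowsum(volb, cells)
      idx <- as.integer(rownames(s))
      vox[[cl]][idx] <<- vox[[cl]][idx] + s[, 1]
      vox[[paste0("vol_", cl)]][idx] <<- vox[[paste0("vol_", cl)]][idx] + b[, 1]
    }
    # effective in-plane footprint: acinar territory for capillary blood,
    # the vessel's own cross-section for conduit blood
    eff_r <- ifelse(parcels$vclass == "capillary", cap_smear_radius,
                    if ("radius_mm" %in% names(parcels)) parcels$radius_mm else 0)
    r_pt <- min(voxel_dims[2:3]) / 2
    smear_grp <- ifelse(eff_r > r_pt, ceiling(eff_r / r_pt), 0L)
    lung_only <- parcels$vclass == "capillary"
    for (cl in c("capillary", "arterial", "venous")) {
      sel <- parcels$vclass == cl & smear_grp == 0L
      if (any(sel))
        deposit(cl, cell[sel], parcels$signal[sel], parcels$volume[sel])
    }
    for (grp in setdiff(unique(smear_grp), 0L)) {
      w <- which(smear_grp == grp)
      r_g <- max(eff_r[w])
      mi <- ceiling(r_g / voxel_dims[2])
      mj <- ceiling(r_g / voxel_dims[3])
      off <- expand.grid(di = -mi:mi, dj = -mj:mj)
      off <- off[(off$di * voxel_dims[2])^2 + (off$dj * voxel_dims[3])^2 <=
                   r_g^2, ]
      n_off <- nrow(off)
      ti_ <- rep(pi_[w], each = n_off) + rep(off$di, length(w))
      tj <- rep(pj[w], each = n_off) + rep(off$dj, length(w))
      src <- rep(seq_along(w), each = n_off)
      ok <- ti_ >= 1 & ti_ <= ny & tj >= 1 & tj <= nz
      tcell <- (tj - 1L) * ny + ti_
      # capillary blood spreads over lung voxels only
      restr <- lung_only[w[src]]
      ok[ok & restr] <- vox$in_lung[tcell[ok & restr]]
      n_ok <- tabulate(src[ok], nbins = length(w))
      # parcels with no valid receiver fall back to their own voxel
      fb <- which(n_ok == 0)
      for (cl in unique(parcels$vclass[w])) {
        sel_fb <- w[fb][parcels$vclass[w[fb]] == cl]
        if (length(sel_fb))
          deposit(cl, cell[sel_fb], parcels$signal[sel_fb],
                  parcels$volume[sel_fb])
        keep <- ok & n_ok[src] > 0 & parcels$vclass[w[src]] == cl
        if (any(keep)) {
          share <- 1 / n_ok[src[keep]]
          deposit(cl, tcell[keep],
                  parcels$signal[w[src[keep]]] * share,
                  parcels$volume[w[src[keep]]] * share)
        }
      }
    }
  }
  vox$total <- vox$capillary + vox$arterial + vox$venous
  vox$vol_total <- vox$vol_capillary + vox$vol_arterial + vox$vol_venous
  vox$in_lung <- vox$in_lung | vox$vol_total > 0
  structure(vox, class = c("voxel_grid", "data.frame"),
            slice_index = slice$index, slice_center = xc,
            ti = mr$ti, voxel_dims = voxel_dims,
            voxel_volume = prod(voxel_dims),
            s_full = prod(voxel_dims),
            dims = c(ny, nz))
}

#' Per-voxel ASL rate
#'
#' Converts the delivered (signal-weighted, volume-equivalent) blood volume
#' of each voxel to a perfusion-style rate in mL/min/cm^3:
#' `rate = (delivered / voxel volume) * 60000 / TI`. The full-voxel
#' reference in rate units is `60000 / TI`.
#'
#' @param grid a `voxel_grid`
#' @param component which signal component to convert ("total",
#'   "capillary", "arterial", "venous")
#' @return numeric vector of per-voxel rates
#' @export
asl_rate <- function(grid, component = "total") {
  ti <- attr(grid, "ti")
  grid[[component]] / attr(grid, "voxel_volume") * (60000 / ti)
}

#' Simulate the ASL bright image for one slice
#'
#' Runs the three-step forward model: collect all blood inside the slab,
#' trace each parcel back to its tagging-time position, apply the labeling
#' profile and the inversion-recovery signal equations, and voxelize with
#' capillary/arterial/venous component labels. Parcels whose trace exits
#' the network inlet are treated as fully magnetized (outside-band) blood.
#'
#' @param network a `vascular_network`
#' @param solution a converged `flow_solution`
#' @param slice a [slice_plane()]
#' @param mr an [mr_params()]
#' @param profile an [inversion_profile()]
#' @param quantum parcel discretization (mm)
#' @param voxel_dims voxel dimensions (mm)
#' @param cap_smear_radius in-plane smear radius for capillary (acinar)
#'   blood; the default is the radius of a sphere holding one terminal
#'   unit's share of the domain volume, so unit territories tile the lung
#' @return a `voxel_grid`
#' @export
simulate_asl_slice <- function(network, solution, slice, mr = mr_params(),
                               profile = inversion_profile(), quantum = 1,
                               voxel_dims = c(15, 3, 1.5),
                               cap_smear_radius = NULL) {
  if (is.null(cap_smear_radius)) {
    a <- network$domain$semi_axes
    v_unit <- (2 / 3) * pi * a[1] * a[2] * a[3] / network$n_terminal_units
    cap_smear_radius <- (3 * v_unit / (4 * pi))^(1 / 3)
  }
  parcels <- blood_in_slice(network, solution, slice, quantum)
  if (nrow(parcels) == 0)
    return(voxelize(cbind(parcels, signal = numeric(0)), slice,
                    network$domain, mr, voxel_dims))
  orig <- trace_origin(parcels, network, solution, mr$ti)
  mag <- magnetization_at_origin(orig$ox - slice$center, slice, profile)
  m0 <- mag$m0
  in_band <- mag$in_band & !orig$exited_inlet
  raw <- parcel_signal(orig$volume, m0, in_band, mr)
  sig_ve <- raw / exp(-mr$te / mr$t2)   # volume-equivalent units
  sub <- parcels[match(orig$parcel, parcels$parcel), ]
  sub$volume <- orig$volume
  sub$signal <- sig_ve
  voxelize(sub, slice, network$domain, mr, voxel_dims, cap_smear_radius)
}

#' Export a voxel grid as tidy CSV
#'
#' @param grid a `voxel_grid`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_voxel_csv <- function(grid, path) {
  df <- as.data.frame(grid)
  df$rate <- asl_rate(grid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a voxel grid as NIfTI volumes
#'
#' Writes one single-slice NIfTI file per component plus the total, with an
#' affine encoding the mm grid. Requires the RNifti package.
#'
#' @param grid a `voxel_grid`
#' @param dir output directory
#' @return the directory, invisibly
#' @export
write_voxel_nifti <- function(grid, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- attr(grid, "dims")
  vd <- attr(grid, "voxel_dims")
  for (cl in c("capillary", "arterial", "venous", "total")) {
    img <- array(0, c(1, dims[1], dims[2]))
    img[1, cbind(grid$i, grid$j)] <- grid[[cl]]
    nii <- RNifti::asNifti(img)
    RNifti::pixdim(nii) <- c(vd[1], vd[2], vd[3])
    RNifti::writeNifti(nii, file.path(dir, paste0(cl, ".nii.gz")))
  }
  invisible(dir)
}
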