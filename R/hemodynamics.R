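#' Blood properties
#'
#' @param density blood density (kg m^-3)
#' @param viscosity dynamic viscosity of whole blood in conduit vessels,
#'   arterioles and venules (Pa s)
#' @param cap_viscosity apparent viscosity in the capillary sheet (Pa s);
#'   enters the model through the aggregated sheet conductance calibration
#' @return object of class `blood_properties`
#' @export
blood_properties <- function(density = 1050, viscosity = 3.36e-3,
                             cap_viscosity = 1.92e-3) {
  if (density <= 0 || viscosity <= 0 || cap_viscosity <= 0)
    stop("blood properties must be positive")
  structure(list(density = density, viscosity = viscosity,
                 cap_viscosity = cap_viscosity), class = "blood_properties")
}

#' Gravity state
#'
#' Supine posture has gravity acting toward the dorsal side (-y in the
#' domain frame); prone reverses the direction.
#'
#' @param posture "supine" or "prone"
#' @param magnitude g (m s^-2)
#' @return object of class `gravity_state` with a unit `direction` vector
#' @export
gravity_state <- function(posture = c("supine", "prone"), magnitude = 9.81) {
  posture <- match.arg(posture)
  dir <- if (posture == "supine") c(0, -1, 0) else c(0, 1, 0)
  structure(list(posture = posture, magnitude = magnitude, direction = dir),
            class = "gravity_state")
}

#' Flow boundary conditions
#'
#' @param co cardiac output applied at the pulmonary trunk (L/min)
#' @param p_la left atrial pressure applied at the outlet (mmHg)
#' @return object of class `boundary_conditions`
#' @export
boundary_conditions <- function(co = 5, p_la = 5) {
  if (co <= 0) stop("cardiac output must be > 0")
  structure(list(co = co, p_la = p_la), class = "boundary_conditions")
}

#' Conduit vessel distension parameters
#'
#' Linear radius-transmural-pressure law with a saturation cap; negative
#' transmural pressure leaves conduit vessels at their reference radius
#' (no collapse).
#'
#' @param alpha_d fractional radius change per cmH2O
#' @param max_ratio maximum distension ratio r/r0
#' @param p_external external (pleural/alveolar) reference pressure (Pa)
#' @return object of class `distension_params`
#' @export
distension_params <- function(alpha_d = 0.02, max_ratio = 1.5, p_external = 0) {
  if (alpha_d < 0) stop("alpha_d must be >= 0")
  structure(list(alpha_d = alpha_d, max_ratio = max_ratio,
                 p_external = p_external), class = "distension_params")
}

#' Fung-Sobin capillary sheet parameters
#'
#' The alveolar septum is treated as a compliant sheet whose thickness, and
#' hence conductance, grows linearly with transmural pressure; flow across
#' a unit is `c_sheet * f * (h_a^4 - h_v^4)` with zone-2 sluicing when the
#' venular transmural pressure is negative and recruitment fraction `f`
#' rising with arteriolar transmural pressure.
#'
#' @param h0 reference sheet thickness (um) at zero transmural pressure
#' @param alpha_c sheet compliance (um per cmH2O)
#' @param c_sheet aggregated sheet conductance (mm^3 s^-1 per um^4) per
#'   terminal unit; `NULL` requests calibration at solve time so the total
#'   trunk-to-atrium pressure drop at 5 L/min sits in a physiological window
#' @param h_max maximum sheet thickness (um)
#' @param eps_collapse residual thickness fraction when the sheet collapses
#'   (transmural pressure <= 0)
#' @param p_full_recruit arteriolar transmural pressure (cmH2O) at which the
#'   sheet is fully recruited
#' @param f_min minimum open fraction
#' @param sheet_area capillary sheet area per terminal unit (mm^2); with the
#'   thickness this sets capillary blood volume
#' @return object of class `sheet_params`
#' @export
sheet_params <- function(h0 = 3.5, alpha_c = 0.127, c_sheet = NULL,
                         h_max = 7, eps_collapse = 0.01,
                         p_full_recruit = 10, f_min = 0.1,
                         sheet_area = 1e4) {
  if (h0 <= 0) stop("h0 must be > 0")
  if (alpha_c < 0) stop("alpha_c must be >= 0")
  structure(list(h0 = h0, alpha_c = alpha_c, c_sheet = c_sheet, h_max = h_max,
                 eps_collapse = eps_collapse, p_full_recruit = p_full_recruit,
                 f_min = f_min, sheet_area = sheet_area),
            class = "sheet_params")
}

#' Poiseuille resistance of a cylindrical vessel
#'
#' @param length vessel length (mm)
#' @param radius vessel radius (mm)
#' @param viscosity dynamic viscosity (Pa s)
#' @return resistance 8 mu L / (pi r^4) in Pa s mm^-3
#' @export
poiseuille_resistance <- function(length, radius, viscosity) {
  if (any(length <= 0) || any(radius <= 0) || any(viscosity <= 0))
    stop("length, radius and viscosity must be > 0")
  8 * viscosity * length / (pi * radius^4)
}

#' Hydrostatic pressure offset along an element
#'
#' Returns `rho g (h_in - h_out)` (Pa) where h is the height of each
#' endpoint against the gravity direction; the momentum balance is
#' `P_out = P_in - Q R + rho g (h_in - h_out)`, so blood flowing downward
#' gains pressure.
#'
#' @param p_in,p_out endpoint positions (mm), vectors or n x 3 matrices
#' @param gravity a [gravity_state()]
#' @param density blood density (kg m^-3)
#' @return pressure offset (Pa)
#' @export
hydrostatic_drop <- function(p_in, p_out, gravity, density = 1050) {
  p_in <- matrix(as.numeric(p_in), ncol = 3)
  p_out <- matrix(as.numeric(p_out), ncol = 3)
  up <- -gravity$direction
  h_in <- drop(p_in %*% up) * 1e-3   # mm -> m
  h_out <- drop(p_out %*% up) * 1e-3
  density * gravity$magnitude * (h_in - h_out)
}

#' Distended conduit radius
#'
#' @param r0 reference radius (mm)
#' @param ptm transmural pressure (Pa)
#' @param params a [distension_params()]
#' @return radius (mm), monotone non-decreasing in `ptm`
#' @export
distended_radius <- function(r0, ptm, params = distension_params()) {
  if (any(r0 <= 0)) stop("r0 must be > 0")
  ptm_cm <- Pa_to_cmH2O(ptm)
  ratio <- pmin(1 + params$alpha_d * pmax(ptm_cm, 0), params$max_ratio)
  r0 * ratio
}

# sheet thickness law (um); ptm in Pa. The collapse at negative transmural
# pressure is a continuous ramp down to the residual thickness
# h0 * eps_collapse (a discontinuous jump at zero admits no fixed point and
# makes the flow solve cycle).
sheet_thickness <- function(ptm, params) {
  ptm_cm <- Pa_to_cmH2O(ptm)
  pmin(pmax(params$h0 + params$alpha_c * ptm_cm,
            params$h0 * params$eps_collapse), params$h_max)
}

# fourth-power sheet potential with linear extensions beyond the thickness
# caps: inside the compliant range phi = h(Ptm)^4; outside, phi continues
# with the tangent slope 4 h^3 alpha so a fully distended (or collapsed)
# sheet still conducts and the flow law stays strictly monotone
sheet_potential <- function(ptm, params) {
  p_cm <- Pa_to_cmH2O(ptm)
  h_lin <- params$h0 + params$alpha_c * p_cm
  h_flr <- params$h0 * params$eps_collapse
  p_hi <- (params$h_max - params$h0) / params$alpha_c
  p_lo <- (h_flr - params$h0) / params$alpha_c
  ifelse(p_cm > p_hi,
         params$h_max^4 + 4 * params$h_max^3 * params$alpha_c * (p_cm - p_hi),
         ifelse(p_cm < p_lo,
                h_flr^4 + 4 * h_flr^3 * params$alpha_c * (p_cm - p_lo),
                h_lin^4))
}

#' Fung-Sobin sheet flow through a terminal capillary unit
#'
#' Flow is `c_sheet * f * (phi(Ptm_a) - phi_v)` where `phi` is the
#' fourth power of the compliant sheet thickness (extended linearly beyond
#' the thickness caps so a saturated sheet still conducts). In zone 2
#' (venular transmural pressure <= 0 < arteriolar) the downstream potential
#' is the zero-pressure value h0^4 (sluicing: flow is independent of
#' venular pressure); the recruitment fraction is
#' `f = clamp(Ptm_a / p_full_recruit, f_min, 1)`.
#'
#' @param ptm_a arteriolar-end transmural pressure (Pa)
#' @param ptm_v venular-end transmural pressure (Pa)
#' @param params a [sheet_params()] with `c_sheet` set
#' @return flow (mm^3 s^-1)
#' @export
sheet_flow <- function(ptm_a, ptm_v, params = sheet_params(c_sheet = 1)) {
  if (is.null(params$c_sheet))
    stop("sheet_params$c_sheet is not set (run calibrate_sheet_conductance)")
  phi_a <- sheet_potential(ptm_a, params)
  phi_v <- ifelse(Pa_to_cmH2O(ptm_v) <= 0 & Pa_to_cmH2O(ptm_a) > 0,
                  params$h0^4, sheet_potential(ptm_v, params))
  f <- pmin(pmax(Pa_to_cmH2O(ptm_a) / params$p_full_recruit, params$f_min), 1)
  params$c_sheet * f * (phi_a - phi_v)
}

# --- solver internals -------------------------------------------------------

# per-element hydraulic state used by the fixed-point loop
element_tables <- function(network, blood, gravity, n_parallel) {
  el <- network$elements
  nd <- network$nodes
  iu <- match(el$node_in, nd$id)
  iv <- match(el$node_out, nd$id)
  pos <- as.matrix(nd[, c("x_mm", "y_mm", "z_mm")])
  b <- numeric(nrow(el))
  conduits <- el$type %in% c("artery", "vein")
  if (any(conduits))
    b[conduits] <- hydrostatic_drop(pos[iu[conduits], , drop = FALSE],
                                    pos[iv[conduits], , drop = FALSE],
                                    gravity, blood$density)
  list(el = el, iu = iu, iv = iv, b = b,
       is_cond = conduits,
       is_cap = el$type == "capillary",
       is_micro = el$type %in% c("arteriole", "venule"),
       n_par = n_parallel)
}

solve_linear_system <- function(tab, G, co_mm3s, p_la_pa, outlet_node) {
  n <- max(tab$iu, tab$iv)
  iu <- tab$iu; iv <- tab$iv
  i <- c(iu, iu, iv, iv)
  j <- c(iu, iv, iv, iu)
  x <- c(G, -G, G, -G)
  rhs <- numeric(n)
  rhs_add <- tapply(c(-G * tab$b, G * tab$b), c(iu, iv), sum)
  rhs[as.integer(names(rhs_add))] <- rhs_add
  inlet_node <- iu[tab$el$id == attr(tab, "inlet_element")]
  keep <- i != outlet_node
  A <- Matrix::sparseMatrix(i = c(i[keep], outlet_node),
                            j = c(j[keep], outlet_node),
                            x = c(x[keep], 1), dims = c(n, n))
  rhs[outlet_node] <- p_la_pa
  rhs[attr(tab, "inlet_node")] <- rhs[attr(tab, "inlet_node")] + co_mm3s
  as.numeric(Matrix::solve(A, rhs))
}

default_n_parallel <- function(network) {
  if (!is.null(network$config) && !is.null(network$config$n_parallel))
    return(network$config$n_parallel)
  max(1, round(7.5e5 / network$n_terminal_units))
}

#' Calibrate the aggregated sheet conductance
#'
#' Chooses `c_sheet` so that the trunk-to-atrium pressure drop at a
#' reference cardiac output of 5 L/min lies in a physiological window
#' (default 10 mmHg): the conduit-only drop is measured with capillaries
#' shorted, the remaining drop is assigned to the capillary beds, and
#' `c_sheet` is set from the nominal sheet thicknesses at the implied
#' transmural pressures.
#'
#' @param network a `vascular_network`
#' @param blood a [blood_properties()]
#' @param sheet a [sheet_params()]
#' @param target_drop_mmHg target total pressure drop at 5 L/min
#' @return `c_sheet` (mm^3 s^-1 per um^4) with a `calibration` attribute
#'   recording the conduit and capillary drops used
#' @export
calibrate_sheet_conductance <- function(network, blood = blood_properties(),
                                        sheet = sheet_params(),
                                        target_drop_mmHg = 10) {
  n_par <- default_n_parallel(network)
  tab <- element_tables(network, blood, gravity_state("supine", magnitude = 0),
                        n_par)
  attr(tab, "inlet_element") <- network$inlet_element
  attr(tab, "inlet_node") <- tab$iu[tab$el$id == network$inlet_element]
  outlet_node <- tab$iv[tab$el$id == network$outlet_element]
  R <- poiseuille_resistance(tab$el$length_mm, tab$el$radius0_mm, blood$viscosity)
  G <- 1 / R
  G[tab$is_micro] <- n_par / R[tab$is_micro]
  G[tab$is_cap] <- max(G) * 1e3          # shorted capillaries
  co <- Lmin_to_mm3s(5)
  P <- solve_linear_system(tab, G, co, mmHg_to_Pa(5), outlet_node)
  drop_conduit <- P[attr(tab, "inlet_node")] - mmHg_to_Pa(5)
  target <- mmHg_to_Pa(target_drop_mmHg)
  drop_cap <- min(max(target - drop_conduit, 0.2 * target), target)
  g_unit <- (co / network$n_terminal_units) / drop_cap
  ptm_v <- mmHg_to_Pa(5)
  ptm_a <- ptm_v + drop_cap
  h_a <- sheet_thickness(ptm_a, sheet)
  h_v <- sheet_thickness(ptm_v, sheet)
  f <- min(max(Pa_to_cmH2O(ptm_a) / sheet$p_full_recruit, sheet$f_min), 1)
  c_sheet <- g_unit * drop_cap / (f * (h_a^4 - h_v^4))
  structure(c_sheet, calibration = list(
    conduit_drop_mmHg = drop_conduit / mmHg_to_Pa(1),
    capillary_drop_mmHg = drop_cap / mmHg_to_Pa(1),
    target_drop_mmHg = target_drop_mmHg, n_parallel = n_par))
}

#' Solve steady-state network hemodynamics
#'
#' Damped fixed-point iteration: with the current radii and sheet
#' thicknesses each element is linearized to a conductance (conduits:
#' Poiseuille; capillaries: secant conductance of the sheet-flow law), the
#' sparse node conservation system is solved with the inlet total-flow and
#' outlet pressure constraints and hydrostatic offsets as element source
#' terms, then radii and thicknesses are updated from the new transmural
#' pressures (damping 0.5) until the maximum relative pressure change falls
#' below `tol`.
#'
#' @param network a valid `vascular_network`
#' @param bc a [boundary_conditions()]
#' @param blood a [blood_properties()]
#' @param gravity a [gravity_state()]
#' @param dist a [distension_params()]
#' @param sheet a [sheet_params()]; `c_sheet = NULL` triggers
#'   [calibrate_sheet_conductance()] (logged in the solution)
#' @param tol relative pressure-change tolerance
#' @param max_iter maximum fixed-point iterations
#' @param rigid if `TRUE`, freeze radii at their reference values and every
#'   capillary conductance at its reference-thickness value
#'   `c_sheet h0^4 / (1 cmH2O)`; the problem becomes a single linear solve
#' @return object of class `flow_solution`: per-node pressures (Pa),
#'   per-element flow Q (mm^3/s), mean velocity v (mm/s), blood volume V_B
#'   (mm^3), end pressures, plus a convergence record
#' @export
solve_flow <- function(network, bc = boundary_conditions(),
                       blood = blood_properties(),
                       gravity = gravity_state("supine"),
                       dist = distension_params(),
                       sheet = sheet_params(),
                       tol = 1e-6, max_iter = 200, rigid = FALSE) {
  validate_network(network)
  n_par <- default_n_parallel(network)
  if (is.null(sheet$c_sheet)) {
    cal <- calibrate_sheet_conductance(network, blood, sheet)
    sheet$c_sheet <- as.numeric(cal)
    calibration <- attr(cal, "calibration")
  } else calibration <- NULL

  tab <- element_tables(network, blood, gravity, n_par)
  attr(tab, "inlet_element") <- network$inlet_element
  attr(tab, "inlet_node") <- tab$iu[tab$el$id == network$inlet_element]
  outlet_node <- tab$iv[tab$el$id == network$outlet_element]
  co <- Lmin_to_mm3s(bc$co)
  p_la <- mmHg_to_Pa(bc$p_la)

  el <- tab$el
  r_cur <- el$radius0_mm
  # initial capillary conductance: reference-thickness sheet conductance,
  # also the frozen value in rigid mode
  g_cap0 <- sheet$c_sheet * sheet$h0^4 / cmH2O_to_Pa(1)
  G_cap <- rep(g_cap0, sum(tab$is_cap))

  P_old <- NULL
  resid <- numeric(0)
  h_a <- h_v <- rep(sheet$h0, sum(tab$is_cap))
  relax <- 0.5   # annealed if the fixed point cycles
  for (it in seq_len(max_iter)) {
    R <- poiseuille_resistance(el$length_mm, r_cur, blood$viscosity)
    G <- 1 / R
    G[tab$is_micro] <- n_par / R[tab$is_micro]
    G[tab$is_cap] <- pmax(G_cap, 1e-12)
    P <- solve_linear_system(tab, G, co, p_la, outlet_node)
    if (!is.null(P_old)) {
      resid[it] <- max(abs(P - P_old) / pmax(abs(P), 1))
      if (resid[it] < tol) { P_old <- P; break }
    } else resid[it] <- Inf
    P_old <- P
    if (rigid) { if (it >= 2) break; next }
    # anneal the relaxation once past the initial transient so that
    # open/close limit cycles on heterogeneous networks contract
    if (it > 20) relax <- max(0.01, relax * 0.93)
    # geometry update from new transmural pressures, damped
    ptm_mid <- 0.5 * (P[tab$iu] + P[tab$iv]) - dist$p_external
    r_target <- r_cur
    r_target[tab$is_cond] <- distended_radius(el$radius0_mm[tab$is_cond],
                                              ptm_mid[tab$is_cond], dist)
    r_cur <- r_cur + relax * (r_target - r_cur)
    ci <- which(tab$is_cap)
    ptm_a <- P[tab$iu[ci]]
    ptm_v <- P[tab$iv[ci]]
    q_nl <- sheet_flow(ptm_a, ptm_v, sheet)
    dp <- ptm_a - ptm_v
    g_target <- ifelse(abs(dp) > 1e-9, q_nl / dp, G_cap)
    # reverse-biased sheets close (Starling-resistor behaviour): no
    # sustained retrograde capillary flow; the closure floor is relative to
    # the reference conductance to keep the system well conditioned
    g_eps <- 1e-6 * g_cap0
    g_target[q_nl < 0] <- g_eps
    g_target <- pmax(g_target, g_eps)
    # trust region: conductances move at most 4x per iteration, which
    # damps open/close limit cycles on strongly heterogeneous networks
    g_target <- pmin(pmax(g_target, G_cap / 4), G_cap * 4)
    G_cap <- G_cap + relax * (g_target - G_cap)
    h_a <- sheet_thickness(ptm_a, sheet)
    h_v <- ifelse(Pa_to_cmH2O(ptm_v) <= 0 & Pa_to_cmH2O(ptm_a) > 0,
                  sheet$h0, sheet_thickness(ptm_v, sheet))
  }
  converged <- length(resid) > 0 && resid[length(resid)] < tol
  if (!converged && !rigid) {
    cond <- structure(class = c("pulmoasl_no_convergence", "error", "condition"),
                      list(message = paste0("flow solve did not converge in ",
                                            max_iter, " iterations; final residual ",
                                            signif(resid[length(resid)], 4)),
                           call = NULL, residuals = resid))
    stop(cond)
  }
  P <- P_old
  R <- poiseuille_resistance(el$length_mm, r_cur, blood$viscosity)
  G <- 1 / R
  G[tab$is_micro] <- n_par / R[tab$is_micro]
  G[tab$is_cap] <- pmax(G_cap, 1e-12)
  Q <- G * (P[tab$iu] - P[tab$iv] + tab$b)

  v <- numeric(nrow(el))
  V_B <- numeric(nrow(el))
  cond_or_micro <- tab$is_cond | tab$is_micro
  area <- pi * r_cur^2
  v[tab$is_cond] <- Q[tab$is_cond] / area[tab$is_cond]
  v[tab$is_micro] <- Q[tab$is_micro] / (n_par * area[tab$is_micro])
  V_B[tab$is_cond] <- area[tab$is_cond] * el$length_mm[tab$is_cond]
  V_B[tab$is_micro] <- n_par * area[tab$is_micro] * el$length_mm[tab$is_micro]
  ci <- which(tab$is_cap)
  h_mean_mm <- 0.5 * (h_a + h_v) * 1e-3
  V_B[ci] <- sheet$sheet_area * h_mean_mm
  v[ci] <- Q[ci] * el$length_mm[ci] / V_B[ci]

  structure(list(
    node_pressure = stats::setNames(P, network$nodes$id),
    elements = data.frame(
      id = el$id, type = el$type, node_in = el$node_in, node_out = el$node_out,
      Q = Q, v = v, V_B = V_B,
      P_in = P[tab$iu], P_out = P[tab$iv], radius_mm = r_cur,
      length_mm = el$length_mm, stringsAsFactors = FALSE),
    co = bc$co, posture = gravity$posture,
    iterations = length(resid), residuals = resid,
    converged = converged, calibration = calibration,
    sheet = sheet, n_parallel = n_par
  ), class = "flow_solution")
}

#' Per-element velocity and blood volume
#'
#' Conduits: `v = Q / (pi r^2)`, `V_B = pi r^2 L` at the distended radius
#' (arterioles/venules per parallel channel); capillaries: `V_B` is sheet
#' area times mean thickness and `v = Q L / V_B` (plug transit speed).
#'
#' @param solution a `flow_solution`
#' @param network the solved network (unused; kept for interface symmetry)
#' @return data.frame(id, type, v, V_B)
#' @export
element_velocity_and_volume <- function(solution, network = NULL) {
  solution$elements[, c("id", "type", "v", "V_B")]
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> CO ", x$co, " L/min, ", x$posture, ", ",
      x$iterations, " iterations, residual ",
      signif(x$residuals[length(x$residuals)], 3), "\n", sep = "")
  drop_mmHg <- (max(x$elements$P_in) - min(x$elements$P_out)) / mmHg_to_Pa(1)
  cat("  trunk-to-atrium pressure drop ~", signif(drop_mmHg, 3), "mmHg\n")
  invisible(x)
}
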