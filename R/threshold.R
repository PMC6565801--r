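#' Apply an intensity threshold to a voxel grid
#'
#' Voxels whose total (volume-equivalent) signal strictly exceeds
#' `x/100 * S_full` are removed entirely, all components together; the
#' 100% anchor `S_full` is the fully blood-filled voxel (67.5 at default
#' dimensions). Boundary equality is retained.
#'
#' @param grid a `voxel_grid`
#' @param x threshold in percent, `0 < x <= 100`
#' @return the filtered `voxel_grid` (removed voxels dropped)
#' @export
apply_threshold <- function(grid, x) {
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  s_full <- attr(grid, "s_full")
  keep <- grid$total <= (x / 100) * s_full
  out <- grid[keep, , drop = FALSE]
  for (at in c("slice_index", "slice_center", "ti", "voxel_dims",
               "voxel_volume", "s_full", "dims"))
    attr(out, at) <- attr(grid, at)
  class(out) <- class(grid)
  out
}

#' Lung-masked voxels of a grid
#'
#' @param grid a `voxel_grid`
#' @return the rows flagged as lung (all metrics operate on these)
#' @export
lung_voxels <- function(grid) grid[grid$in_lung, , drop = FALSE]

#' Perfusion metrics of a thresholded grid
#'
#' `Q_fraction` is the capillary share of the total signal in the filtered
#' grid; `Q_remain` the capillary signal retained relative to the
#' unfiltered grid; `C_removed` the conduit (arterial + venous) signal
#' removed, `1 - after/prior`. Setting `literal_c_removed = TRUE` returns
#' the remaining-fraction reading instead (after/prior).
#'
#' @param filtered,unfiltered `voxel_grid`s with the same geometry
#' @param literal_c_removed report the conduit signal remaining instead of
#'   removed
#' @return list(Q_fraction, Q_remain, C_removed), each in `[0, 1]` for
#'   non-negative signal fields
#' @export
perfusion_metrics <- function(filtered, unfiltered,
                              literal_c_removed = FALSE) {
  f <- lung_voxels(filtered); u <- lung_voxels(unfiltered)
  cap_f <- sum(f$capillary); cap_u <- sum(u$capillary)
  con_f <- sum(f$arterial + f$venous); con_u <- sum(u$arterial + u$venous)
  tot_f <- sum(f$total)
  q_fraction <- if (tot_f == 0) 0 else cap_f / tot_f
  q_remain <- if (cap_u == 0) 1 else cap_f / cap_u
  c_removed <- if (con_u == 0) 1 else 1 - con_f / con_u
  if (literal_c_removed) c_removed <- if (con_u == 0) 0 else con_f / con_u
  list(Q_fraction = q_fraction, Q_remain = q_remain, C_removed = c_removed)
}

#' Gravitational gradient of a voxel field
#'
#' Bins retained lung voxels into `n_bins` equal intervals of gravitational
#' height over the slice's lung extent and fits per-bin mean value against
#' per-bin mean height (cm) by ordinary least squares (regressing on the
#' bin's mean height rather than its centre makes the fit exact on linear
#' fields regardless of voxel layout). With height increasing toward the
#' non-dependent (ventral, supine) side, a negative gradient means flow
#' decreasing away from the dependent region.
#'
#' @param grid a `voxel_grid` (possibly thresholded)
#' @param values per-voxel values to fit (defaults to the total signal)
#' @param up_sign +1 if +y is the non-dependent direction (supine), -1 for
#'   prone
#' @param n_bins number of height bins
#' @return slope (value units per cm of height)
#' @export
gravitational_gradient <- function(grid, values = NULL, up_sign = 1,
                                   n_bins = 10) {
  g <- lung_voxels(grid)
  if (is.null(values)) values <- g$total else values <- values[grid$in_lung]
  h <- up_sign * g$y_mm / 10   # cm along the non-dependent direction
  if (nrow(g) < 2) stop("gradient undefined: fewer than 2 lung voxels")
  br <- seq(min(h), max(h), length.out = n_bins + 1)
  bin <- findInterval(h, br, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L; bin[bin > n_bins] <- n_bins
  mu <- tapply(values, bin, mean)
  xs <- as.numeric(tapply(h, bin, mean))
  if (length(mu) < 2) stop("gradient undefined: fewer than 2 non-empty bins")
  xbar <- mean(xs); ybar <- mean(mu)
  sum((xs - xbar) * (mu - ybar)) / sum((xs - xbar)^2)
}

#' Coefficient of variation of a voxel field
#'
#' Population standard deviation over mean of the retained lung-masked
#' voxel values.
#'
#' @param grid a `voxel_grid`
#' @param values per-voxel values (defaults to the total signal)
#' @return unitless COV
#' @export
voxel_cov <- function(grid, values = NULL) {
  g <- lung_voxels(grid)
  if (is.null(values)) values <- g$total else values <- values[grid$in_lung]
  if (length(values) < 2) stop("COV undefined: fewer than 2 voxels")
  m <- mean(values)
  if (m == 0) stop("COV undefined: zero mean")
  sqrt(mean((values - m)^2)) / m
}

#' Five-term threshold cost
#'
#' `C(x) = (1 - Q_fraction) + (1 - Q_remain) + (1 - C_removed) +
#' dCOV + dgrad`, where `dCOV = |COV_ASL - COV_Q| / COV_Q` and
#' `dgrad = |grad_ASL - grad_Q| / |grad_Q|` are fractional absolute
#' differences against the unfiltered capillary (perfusion) references.
#' A zero reference drops its term with a warning.
#'
#' @param metrics list with Q_fraction, Q_remain, C_removed, cov_asl,
#'   cov_q, grad_asl, grad_q
#' @return the cost value
#' @export
threshold_cost <- function(metrics) {
  d_cov <- if (is.na(metrics$cov_q) || metrics$cov_q == 0) {
    warning("COV reference is zero; dCOV term dropped"); 0
  } else abs(metrics$cov_asl - metrics$cov_q) / metrics$cov_q
  d_grad <- if (is.na(metrics$grad_q) || metrics$grad_q == 0) {
    warning("gradient reference is zero; dgrad term dropped"); 0
  } else abs(metrics$grad_asl - metrics$grad_q) / abs(metrics$grad_q)
  (1 - metrics$Q_fraction) + (1 - metrics$Q_remain) +
    (1 - metrics$C_removed) + d_cov + d_grad
}

#' Threshold sweep over a voxel grid
#'
#' Sweeps the intensity threshold from 100% down to 5% in steps of 5,
#' computing the five cost-function terms at each threshold. The COV and
#' gradient references are taken from the unfiltered capillary component.
#'
#' @param grid an unfiltered `voxel_grid`
#' @param thresholds descending percent grid
#' @param up_sign gravity orientation for the gradient (see
#'   [gravitational_gradient()])
#' @param literal_c_removed see [perfusion_metrics()]
#' @return object of class `threshold_sweep`: data.frame(x, Q_fraction,
#'   Q_remain, C_removed, cov_asl, cov_q, grad_asl, grad_q, d_cov, d_grad,
#'   cost, n_voxels)
#' @export
threshold_sweep <- function(grid, thresholds = seq(100, 5, by = -5),
                            up_sign = 1, literal_c_removed = FALSE) {
  if (any(diff(thresholds) >= 0)) stop("thresholds must be strictly descending")
  if (any(thresholds < 5 - 1e-9) || any(thresholds > 100))
    stop("thresholds must lie in [5, 100]")
  cov_q <- tryCatch(voxel_cov(grid, grid$capillary), error = function(e) NA_real_)
  grad_q <- tryCatch(gravitational_gradient(grid, grid$capillary, up_sign),
                     error = function(e) NA_real_)
  rows <- lapply(thresholds, function(x) {
    f <- apply_threshold(grid, x)
    pm <- perfusion_metrics(f, grid, literal_c_removed)
    cov_asl <- tryCatch(voxel_cov(f), error = function(e) NA_real_)
    grad_asl <- tryCatch(gravitational_gradient(f, NULL, up_sign),
                         error = function(e) NA_real_)
    m <- c(pm, list(cov_asl = cov_asl, cov_q = cov_q,
                    grad_asl = grad_asl, grad_q = grad_q))
    d_cov <- if (is.na(cov_q) || cov_q == 0 || is.na(cov_asl)) NA_real_
    else abs(cov_asl - cov_q) / cov_q
    d_grad <- if (is.na(grad_q) || grad_q == 0 || is.na(grad_asl)) NA_real_
    else abs(grad_asl - grad_q) / abs(grad_q)
    cost <- (1 - pm$Q_fraction) + (1 - pm$Q_remain) + (1 - pm$C_removed) +
      ifelse(is.na(d_cov), 0, d_cov) + ifelse(is.na(d_grad), 0, d_grad)
    data.frame(x = x, Q_fraction = pm$Q_fraction, Q_remain = pm$Q_remain,
               C_removed = pm$C_removed, cov_asl = cov_asl, cov_q = cov_q,
               grad_asl = grad_asl, grad_q = grad_q, d_cov = d_cov,
               d_grad = d_grad, cost = cost,
               n_voxels = nrow(lung_voxels(f)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' Optimal threshold from a sweep
#'
#' The argmin of the cost over the sweep grid; ties are broken toward the
#' larger threshold (least filtering).
#'
#' @param sweep a `threshold_sweep`
#' @return the optimal threshold x* (percent)
#' @export
optimal_threshold <- function(sweep) {
  cmin <- min(sweep$cost)
  max(sweep$x[sweep$cost <= cmin + 1e-12])
}
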