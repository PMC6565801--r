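#' Inversion time from heart rate
#'
#' TI is 80% of the R-R interval, rounded to the nearest millisecond:
#' HR 48, 60, 72, 96 bpm give 1000, 800, 667, 500 ms and HR 80, 86, 90
#' give 600, 558, 533 ms.
#'
#' @param hr heart rate (beats per minute)
#' @return TI (ms)
#' @export
ti_from_hr <- function(hr) {
  if (any(hr <= 0)) stop("HR must be > 0")
  round(0.8 * 60000 / hr)
}

#' Stroke volume from cardiac output and heart rate
#'
#' @param co cardiac output (L/min)
#' @param hr heart rate (bpm)
#' @param digits rounding for reporting (3 decimals matches the printed
#'   protocol tables); `NULL` returns the exact value
#' @return SV (L/beat)
#' @export
sv_from_co_hr <- function(co, hr, digits = 3) {
  if (any(co <= 0) || any(hr <= 0)) stop("CO and HR must be > 0")
  sv <- co / hr
  if (is.null(digits)) sv else round(sv, digits)
}

#' The four cardiac-output scenarios
#'
#' Returns the protocol table of the study design: four scenarios of four
#' (SV, HR, CO) rows each -- varying SV at fixed HR, varying HR at fixed
#' SV, constant CO with compensating SV/HR, and varying both -- with the
#' derived TI per row.
#'
#' @return named list of data.frames(sv, hr, co, ti)
#' @export
table1_scenarios <- function() {
  mk <- function(sv, hr, co) data.frame(sv = sv, hr = hr, co = co,
                                        ti = ti_from_hr(hr))
  list(
    varying_SV = mk(c(0.066, 0.083, 0.100, 0.133), c(60, 60, 60, 60),
                    c(4, 5, 6, 8)),
    varying_HR = mk(c(0.083, 0.083, 0.083, 0.083), c(48, 60, 72, 96),
                    c(4, 5, 6, 8)),
    constant_CO = mk(c(0.104, 0.083, 0.069, 0.052), c(48, 60, 72, 96),
                     c(5, 5, 5, 5)),
    varying_HR_and_SV = mk(c(0.050, 0.058, 0.067, 0.083), c(80, 86, 90, 96),
                           c(4, 5, 6, 8))
  )
}

#' Scenario specification
#'
#' @param label scenario name
#' @param rows data.frame(sv, hr, co); TI is derived per row from HR
#' @param posture "supine" or "prone"
#' @param slices slice indices to image
#' @param seed seed recorded for provenance
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(label, rows, posture = "supine", slices = 1:5,
                          seed = 1L) {
  stopifnot(all(c("sv", "hr", "co") %in% names(rows)))
  if (any(abs(rows$sv * rows$hr - rows$co) > 0.05 * rows$co + 1e-9))
    stop("rows violate CO = SV x HR beyond rounding")
  rows$ti <- ti_from_hr(rows$hr)
  structure(list(label = label, rows = rows, posture = posture,
                 slices = slices, seed = as.integer(seed)),
            class = "scenario_spec")
}

# non-dependent direction sign on the y axis for a posture
up_sign_for_posture <- function(posture) {
  if (posture == "supine") 1 else -1
}

#' Histogram of per-voxel ASL values
#'
#' @param grid a `voxel_grid`
#' @param bin_width bin size (mL/min/cm^3)
#' @return data.frame(mid, count)
#' @export
asl_histogram <- function(grid, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  r <- asl_rate(lung_voxels(grid))
  lo <- floor(min(r) / bin_width) * bin_width
  hi <- ceiling(max(r) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  br <- seq(lo, hi, by = bin_width)
  h <- hist(r, breaks = br, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Run one cardiac-output scenario
#'
#' For each (SV, HR, CO) row: solve the flow at inlet flow CO, set TI from
#' HR, simulate each requested slice, run the threshold sweep, and collect
#' summary statistics (median and mean ASL over lung voxels, COV,
#' gravitational gradient, optimal threshold, histogram). A failed row is
#' recorded with its diagnostic and remaining rows still run.
#'
#' @param network a `vascular_network`
#' @param spec a [scenario_spec()]
#' @param mr base [mr_params()] (TI overridden per row)
#' @param sheet a [sheet_params()]; pass a calibrated `c_sheet` to avoid
#'   re-calibrating per row
#' @param thresholds sweep grid
#' @param quantum parcel discretization (mm)
#' @return object of class `run_report`: list(results data.frame, sweeps,
#'   histograms, failures, spec)
#' @export
run_scenario <- function(network, spec, mr = mr_params(),
                         sheet = sheet_params(),
                         thresholds = seq(100, 5, by = -5), quantum = 1) {
  if (is.null(sheet$c_sheet))
    sheet$c_sheet <- as.numeric(calibrate_sheet_conductance(network, sheet = sheet))
  gravity <- gravity_state(spec$posture)
  up <- up_sign_for_posture(spec$posture)
  results <- list(); sweeps <- list(); histograms <- list(); failures <- list()
  for (r in seq_len(nrow(spec$rows))) {
    row <- spec$rows[r, ]
    sol <- tryCatch(
      solve_flow(network, boundary_conditions(co = row$co),
                 gravity = gravity, sheet = sheet),
      error = function(e) e)
    if (inherits(sol, "error")) {
      failures[[length(failures) + 1]] <-
        list(row = r, stage = "solve_flow", message = conditionMessage(sol))
      next
    }
    mr_row <- mr; mr_row$ti <- row$ti
    for (s in spec$slices) {
      key <- paste0("row", r, "_slice", s)
      res <- tryCatch({
        grid <- simulate_asl_slice(network, sol, slice_plane(s), mr_row,
                                   quantum = quantum)
        sw <- threshold_sweep(grid, thresholds, up_sign = up)
        rate <- asl_rate(lung_voxels(grid))
        results[[key]] <- data.frame(
          scenario = spec$label, row = r, sv = row$sv, hr = row$hr,
          co = row$co, ti = row$ti, posture = spec$posture, slice = s,
          median_asl = stats::median(rate), mean_asl = mean(rate),
          total_signal = sum(lung_voxels(grid)$total),
          cov = voxel_cov(grid),
          gradient = gravitational_gradient(grid, NULL, up),
          cov_q = sw$cov_q[1], grad_q = sw$grad_q[1],
          x_opt = optimal_threshold(sw),
          stringsAsFactors = FALSE)
        sweeps[[key]] <- sw
        histograms[[key]] <- asl_histogram(grid)
        NULL
      }, error = function(e) e)
      if (inherits(res, "error"))
        failures[[length(failures) + 1]] <-
          list(row = r, slice = s, stage = "image/sweep",
               message = conditionMessage(res))
    }
  }
  structure(list(
    results = if (length(results)) do.call(rbind, results) else NULL,
    sweeps = sweeps, histograms = histograms, failures = failures,
    spec = spec
  ), class = "run_report")
}

#' Paired supine-prone comparison
#'
#' Pairs per-slice COV and gravitational-gradient values between matched
#' supine and prone runs and applies a paired two-sided t-test.
#'
#' @param supine,prone `run_report`s with matched slice sets
#' @return list with `table` (per-pair values), `cov` and `gradient`
#'   sublists (mean_diff supine - prone, p_value, direction)
#' @export
posture_comparison <- function(supine, prone) {
  a <- supine$results; b <- prone$results
  key <- function(d) paste(d$scenario, d$row, d$slice)
  common <- intersect(key(a), key(b))
  if (length(common) == 0) stop("no matched slice/row pairs")
  a <- a[match(common, key(a)), ]
  b <- b[match(common, key(b)), ]
  tab <- data.frame(pair = common, cov_supine = a$cov, cov_prone = b$cov,
                    grad_supine = a$gradient, grad_prone = b$gradient)
  paired <- function(x, y) {
    d <- x - y
    if (length(d) < 2) {
      warning("fewer than 2 pairs; test skipped")
      return(list(mean_diff = mean(d), p_value = NA_real_,
                  direction = sign(mean(d))))
    }
    p <- if (stats::sd(d) <= 1e-10 * max(abs(d), 1)) {
      # degenerate pairing: identical arms give no difference (p undefined),
      # a constant nonzero difference is a certain-direction effect
      if (max(abs(d)) == 0) NA_real_ else 0
    } else stats::t.test(x, y, paired = TRUE)$p.value
    list(mean_diff = mean(d), p_value = p, direction = sign(mean(d)))
  }
  list(table = tab,
       cov = paired(tab$cov_supine, tab$cov_prone),
       gradient = paired(tab$grad_supine, tab$grad_prone))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$spec$label, ", ", x$spec$posture, ": ",
      if (is.null(x$results)) 0 else nrow(x$results), " results, ",
      length(x$failures), " failures\n", sep = "")
  invisible(x)
}
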