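#' Basin-of-attraction specification
#'
#' Describes a 2-D slice of the 4-D initial-condition space: which two
#' coordinates vary (`plane`), the fixed values of the other two, the
#' ranges, resolutions, and the sinusoidal forcing applied to every cell.
#'
#' @param plane `"asr_asd"` (x = a_sr0, y = a_sd0) or `"asr_V"`
#'   (x = a_sr0, y = V0).
#' @param xlim,ylim axis ranges.
#' @param nx,ny grid resolutions (>= 2).
#' @param fixed named values of the non-varying coordinates; defaults
#'   `V = -60`, `a_r = 0`, `a_sd = 0` (used as applicable to the plane).
#' @param I0,B,omega forcing parameters.
#' @return An object of class `basin_spec`.
#' @export
basin_spec <- function(plane = c("asr_asd", "asr_V"),
                       xlim, ylim, nx, ny,
                       fixed = c(V = -60, a_r = 0, a_sd = 0),
                       I0 = 1.5, B = 0.0475, omega = 0.006) {
  plane <- match.arg(plane)
  if (nx < 2 || ny < 2) stop("resolution must be >= 2 per axis")
  if (!all(is.finite(c(xlim, ylim)))) stop("ranges must be finite")
  structure(list(plane = plane, xlim = xlim, ylim = ylim,
                 nx = as.integer(nx), ny = as.integer(ny),
                 fixed = fixed, I0 = I0, B = B, omega = omega),
            class = "basin_spec")
}

basin_cell_state <- function(spec, x, y) {
  if (spec$plane == "asr_asd") {
    hb_state(spec$fixed[["V"]], spec$fixed[["a_r"]], y, x)
  } else {
    hb_state(y, spec$fixed[["a_r"]], spec$fixed[["a_sd"]], x)
  }
}

#' Compute a basin-of-attraction map
#'
#' Integrates every grid cell independently from its initial condition,
#' classifies the post-transient interspike intervals with
#' [classify_attractor()], and returns the label matrix.  Failures in a
#' cell are recorded as `"undetermined"` and never abort the map.
#'
#' The default per-cell integration is deliberately short (the
#' classification at these settings was validated against long
#' high-resolution runs); pass a custom `config` for higher fidelity.
#'
#' @param spec a [basin_spec()].
#' @param params an [hb_params()].
#' @param config per-cell [integration_config()].
#' @param tol,k_max classifier settings.
#' @return An object of class `basin_map`: `x`, `y` grids and a `labels`
#'   character matrix (`nx` rows, `ny` columns) with values
#'   `"subthreshold"`, `"periodic"`, `"chaotic"`, `"undetermined"`.
#' @export
compute_basin <- function(spec, params = hb_params(),
                          config = integration_config(dt = 0.05,
                                                      t_transient = 1e4,
                                                      t_measure = 3e4),
                          tol = 0.01, k_max = 8) {
  stopifnot(inherits(spec, "basin_spec"))
  xs <- seq(spec$xlim[1], spec$xlim[2], length.out = spec$nx)
  ys <- seq(spec$ylim[1], spec$ylim[2], length.out = spec$ny)
  labels <- matrix("undetermined", spec$nx, spec$ny)
  pr <- forcing_protocol("sinusoidal", I0 = spec$I0, B = spec$B,
                         omega = spec$omega)
  for (j in seq_along(ys)) {
    for (i in seq_along(xs)) {
      lab <- tryCatch({
        tr <- hb_integrate(basin_cell_state(spec, xs[i], ys[j]), pr, config,
                           params, record = FALSE, detect_spikes = TRUE)
        classify_attractor(isi_sequence(spike_train(tr$spike_times)),
                           tol = tol, k_max = k_max)$category
      }, error = function(e) "undetermined")
      labels[i, j] <- lab
    }
  }
  structure(list(x = xs, y = ys, labels = labels, spec = spec),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("basin_map: %d x %d cells, plane %s, omega = %g, B = %g\n",
              length(x$x), length(x$y), x$spec$plane, x$spec$omega,
              x$spec$B))
  print(table(x$labels))
  invisible(x)
}

#' Fraction of epsilon-uncertain initial conditions
#'
#' A point is uncertain at scale `epsilon` when the attractor reached from
#' `(x + epsilon, y)` differs from the one reached from `(x, y)` (one-sided
#' perturbation along the x axis).  For a [compute_basin()] map, `epsilon`
#' is rounded to a whole number of grid spacings and labels are compared
#' column-shifted; for a label *function* `f(x, y)` the comparison is exact
#' for any `epsilon` on a fresh evaluation grid.
#'
#' @param basin a `basin_map`, or a function `f(x, y)` returning a label.
#' @param epsilon perturbation size(s) (x-axis units).
#' @param ... passed to methods.
#' @return Fraction(s) in `[0, 1]`, one per `epsilon`.
#' @export
uncertain_fraction <- function(basin, epsilon, ...) {
  UseMethod("uncertain_fraction")
}

#' @rdname uncertain_fraction
#' @export
uncertain_fraction.basin_map <- function(basin, epsilon, ...) {
  dx <- basin$x[2] - basin$x[1]
  nx <- length(basin$x)
  vapply(epsilon, function(eps) {
    if (eps <= 0) stop("epsilon must be > 0")
    m <- max(1L, as.integer(round(eps / dx)))
    if (m >= nx) stop("epsilon exceeds the basin width")
    a <- basin$labels[seq_len(nx - m), , drop = FALSE]
    b <- basin$labels[seq_len(nx - m) + m, , drop = FALSE]
    mean(a != b)
  }, numeric(1))
}

#' @rdname uncertain_fraction
#' @param xlim,ylim,n evaluation region and grid size for the function
#'   method; `n` may be a pair `c(nx, ny)` (the boundary geometry often
#'   needs resolution only along the perturbation axis).
#' @export
uncertain_fraction.function <- function(basin, epsilon, xlim = c(0, 1),
                                        ylim = c(0, 1), n = 101, ...) {
  nx <- n[1]
  ny <- if (length(n) > 1) n[2] else n[1]
  xs <- seq(xlim[1], xlim[2], length.out = nx)
  ys <- seq(ylim[1], ylim[2], length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  base <- mapply(basin, g$x, g$y)
  vapply(epsilon, function(eps) {
    if (eps <= 0) stop("epsilon must be > 0")
    mean(mapply(basin, g$x + eps, g$y) != base)
  }, numeric(1))
}

#' Uncertainty exponent and fractal dimension of a basin boundary
#'
#' Fits `log f = alpha log epsilon + c` by least squares.  The exponent
#' `alpha` governs the power-law scaling `f(epsilon) ~ epsilon^alpha` of
#' the uncertain fraction; `alpha < 1` signals a fractal basin boundary of
#' dimension `d = D - alpha` in a `D`-dimensional slice.
#'
#' @param epsilons perturbation sizes (> 0).
#' @param f_values uncertain fractions at `epsilons`; zero pairs are
#'   excluded with a warning (log undefined).
#' @param D dimension of the sampled plane (default 2).
#' @return An object of class `uncertainty_estimate`: `alpha`, `dim`
#'   (`= D - alpha`), `D`, the retained `epsilons` and `f_values`,
#'   `r_squared` and `alpha_se`.
#' @examples
#' eps <- 10^seq(-4, -1, length.out = 8)
#' est <- uncertainty_exponent(eps, 0.3 * eps^0.7)
#' est$alpha  # 0.7 to machine precision
#' @export
uncertainty_exponent <- function(epsilons, f_values, D = 2) {
  stopifnot(length(epsilons) == length(f_values))
  if (any(epsilons <= 0)) stop("epsilons must be > 0")
  if (any(f_values < 0 | f_values > 1))
    stop("uncertain fractions must be in [0, 1]")
  keep <- f_values > 0
  if (any(!keep))
    warning(sum(!keep), " epsilon value(s) with f = 0 excluded from the fit")
  if (sum(keep) < 3)
    stop("need at least 3 (epsilon, f > 0) pairs for the power-law fit")
  x <- log(epsilons[keep])
  y <- log(f_values[keep])
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  alpha <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) + alpha * (x - mean(x)))
  ssr <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  structure(list(alpha = alpha, dim = D - alpha, D = D,
                 epsilons = epsilons[keep], f_values = f_values[keep],
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 alpha_se = sqrt(ssr / (n - 2) / sxx)),
            class = "uncertainty_estimate")
}

#' @export
print.uncertainty_estimate <- function(x, ...) {
  cat(sprintf(
    "uncertainty exponent alpha = %.5f (se %.3g, R^2 %.3f)\n",
    x$alpha, x$alpha_se, x$r_squared))
  cat(sprintf("fractal dimension d = D - alpha = %.5f (D = %d)\n",
              x$dim, as.integer(x$D)))
  invisible(x)
}

#' Maximum Lyapunov exponent (Benettin two-trajectory method)
#'
#' Integrates a reference trajectory and a companion displaced by `delta0`
#' (in a norm where V is rescaled by `v_scale` to balance millivolts
#' against dimensionless activations), renormalizes the companion back to
#' separation `delta0` every `renorm_interval` ms, and averages the
#' accumulated log stretch factors over the elapsed time.  The forcing
#' phase is shared by both trajectories (the drive is explicit time, not a
#' state).  Positive exponents signal chaos; for a stable focus the
#' estimate converges to the real part of the leading Jacobian eigenvalue.
#'
#' @param ic initial state.
#' @param protocol an [forcing_protocol()].
#' @param params an [hb_params()].
#' @param t_transient discarded span before accumulation (ms).
#' @param t_accum accumulation span (ms).
#' @param renorm_interval renormalization interval (ms).
#' @param delta0 imposed separation (scaled-norm units).
#' @param v_scale factor applied to V in the separation norm.
#' @param dt integration step (ms).
#' @return An object of class `lyapunov_estimate`: `lambda` (per ms), the
#'   running-estimate `trace`, its standard error `se` (from the spread of
#'   per-interval stretch rates), and the settings.
#' @export
max_lyapunov <- function(ic, protocol, params = hb_params(),
                         t_transient = 1e5, t_accum = 1e6,
                         renorm_interval = 10, delta0 = 1e-8,
                         v_scale = 0.01, dt = 0.01) {
  stopifnot(inherits(protocol, "hb_protocol"))
  B <- if (protocol$kind == "constant") 0 else protocol$B
  omega <- if (protocol$kind == "constant") 0 else protocol$omega
  renorm_steps <- max(1L, as.integer(round(renorm_interval / dt)))
  res <- hb_lyapunov_cpp(as.numeric(as_hb_state(ic)), params_vector(params),
                         protocol$I0, B, omega, protocol$phase0, dt,
                         round(t_transient / dt), round(t_accum / dt),
                         renorm_steps, delta0, v_scale)
  trace <- res$log_stretch
  nren <- length(trace)
  # per-interval stretch rates recovered from the cumulative trace
  cums <- trace * seq_len(nren) * renorm_steps * dt
  rates <- diff(c(0, cums)) / (renorm_steps * dt)
  structure(list(lambda = res$lambda, trace = trace,
                 se = stats::sd(rates) / sqrt(nren),
                 renorm_interval = renorm_steps * dt,
                 t_transient = t_transient, t_accum = t_accum,
                 delta0 = delta0, v_scale = v_scale, dt = dt),
            class = "lyapunov_estimate")
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("max Lyapunov exponent: %.6g / ms (se %.2g) over %g ms\n",
              x$lambda, x$se, x$t_accum))
  invisible(x)
}
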