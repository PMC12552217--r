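#' Parameter continuation in the constant external current
#'
#' Sweeps the constant current in steps (default 0.002 uA/cm^2), with the
#' final state at each point serving as the initial condition for the next
#' (state inheritance), and reports the per-point firing state and mean
#' firing frequency.  A backward (decreasing) sweep started on the quiescent
#' branch locates the Hopf bifurcation where the fixed point loses
#' stability; a forward (increasing) sweep started on the spiking branch
#' locates the quiescence current `I*` where the limit cycle dies.  Between
#' the two the branches disagree: the bistability window.
#'
#' Residence at each point is adaptive.  The escape rate from the focus
#' shrinks to ~1e-6/ms next to the Hopf point, so a fixed residence either
#' reports the bifurcation several steps late or wastes enormous time on
#' clearly stable points.  Each point is integrated until the verdict is
#' clear: `spike_target` spikes (spiking), or a subthreshold V-oscillation
#' whose block-wise amplitude has contracted twice in a row (quiescent),
#' with a hard cap `t_max`.  Spiking points are then measured for
#' `t_measure` ms to estimate the firing frequency.
#'
#' @param I_start,I_end sweep limits (uA/cm^2); direction is inferred from
#'   their order.
#' @param ic initial state at `I_start`.
#' @param step current increment (uA/cm^2).
#' @param params an [hb_params()].
#' @param dt integration step (ms).
#' @param t_settle minimum residence before a quiescent verdict (ms).
#' @param t_block amplitude-comparison block (ms); spans several periods of
#'   the ~0.008 rad/ms subthreshold oscillation.
#' @param t_max residence cap per point (ms).
#' @param t_measure span used to measure the firing frequency of spiking
#'   points (ms).
#' @param spike_target spikes that define "firing" (default 3).
#' @param threshold,refractory spike criterion, see [detect_spikes()].
#' @return An object of class `hb_continuation`: data.frame `points`
#'   (`I`, `verdict`, `n_spikes`, `freq` in rad/ms, 0 when quiescent),
#'   `end_states` matrix, `direction`, and `onset` / `offset` currents
#'   (first firing / first quiescent point in sweep order, `NA` when the
#'   transition is absent).
#' @export
continuation_sweep <- function(I_start, I_end, ic, step = 0.002,
                               params = hb_params(), dt = 0.01,
                               t_settle = 2e4, t_block = 5e3, t_max = 2e6,
                               t_measure = 3.5e4, spike_target = 3,
                               threshold = -20, refractory = 20) {
  direction <- if (I_end < I_start) "backward" else "forward"
  I_grid <- seq(I_start, I_end, by = if (direction == "backward") -step else step)
  pv <- params_vector(params)
  st <- as.numeric(as_hb_state(ic))
  n <- length(I_grid)
  verdict <- character(n)
  nspk <- integer(n)
  freq <- numeric(n)
  ends <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("V", "a_r", "a_sd", "a_sr")))
  for (i in seq_len(n)) {
    res <- hb_settle_cpp(st, pv, I_grid[i], dt, t_settle, t_block, t_max,
                         as.integer(spike_target), threshold, refractory)
    verdict[i] <- res$verdict
    st <- res$end_state
    if (res$verdict == "spiking") {
      pr <- forcing_protocol("constant", I0 = I_grid[i])
      cfg <- integration_config(dt = dt, t_transient = 0,
                                t_measure = t_measure, record_stride = 1)
      tr <- hb_integrate(hb_state(st[1], st[2], st[3], st[4]), pr, cfg,
                         params, record = FALSE, detect_spikes = TRUE,
                         threshold = threshold, refractory = refractory)
      st <- as.numeric(tr$end_state)
      nspk[i] <- length(tr$spike_times)
      f <- mean_firing_frequency(spike_train(tr$spike_times))
      freq[i] <- if (is.na(f)) 0 else f
    } else {
      nspk[i] <- length(res$spike_times)
      freq[i] <- 0
    }
    ends[i, ] <- st
  }
  firing <- verdict == "spiking"
  onset <- if (any(firing)) I_grid[which(firing)[1]] else NA_real_
  offset <- if (any(!firing & cumsum(firing) > 0))
    I_grid[which(!firing & cumsum(firing) > 0)[1]] else NA_real_
  structure(list(points = data.frame(I = I_grid, verdict = verdict,
                                     n_spikes = nspk, freq = freq),
                 end_states = ends, direction = direction, step = step,
                 onset = onset, offset = offset),
            class = "hb_continuation")
}

#' @export
print.hb_continuation <- function(x, ...) {
  cat(sprintf("%s continuation over [%g, %g], step %g\n", x$direction,
              min(x$points$I), max(x$points$I), x$step))
  if (!is.na(x$onset))
    cat(sprintf("  first firing point:    I = %g\n", x$onset))
  if (!is.na(x$offset))
    cat(sprintf("  first quiescent point: I = %g\n", x$offset))
  invisible(x)
}

#' Frequency-ratio map over the (B, omega) forcing plane
#'
#' Evaluates [frequency_ratio()] on every cell of a `B x omega` grid, each
#' cell integrated independently from the same stated initial condition
#' (no inheritance: the map is an initial-condition-dependence instrument).
#' Cells with no firing get ratio 0.
#'
#' @param B_grid forcing amplitudes.
#' @param omega_grid forcing frequencies (rad/ms).
#' @param ic initial state used for every cell.
#' @param I0 base current.
#' @param params an [hb_params()].
#' @param config an [integration_config()].
#' @param I_star quiescence current used to warn about inadmissible
#'   amplitudes.
#' @return An object of class `hb_resonance_map`: `ratio` matrix
#'   (rows = `B_grid`, cols = `omega_grid`), the grids, and the IC.
#' @export
resonance_map <- function(B_grid, omega_grid, ic, I0 = 1.5,
                          params = hb_params(),
                          config = integration_config(t_transient = 5e4,
                                                      t_measure = 1e5),
                          I_star = 1.42) {
  B_max <- 1 - I_star / I0
  if (any(B_grid > B_max))
    warning(sprintf("B values above B_max = %.5f leave the subthreshold regime",
                    B_max))
  ratio <- matrix(NA_real_, length(B_grid), length(omega_grid))
  for (i in seq_along(B_grid)) {
    for (j in seq_along(omega_grid)) {
      if (B_grid[i] == 0) {
        pr <- forcing_protocol("constant", I0 = I0)
      } else {
        pr <- forcing_protocol("sinusoidal", I0 = I0, B = B_grid[i],
                               omega = omega_grid[j])
      }
      tr <- hb_integrate(as_hb_state(ic), pr, config, params,
                         record = FALSE, detect_spikes = TRUE)
      ratio[i, j] <- frequency_ratio(spike_train(tr$spike_times),
                                     omega_grid[j])
    }
  }
  structure(list(B_grid = B_grid, omega_grid = omega_grid, ratio = ratio,
                 ic = as.numeric(as_hb_state(ic)), I0 = I0),
            class = "hb_resonance_map")
}

#' p:q locking fractions and the Farey mediant
#'
#' A `locking_fraction(p, q)` is a p:q frequency-locked state (p spikes per
#' q forcing cycles) stored in reduced form.  The mediant (Farey sum) of
#' p:q and p':q' is `(p + p') : (q + q')`, the rational with the smallest
#' denominator lying between them; it generates the ordering of locking
#' plateaus along the staircase.
#'
#' @param p,q positive integers.
#' @return An object of class `locking_fraction` with fields `p`, `q`.
#' @examples
#' farey_mediant(locking_fraction(1, 1), locking_fraction(1, 2)) # 2:3
#' @export
locking_fraction <- function(p, q) {
  if (p < 0 || q < 1 || p != round(p) || q != round(q))
    stop("need integers p >= 0, q >= 1")
  g <- if (p == 0) q else gcd(p, q)
  structure(list(p = as.integer(p / g), q = as.integer(q / g)),
            class = "locking_fraction")
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' @rdname locking_fraction
#' @param a,b `locking_fraction` objects.
#' @export
farey_mediant <- function(a, b) {
  stopifnot(inherits(a, "locking_fraction"), inherits(b, "locking_fraction"))
  locking_fraction(a$p + b$p, a$q + b$q)
}

#' @export
print.locking_fraction <- function(x, ...) {
  cat(sprintf("%d:%d locking (ratio %.4f)\n", x$p, x$q, x$p / x$q))
  invisible(x)
}

#' @export
format.locking_fraction <- function(x, ...) sprintf("%d:%d", x$p, x$q)

#' The n:(n+1) staircase sequence
#'
#' The sequence of locking fractions `n:(n+1)` for `n = n_max, ..., 1`,
#' i.e. ratios descending from `n_max/(n_max+1)` toward 1/2: the plateau
#' order observed between the 1:1 and 1:2 lockings.  Each member is the
#' mediant of 1:1 with the next member.
#'
#' @param n_max largest `n`.
#' @return List of [locking_fraction()]s.
#' @export
staircase_sequence <- function(n_max) {
  if (n_max < 1) stop("n_max must be >= 1")
  lapply(seq(n_max, 1), function(n) locking_fraction(n, n + 1))
}

#' Detect locking plateaus in a staircase scan
#'
#' Matches each measured frequency ratio to the rational `p/q` with the
#' smallest denominator `q <= q_max` within `tol`, then merges maximal runs
#' of consecutive grid points carrying the same fraction into plateaus.
#' Unmatched points (chaotic or quasiperiodic candidates) separate plateaus.
#'
#' @param omega grid of forcing frequencies (rad/ms), increasing.
#' @param ratio measured frequency ratios at `omega`.
#' @param tol absolute tolerance on the ratio (default 5e-3).
#' @param q_max largest denominator considered.
#' @return data.frame with one row per plateau: `p`, `q`, `ratio`,
#'   `omega_min`, `omega_max`, `n_points`.
#' @export
detect_plateaus <- function(omega, ratio, tol = 5e-3, q_max = 8) {
  stopifnot(length(omega) == length(ratio))
  best_p <- integer(length(ratio))
  best_q <- integer(length(ratio))
  for (i in seq_along(ratio)) {
    r <- ratio[i]
    if (!is.finite(r) || r <= 0) {
      best_q[i] <- 0L
      next
    }
    found <- FALSE
    for (q in seq_len(q_max)) {
      p <- round(r * q)
      if (p >= 1 && abs(r - p / q) <= tol) {
        g <- gcd(p, q)
        best_p[i] <- as.integer(p / g)
        best_q[i] <- as.integer(q / g)
        found <- TRUE
        break
      }
    }
    if (!found) best_q[i] <- 0L
  }
  key <- paste(best_p, best_q)
  runs <- rle(key)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  keep <- best_q[idx_start] > 0
  data.frame(p = best_p[idx_start[keep]],
             q = best_q[idx_start[keep]],
             ratio = best_p[idx_start[keep]] / best_q[idx_start[keep]],
             omega_min = omega[idx_start[keep]],
             omega_max = omega[idx_end[keep]],
             n_points = runs$lengths[keep])
}
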