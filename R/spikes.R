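#' Spike detection by threshold crossing
#'
#' A spike is an upward crossing of `threshold` by the membrane potential;
#' the crossing time is linearly interpolated between samples, and crossings
#' closer than `refractory` to the previous accepted spike are discarded.
#' Action potentials in this model overshoot far above 0 mV while
#' subthreshold oscillations stay below about -40 mV, so any threshold in
#' (-40, 0) gives identical trains; -20 mV is the midpoint convention.
#'
#' @param traj an [hb_integrate()] trajectory (or any list with `t` and `V`).
#' @param threshold crossing level (mV).
#' @param refractory minimum spike separation (ms).
#' @return An object of class `spike_train` with the crossing `times` (ms).
#' @export
detect_spikes <- function(traj, threshold = -20, refractory = 20) {
  v <- traj$V
  tt <- traj$t
  n <- length(v)
  times <- numeric(0)
  if (n >= 2) {
    up <- which(v[-n] < threshold & v[-1] >= threshold)
    if (length(up)) {
      tc <- tt[up] + (tt[up + 1] - tt[up]) *
        (threshold - v[up]) / (v[up + 1] - v[up])
      last <- -Inf
      keep <- logical(length(tc))
      for (i in seq_along(tc)) {
        if (tc[i] - last >= refractory) {
          keep[i] <- TRUE
          last <- tc[i]
        }
      }
      times <- tc[keep]
    }
  }
  spike_train(times, threshold = threshold, refractory = refractory)
}

#' Construct a spike train
#'
#' @param times strictly increasing spike times (ms).
#' @param threshold,refractory detection settings carried as provenance.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, threshold = NA_real_, refractory = 0) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("spike times must be strictly increasing")
  structure(list(times = times, threshold = threshold,
                 refractory = refractory),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes", length(x$times)))
  if (length(x$times) > 1)
    cat(sprintf(", mean ISI %.1f ms", mean(diff(x$times))))
  cat("\n")
  invisible(x)
}

#' Interspike intervals
#'
#' @param train a [spike_train()].
#' @return Numeric vector of consecutive differences (ms), all positive.
#' @export
isi_sequence <- function(train) {
  if (inherits(train, "spike_train")) diff(train$times) else diff(train)
}

#' Mean firing frequency (angular)
#'
#' `2 pi (N - 1) / (t_N - t_1)` in rad/ms, so that a train with constant
#' 1000 ms intervals has frequency `2 pi / 1000 = 0.0063` rad/ms, directly
#' comparable to the forcing frequency `omega`.
#'
#' @param train a [spike_train()].
#' @return Frequency in rad/ms, or `NA_real_` when fewer than 2 spikes
#'   (no firing).
#' @export
mean_firing_frequency <- function(train) {
  ts <- if (inherits(train, "spike_train")) train$times else train
  n <- length(ts)
  if (n < 2) return(NA_real_)
  2 * pi * (n - 1) / (ts[n] - ts[1])
}

#' Frequency ratio of a spike train to the forcing
#'
#' `mean_firing_frequency(train) / omega`; equals `p/q` in the long-run
#' limit for a p:q frequency-locked train (p spikes per q forcing cycles).
#' Non-firing trains give 0 (rendered black in resonance maps).
#'
#' @param train a [spike_train()].
#' @param omega forcing angular frequency (rad/ms), > 0.
#' @return Dimensionless ratio (0 when not firing).
#' @export
frequency_ratio <- function(train, omega) {
  if (omega <= 0) stop("omega must be > 0")
  f <- mean_firing_frequency(train)
  if (is.na(f)) 0 else f / omega
}

#' Three-way attractor classification from interspike intervals
#'
#' Post-transient windows are labelled `"subthreshold"` (no firing),
#' `"periodic"` with a period `k` (the ISI sequence repeats with period `k`
#' within relative tolerance `tol`, for the smallest `k <= k_max` having at
#' least `min_repeats * k` intervals), or `"chaotic"` (firing with no such
#' `k`).  Bursting counts as periodic with `k > 1` (alternating short/long
#' intervals).  Windows with 1-3 intervals return `"undetermined"`, since no
#' periodicity verdict is possible.
#'
#' @param isi interspike intervals (ms), e.g. from [isi_sequence()].
#' @param tol relative tolerance of the periodicity match.
#' @param k_max largest period tested.
#' @param min_repeats minimum pattern repetitions required for a periodic
#'   verdict at period `k`.
#' @return An object of class `attractor_label` with fields `category`,
#'   `period_k` (`NA` unless periodic) and `diagnostics`.
#' @examples
#' classify_attractor(numeric(0))$category        # "subthreshold"
#' classify_attractor(rep(c(800, 1200), 10))      # periodic, k = 2
#' @export
classify_attractor <- function(isi, tol = 0.01, k_max = 8, min_repeats = 4) {
  isi <- as.numeric(isi)
  if (length(isi) && any(isi <= 0)) stop("ISIs must be positive")
  if (!length(isi)) {
    return(attractor_label("subthreshold"))
  }
  if (length(isi) < min_repeats) {
    return(attractor_label("undetermined",
                           diagnostics = list(n_isi = length(isi))))
  }
  for (k in seq_len(k_max)) {
    if (length(isi) < min_repeats * k) break
    ref <- isi[seq_len(length(isi) - k)]
    dev <- abs(isi[-seq_len(k)] - ref)
    if (all(dev <= tol * ref)) {
      return(attractor_label("periodic", period_k = k,
                             diagnostics = list(n_isi = length(isi),
                                                max_rel_dev = max(dev / ref))))
    }
  }
  attractor_label("chaotic",
                  diagnostics = list(n_isi = length(isi),
                                     isi_cv = stats::sd(isi) / mean(isi)))
}

#' @rdname classify_attractor
#' @param category one of `"subthreshold"`, `"periodic"`, `"chaotic"`,
#'   `"undetermined"`.
#' @param period_k positive integer, required iff `category = "periodic"`.
#' @param diagnostics optional list of classifier evidence.
#' @export
attractor_label <- function(category = c("subthreshold", "periodic",
                                         "chaotic", "undetermined"),
                            period_k = NA_integer_, diagnostics = list()) {
  category <- match.arg(category)
  if (category == "periodic" && (is.na(period_k) || period_k < 1))
    stop("periodic labels need a positive period_k")
  if (category != "periodic") period_k <- NA_integer_
  structure(list(category = category, period_k = as.integer(period_k),
                 diagnostics = diagnostics),
            class = "attractor_label")
}

#' @export
print.attractor_label <- function(x, ...) {
  cat(switch(x$category,
             periodic = sprintf("attractor: periodic (k = %d)\n", x$period_k),
             sprintf("attractor: %s\n", x$category)))
  invisible(x)
}

#' ISI bifurcation scan over forcing frequency
#'
#' For each `omega`, integrates independently from the same initial
#' condition (fresh start, no state inheritance), detects spikes and
#' returns post-transient interspike intervals with the attractor label.
#'
#' @param omega_grid forcing frequencies (rad/ms).
#' @param B forcing amplitude.
#' @param ic initial state (4-vector).
#' @param I0 base current.
#' @param params an [hb_params()].
#' @param config an [integration_config()]; a shorter-than-default window
#'   already resolves the plateau structure at desk scale.
#' @param tol,k_max classifier settings, see [classify_attractor()].
#' @return A list with `isi`: data.frame (`omega`, `isi`) in long format,
#'   and `labels`: data.frame (`omega`, `category`, `period_k`, `ratio`).
#' @export
isi_bifurcation_scan <- function(omega_grid, B, ic, I0 = 1.5,
                                 params = hb_params(),
                                 config = integration_config(
                                   t_transient = 1e5, t_measure = 3e5),
                                 tol = 0.01, k_max = 8) {
  rows <- vector("list", length(omega_grid))
  labs <- vector("list", length(omega_grid))
  for (i in seq_along(omega_grid)) {
    om <- omega_grid[i]
    pr <- forcing_protocol("sinusoidal", I0 = I0, B = B, omega = om)
    tr <- hb_integrate(as_hb_state(ic), pr, config, params,
                       record = FALSE, detect_spikes = TRUE)
    st <- spike_train(tr$spike_times)
    isi <- isi_sequence(st)
    lab <- classify_attractor(isi, tol = tol, k_max = k_max)
    rows[[i]] <- if (length(isi))
      data.frame(omega = om, isi = isi) else NULL
    labs[[i]] <- data.frame(omega = om, category = lab$category,
                            period_k = lab$period_k,
                            ratio = frequency_ratio(st, om))
  }
  list(isi = do.call(rbind, rows), labels = do.call(rbind, labs))
}
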