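#' Synthetic fixtures with analytically known ground truth
#'
#' Fast, integrator-free stand-ins used to test the analysis stages:
#'
#' * `"isi_periodic"` -- a k-periodic ISI sequence (optional multiplicative
#'   jitter), ground truth for [classify_attractor()].
#' * `"isi_chaotic_surrogate"` -- aperiodic ISIs driven by the chaotic
#'   logistic map `x -> 4 x (1 - x)`, mapped into a physiological ISI range;
#'   stress case for the periodicity test.
#' * `"basin_stripes"` -- a two-class vertical-stripe label function of
#'   stripe width `w`; the one-sided uncertain fraction is exactly
#'   `f(eps) = min(eps / w, 1)` for uniformly sampled x.
#' * `"basin_power_law"` -- an `(epsilons, f)` table following
#'   `f = c eps^alpha` exactly; ground truth for [uncertainty_exponent()].
#' * `"ringdown"` -- a damped sinusoid
#'   `V(t) = V_base + A exp(-gamma t) sin(freq t)` sampled on a uniform
#'   grid, with its construction frequency carried as ground truth.
#'
#' Randomness (jitter and the surrogate's seed point) is controlled by
#' `seed` and confined to fixtures; the scientific pipeline itself is
#' seed-free.
#'
#' @param kind fixture kind, see above.
#' @param ... kind-specific settings:
#'   `isi_periodic`: `pattern` (base ISIs, default `c(800, 1200)`),
#'   `n_repeats` (default 10), `jitter` (relative sd, default 0);
#'   `isi_chaotic_surrogate`: `n` (default 50), `range` (default
#'   `c(800, 1200)`);
#'   `basin_stripes`: `w` (stripe width, default 0.1);
#'   `basin_power_law`: `alpha` (default 0.7), `c0` (default 0.3),
#'   `epsilons` (default `10^seq(-4, -1.5, length.out = 8)`);
#'   `ringdown`: `freq` (rad/ms, default 0.008263), `gamma` (default
#'   7.3e-4), `A` (default 5), `V_base` (default -65), `t_max`, `dt`.
#' @param seed integer seed for fixture randomness (jitter, surrogate
#'   start); `NULL` leaves the RNG alone and uses deterministic defaults.
#' @return A list with `kind`, the generating parameters, the payload, and
#'   the ground truth.
#' @export
make_fixture <- function(kind = c("isi_periodic", "isi_chaotic_surrogate",
                                  "basin_stripes", "basin_power_law",
                                  "ringdown"),
                         ..., seed = NULL) {
  kind <- match.arg(kind)
  opts <- list(...)
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
    isi_periodic = {
      pattern <- opts$pattern %||% c(800, 1200)
      n_repeats <- opts$n_repeats %||% 10
      jitter <- opts$jitter %||% 0
      isi <- rep(pattern, n_repeats)
      if (jitter > 0) isi <- isi * (1 + stats::rnorm(length(isi), 0, jitter))
      list(kind = kind, k = length(pattern), pattern = pattern,
           jitter = jitter, isi = isi,
           spike_times = cumsum(c(0, isi)))
    },
    isi_chaotic_surrogate = {
      n <- opts$n %||% 50
      rng <- opts$range %||% c(800, 1200)
      x <- if (is.null(seed)) 0.3141592653589793 else runif(1, 0.05, 0.95)
      xs <- numeric(n)
      for (i in seq_len(n)) {
        x <- 4 * x * (1 - x)
        xs[i] <- x
      }
      isi <- rng[1] + diff(rng) * xs
      list(kind = kind, isi = isi, spike_times = cumsum(c(0, isi)),
           logistic_r = 4)
    },
    basin_stripes = {
      w <- opts$w %||% 0.1
      lab <- local({
        w_ <- w
        function(x, y) if (floor(x / w_) %% 2 == 0) "A" else "B"
      })
      list(kind = kind, w = w, label_fun = lab,
           f_expected = function(eps) pmin(eps / w, 1))
    },
    basin_power_law = {
      alpha <- opts$alpha %||% 0.7
      c0 <- opts$c0 %||% 0.3
      eps <- opts$epsilons %||% 10^seq(-4, -1.5, length.out = 8)
      list(kind = kind, alpha = alpha, c0 = c0, epsilons = eps,
           f_values = c0 * eps^alpha)
    },
    ringdown = {
      freq <- opts$freq %||% 0.008263
      gamma <- opts$gamma %||% 7.3e-4
      A <- opts$A %||% 5
      V_base <- opts$V_base %||% -65
      t_max <- opts$t_max %||% 6000
      dt <- opts$dt %||% 0.5
      tt <- seq(0, t_max, by = dt)
      list(kind = kind, freq = freq, gamma = gamma, A = A, V_base = V_base,
           t = tt, V = V_base + A * exp(-gamma * tt) * sin(freq * tt))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dominant angular frequency of a uniformly sampled signal
#'
#' Peak of the discrete Fourier amplitude spectrum (mean removed),
#' returned in rad per time unit.  Used to check ringdown fixtures and
#' simulated subthreshold oscillations against the linearized frequency.
#'
#' @param t uniform time grid.
#' @param x signal samples.
#' @return Angular frequency (rad/ms for ms grids).
#' @export
dominant_frequency <- function(t, x) {
  n <- length(x)
  stopifnot(length(t) == n, n > 3)
  dt <- t[2] - t[1]
  sp <- Mod(fft(x - mean(x)))[seq_len(floor(n / 2))]
  k <- which.max(sp[-1])  # skip the zero-frequency bin
  2 * pi * k / (n * dt)
}
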