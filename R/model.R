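#' Steady-state activation sigmoid
#'
#' `a_x_inf(V) = 1 / (1 + exp(-s_x (V - V0_x)))` for the channels with
#' voltage-dependent activation (`d`, `r`, `sd`).  Strictly increasing in
#' `V`, bounded in (0, 1), equal to 1/2 at the half-activation potential.
#'
#' @param V membrane potential (mV); may be a vector.
#' @param channel one of `"d"`, `"r"`, `"sd"`.
#' @param params an [hb_params()] object.
#' @return Activation value(s) in (0, 1).
#' @export
steady_state_activation <- function(V, channel, params = hb_params()) {
  channel <- match.arg(channel, c("d", "r", "sd"))
  s <- params[[paste0("s_", channel)]]
  V0 <- params[[paste0("V0_", channel)]]
  1 / (1 + exp(-s * (V - V0)))
}

#' Ionic and leak currents
#'
#' `ionic_current()` returns `rho * g_x * a * (V - V_x)` for channel
#' `x` in `d`, `r`, `sd`, `sr`; `leak_current()` returns `g_l * (V - V_l)`
#' (the leak is not temperature-scaled).  Units: uA/cm^2.
#'
#' @param channel one of `"d"`, `"r"`, `"sd"`, `"sr"`.
#' @param V membrane potential (mV).
#' @param a activation (>= 0); for channel `d` normally
#'   `steady_state_activation(V, "d")`.
#' @param params an [hb_params()] object.
#' @return Current in uA/cm^2.
#' @export
ionic_current <- function(channel, V, a, params = hb_params()) {
  channel <- match.arg(channel, c("d", "r", "sd", "sr"))
  if (any(a < 0)) stop("activation must be >= 0")
  g <- params[[paste0("g_", channel)]]
  Vx <- params[[paste0("V_", channel)]]
  params$rho * g * a * (V - Vx)
}

#' @rdname ionic_current
#' @export
leak_current <- function(V, params = hb_params()) {
  params$g_l * (V - params$V_l)
}

#' Huber-Braun vector field
#'
#' Time derivative of the state `(V, a_r, a_sd, a_sr)`:
#' \deqn{C_m dV/dt = -I_l - I_d - I_r - I_{sd} - I_{sr} - I_{ext}}
#' with `a_d = a_d_inf(V)` instantaneous, first-order relaxation of `a_r`
#' and `a_sd` toward their sigmoids at rate `phi / tau`, and
#' `da_sr/dt = phi (-eta I_sd - theta a_sr) / tau_sr` (calcium build-up by
#' the slow depolarizing current, relaxed at rate `theta`).
#'
#' @param t time (ms); unused by the autonomous field but kept so the
#'   signature matches time-dependent integration.
#' @param state an [hb_state()] (or any 4-vector `V, a_r, a_sd, a_sr`).
#' @param i_ext external current (uA/cm^2).
#' @param params an [hb_params()] object.
#' @return Named numeric vector of the four derivatives (per ms).
#' @export
hb_vector_field <- function(t, state, i_ext, params = hb_params()) {
  s <- as_hb_state(state)
  V <- s[[1]]; a_r <- s[[2]]; a_sd <- s[[3]]; a_sr <- s[[4]]
  a_d <- steady_state_activation(V, "d", params)
  I_l <- leak_current(V, params)
  I_d <- ionic_current("d", V, a_d, params)
  I_r <- params$rho * params$g_r * a_r * (V - params$V_r)
  I_sd <- params$rho * params$g_sd * a_sd * (V - params$V_sd)
  I_sr <- params$rho * params$g_sr * a_sr * (V - params$V_sr)
  c(V = -(I_l + I_d + I_r + I_sd + I_sr + i_ext) / params$C_m,
    a_r = params$phi * (steady_state_activation(V, "r", params) - a_r) /
      params$tau_r,
    a_sd = params$phi * (steady_state_activation(V, "sd", params) - a_sd) /
      params$tau_sd,
    a_sr = params$phi * (-params$eta * I_sd - params$theta * a_sr) /
      params$tau_sr)
}

# 1-D reduction of the equilibrium problem: at a fixed point the activation
# equations give a_r = a_r_inf(V), a_sd = a_sd_inf(V),
# a_sr = -eta I_sd / theta, leaving a single equation in V.
fixed_point_residual_V <- function(V, i_ext, params) {
  a_d <- steady_state_activation(V, "d", params)
  a_r <- steady_state_activation(V, "r", params)
  a_sd <- steady_state_activation(V, "sd", params)
  I_sd <- params$rho * params$g_sd * a_sd * (V - params$V_sd)
  a_sr <- -params$eta * I_sd / params$theta
  I_l <- params$g_l * (V - params$V_l)
  I_d <- params$rho * params$g_d * a_d * (V - params$V_d)
  I_r <- params$rho * params$g_r * a_r * (V - params$V_r)
  I_sr <- params$rho * params$g_sr * a_sr * (V - params$V_sr)
  -(I_l + I_d + I_r + I_sd + I_sr + i_ext)
}

#' Fixed point of the model at constant current
#'
#' Solves for the equilibrium state at constant external current.  The
#' four-dimensional root problem reduces algebraically to one equation in
#' `V` (activations take their equilibrium values), which is bracketed on
#' `interval` and solved to tolerance `1e-12` in `V`.
#'
#' @param i_ext constant external current (uA/cm^2).
#' @param params an [hb_params()] object.
#' @param interval voltage bracket (mV) searched for a sign change.
#' @return An [hb_state()] at which [hb_vector_field()] vanishes (residual
#'   below 1e-9 in every component).
#' @export
find_fixed_point <- function(i_ext, params = hb_params(),
                             interval = c(-90, -30)) {
  grid <- seq(interval[1], interval[2], length.out = 241)
  fv <- vapply(grid, fixed_point_residual_V, numeric(1),
               i_ext = i_ext, params = params)
  sg <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (!length(sg))
    stop("no equilibrium: no sign change of the reduced equation in (",
         interval[1], ", ", interval[2], ") mV")
  r <- uniroot(fixed_point_residual_V, c(grid[sg[1]], grid[sg[1] + 1]),
               i_ext = i_ext, params = params, tol = 1e-12)
  V <- r$root
  a_sd <- steady_state_activation(V, "sd", params)
  I_sd <- params$rho * params$g_sd * a_sd * (V - params$V_sd)
  hb_state(V,
           a_r = steady_state_activation(V, "r", params),
           a_sd = a_sd,
           a_sr = -params$eta * I_sd / params$theta)
}

#' Jacobian of the vector field
#'
#' Closed-form 4x4 Jacobian at a state, with the instantaneous activation
#' `a_d = a_d_inf(V)` eliminated (its V-dependence enters dV/dt through the
#' product rule).  Used by [linearized_eigenvalues()]; exported so it can be
#' cross-checked against finite differences.
#'
#' @param state an [hb_state()].
#' @param params an [hb_params()] object.
#' @return A 4x4 numeric matrix (per ms).
#' @export
hb_jacobian <- function(state, params = hb_params()) {
  s <- as_hb_state(state)
  V <- s[[1]]; a_r <- s[[2]]; a_sd <- s[[3]]; a_sr <- s[[4]]
  p <- params
  a_d <- steady_state_activation(V, "d", p)
  dsig <- function(a, slope) slope * a * (1 - a)
  a_d_p <- dsig(a_d, p$s_d)
  a_r_p <- dsig(steady_state_activation(V, "r", p), p$s_r)
  a_sd_p <- dsig(steady_state_activation(V, "sd", p), p$s_sd)
  J <- matrix(0, 4, 4,
              dimnames = list(c("V", "a_r", "a_sd", "a_sr"),
                              c("V", "a_r", "a_sd", "a_sr")))
  J[1, 1] <- -(p$g_l +
                 p$rho * p$g_d * (a_d_p * (V - p$V_d) + a_d) +
                 p$rho * p$g_r * a_r +
                 p$rho * p$g_sd * a_sd +
                 p$rho * p$g_sr * a_sr) / p$C_m
  J[1, 2] <- -p$rho * p$g_r * (V - p$V_r) / p$C_m
  J[1, 3] <- -p$rho * p$g_sd * (V - p$V_sd) / p$C_m
  J[1, 4] <- -p$rho * p$g_sr * (V - p$V_sr) / p$C_m
  J[2, 1] <- p$phi * a_r_p / p$tau_r
  J[2, 2] <- -p$phi / p$tau_r
  J[3, 1] <- p$phi * a_sd_p / p$tau_sd
  J[3, 3] <- -p$phi / p$tau_sd
  J[4, 1] <- -p$phi * p$eta * p$rho * p$g_sd * a_sd / p$tau_sr
  J[4, 3] <- -p$phi * p$eta * p$rho * p$g_sd * (V - p$V_sd) / p$tau_sr
  J[4, 4] <- -p$phi * p$theta / p$tau_sr
  J
}

#' Eigenvalues of the linearization at the fixed point
#'
#' Eigenvalues of [hb_jacobian()] evaluated at [find_fixed_point()], sorted
#' by descending real part.  The leading complex-conjugate pair gives the
#' damped-oscillation (subthreshold) frequency `|Im|` in rad/ms and the
#' focus stability `Re`; its sign change locates the Hopf bifurcation of
#' the quiescent branch.
#'
#' @inheritParams find_fixed_point
#' @return Complex vector of length 4, sorted by descending real part.
#' @export
linearized_eigenvalues <- function(i_ext, params = hb_params()) {
  fp <- find_fixed_point(i_ext, params)
  ev <- eigen(hb_jacobian(fp, params), only.values = TRUE)$values
  ev[order(-Re(ev))]
}
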