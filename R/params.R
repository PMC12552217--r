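#' Huber-Braun model parameters
#'
#' Builds the full parameter set of the Huber-Braun (HB) thermosensitive
#' neuron: a Hodgkin-Huxley-type membrane with two fast spike-generating
#' currents (`d`, depolarizing Na-like; `r`, repolarizing K-like) and two slow
#' subthreshold currents (`sd`, slow depolarizing; `sr`, slow repolarizing,
#' a simplified Ca-dependent K current).  Temperature enters only through two
#' Q10 scaling factors: `rho` multiplies all maximal conductances and `phi`
#' multiplies all activation kinetics (see [temperature_factors()]).
#'
#' Defaults are the standard constants of the model at temperature
#' `T = 18` degrees Celsius with reference `T0 = 25`.  Units are fixed
#' package-wide: mV, ms, uA/cm^2, mS/cm^2, uF/cm^2.
#'
#' @param ... named overrides of any default constant, e.g. `g_sd = 0.3` or
#'   `T = 25`.
#' @return An object of class `hb_params`: a named list of all constants plus
#'   the derived temperature factors `rho` and `phi`.
#' @examples
#' p <- hb_params()
#' p$rho                 # 1.3^((18-25)/10)
#' hb_params(T = 25)$phi # 1 at the reference temperature
#' @export
hb_params <- function(...) {
  p <- list(
    C_m = 1,
    g_l = 0.1, g_d = 1.5, g_r = 2, g_sd = 0.25, g_sr = 0.4,
    V_l = -60, V_d = 50, V_r = -90, V_sd = 50, V_sr = -90,
    tau_r = 2, tau_sd = 10, tau_sr = 20,
    s_d = 0.25, s_r = 0.25, s_sd = 0.09,
    V0_d = -25, V0_r = -25, V0_sd = -40,
    eta = 0.012, theta = 0.17,
    T = 18, T0 = 25,
    q10_cond = 1.3, q10_kin = 3.0
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  tf <- temperature_factors(p$T, p$T0, p$q10_cond, p$q10_kin)
  p$rho <- tf$rho
  p$phi <- tf$phi
  validate_hb_params(p)
  structure(p, class = "hb_params")
}

validate_hb_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all parameters must be numeric")
  if (!all(vapply(p, function(x) all(is.finite(x)), logical(1))))
    stop("all parameters must be finite")
  g <- unlist(p[c("g_l", "g_d", "g_r", "g_sd", "g_sr")])
  if (any(g <= 0)) stop("all conductances must be > 0")
  tau <- unlist(p[c("tau_r", "tau_sd", "tau_sr")])
  if (any(tau <= 0)) stop("all time constants must be > 0")
  if (p$C_m <= 0) stop("C_m must be > 0")
  invisible(p)
}

#' @export
print.hb_params <- function(x, ...) {
  cat("Huber-Braun parameters (mV, ms, uA/cm^2, mS/cm^2, uF/cm^2)\n")
  cat(sprintf("  T = %g C (T0 = %g C): rho = %.6f, phi = %.6f\n",
              x$T, x$T0, x$rho, x$phi))
  flat <- unlist(x[setdiff(names(x), c("rho", "phi"))])
  print(flat)
  invisible(x)
}

#' Q10 temperature scaling factors
#'
#' The conductance factor `rho = q10_cond^((T - T0)/10)` and the kinetics
#' factor `phi = q10_kin^((T - T0)/10)` (van't Hoff scaling).  Both equal 1
#' at the reference temperature.
#'
#' @param T temperature (degrees Celsius).
#' @param T0 reference temperature (degrees Celsius).
#' @param q10_cond Q10 for maximal conductances (default 1.3).
#' @param q10_kin Q10 for activation kinetics (default 3.0).
#' @return A list with components `rho` and `phi`.
#' @examples
#' temperature_factors(25, 25) # both 1
#' temperature_factors(35, 25) # rho = 1.3, phi = 3
#' @export
temperature_factors <- function(T, T0, q10_cond = 1.3, q10_kin = 3.0) {
  if (!is.finite(T) || !is.finite(T0))
    stop("temperatures must be finite")
  ex <- (T - T0) / 10
  list(rho = q10_cond^ex, phi = q10_kin^ex)
}

#' Neuron state vector
#'
#' The four dynamical variables: membrane potential `V` (mV) and the
#' activation variables `a_r`, `a_sd`, `a_sr` (dimensionless).  The fast
#' depolarizing activation `a_d` is instantaneous (a sigmoid of `V`) and is
#' therefore not a state variable.
#'
#' @param V membrane potential (mV).
#' @param a_r,a_sd,a_sr activation variables.
#' @return A named numeric vector of class `hb_state`.
#' @export
hb_state <- function(V, a_r = 0, a_sd = 0, a_sr = 0) {
  s <- c(V = V, a_r = a_r, a_sd = a_sd, a_sr = a_sr)
  if (!all(is.finite(s))) stop("state must be finite")
  structure(s, class = "hb_state")
}

as_hb_state <- function(x) {
  if (inherits(x, "hb_state")) return(x)
  x <- as.numeric(x)
  if (length(x) != 4 || !all(is.finite(x)))
    stop("a state is 4 finite numbers (V, a_r, a_sd, a_sr)")
  hb_state(x[1], x[2], x[3], x[4])
}

# Flat named vector handed to the compiled kernel.
params_vector <- function(p) {
  unlist(p[c("C_m", "g_l", "g_d", "g_r", "g_sd", "g_sr",
             "V_l", "V_d", "V_r", "V_sd", "V_sr",
             "tau_r", "tau_sd", "tau_sr",
             "s_d", "s_r", "s_sd", "V0_d", "V0_r", "V0_sd",
             "eta", "theta", "rho", "phi")])
}

#' Read or write a parameter set as flat JSON
#'
#' Parameter files are flat key-value JSON with keys named after the model
#' symbols (`g_sd`, `V0_sd`, `tau_sr`, ...).  The packaged file
#' `system.file("extdata", "hb_default_params.json", package = "hbneuron")`
#' reproduces the default constants.
#'
#' @param path file path.
#' @param params an `hb_params` object.
#' @return `read_params_json()` returns an `hb_params` object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- x[setdiff(names(x), c("rho", "phi"))]
  do.call(hb_params, as.list(x))
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "hb_params"))
  x <- params[setdiff(names(params), c("rho", "phi"))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
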