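#' Osmotic membrane specification
#'
#' Describes the forward-osmosis membrane separating the actuation chamber
#' from the pure-water reservoir. Water permeability defaults to the
#' cellulose-triacetate membrane value (3e-13 m s^-1 Pa^-1). Reflection
#' coefficients follow the known rejection coefficients (KCl 50-70\%, upper
#' end adopted; D-Glc 99\%; L-Gln ~100\%); the solute permeabilities are
#' effective backflow coefficients of the pressurized device, calibrated so
#' that the simulator reproduces the observed expansion/turgor orderings
#' (see the methods vignette). Complexes always carry sigma = 1 and P_s = 0.
#'
#' @param S_OM Membrane surface area, m^2.
#' @param alpha_OM Water permeability, m s^-1 Pa^-1.
#' @param sigma Named reflection coefficients in [0, 1] per solute.
#' @param P_s Named diffusive solute permeabilities, m/s, >= 0.
#' @param pore_size_nm Annotation, nm.
#' @return Object of class \code{membrane_spec}.
#' @export
membrane_spec <- function(S_OM = 1e-4, alpha_OM = 3e-13,
                          sigma = c("KCl" = 0.70, "D-Glc" = 0.99,
                                    "L-Gln" = 1.0),
                          P_s = c("KCl" = 1e-4, "D-Glc" = 3e-6,
                                  "L-Gln" = 0),
                          pore_size_nm = c(0.3, 0.5)) {
  stopifnot(S_OM > 0, alpha_OM > 0,
            all(sigma >= 0), all(sigma <= 1), all(P_s >= 0))
  structure(list(S_OM = S_OM, alpha_OM = alpha_OM, sigma = sigma,
                 P_s = P_s, pore_size_nm = pore_size_nm),
            class = "membrane_spec")
}

#' Actuator configuration
#'
#' Geometry, elasticity and operating mode of the plant-cell-inspired
#' osmotic device. In \code{turgor} mode the elastomeric bulging disk
#' opposes expansion with a linear elastic pressure
#' P = k_BD (V - V0) / V0; in \code{piston} mode a frictionless piston
#' keeps the chamber at reservoir pressure (P = 0) and the device expands
#' freely. The default disk stiffness is back-solved so that, at the
#' reference potential \code{Pi0_ref}, the analytic characteristic time is
#' 60 s (actuation on the minute timescale).
#'
#' @param membrane A \code{membrane_spec}.
#' @param V_0 Initial chamber volume, m^3.
#' @param k_BD Bulging-disk stiffness, Pa per unit relative volume change;
#'   \code{NULL} back-solves it from \code{ts_target}.
#' @param mode \code{"turgor"} or \code{"piston"}.
#' @param P_ref Reference pressure defining the characteristic time, Pa.
#' @param coupling Optional \code{complex_model}: re-speciate the chamber
#'   contents at every step so that complexed osmolytes are fully retained.
#' @param piston_area Piston cross-section, m^2 (piston mode displacement
#'   readout).
#' @param Pi0_ref Reference initial osmotic potential used to back-solve
#'   \code{k_BD}, Pa (default: the measured potential of the motor-cell
#'   model cytosol, 4.88 MPa).
#' @param ts_target Characteristic time realized at \code{Pi0_ref}, s.
#' @return Object of class \code{actuator_config}.
#' @export
actuator_config <- function(membrane = membrane_spec(), V_0 = 3e-6,
                            k_BD = NULL, mode = c("turgor", "piston"),
                            P_ref = 1e6, coupling = NULL,
                            piston_area = 2e-4,
                            Pi0_ref = 4.88e6, ts_target = 60) {
  mode <- match.arg(mode)
  stopifnot(inherits(membrane, "membrane_spec"), V_0 > 0, P_ref > 0,
            piston_area > 0)
  if (is.null(k_BD))
    k_BD <- P_ref * V_0 /
      (membrane$S_OM * membrane$alpha_OM * Pi0_ref * ts_target)
  if (mode == "turgor" && k_BD <= 0) stop("k_BD must be > 0 in turgor mode")
  if (!is.null(coupling)) stopifnot(inherits(coupling, "complex_model"))
  structure(list(membrane = membrane, V_0 = V_0, k_BD = k_BD, mode = mode,
                 P_ref = P_ref, coupling = coupling,
                 piston_area = piston_area),
            class = "actuator_config")
}

#' Analytic characteristic actuation time
#'
#' t_s = P_ref V_0 / (S_OM alpha_OM k_BD Pi_0 sigma_eff): the time for the
#' chamber pressure to reach P_ref at the initial pressurization rate,
#' where sigma_eff is the amount-weighted mean reflection coefficient of
#' the load. Decreases when membrane area, permeability, disk stiffness or
#' initial potential increase.
#'
#' @param config An \code{actuator_config} (turgor mode).
#' @param Pi_0 Initial osmotic potential, Pa (> 0). The measured potential
#'   of the loaded mixture is the intended argument.
#' @param sigma_eff Amount-weighted mean reflection coefficient
#'   (\code{\link{sigma_effective}}); 1 for a fully retained load.
#' @return Seconds.
#' @export
characteristic_time <- function(config, Pi_0, sigma_eff = 1) {
  stopifnot(inherits(config, "actuator_config"))
  if (config$mode != "turgor")
    stop("characteristic time is defined for turgor mode")
  if (!is.finite(Pi_0) || Pi_0 <= 0) stop("Pi_0 must be > 0")
  if (sigma_eff <= 0) stop("sigma_eff must be > 0")
  mem <- config$membrane
  config$P_ref * config$V_0 /
    (mem$S_OM * mem$alpha_OM * config$k_BD * Pi_0 * sigma_eff)
}

#' Amount-weighted mean reflection coefficient of a mixture
#'
#' @param mix A \code{mixture}.
#' @param membrane A \code{membrane_spec}.
#' @return Dimensionless sigma_eff in [0, 1].
#' @export
sigma_effective <- function(mix, membrane = membrane_spec()) {
  m <- mix$species_molarity
  sig <- lookup_map(membrane$sigma, names(m), "sigma")
  sum(sig * m) / sum(m)
}

#' Simulated characteristic time (first P_ref crossing)
#'
#' Numeric variant of \code{\link{characteristic_time}}: simulates the
#' turgor transient and returns the (linearly interpolated) first time the
#' chamber pressure crosses \code{P_ref}.
#'
#' @param config An \code{actuator_config} in turgor mode.
#' @param mix The loaded \code{mixture}.
#' @param params An \code{osmo_params}.
#' @param horizon Simulation horizon, s.
#' @return Seconds (NA if P_ref is not reached within the horizon).
#' @export
characteristic_time_numeric <- function(config, mix,
                                        params = osmotic_model_params(),
                                        horizon = 3600) {
  tr <- simulate_actuator(config, mix, duration = horizon, params = params,
                          n_samples = 2000)
  above <- which(tr$pressure >= config$P_ref)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(tr$time[1])
  # linear interpolation between the bracketing samples
  t0 <- tr$time[i - 1]; t1 <- tr$time[i]
  p0 <- tr$pressure[i - 1]; p1 <- tr$pressure[i]
  t0 + (config$P_ref - p0) / (p1 - p0) * (t1 - t0)
}

lookup_map <- function(map, keys, what) {
  miss <- setdiff(keys, names(map))
  if (length(miss))
    stop("unknown solute in ", what, " map: ", paste(miss, collapse = ", "))
  vapply(keys, function(k) unname(map[[k]]), numeric(1))
}

#' Simulate the osmotic actuator
#'
#' Integrates the volume/solute transport equations against an infinite
#' well-stirred pure-water reservoir at zero pressure:
#' \deqn{dV/dt = S\,\alpha\,(\sum_k \sigma_k \gamma_k R T c_k - P)}
#' \deqn{dN_k/dt = -P_{s,k} S c_k - (1-\sigma_k)\,c_k\,dV/dt}
#' with P = k_BD (V - V0)/V0 in turgor mode and P = 0 in piston mode.
#' If \code{config$coupling} is set, chamber concentrations are
#' re-speciated through the mass-action complex model at every derivative
#' evaluation; free species are sigma/gamma-weighted individually while
#' the complex is fully retained (sigma = 1, one ideal particle, no leak).
#'
#' @param config An \code{actuator_config}.
#' @param mix The loaded \code{mixture} (nonempty).
#' @param duration Simulated time, s (> 0).
#' @param params An \code{osmo_params}.
#' @param n_samples Number of output samples (evenly spaced, including
#'   \code{duration}).
#' @param sample_times Optional explicit sample times, s (overrides
#'   \code{n_samples}).
#' @param rtol Relative tolerance of the adaptive integrator.
#' @param method \code{"rk45"} (adaptive Cash-Karp) or \code{"rk4"}
#'   (fixed step, oracle use).
#' @param h_fixed Step size for \code{method = "rk4"}, s.
#' @return A \code{data.frame} of class \code{turgor_trace} with columns
#'   \code{time} (s), \code{volume} (m^3), \code{pressure} (Pa),
#'   \code{pi_internal} (Pa, gamma-weighted internal potential) and one
#'   \code{amount_<species>} column (mol) per solute.
#' @export
simulate_actuator <- function(config, mix, duration,
                              params = osmotic_model_params(),
                              n_samples = 400, sample_times = NULL,
                              rtol = 1e-8,
                              method = c("rk45", "rk4"), h_fixed = 1e-3) {
  method <- match.arg(method)
  stopifnot(inherits(config, "actuator_config"), inherits(mix, "mixture"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (length(mix$species_molarity) == 0) stop("mixture is empty")
  sp <- names(mix$species_molarity)
  mem <- config$membrane
  gam <- vapply(sp, function(s) gamma_factor(s, params), numeric(1))
  sig <- lookup_map(mem$sigma, sp, "sigma")
  ps <- lookup_map(mem$P_s, sp, "P_s")
  K <- 0
  idx <- c(-1L, -1L, -1L)
  if (!is.null(config$coupling) && config$coupling$K_assoc > 0) {
    need <- c("KCl", "D-Glc", "L-Gln")
    if (!all(need %in% sp))
      stop("complex coupling needs KCl, D-Glc and L-Gln in the mixture")
    K <- config$coupling$K_assoc
    idx <- as.integer(match(need, sp) - 1L)
  }
  if (is.null(sample_times))
    sample_times <- seq(0, duration, length.out = n_samples + 1)
  stopifnot(!is.unsorted(sample_times), max(sample_times) <= duration)
  # initial amounts: mol = (mol/L -> mol/m^3) * m^3
  N0 <- mix$species_molarity * 1000 * config$V_0
  y0 <- c(config$V_0, unname(N0))
  pars <- list(gamma = unname(gam), sigma = unname(sig), Ps = unname(ps),
               S = mem$S_OM, alpha = mem$alpha_OM, kBD = config$k_BD,
               V0 = config$V_0, RT = params$R * params$T,
               turgor = config$mode == "turgor", K = K, idx = idx)
  out <- actuator_integrate_cpp(y0, sample_times, pars, rtol, method,
                                h_fixed)
  V <- out[, 2]
  P <- if (config$mode == "turgor")
    config$k_BD * (V - config$V_0) / config$V_0 else rep(0, length(V))
  amounts <- out[, -(1:2), drop = FALSE]
  colnames(amounts) <- paste0("amount_", sp)
  conc <- sweep(amounts, 1, V, "/")  # mol/m^3
  pi_int <- trace_internal_potential(conc, sp, gam, K, idx, params)
  tr <- data.frame(time = out[, 1], volume = V, pressure = P,
                   pi_internal = pi_int, check.names = FALSE)
  tr <- cbind(tr, as.data.frame(amounts, check.names = FALSE))
  class(tr) <- c("turgor_trace", "data.frame")
  attr(tr, "mode") <- config$mode
  attr(tr, "V_0") <- config$V_0
  attr(tr, "piston_area") <- config$piston_area
  attr(tr, "species") <- sp
  tr
}

# gamma-weighted internal osmotic potential (Pa) per trace row, with
# optional complex re-speciation; conc in mol/m^3.
trace_internal_potential <- function(conc, sp, gam, K, idx, params) {
  RT <- params$R * params$T
  vapply(seq_len(nrow(conc)), function(i) {
    c_i <- conc[i, ]
    x <- 0
    if (K > 0) {
      x <- 1000 * solve_extent4_cpp(c_i[idx[1] + 1] / 1000,
                                    c_i[idx[2] + 1] / 1000,
                                    c_i[idx[3] + 1] / 1000, K)
      c_i[idx + 1] <- pmax(c_i[idx + 1] - x, 0)
    }
    RT * (sum(gam * c_i) + x)
  }, numeric(1))
}

#' Non-dimensionalise a trace by its characteristic time
#'
#' Divides the time column by \code{t_s}; all other columns are unchanged.
#'
#' @param trace A \code{turgor_trace}.
#' @param t_s Characteristic time, s (> 0).
#' @return The trace with rescaled time; the cumulative scale is recorded
#'   in \code{attr(trace, "t_s")}.
#' @export
nondimensionalize <- function(trace, t_s) {
  if (!is.finite(t_s) || t_s <= 0) stop("t_s must be > 0")
  trace$time <- trace$time / t_s
  prev <- attr(trace, "t_s")
  attr(trace, "t_s") <- if (is.null(prev)) t_s else prev * t_s
  trace
}

#' Piston displacement implied by a piston-mode trace
#'
#' @param trace A piston-mode \code{turgor_trace}.
#' @return Displacement in m, (V - V0) / piston_area.
#' @export
piston_displacement <- function(trace) {
  if (!identical(attr(trace, "mode"), "piston"))
    stop("displacement is defined for piston-mode traces")
  area <- attr(trace, "piston_area")
  if (is.null(area)) stop("missing piston area")
  (trace$volume - attr(trace, "V_0")) / area
}
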