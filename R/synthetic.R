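#' Instrument noise specification
#'
#' Statistical model of the two instruments: the cryo-osmometer (Gaussian
#' replicate scatter, five repetitions per mixture, standard deviations at
#' the 0.01-0.04 MPa level as tabulated) and the differential pressure
#' sensor (additive Gaussian noise, uniform quantization at the 0.01 MPa
#' sensitivity, 1.72 MPa full scale, triplicate runs).
#'
#' @param osmometry_sd Osmometer replicate sd, MPa.
#' @param pressure_quantum Sensor resolution, MPa.
#' @param pressure_full_scale Sensor full scale, MPa.
#' @param pressure_noise_sd Sensor additive noise sd, MPa (default: half a
#'   quantum).
#' @param displacement_noise_sd Piston displacement readout sd, m
#'   (camera/image-processing precision, default 0.1 mm).
#' @param n_replicates Replicates per condition (5 for osmometry, 3 for
#'   traces).
#' @param seed Root RNG seed; per-replicate seeds are derived by fixed
#'   increments.
#' @return Object of class \code{noise_spec}.
#' @export
noise_spec <- function(osmometry_sd = 0.02, pressure_quantum = 0.01,
                       pressure_full_scale = 1.72,
                       pressure_noise_sd = 0.005,
                       displacement_noise_sd = 1e-4,
                       n_replicates = 5L, seed = 1L) {
  stopifnot(osmometry_sd >= 0, pressure_quantum > 0,
            pressure_full_scale > 0, pressure_noise_sd >= 0,
            displacement_noise_sd >= 0, n_replicates >= 1)
  structure(list(osmometry_sd = osmometry_sd,
                 pressure_quantum = pressure_quantum,
                 pressure_full_scale = pressure_full_scale,
                 pressure_noise_sd = pressure_noise_sd,
                 displacement_noise_sd = displacement_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Quantize and clip a pressure signal
#'
#' Rounds to the nearest multiple of the sensor quantum and clips into
#' [0, full scale]. Idempotent.
#'
#' @param p Pressure, MPa.
#' @param quantum Sensor resolution, MPa.
#' @param full_scale Sensor full scale, MPa.
#' @return Quantized pressure, MPa.
#' @export
quantize_pressure <- function(p, quantum = 0.01, full_scale = 1.72) {
  pmin(pmax(round(p / quantum) * quantum, 0), full_scale)
}

#' Generate synthetic cryo-osmometry replicates
#'
#' Independent Gaussian draws around the true potential, reproducing the
#' tabulated mean +/- sd (n = 5) structure.
#'
#' @param true_pi True osmotic potential, MPa (>= 0).
#' @param spec A \code{noise_spec}.
#' @return Numeric vector of \code{spec$n_replicates} measurements, MPa.
#' @export
#' @examples
#' gen_osmometry(2.93, noise_spec(osmometry_sd = 0.02, seed = 7))
gen_osmometry <- function(true_pi, spec = noise_spec()) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!is.finite(true_pi) || true_pi < 0) stop("true_pi must be >= 0")
  with_seed(spec$seed,
            stats::rnorm(spec$n_replicates, true_pi, spec$osmometry_sd))
}

#' Generate noisy, quantized turgor-pressure traces
#'
#' Simulates the actuator once, then emits \code{spec$n_replicates} sensor
#' realizations: Gaussian noise added to the pressure, quantization at the
#' sensor resolution, clipping at full scale. Replicate r uses seed
#' \code{spec$seed + r - 1}.
#'
#' @param config,mix,duration,params,n_samples Passed to
#'   \code{\link{simulate_actuator}}.
#' @param spec A \code{noise_spec}.
#' @return List of \code{turgor_trace}s whose \code{pressure} column is in
#'   MPa quantized units times 1e6 (i.e. still Pa, but quantized at
#'   \code{pressure_quantum} MPa); the clean trace is attached as
#'   \code{attr(, "clean")}.
#' @export
gen_turgor_trace <- function(config, mix, spec = noise_spec(n_replicates = 3L),
                             duration, params = osmotic_model_params(),
                             n_samples = 200) {
  clean <- simulate_actuator(config, mix, duration, params,
                             n_samples = n_samples)
  p_mpa <- clean$pressure / 1e6
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    noisy <- with_seed(spec$seed + r - 1L,
                       p_mpa + stats::rnorm(length(p_mpa), 0,
                                            spec$pressure_noise_sd))
    q <- quantize_pressure(noisy, spec$pressure_quantum,
                           spec$pressure_full_scale)
    tr <- clean
    tr$pressure <- q * 1e6
    tr
  })
  attr(reps, "clean") <- clean
  reps
}

#' Generate noisy piston-displacement traces
#'
#' Piston-mode simulation converted to displacement through the piston
#' cross-section, with Gaussian readout noise per replicate.
#'
#' @param config Piston-mode \code{actuator_config} (with
#'   \code{piston_area}).
#' @param mix The loaded \code{mixture}.
#' @param spec A \code{noise_spec}.
#' @param duration Trace duration, s (default four hours).
#' @param params,n_samples Passed to \code{\link{simulate_actuator}}.
#' @return List of data.frames \code{(time, displacement)} in s and m; the
#'   clean trace is attached as \code{attr(, "clean")}.
#' @export
gen_piston_trace <- function(config, mix, spec = noise_spec(n_replicates = 3L),
                             duration = 4 * 3600,
                             params = osmotic_model_params(),
                             n_samples = 200) {
  if (config$mode != "piston") stop("config must be in piston mode")
  if (is.null(config$piston_area)) stop("missing piston area")
  clean <- simulate_actuator(config, mix, duration, params,
                             n_samples = n_samples)
  d <- piston_displacement(clean)
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    noisy <- with_seed(spec$seed + r - 1L,
                       d + stats::rnorm(length(d), 0,
                                        spec$displacement_noise_sd))
    data.frame(time = clean$time, displacement = noisy)
  })
  attr(reps, "clean") <- clean
  reps
}

#' Recover the membrane water permeability from traces
#'
#' One-parameter least-squares fit of alpha_OM: each candidate value
#' re-simulates the device and the squared pressure (turgor traces) or
#' displacement (piston traces) residuals are minimized by golden-section
#' search on log10(alpha). Each replicate is fitted independently; the
#' across-replicate mean and sd are reported.
#'
#' @param traces List of traces from \code{\link{gen_turgor_trace}} (or
#'   \code{gen_piston_trace}).
#' @param config The \code{actuator_config} used to generate them (its
#'   \code{membrane$alpha_OM} is ignored).
#' @param mix The loaded \code{mixture}.
#' @param params An \code{osmo_params}.
#' @param log10_bracket Search bracket for log10(alpha_OM).
#' @param rtol Integrator tolerance during fitting.
#' @return List with \code{estimate} (mean over replicates),
#'   \code{sd} (NA for a single replicate) and \code{per_replicate}.
#' @export
recover_permeability <- function(traces, config, mix,
                                 params = osmotic_model_params(),
                                 log10_bracket = c(-14, -11),
                                 rtol = 1e-6) {
  stopifnot(length(traces) >= 1)
  piston <- "displacement" %in% names(traces[[1]])
  times <- traces[[1]]$time
  if (max(times) <= 0 ||
      all(abs(traces[[1]][[if (piston) "displacement" else "pressure"]]) <
          .Machine$double.eps))
    stop("degenerate (flat) trace")
  sim_col <- function(alpha) {
    mem <- config$membrane
    mem$alpha_OM <- alpha
    cfg <- config
    cfg$membrane <- mem
    tr <- simulate_actuator(cfg, mix, duration = max(times),
                            params = params, sample_times = times,
                            rtol = rtol)
    if (piston) piston_displacement(tr) else tr$pressure
  }
  fit_one <- function(tr) {
    obs <- if (piston) tr$displacement else tr$pressure
    sse <- function(la) sum((sim_col(10^la) - obs)^2)
    opt <- stats::optimize(sse, log10_bracket, tol = 1e-4)
    10^opt$minimum
  }
  est <- vapply(traces, fit_one, numeric(1))
  list(estimate = mean(est),
       sd = if (length(est) > 1) stats::sd(est) else NA_real_,
       per_replicate = est)
}

#' Recover the association degree from a dilution series of osmometry
#'
#' Fits the complex association constant to measured potentials at several
#' dilution factors by least squares against
#' \code{\link{effective_osmotic_potential}}, then reports the implied
#' association degree (100 x fraction associated) at stock concentration.
#'
#' @param series \code{data.frame} with columns \code{factor} (>= 1) and
#'   \code{pi_MPa} (measured potential at that dilution); at least two
#'   rows.
#' @param mix The stock \code{mixture}.
#' @param params An \code{osmo_params}.
#' @param log10K_bracket Search bracket for log10(K_assoc).
#' @return List with \code{degree_percent}, \code{K_assoc} and
#'   \code{fraction_associated} at stock.
#' @export
recover_association <- function(series, mix,
                                params = osmotic_model_params(),
                                log10K_bracket = c(-3, 8)) {
  stopifnot(is.data.frame(series),
            all(c("factor", "pi_MPa") %in% names(series)))
  if (nrow(series) < 2) stop("need at least two dilution points")
  totals <- member_totals(mix)
  pred <- function(lk) {
    vapply(series$factor, function(lam) {
      sp <- speciate(totals / lam, complex_model(10^lk), params)
      effective_osmotic_potential(sp, params)
    }, numeric(1))
  }
  sse <- function(lk) sum((pred(lk) - series$pi_MPa)^2)
  opt <- stats::optimize(sse, log10K_bracket, tol = 1e-6)
  # prefer K = 0 when the fit does not beat the no-association model
  sse0 <- sum((vapply(series$factor, function(lam) {
    effective_osmotic_potential(speciate(totals / lam, complex_model(0),
                                         params), params)
  }, numeric(1)) - series$pi_MPa)^2)
  K <- if (sse0 <= opt$objective) 0 else 10^opt$minimum
  sp <- speciate(totals, complex_model(K), params)
  list(degree_percent = 100 * sp$fraction_associated,
       K_assoc = K,
       fraction_associated = sp$fraction_associated)
}

#' Materialize the synthetic measurement fixture set
#'
#' Writes (a) a synthetic replicate table for every packaged model cytosol
#' (osmometry, n = 5, per-mixture sds as tabulated) and (b) one triplicate
#' turgor trace bundle, as CSV under \code{dir}. Used by the command-line
#' \code{synth} command; everything is derived at run time from the
#' packaged fixtures and the seed.
#'
#' @param dir Output directory.
#' @param seed Root seed.
#' @param params An \code{osmo_params}.
#' @return Invisibly, the paths written.
#' @export
synth_fixtures <- function(dir, seed = 1L,
                           params = osmotic_model_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mixes <- table1_mixtures()
  meas <- table1_measured()
  rows <- do.call(rbind, lapply(names(mixes), function(nm) {
    sdv <- meas$sd_MPa[match(nm, meas$name)]
    reps <- gen_osmometry(meas$measured_MPa[match(nm, meas$name)],
                          noise_spec(osmometry_sd = sdv,
                                     seed = seed + match(nm, names(mixes))))
    data.frame(name = nm, replicate = seq_along(reps), pi_MPa = reps)
  }))
  p1 <- file.path(dir, "synthetic_osmometry.csv")
  write_csv_provenance(rows, p1, seed = seed)
  cfg <- actuator_config(mode = "turgor")
  m2 <- mixes[["M2"]]
  tset <- gen_turgor_trace(cfg, m2, noise_spec(n_replicates = 3L,
                                               seed = seed),
                           duration = 240, params = params)
  paths <- c(p1)
  for (r in seq_along(tset)) {
    p <- file.path(dir, sprintf("synthetic_turgor_rep%d.csv", r))
    write_trace_csv(tset[[r]], p, t_s = 60, seed = seed)
    paths <- c(paths, p)
  }
  invisible(paths)
}
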