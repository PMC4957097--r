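#' Read mixture definitions from a YAML file
#'
#' The file holds a top-level \code{mixtures:} list; each entry has
#' \code{name}, either \code{ratio} (a string such as \code{"5:12:3"},
#' interpreted over \code{species}) plus \code{total_molarity}, or
#' \code{molarities} (a named map in mol/L), and optionally \code{pH}.
#'
#' @param path YAML file path.
#' @param species Species order for ratio strings.
#' @return Named list of \code{mixture} objects.
#' @export
read_mixtures <- function(path, species = c("KCl", "D-Glc", "L-Gln")) {
  doc <- yaml::read_yaml(path)
  entries <- if (!is.null(doc$mixtures)) doc$mixtures else doc
  if (length(entries) == 0) stop("no mixtures in ", path)
  out <- lapply(entries, function(e) {
    if (is.null(e$name)) stop("mixture entry without a name in ", path)
    ph <- if (is.null(e$pH)) 7.0 else e$pH
    if (!is.null(e$ratio)) {
      if (is.null(e$total_molarity))
        stop("mixture ", e$name, ": ratio given without total_molarity")
      mixture_from_ratio(e$ratio, e$total_molarity, pH = ph,
                         species = species, name = e$name)
    } else if (!is.null(e$molarities)) {
      mixture(unlist(e$molarities), pH = ph, name = e$name)
    } else {
      stop("mixture ", e$name, ": needs either 'ratio' or 'molarities'")
    }
  })
  names(out) <- vapply(entries, `[[`, character(1), "name")
  out
}

#' Packaged model-cytosol definitions
#'
#' The eight packaged mixtures (M1, M1a-M1c, M2, M2a, M2b and the 1.5 M
#' KCl reference) as defined by their composition ratios and total
#' molarities.
#'
#' @return Named list of \code{mixture} objects.
#' @export
table1_mixtures <- function() {
  read_mixtures(system.file("extdata", "table1_mixtures.yaml",
                            package = "turgorkit", mustWork = TRUE))
}

#' Packaged measured osmotic potentials
#'
#' Cryo-osmometric means and standard deviations (n = 5) for the packaged
#' mixtures.
#'
#' @return \code{data.frame} with columns \code{name, measured_MPa, sd_MPa,
#'   n}.
#' @export
table1_measured <- function() {
  utils::read.csv(system.file("extdata", "table1_measured.csv",
                              package = "turgorkit", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# Deterministic provenance header for output files: package version, a
# content hash of the configuration, and the seed. No timestamps, so
# re-runs are byte-identical.
provenance_header <- function(config = NULL, seed = NA) {
  ver <- as.character(utils::packageVersion("turgorkit"))
  h <- digest::digest(config, algo = "sha256")
  c(sprintf("# turgorkit %s", ver),
    sprintf("# config_sha256 %s", substr(h, 1, 16)),
    sprintf("# seed %s", as.character(seed)))
}

write_csv_provenance <- function(df, path, config = NULL, seed = NA) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(provenance_header(config, seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_provenance <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Write a simulated trace as CSV
#'
#' Columns: \code{t_s} (time, s), \code{t_over_ts}, \code{volume_m3},
#' \code{pressure_MPa}, and one \code{amount_<species>_mol} per solute,
#' preceded by \code{#} provenance comment lines.
#'
#' @param trace A \code{turgor_trace}.
#' @param path Output path.
#' @param t_s Characteristic time used for the \code{t_over_ts} column, s.
#' @param seed Seed recorded in the provenance header.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path, t_s = NA, seed = NA) {
  sp <- attr(trace, "species")
  df <- data.frame(t_s = trace$time,
                   t_over_ts = if (is.finite(t_s)) trace$time / t_s
                               else NA_real_,
                   volume_m3 = trace$volume,
                   pressure_MPa = trace$pressure / 1e6,
                   check.names = FALSE)
  for (s in sp)
    df[[sprintf("amount_%s_mol", s)]] <- trace[[paste0("amount_", s)]]
  write_csv_provenance(df, path, config = list(t_s = t_s, species = sp),
                       seed = seed)
}

#' Read a trace CSV back
#'
#' @param path CSV written by \code{\link{write_trace_csv}}.
#' @return \code{data.frame} with the stored columns.
#' @export
read_trace_csv <- function(path) read_csv_provenance(path)

#' Read an actuator configuration from YAML
#'
#' Keys: \code{membrane: \{S_OM, alpha_OM, sigma: \{...\}, P_s: \{...\}\}},
#' \code{V0}, \code{k_BD}, \code{mode}, \code{P_ref},
#' \code{coupling: \{K_assoc\}}; all optional except that unknown keys are
#' rejected, missing ones fall back to package defaults.
#'
#' @param path YAML file path.
#' @return An \code{actuator_config}.
#' @export
read_actuator_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("membrane", "V0", "k_BD", "mode", "P_ref", "coupling",
             "piston_area")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  mem_args <- list()
  if (!is.null(doc$membrane)) {
    md <- doc$membrane
    mem_known <- c("S_OM", "alpha_OM", "sigma", "P_s")
    extra <- setdiff(names(md), mem_known)
    if (length(extra))
      stop("unknown membrane key(s): ", paste(extra, collapse = ", "))
    if (!is.null(md$S_OM)) mem_args$S_OM <- md$S_OM
    if (!is.null(md$alpha_OM)) mem_args$alpha_OM <- md$alpha_OM
    defaults <- membrane_spec()
    if (!is.null(md$sigma)) {
      s <- defaults$sigma
      ov <- unlist(md$sigma)
      unknown <- setdiff(names(ov), names(s))
      if (length(unknown))
        stop("unknown solute in sigma map: ",
             paste(unknown, collapse = ", "))
      s[names(ov)] <- ov
      mem_args$sigma <- s
    }
    if (!is.null(md$P_s)) {
      ps <- defaults$P_s
      ov <- unlist(md$P_s)
      unknown <- setdiff(names(ov), names(ps))
      if (length(unknown))
        stop("unknown solute in P_s map: ", paste(unknown, collapse = ", "))
      ps[names(ov)] <- ov
      mem_args$P_s <- ps
    }
  }
  args <- list(membrane = do.call(membrane_spec, mem_args))
  if (!is.null(doc$V0)) args$V_0 <- doc$V0
  if (!is.null(doc$k_BD)) args$k_BD <- doc$k_BD
  if (!is.null(doc$mode)) args$mode <- doc$mode
  if (!is.null(doc$P_ref)) args$P_ref <- doc$P_ref
  if (!is.null(doc$piston_area)) args$piston_area <- doc$piston_area
  if (!is.null(doc$coupling) && !is.null(doc$coupling$K_assoc))
    args$coupling <- complex_model(doc$coupling$K_assoc)
  do.call(actuator_config, args)
}

#' Compute and write the derived mixture table
#'
#' Reads mixture definitions and measured potentials, assembles the
#' derived columns (estimated potential, ratio, association degree) with
#' the display rounding convention, and writes them as CSV. Missing
#' measured values leave the ratio columns blank with a warning.
#'
#' @param mixture_file YAML mixture file (see \code{\link{read_mixtures}}).
#' @param measured_file CSV with columns \code{name, measured_MPa}.
#' @param out Output CSV path.
#' @param params An \code{osmo_params}.
#' @return The formatted table, invisibly.
#' @export
run_table1 <- function(mixture_file, measured_file, out,
                       params = osmotic_model_params()) {
  mixes <- read_mixtures(mixture_file)
  meas_df <- utils::read.csv(measured_file, comment.char = "#",
                             stringsAsFactors = FALSE)
  measured <- stats::setNames(meas_df$measured_MPa, meas_df$name)
  miss <- setdiff(names(mixes), names(measured))
  if (length(miss))
    warning("no measured value for: ", paste(miss, collapse = ", "),
            " (ratio columns left blank)")
  tab <- format_table1(table1_report(mixes, measured, params))
  write_csv_provenance(tab, out,
                       config = list(mixtures = mixture_file,
                                     measured = measured, T = params$T))
  invisible(tab)
}

#' Simulate the actuator from configuration files
#'
#' @param config_file Actuator YAML (see
#'   \code{\link{read_actuator_config}}).
#' @param mixture_file Mixture YAML; the first mixture is loaded unless
#'   \code{mixture_name} is given.
#' @param out Output trace CSV path.
#' @param mode Override the configured mode (\code{"piston"} or
#'   \code{"turgor"}).
#' @param duration Duration in seconds, or a string such as \code{"4h"} or
#'   \code{"4ts"} (multiples of the analytic characteristic time).
#' @param nondim Write the time column divided by t_s.
#' @param mixture_name Which mixture to load.
#' @param params An \code{osmo_params}.
#' @return The trace, invisibly.
#' @export
run_simulate <- function(config_file, mixture_file, out,
                         mode = NULL, duration = "4ts", nondim = FALSE,
                         mixture_name = NULL,
                         params = osmotic_model_params()) {
  config <- read_actuator_config(config_file)
  if (!is.null(mode)) {
    if (!mode %in% c("piston", "turgor")) stop("invalid mode: ", mode)
    config$mode <- mode
  }
  mixes <- read_mixtures(mixture_file)
  mix <- if (is.null(mixture_name)) mixes[[1]]
         else if (mixture_name %in% names(mixes)) mixes[[mixture_name]]
         else stop("mixture not found: ", mixture_name)
  pi0 <- estimate_osmotic_potential(mix, params) * 1e6
  ts <- if (config$mode == "turgor")
    characteristic_time(config, pi0, sigma_effective(mix, config$membrane))
  else NA
  dur <- parse_duration(duration, ts)
  tr <- simulate_actuator(config, mix, dur, params)
  if (nondim) {
    if (!is.finite(ts)) stop("cannot non-dimensionalise: t_s undefined")
    tr <- nondimensionalize(tr, ts)
    write_trace_csv(tr, out, t_s = 1)
  } else {
    write_trace_csv(tr, out, t_s = ts)
  }
  invisible(tr)
}

# "240", "4h", "30min", "4ts" -> seconds (ts = characteristic time).
parse_duration <- function(x, t_s = NA) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^([0-9.]+)\\s*(h|min|s|ts)?$", x))[[1]]
  if (length(m) == 0) stop("unparseable duration: ", x)
  v <- as.numeric(m[2])
  unit <- if (is.na(m[3]) || m[3] == "") "s" else m[3]
  switch(unit,
         s = v, min = 60 * v, h = 3600 * v,
         ts = {
           if (!is.finite(t_s))
             stop("duration in characteristic times needs turgor mode")
           v * t_s
         })
}
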