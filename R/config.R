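#' Default run configuration
#'
#' The documented defaults for every configuration key: the nominal
#' oscillatory parameter set for the model block, a 600-time-unit delayed
#' simulation, the reference dosage-selection settings (`Ps = 1`, `T = 60`,
#' `S` on `[0, 200]`), and the analysis tolerances.
#'
#' @return A nested list of class `rnai_config`.
#' @export
default_config <- function() {
  structure(list(
    model = list(km = 10, dm = 0.05, kp = 1, dp = 0.01, r = 0.5062,
                 theta = 10, n = 4, S = 30, tau1 = 3.3594, tau2 = 1,
                 M0 = 160, P0 = 10000),
    simulation = list(horizon = 600, dt = NULL, delayed = TRUE),
    control = list(Ps = 1, T = 60, S_min = 0, S_max = 200, delayed = TRUE,
                   dt = 0.01),
    analysis = list(transient_fraction = 0.5, hopf_tol = 1e-3,
                    gap_spread_tol = 0.02, amp_spread_tol = 0.05,
                    sensitivity_parameters = sens_parameters)),
    class = "rnai_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with (any subset of) the sections `model`, `simulation`,
#' `control` and `analysis`. Unknown sections or keys are rejected with the
#' offending key named; missing keys fall back to the [default_config()]
#' values. The model block uses the exact parameter names
#' `km, dm, kp, dp, r, theta, n, S, tau1, tau2, M0, P0`.
#'
#' @param path path to a YAML configuration file.
#' @return A validated `rnai_config` list with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad))
    stop("unknown config section: '", bad[1], "'", call. = FALSE)
  cfg <- defaults
  for (sec in names(raw)) {
    # YAML 1.1 reads a bare key `n` as the boolean FALSE; map it back
    names(raw[[sec]])[names(raw[[sec]]) == "FALSE"] <- "n"
    badk <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (length(badk))
      stop("unknown config key: '", sec, ".", badk[1], "'", call. = FALSE)
    for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
  }
  # validation through the constructors
  config_params(cfg)
  config_init(cfg)
  if (cfg$model$M0 < 0 || cfg$model$P0 < 0)
    stop("config key 'model.M0'/'model.P0' must be non-negative", call. = FALSE)
  class(cfg) <- "rnai_config"
  cfg
}

#' @rdname load_config
#' @param cfg an `rnai_config` list.
#' @export
config_params <- function(cfg) {
  m <- cfg$model
  rnai_params(km = m$km, dm = m$dm, kp = m$kp, dp = m$dp, r = m$r,
              theta = m$theta, n = m$n, S = m$S, tau1 = m$tau1, tau2 = m$tau2)
}

#' @rdname load_config
#' @export
config_init <- function(cfg) {
  initial_condition(M0 = cfg$model$M0, P0 = cfg$model$P0)
}
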