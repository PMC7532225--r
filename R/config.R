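# flat config keys accepted in YAML/JSON files, mapped onto the
# bioheat_params() constructor arguments (all SI except Q_0, W/cm^2)
.config_keys <- c("rho_t", "c_t", "k", "k_star",
                  "rho_b", "c_b", "omega_b", "T_a",
                  "tau_q", "tau_T", "tau_v", "L",
                  "variant", "case", "theta_0", "T_0", "Q_0", "R_d",
                  "flux_convention", "Q_m", "Q_laser")

#' Load a parameter configuration file
#'
#' Reads a flat YAML or JSON file whose keys match the
#' [bioheat_params()] argument names (values in SI units, except `Q_0`
#' which is in W/cm^2 as conventionally printed) and returns a validated
#' parameter set.  Missing keys take the reference defaults; an empty file
#' yields the full default set; unknown keys are listed and rejected.
#'
#' @param path file path; format chosen by extension (`.json` for JSON,
#'   anything else parsed as YAML, of which JSON is a subset).
#' @return a `bioheat_params` object.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  raw <- lapply(raw, function(x) if (is.numeric(x)) as.numeric(x) else x)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$theta_0)) raw$T_0 <- NULL
  do.call(bioheat_params, raw)
}

#' Write a parameter configuration file
#'
#' Inverse of [load_config()]: serialises a parameter set as a flat YAML
#' or JSON file using the constructor key names, with `Q_0` converted back
#' to W/cm^2.  `load_config(write_config(p, f))` reproduces `p`.
#'
#' @param params a `bioheat_params` object.
#' @param path output path (`.json` for JSON, else YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_params(params)
  flat <- list(
    rho_t = params$tissue$rho_t, c_t = params$tissue$c_t,
    k = params$tissue$k, k_star = params$tissue$k_star,
    rho_b = params$blood$rho_b, c_b = params$blood$c_b,
    omega_b = params$blood$omega_b, T_a = params$blood$T_a,
    tau_q = params$lags$tau_q, tau_T = params$lags$tau_T,
    tau_v = params$lags$tau_v, L = params$geom$L,
    variant = params$variant, case = params$load$case,
    theta_0 = params$load$theta_0,
    Q_0 = params$load$Q_0 / 1e4, R_d = params$load$R_d,
    flux_convention = params$load$flux_convention,
    Q_m = params$sources$Q_m, Q_laser = params$sources$Q_laser
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}
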