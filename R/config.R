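# Analysis configuration: thresholds, correlation options, seed.

#' Default analysis configuration
#'
#' Returns the fully populated configuration used by the pipeline when
#' no config file is given.  Defaults follow the study design the
#' package models: per-feature significance is controlled at a false
#' discovery rate of 0.05; feature-trait correlation filters use a raw
#' significance level of P < 0.01 (primary) and P < 0.05 (secondary);
#' modules are reported when they hold at least `module_min_size`
#' features with an average degree of correlation above
#' `module_min_avg_corr`.
#'
#' @return a named list of class `gxd_config`.
#' @export
default_config <- function() {
  structure(list(
    fdr_q               = 0.05,
    corr_p_primary      = 0.01,
    corr_p_secondary    = 0.05,
    module_min_size     = 3L,
    module_min_avg_corr = 0.5,
    correlation_method  = "pearson",
    sharpness_grid      = 1:30,
    rng_seed            = 1L,
    replicate_collapse  = "line_diet"
  ), class = "gxd_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Absent keys take their defaults (see [default_config()]); present
#' keys are validated against their admissible ranges.
#'
#' @param path path to a YAML key/value file, or `NULL` for pure
#'   defaults.
#' @return a validated `gxd_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  cfg <- validate_config(cfg)
  log_stage("config", "effective config: ",
            paste(names(cfg), vapply(cfg, function(x)
              paste(format(x), collapse = ","), ""), sep = "=",
              collapse = "; "))
  cfg
}

validate_config <- function(cfg) {
  chk01 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop(sprintf("config key '%s' must lie in (0, 1), got %s",
                   key, paste(format(v), collapse = ",")))
    }
  }
  chk01("fdr_q"); chk01("corr_p_primary"); chk01("corr_p_secondary")
  if (!is.numeric(cfg$module_min_size) || cfg$module_min_size < 1) {
    stop("config key 'module_min_size' must be a positive integer")
  }
  cfg$module_min_size <- as.integer(cfg$module_min_size)
  if (!is.numeric(cfg$module_min_avg_corr) ||
      cfg$module_min_avg_corr < 0 || cfg$module_min_avg_corr > 1) {
    stop("config key 'module_min_avg_corr' must lie in [0, 1]")
  }
  cfg$correlation_method <- match.arg(cfg$correlation_method,
                                      c("pearson", "spearman"))
  g <- cfg$sharpness_grid
  if (!is.numeric(g) || length(g) == 0L || any(g <= 0) ||
      is.unsorted(g, strictly = TRUE)) {
    stop("config key 'sharpness_grid' must be a nonempty strictly ",
         "increasing vector of positive reals")
  }
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$replicate_collapse <- match.arg(cfg$replicate_collapse,
                                      c("line_diet", "line_diet_replicate"))
  class(cfg) <- "gxd_config"
  cfg
}

#' @export
print.gxd_config <- function(x, ...) {
  cat("gxdmod analysis configuration\n")
  for (k in names(x)) {
    cat(sprintf("  %-20s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  invisible(x)
}
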