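# Run configuration: a flat YAML document mirroring the command-line
# flags, validated against the set of known keys so typos fail loudly.

run_config_defaults <- function() {
  list(
    network = NULL, seeds_a = NULL, seeds_b = NULL, dialect = "auto",
    nrand = 200L, ss_cut = 0.9, swap_multiplier = 10, specificity = TRUE,
    avgd = NULL, seed = 1L, out = "s2b_results.tsv"
  )
}

#' Read a run configuration file
#'
#' A flat YAML key-value document; unknown keys are rejected. `overrides`
#' (typically command-line flags) take precedence over file values.
#'
#' @param path Path to a YAML file, or `NULL` for defaults only.
#' @param overrides Named list of values overriding the file.
#' @return Named list with the resolved configuration.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(vals)] <- vals
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Write the resolved configuration next to the outputs
#'
#' @param cfg Configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}
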