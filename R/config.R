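#' Analysis configuration with optional YAML overrides
#'
#' Central defaults for every tunable threshold of the pipeline, optionally
#' overridden from a YAML file (flat or nested `key: value` pairs).  The
#' result can be passed as `config` to [compute_feature_table()] and to the
#' study generator.
#'
#' @param path Optional YAML file of overrides.
#' @param overrides Optional named list of overrides (applied after the
#'   file).
#' @return Named list of configuration values.
#' @export
topoland_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    identity_threshold = 0.90,
    disorder_threshold = 0.5,
    idp_threshold = 0.30,
    early_folding_threshold = 0.163,
    aggregation_threshold = 5.0,
    min_len = 5L,
    gatekeeper_flank = 3L,
    contact_cutoff = 6.0,
    min_sep = 1L,
    ca_only = FALSE,
    vs_method = "log_sd",
    popular_frac = 0.03)
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}
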