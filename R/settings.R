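#' Construct a simulation setting specification
#'
#' A setting fixes the dimensions and calibration targets for one simulation
#' scenario: development/validation sample sizes, the predictor block
#' structure, the target median VIF of the correlation matrix, and the target
#' expected number of outcome events in the development data (so that
#' `target_events / p` is the setting's events-per-variable, EPV).
#'
#' @param name setting label, e.g. `"A"` or `"A_hi"`.
#' @param outcome outcome label (`"xerostomia"` or `"dysphagia"`).
#' @param block_structure a [block_structure()].
#' @param target_median_vif target median VIF (> 1).
#' @param target_events expected number of events in the development sample.
#' @param n_dev development sample size (default 592).
#' @param n_val validation sample size (default 10000).
#' @param collinearity `"low"` or `"high"` (plot grouping only).
#' @param seed integer seed for the setting's calibration artifacts.
#' @return an object of class `setting_spec`.
#' @export
setting_spec <- function(name, outcome, block_structure, target_median_vif,
                         target_events, n_dev = 592, n_val = 10000,
                         collinearity = c("low", "high"), seed = 1L) {
  stopifnot(inherits(block_structure, "block_structure"))
  collinearity <- match.arg(collinearity)
  p <- block_structure$p
  if (n_dev <= p)
    stopf("setting %s: n_dev (%d) must exceed p (%d)", name, n_dev, p)
  if (target_median_vif <= 1)
    stopf("setting %s: target median VIF must be > 1", name)
  if (target_events <= 0 || target_events >= n_dev)
    stopf("setting %s: target_events must lie in (0, n_dev)", name)
  structure(list(name = name, outcome = outcome,
                 block_structure = block_structure, p = p,
                 n_dev = as.integer(n_dev), n_val = as.integer(n_val),
                 target_median_vif = target_median_vif,
                 target_events = target_events,
                 prevalence = target_events / n_dev,
                 epv = target_events / p,
                 collinearity = collinearity,
                 seed = as.integer(seed)),
            class = "setting_spec")
}

#' @export
print.setting_spec <- function(x, ...) {
  cat(sprintf(
    "<setting %s> outcome=%s p=%d n_dev=%d EPV=%.3g median VIF target=%.3g (%s collinearity)\n",
    x$name, x$outcome, x$p, x$n_dev, x$epv, x$target_median_vif,
    x$collinearity))
  invisible(x)
}

#' Load the shipped settings catalogue
#'
#' Reads the eight-setting catalogue (two outcomes, small and large predictor
#' sets, low/high collinearity variants) from the YAML file shipped with the
#' package, or from a user-supplied file with the same schema.
#'
#' @param file path to a YAML catalogue; defaults to the shipped one.
#' @return named list of [setting_spec()] objects.
#' @export
default_settings <- function(file = system.file("extdata", "settings.yaml",
                                                package = "collinsim")) {
  cfg <- yaml::read_yaml(file)
  defs <- cfg$defaults %||% list()
  out <- lapply(cfg$settings, function(s) {
    bs <- block_structure(unlist(s$block_sizes),
                          within_block_r = s$within_block_r,
                          between_block_r = s$between_block_r %||% 0,
                          n_clinical = s$n_clinical %||% defs$n_clinical %||% 0)
    if (bs$p != s$p)
      stopf("setting %s: block structure implies p=%d but catalogue says %d",
            s$name, bs$p, s$p)
    setting_spec(name = s$name, outcome = s$outcome, block_structure = bs,
                 target_median_vif = s$target_median_vif,
                 target_events = s$target_events,
                 n_dev = s$n_dev %||% defs$n_dev %||% 592,
                 n_val = s$n_val %||% defs$n_val %||% 10000,
                 collinearity = s$collinearity, seed = s$seed %||% 1L)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Build the calibrated artifacts of a setting
#'
#' Constructs and VIF-calibrates the setting's correlation matrix, then builds
#' the ground-truth logistic model (prevalence- and AUC-calibrated). These
#' artifacts are shared by all repetitions of the setting.
#'
#' @param setting a [setting_spec()].
#' @param gt_mode ground-truth construction mode, `"ridge_distill"`
#'   (default) or `"draw"`; see [make_ground_truth()].
#' @return list with elements `setting`, `corr` (calibrated
#'   `correlation_structure`) and `truth` (`ground_truth` model).
#' @export
build_setting_artifacts <- function(setting, gt_mode = "ridge_distill") {
  stopifnot(inherits(setting, "setting_spec"))
  base <- build_block_correlation(setting$block_structure)
  corr <- calibrate_collinearity(base, setting$target_median_vif,
                                 bs = setting$block_structure)
  truth <- make_ground_truth(corr, setting, mode = gt_mode,
                             seed = setting$seed)
  list(setting = setting, corr = corr, truth = truth)
}
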