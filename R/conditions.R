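# Classed conditions so callers (and tests) can distinguish failure modes.
# Classes: rf_input_error, rf_geometry_error, rf_detection_error,
# rf_param_error, rf_stats_error, rf_segmentation_error, rf_config_error,
# rf_logic_error.

rf_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "rf_error"),
                      call = sys.call(-1)))
}

rf_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) rf_stop(class, msg, ...)
  invisible(TRUE)
}
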