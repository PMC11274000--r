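# Structured error conditions. Every user-facing failure carries a subclass
# so callers (and the pipeline's per-animal error handling) can dispatch on
# the kind of failure rather than on message text.

ovi_stop <- function(message, class) {
  stop(structure(
    class = c(class, "ovimorph_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# classes used throughout:
#   validation_error          bad arguments / malformed inputs
#   io_error                  unreadable or unwritable files
#   empty_mask_error          operation needs at least one foreground pixel
#   degenerate_geometry_error collinear or otherwise rank-deficient point sets
#   landmark_error            an anatomical feature point could not be located
#   unsupported_posture_error body measures requested for a jump frame
#   calibration_error         non-physical ratio or rank-deficient fit
#   metric_error              undefined evaluation metric (zero denominator)
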