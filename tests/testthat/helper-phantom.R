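# shared helpers for phantom-based tests

lm_matrix <- function(lm) rbind(lm$L_p, lm$L_d0, lm$L_d1)

# landmark error of a recovered transform: moving landmarks mapped by the
# transform vs their ground-truth positions in the fused frame
recovery_errors <- function(pair, transform) {
  rec <- apply_point(transform, lm_matrix(pair$moving$landmarks))
  sqrt(rowSums((rec - pair$fixed$fused_targets)^2))
}

phantom_alignment_config <- function(...) {
  # the phantom's consistent study conditions: physis offset and width both
  # equal to the generated bone width (10 mm)
  alignment_config(d = 10, w = 10, ...)
}
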