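# The desk-scale recovery experiment takes a few minutes, so it is run
# once per session and shared by the acceptance blocks that inspect it.
.recovery_cache <- new.env(parent = emptyenv())

get_recovery_result <- function() {
  if (is.null(.recovery_cache$res)) {
    .recovery_cache$res <- suppressWarnings(run_recovery_experiment(seed = 1L))
  }
  .recovery_cache$res
}
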