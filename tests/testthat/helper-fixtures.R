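# Small shared fixtures. Heavy simulations live inside the test files that
# use them; this helper only builds cheap, deterministic objects.

tiny_config <- function(...) {
  # single-purpose small network: modest grid, standard dynamics otherwise
  sim_config(N = 50, C = 10, ds = 50, ...)
}
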