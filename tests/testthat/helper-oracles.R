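# Shared helpers: seeded draws used by ensemble tests.

.rnorm_seeded <- function(n, sd, seed) {
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}
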