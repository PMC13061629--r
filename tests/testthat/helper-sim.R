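# Scaled-down configurations for fast unit tests. The full demo conditions
# live in test-acceptance.R.

small_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_pirnas = 40L, n_loci = 6L,
             ablated_loci = c("locus01", "locus02"),
             n_transcripts = 60L, n_targets = 8L,
             n_bystander_ablated = 30L, n_ctrl_cleaved = 8L,
             n_bystander_control = 8L, n_seed_only = 4L, n_decoys = 8L,
             smallrna_depth = 2e5, ...)
}
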