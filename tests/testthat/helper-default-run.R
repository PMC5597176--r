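## One shared run of the default eight-sample experiment, computed lazily
## and reused by the acceptance checks that probe different facets of it.
.acc_cache <- new.env(parent = emptyenv())

acceptance_default_run <- function() {
  if (is.null(.acc_cache$run)) {
    cfg <- run_config(seed = 1L)
    sim <- simulate_experiment(cfg)
    res <- analyse_experiment(sim, cfg)
    .acc_cache$run <- list(cfg = cfg, sim = sim, res = res)
  }
  .acc_cache$run
}
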