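# Shared small fixtures, built in code at load time (cheap, deterministic).

fixed_length_params <- function(utr5 = 100, cds = 300, utr3 = 200,
                                n_exons = 1) {
  list(utr5 = c(log(utr5), 0), cds = c(log(cds), 0), utr3 = c(log(utr3), 0),
       intron = c(log(100), 0), n_exons = c(log(n_exons), 0))
}

tiny_annotation <- function(n_genes = 30, seed = 401) {
  simulate_annotation(n_genes, seed = seed)
}

tiny_rbp_spec <- function() {
  tibble::tibble(
    rbp_id = sprintf("G%05d", 1:4),
    trait = c("mRNA", "TE", "both", "null"),
    n_targets = 20L,
    effect_size = 1,
    effect_sign = 1
  )
}

tiny_cohort <- function(n_genes = 200, n_samples = 40, seed = 402, ...) {
  cfg <- sim_config(n_genes, n_samples = n_samples, rbps = tiny_rbp_spec(),
                    seed = seed, ...)
  ann <- tiny_annotation(n_genes, seed = seed + 1)
  list(config = cfg, annotation = ann,
       cohort = simulate_cohort(cfg, ann))
}
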