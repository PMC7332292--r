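# shared fixtures, built in code

# a single dorsal embryo row with fixed metadata
fixture_embryo <- function(genotype = "stau", age = 30, orientation = 0,
                           length_um = 500) {
  data.frame(embryo_id = "fix_001", genotype = genotype, length_um = length_um,
             true_age = age, recorded_age = age,
             orientation_deg = orientation, stringsAsFactors = FALSE)
}

# noiseless logistic profile with midpoint xb (fraction EL)
fixture_logistic <- function(xb = 0.45, w = 0.02, n = 101) {
  x <- seq(0, 1, length.out = n)
  expression_profile(x, 1 / (1 + exp((x - xb) / w)),
                     meta = list(embryo_id = "fix", genotype = "WT",
                                 time_min = 30, orientation_deg = 0,
                                 length_um = 500, gene = "hb"))
}

# boundary table generated through the full generate -> detect pipeline
fixture_boundaries <- function(genotype, n, seed, residual_sd = NULL,
                               noise = noise_spec()) {
  cfg <- generator_config(genotype)
  emb <- sample_embryos(cfg, n, seed)
  spec <- default_trend(genotype, residual_sd = residual_sd)
  do.call(rbind, lapply(seq_len(n), function(i) {
    detect_boundary(generate_hb_profile(emb[i, ], spec, noise,
                                        seed = derive_seed(seed, i)))
  }))
}
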