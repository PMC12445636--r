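# small simulation fixtures shared across test files

flat_trait <- function(name = "y", a = 4, pe = 3, hys = 0, clt = 0, e = 5,
                       mean = 10, cor_a = diag(3), cor_pe = diag(3)) {
  trait_spec(name, mean = mean,
             components = cbind(a = a, pe = pe, hys = hys, clt = clt, e = e)[rep(1, 3), ],
             cor_a = cor_a, cor_pe = cor_pe)
}

small_dataset <- function(seed = 1L, n_founders = 8L, n_matings = c(6L, 6L),
                          progeny = c(2L, 2L), ages = c(8L, 10L, 12L, 13L),
                          trait = flat_trait(), culling = NULL,
                          phenotyped = "nonfounders") {
  cfg <- sim_config(pedigree = list(n_founders = n_founders,
                                    n_matings = n_matings, progeny = progeny),
                    schedule = data.frame(age_month = ages, n_per_month = 1L),
                    traits = list(trait), culling = culling,
                    phenotyped = phenotyped, seed = seed)
  simulate_dataset(cfg)
}

cor3 <- function(r12, r13, r23) {
  matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3L, 3L)
}
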