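# Small scenarios shared across test files.

tiny_scenario <- function(...) {
  defaults <- list(n_features_common = 40, n_specific_a = 15, n_specific_b = 5,
                   ion_multiplicity = 3, tissue_effect_sd = 2, noise_sd = 0.4,
                   dropout_rate = 0.1, shared_ion_rate = 0.05, rng_seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(omics_scenario, args)
}

# Hand-built peptide-ion rows for unit tests.
ion_row <- function(ion, prot, tissue, rep, area) {
  data.frame(ion_id = ion, protein_ids = prot, tissue = tissue,
             replicate = rep, area = area, stringsAsFactors = FALSE)
}

# A 3+3 probe matrix from an intensity matrix and a call matrix.
make_pm <- function(intensity, calls = NULL) {
  if (is.null(calls)) {
    calls <- matrix("P", nrow(intensity), ncol(intensity),
                    dimnames = dimnames(intensity))
  }
  design <- data.frame(sample = colnames(intensity),
                       tissue = rep(c("embryo", "endosperm"), each = 3),
                       replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  probe_matrix(intensity, calls, design)
}

rand_intensity <- function(n, seed = 1, embryo_mu = 8, endosperm_mu = 8,
                           sd = 0.5) {
  set.seed(seed)
  m <- cbind(matrix(rnorm(n * 3, embryo_mu, sd), n),
             matrix(rnorm(n * 3, endosperm_mu, sd), n))
  dimnames(m) <- list(sprintf("p%03d", seq_len(n)),
                      c("emb_1", "emb_2", "emb_3", "end_1", "end_2", "end_3"))
  m
}
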