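# Shared fixtures: small designs and noise-free truths keep most tests fast;
# full-size runs live in the validation/acceptance tests only.

small_design <- function(seed = 1L, n_replicates = 2) {
  experiment_design(n_replicates = n_replicates, seed = seed)
}

noiseless_truth <- function(design, ...) {
  synthetic_truth(design, power_noise_sd = 0, co2c_noise_sd = 0,
                  atom_noise_sd = 0, ...)
}

# Two-group block dissimilarity: d = 0 within, `between` across groups.
block_dissimilarity <- function(n1 = 3, n2 = 3, between = 1) {
  n <- n1 + n2
  d <- matrix(between, n, n)
  d[seq_len(n1), seq_len(n1)] <- 0
  d[n1 + seq_len(n2), n1 + seq_len(n2)] <- 0
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d
}

random_counts <- function(n_taxa, n_samples, seed, lambda = 40) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  m
}
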