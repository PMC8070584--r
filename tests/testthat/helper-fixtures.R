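# Small planted configurations used across test files. Kept deliberately
# smaller than the package defaults so unit tests stay fast; the default
# configuration is exercised in test-acceptance.R.

small_config <- function(seed = 1) {
  truth_config(n_tfs = 6, n_mr = 4, cluster_sizes = c(2, 2), n_genes = 120,
               targets_per_regulon = 20, cross_shared_fraction = 0.3,
               decoy_targets = 4, seed = seed)
}

small_truth <- function(seed = 1) generate_truth(small_config(seed))

# Deterministic toy expression matrix
toy_matrix <- function(n_genes = 10, n_samples = 6, seed = 42) {
  withr_seed <- seed
  set.seed(withr_seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Exhaustive hypergeometric tail: sum the pmf over j >= k using exact
# binomial coefficients. Independent of stats::phyper.
hyper_tail_enum <- function(k, K, n, N) {
  j <- seq(max(k, 0), min(K, n))
  if (length(j) == 0) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Survival records helper
recs <- function(time, event, prefix = "s") {
  data.frame(sample = paste0(prefix, seq_along(time)), time = time,
             event = event, stringsAsFactors = FALSE)
}

random_records <- function(n, censor = 0.2) {
  t_ev <- rexp(n, rate = 1)
  cens <- rbinom(n, 1, censor)
  data.frame(sample = paste0("r", seq_len(n)),
             time = ifelse(cens == 1, t_ev * runif(n), t_ev),
             event = 1 - cens, stringsAsFactors = FALSE)
}
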