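# small scenario and replicate builders shared across test files

tiny_config <- function(prevalence = 0.1, rho = 0.3, n_total = 60L,
                        hypothesis = "alternative", mechanism = "none",
                        dropout_pattern = "equal", n_reps = 1L, seed = 1L,
                        ...) {
  scenario_config(prevalence = prevalence, rho = rho, n_total = n_total,
                  hypothesis = hypothesis, mechanism = mechanism,
                  dropout_pattern = dropout_pattern, n_reps = n_reps,
                  seed = seed, ...)
}

# deterministic small trial for analysis-level tests
small_trial <- function(seed = 42L, ...) {
  cfg <- tiny_config(...)
  set.seed(seed)
  generate_complete_replicate(cfg)
}

# long-format data with independent Bernoulli outcomes (no clustering),
# used to test the sigma_b^2 = 0 reduction to plain logistic regression
unclustered_trial <- function(n = 200L, J = 3L, p = 0.3, seed = 1L) {
  set.seed(seed)
  arm <- rep(c(1L, 0L), each = n %/% 2L)
  data.frame(subject = rep(seq_len(n), each = J),
             arm = rep(arm, each = J),
             visit = rep(seq_len(J), times = n),
             p = p,
             y = rbinom(n * J, 1L, p),
             missing = FALSE)
}
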