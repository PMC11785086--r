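# Small simulation configurations used across the suite. Panel sizes and
# cohort sizes are scaled to keep unit tests fast; the generator's default
# study conditions are exercised in the acceptance suite.

small_config <- function(n = 2000, p = 12, n_blocks = 3, rho = 0.5,
                         seed = 1, ...) {
  sim_config(n_participants = n,
             panel = small_panel(p),
             n_blocks = n_blocks, within_block_rho = rho,
             seed = seed, ...)
}

# Null configuration: no planted effects of any kind (individually
# overridable).
null_config <- function(n = 2000, p = 12, n_blocks = 3, rho = 0.5,
                        seed = 1, beta_prs = 0, gamma_interaction = 0,
                        beta_resilience_main = 0,
                        covariate_effects = numeric(0), missing_rate = 0,
                        ...) {
  small_config(n = n, p = p, n_blocks = n_blocks, rho = rho, seed = seed,
               beta_prs = beta_prs, gamma_interaction = gamma_interaction,
               beta_resilience_main = beta_resilience_main,
               covariate_effects = covariate_effects,
               missing_rate = missing_rate, ...)
}

# Brute-force AUC oracle: pairwise wins over all case/non-case pairs,
# ties counted one half. Quadratic; only for small vectors.
auc_bruteforce <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent effective-tests oracle: correlation from complete data via
# crossprod of standardized columns, eigenvalues via singular values.
nef_bruteforce <- function(mat, threshold = 0.01) {
  z <- scale(mat)
  s <- svd(z, nu = 0, nv = 0)$d^2 / (nrow(mat) - 1)
  s <- c(s, rep(0, ncol(mat) - length(s)))
  max(1, sum(s / ncol(mat) > threshold))
}
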