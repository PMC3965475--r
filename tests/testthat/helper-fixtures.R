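# Shared fixtures, all built in code.

# Three-bin grid where every bin is VLDL; with unit-rate shapes and
# production concentrated in the largest bin this realises the textbook
# cascade c = (5, 2.5, 1.25) from the largest bin down.
toy_grid3 <- function() {
  size_grid(n_bins = 3L, d_min = 27, d_max = 80,
            subclass_bounds = list(v1 = c(27, 38), v2 = c(38, 55),
                                   v3 = c(55, 80)),
            vldl_min = 27, idl_min = 23)
}

# Flat size-dependence: lambda_i = k_lpl + k_hl, a_i = k_att in every bin.
flat_shapes <- function() {
  rate_shapes(f_lpl = function(d) rep(1, length(d)),
              f_hl = function(d) rep(1, length(d)),
              g_att = function(d) rep(1, length(d)))
}

# Production 10 into the largest bin only (tight log-normal at the top bin
# centre), lambda = 1 (all LPL), a = 1.
toy_params_cascade <- function() {
  g <- toy_grid3()
  d_top <- g$diameters[3]
  kinetic_params(f_prod_total = 10, prod_mu = d_top, prod_sigma = 1e-3,
                 k_lpl = 1, k_hl = 0, k_att = 1)
}

test_grid <- function() size_grid(30)

# A representative population draw of canonical parameters.
test_params <- function(i = 1) {
  pars <- sample_kinetic_population(cohort_config(n_subjects = 8,
                                                  seed = 42), 8)
  canonicalize_params(pars[[i]])
}

# Small feature table with a planted signal for SVM tests.
toy_signal_data <- function(n = 300, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("s1", "s2", "noise")))
  y <- rbinom(n, 1, expit(-1 + 1.5 * x[, 1] - x[, 2]))
  data.frame(x, cvd10y = y)
}

# Independent dense linear-system oracle for the steady state:
# solve A c = P where A has (lambda_i + a_i) on the diagonal and
# -lambda_{i+1} on the superdiagonal (inflow from the next-larger bin).
steady_state_dense_oracle <- function(params, grid, shapes = rate_shapes()) {
  d <- grid$diameters
  n <- length(d)
  lam <- params$k_lpl * shapes$f_lpl(d) + params$k_hl * shapes$f_hl(d)
  a <- params$k_att * shapes$g_att(d)
  w <- diff(plnorm(grid$edges, log(params$prod_mu), params$prod_sigma))
  P <- params$f_prod_total * w / sum(w)
  A <- diag(lam + a)
  for (i in seq_len(n - 1)) A[i, i + 1] <- -lam[i + 1]
  drop(solve(A, P))
}

# Brute-force AUC by exhaustive pair counting over all case/control pairs.
auc_bruteforce <- function(scores, y) {
  cs <- scores[y == 1]; ns <- scores[y == 0]
  tot <- 0
  for (a in cs) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ns))
}
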