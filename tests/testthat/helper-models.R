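# small builders shared across test files

sticky_matrix <- function(m, p) {
  M <- matrix(if (m > 1) (1 - p) / (m - 1) else 0, m, m)
  diag(M) <- p
  if (m == 1) M[] <- 1
  M
}

# single-factor deterministic cycle: permutation B, delta D, identity A
deterministic_chain <- function(m = 2, T_steps = 3) {
  P <- diag(m)[, c(2:m, 1), drop = FALSE]
  mp_model(B = P, D = c(1, rep(0, m - 1)), A = diag(m), T_steps = T_steps)
}

# the forced state/outcome path of a deterministic chain
forced_path <- function(m, T_steps) {
  s <- integer(T_steps)
  s[1] <- 1
  for (tau in seq_len(T_steps - 1)) s[tau + 1] <- (s[tau] %% m) + 1
  s
}

# fully uniform single-factor model
uniform_model <- function(m = 3, O = 3, T_steps = 4) {
  mp_model(B = matrix(1 / m, m, m), D = rep(1 / m, m),
           A = matrix(1 / O, O, m), T_steps = T_steps)
}

# mean-field coordinate ascent, written independently of the package's
# dynamics: sequential sweeps of q_tau <- softmax(mean-field log-target)
coordinate_ascent_oracle <- function(model, obs, n_sweeps = 500) {
  lapply(seq_along(model$factors), function(f) {
    fac <- model$factors[[f]]
    L <- log(neuralmp:::factor_likelihood(model, obs, f) + 1e-16)
    lnB <- log(fac$B + 1e-16)
    lnD <- log(fac$D + 1e-16)
    Tn <- model$T
    q <- matrix(1 / fac$m, fac$m, Tn)
    for (it in seq_len(n_sweeps)) {
      for (tau in seq_len(Tn)) {
        tg <- L[, tau] +
          (if (tau == 1) lnD else lnB %*% q[, tau - 1]) +
          (if (tau == Tn) 0 else crossprod(lnB, q[, tau + 1]))
        tg <- tg - max(tg)
        q[, tau] <- exp(tg) / sum(exp(tg))
      }
    }
    q
  })
}

max_pairwise_kl <- function(fits) {
  worst <- 0
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i == j) next
    worst <- max(worst, max(kl_marginals(fits[[i]], fits[[j]])$per_tau))
  }
  worst
}
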