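# Seeded generators for models and observation sequences.

#' Two-factor benchmark model with one observed factor
#'
#' Builds the benchmark generative model used throughout the package's
#' simulations: independent hidden factors with deterministic initial
#' states and "sticky" stochastic transitions, and a single outcome
#' modality that depends on the first factor only.  The second factor is
#' never observed, so beliefs about it should grow more uncertain with
#' distance from the (deterministic) initial state — the regime in which
#' mean-field inference shows its characteristic overconfidence.
#'
#' Each transition-matrix column places `stickiness` on the self
#' transition, spreading the remainder evenly; each likelihood column
#' places `acuity` on the matched outcome.  `stickiness = 1, acuity = 1`
#' gives the fully deterministic limit.
#'
#' @param n_factors number of hidden factors (the first is observed).
#' @param levels integer vector of levels per factor.
#' @param T_steps horizon.
#' @param stickiness probability mass on the self-transition per column.
#' @param acuity probability mass on the dominant outcome per state.
#' @return A validated [mp_model()].
#' @export
benchmark_model <- function(n_factors = 2, levels = c(3, 3), T_steps = 15,
                       stickiness = 0.7, acuity = 0.8) {
  stopifnot(stickiness >= 0, stickiness <= 1, acuity >= 0, acuity <= 1,
            length(levels) == n_factors)
  sticky <- function(m, p) {
    M <- matrix(if (m > 1) (1 - p) / (m - 1) else 0, m, m)
    diag(M) <- p
    if (m == 1) M[] <- 1
    M
  }
  B <- lapply(levels, sticky, p = stickiness)
  D <- lapply(levels, function(m) c(1, rep(0, m - 1)))
  A <- sticky(levels[1], acuity)
  mp_model(B = B, D = D, A = A, A_factor = 1L, T_steps = T_steps)
}

#' Random model with Dirichlet-distributed probability columns
#'
#' Draws every column of every transition and likelihood matrix, and every
#' initial prior, independently from a symmetric Dirichlet distribution.
#' Deterministic given `seed`; the global RNG state is restored afterwards.
#'
#' @param levels integer vector of levels per hidden factor.
#' @param T_steps horizon.
#' @param n_outcomes outcomes per modality; by default one modality per
#'   factor with as many outcomes as levels.  Use `n_outcomes = integer(0)`
#'   together with `A_factor = integer(0)` for a fully unobserved model.
#' @param A_factor factor observed by each modality (default: modality `g`
#'   observes factor `g`).
#' @param concentration symmetric Dirichlet concentration (> 0); large
#'   values give near-uniform columns.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A validated [mp_model()].
#' @export
random_model <- function(levels = c(2), T_steps = 4,
                         n_outcomes = levels, A_factor = seq_along(n_outcomes),
                         concentration = 1, seed = NULL) {
  stopifnot(concentration > 0)
  with_seed(seed, {
    rdir_cols <- function(nr, nc) {
      M <- matrix(stats::rgamma(nr * nc, shape = concentration), nr, nc)
      sweep(M, 2, colSums(M), "/")
    }
    B <- lapply(levels, function(m) rdir_cols(m, m))
    D <- lapply(levels, function(m) drop(rdir_cols(m, 1)))
    A <- mapply(function(o, f) rdir_cols(o, levels[f]),
                n_outcomes, A_factor, SIMPLIFY = FALSE)
    mp_model(B = B, D = D, A = A, A_factor = A_factor, T_steps = T_steps)
  })
}

#' Sample an observation sequence from a model
#'
#' Ancestral sampling: `s_1 ~ D`, `s_{tau+1} ~ B[, s_tau]`, and one outcome
#' per modality per step from `A[, s]`.  The generating states are stored
#' in the returned record.  Deterministic given `seed`.
#'
#' @param object an [mp_model()].
#' @param nsim number of independent sequences; if 1 (default) a single
#'   [mp_obs()] is returned, otherwise a list of them.
#' @param seed integer seed, or `NULL`.
#' @param ... unused.
#' @return An [mp_obs()] with `true_states`, or a list of them.
#' @export
simulate.mp_model <- function(object, nsim = 1, seed = NULL, ...) {
  model <- validate_model(object)
  out <- with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      Tn <- model$T
      nf <- length(model$factors)
      S <- matrix(0L, Tn, nf)
      for (f in seq_len(nf)) {
        fac <- model$factors[[f]]
        S[1, f] <- sample.int(fac$m, 1, prob = fac$D)
        for (tau in seq_len(Tn - 1)) {
          S[tau + 1, f] <- sample.int(fac$m, 1, prob = fac$B[, S[tau, f]])
        }
      }
      G <- length(model$modalities)
      O <- matrix(NA_integer_, Tn, G)
      for (g in seq_len(G)) {
        mod <- model$modalities[[g]]
        for (tau in seq_len(Tn)) {
          O[tau, g] <- sample.int(mod$O, 1, prob = mod$A[, S[tau, mod$factor]])
        }
      }
      mp_obs(O, true_states = S)
    })
  })
  if (nsim == 1) out[[1]] else out
}
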