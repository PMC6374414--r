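# Free-energy functionals of the three schemes.  All values are in nats.
# Factors are mutually independent in this model class, so every functional
# sums over factors.  Logarithms of model probabilities use the numerical
# floor (log(x + 1e-16)) to tolerate structural zeros; entropies and KL
# terms use the 0 log 0 = 0 convention.

#' Variational (mean-field) free energy
#'
#' Energy minus entropy under a fully factorised posterior: the energy
#' takes expectations of the log transition probabilities under outer
#' products of adjacent singleton marginals (the first step uses the
#' initial prior) plus the expected log likelihood of the observed
#' outcomes; the entropy is the sum of the marginal Shannon entropies.
#' Upper-bounds the negative log evidence for any valid mean-field `Q`.
#'
#' @param model an [mp_model()].
#' @param obs an [mp_obs()] or `NULL`; unobserved outcomes contribute zero.
#' @param Q posterior singleton marginals: an `mp_fit`, or a list of
#'   `m x T` probability matrices (one per factor).
#' @return Free energy in nats.
#' @export
variational_free_energy <- function(model, obs, Q) {
  if (is.null(obs)) obs <- empty_obs(model)
  Q <- as_marginals(Q)
  total <- 0
  for (f in seq_along(model$factors)) {
    fac <- model$factors[[f]]
    q <- Q[[f]]
    if (!is.matrix(q) || any(dim(q) != c(fac$m, model$T)))
      stop(sprintf("Q for factor %d must be a %d x %d matrix", f, fac$m, model$T))
    lnL <- flog(factor_likelihood(model, obs, f))
    energy <- sum(q[, 1] * flog(fac$D)) + sum(q * lnL)
    if (model$T > 1) for (tau in 2:model$T) {
      energy <- energy + drop(crossprod(q[, tau], flog(fac$B) %*% q[, tau - 1]))
    }
    ent <- sum(apply(q, 2, entropy))
    total <- total - energy - ent
  }
  total
}

#' Bethe free energy
#'
#' Free energy under the posterior family that retains pairwise
#' interactions between temporally adjacent states.  The energy uses the
#' true pairwise expectations of the log transitions; the Bethe entropy is
#' the sum of singleton entropies minus the mutual information carried by
#' each adjacent pair.  On this acyclic model class it is exact: evaluated
#' at the exact posterior it equals the negative log evidence.
#'
#' @inheritParams variational_free_energy
#' @param Q_pair pairwise marginals: one `m x m x (T-1)` array per factor
#'   (entry `[i, j, tau-1] = Q(s_{tau-1}=i, s_tau=j)`), e.g. from
#'   [pairwise_marginals()] or [pairwise_from_fit()].
#' @param check_tol maximum allowed discrepancy between the pairwise
#'   tables' margins and the singleton marginals; a larger mismatch signals
#'   an invalid member of the Bethe family and is an error.
#' @return Free energy in nats.
#' @export
bethe_free_energy <- function(model, obs, Q, Q_pair, check_tol = 1e-6) {
  if (is.null(obs)) obs <- empty_obs(model)
  Q <- as_marginals(Q)
  total <- 0
  for (f in seq_along(model$factors)) {
    fac <- model$factors[[f]]
    q <- Q[[f]]
    qp <- Q_pair[[f]]
    lnL <- flog(factor_likelihood(model, obs, f))
    energy <- sum(q[, 1] * flog(fac$D)) + sum(q * lnL)
    ent <- sum(apply(q, 2, entropy))
    if (model$T > 1) for (tau in 2:model$T) {
      P <- qp[, , tau - 1]
      err <- max(abs(rowSums(P) - q[, tau - 1]), abs(colSums(P) - q[, tau]))
      if (err > check_tol)
        stop(sprintf("pairwise marginal at (factor %d, pair %d-%d) inconsistent with singletons (max error %.2e)",
                     f, tau - 1, tau, err))
      energy <- energy + sum(P * t(flog(fac$B)))
      prod_q <- outer(q[, tau - 1], q[, tau])
      i <- P > 0
      mi <- sum(P[i] * (log(P[i]) - log(prod_q[i])))
      ent <- ent - mi
    }
    total <- total - energy - ent
  }
  total
}

#' Forward, backward and marginal free energies
#'
#' Per-time-step functionals of the marginal scheme.  The forward free
#' energy at `tau` scores beliefs against an empirical prior propagated
#' from the past marginal through the transition matrix (expectation inside
#' the log); the backward free energy uses the time-reversed transition
#' matrix and the future marginal.  The marginal free energy is their
#' equal mixture, which counts the likelihood and entropy terms once and
#' halves each directed log-message — the landscape whose stationary points
#' are the marginal message passing fixed points.
#'
#' Boundaries: at `tau = 1` the past term is the initial prior (halved in
#' the mixture); at `tau = T` there is no future term.
#'
#' @inheritParams variational_free_energy
#' @return A list with vectors `F_forward`, `F_backward`, `F_marginal`
#'   (length `T`, summed over factors, in nats).
#' @export
marginal_free_energies <- function(model, obs, Q) {
  if (is.null(obs)) obs <- empty_obs(model)
  Q <- as_marginals(Q)
  Tn <- model$T
  FF <- FB <- numeric(Tn)
  for (f in seq_along(model$factors)) {
    fac <- model$factors[[f]]
    q <- Q[[f]]
    Bdag <- reverse_transition(fac$B)
    lnL <- flog(factor_likelihood(model, obs, f))
    for (tau in seq_len(Tn)) {
      H <- entropy(q[, tau])
      past <- if (tau == 1) flog(fac$D) else flog(fac$B %*% q[, tau - 1])
      FF[tau] <- FF[tau] - sum(q[, tau] * (lnL[, tau] + past)) - H
      fut <- if (tau == Tn) 0 else flog(Bdag %*% q[, tau + 1])
      FB[tau] <- FB[tau] - sum(q[, tau] * (lnL[, tau] + fut)) - H
    }
  }
  list(F_forward = FF, F_backward = FB, F_marginal = (FF + FB) / 2)
}

#' Jensen gap of a mean-field posterior
#'
#' `F_variational + ln P(o)`: the slack in the evidence bound, equal to the
#' KL divergence from the mean-field posterior to the true joint posterior.
#' Non-negative for every valid `Q`.
#'
#' @inheritParams variational_free_energy
#' @return Gap in nats (>= 0 up to numerical error).
#' @export
jensen_gap <- function(model, obs, Q) {
  variational_free_energy(model, obs, Q) + log_evidence(model, obs)
}

#' Empirical check of the forward-plus-backward free-energy inequality
#'
#' Computes, per time step, the slack `F_F(tau) + F_B(tau) - RHS(tau)`
#' where the right-hand side is the negative expected log of the exact
#' leave-one-out predictive `P(o_tau, s_tau | o_{\\tau})` minus the belief
#' entropy.  The predictive is computed by brute-force enumeration only
#' (size-guarded), keeping the check honest.  The inequality (slack >= 0)
#' is conjectured, not proven: negative slack is reported, never clipped.
#'
#' @inheritParams variational_free_energy
#' @return Numeric vector of per-step slacks (nats), summed over factors.
#' @export
conjecture_slack <- function(model, obs, Q) {
  if (is.null(obs)) obs <- empty_obs(model)
  Q <- as_marginals(Q)
  Tn <- model$T
  fe <- marginal_free_energies(model, obs, Q)
  lhs <- fe$F_forward + fe$F_backward
  rhs <- numeric(Tn)
  bf_full <- brute_force_posterior(model, obs)
  for (tau in seq_len(Tn)) {
    obs_loo <- obs
    obs_loo$outcomes[tau, ] <- NA_integer_
    bf_loo <- brute_force_posterior(model, obs_loo)
    for (f in seq_along(model$factors)) {
      q <- Q[[f]]
      # P(o_tau, s_tau | o_{\tau}) = P(all obs, s_tau) / P(obs without tau)
      ln_pred <- flog(bf_full$marginals[[f]][, tau]) + bf_full$log_evidence -
        bf_loo$log_evidence
      rhs[tau] <- rhs[tau] - sum(q[, tau] * ln_pred) - entropy(q[, tau])
    }
  }
  lhs - rhs
}

#' Full free-energy report for a set of beliefs
#'
#' Evaluates every functional the package defines for one belief state:
#' variational and Bethe free energies, the per-step forward/backward/
#' marginal free energies, the log evidence, the Jensen gap, and (for
#' models small enough to enumerate) the per-step slack of the
#' forward-plus-backward inequality.
#'
#' @inheritParams bethe_free_energy
#' @param conjecture if `TRUE` and the model is small enough, include the
#'   enumeration-based slack check.
#' @return An object of class `mp_fe_report`.
#' @export
free_energy_report <- function(model, obs, Q, Q_pair = NULL,
                               conjecture = FALSE) {
  if (is.null(obs)) obs <- empty_obs(model)
  Q <- as_marginals(Q)
  lev <- log_evidence(model, obs)
  Fv <- variational_free_energy(model, obs, Q)
  mfe <- marginal_free_energies(model, obs, Q)
  rep <- list(
    F_variational = Fv,
    F_bethe = if (is.null(Q_pair)) NA_real_
              else bethe_free_energy(model, obs, Q, Q_pair),
    F_forward = mfe$F_forward, F_backward = mfe$F_backward,
    F_marginal = mfe$F_marginal,
    ln_evidence = lev,
    jensen_gap = Fv + lev,
    conjecture_slack = if (conjecture) conjecture_slack(model, obs, Q) else NULL)
  class(rep) <- "mp_fe_report"
  rep
}

#' @export
print.mp_fe_report <- function(x, ...) {
  cat("Free-energy report (nats)\n")
  cat("  ln evidence     :", format(x$ln_evidence, digits = 6), "\n")
  cat("  F variational   :", format(x$F_variational, digits = 6),
      " (Jensen gap ", format(x$jensen_gap, digits = 4), ")\n", sep = "")
  if (!is.na(x$F_bethe))
    cat("  F Bethe         :", format(x$F_bethe, digits = 6), "\n")
  cat("  sum F marginal  :", format(sum(x$F_marginal), digits = 6), "\n")
  if (!is.null(x$conjecture_slack))
    cat("  min slack (F_F + F_B bound):",
        format(min(x$conjecture_slack), digits = 4), "\n")
  invisible(x)
}
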