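# Scheduled sum-product belief propagation on the HMM chain (the exact
# reference scheme), plus a brute-force enumeration oracle.
#
# Because every outcome modality observes exactly one hidden factor, the
# posterior factorises over factors and all computations here run per
# factor.  Messages are normalised at every step for numerical stability,
# with the forward normalisers retained: their log-sum is the log evidence
# (the standard filtering identity).

#' Forward messages of scheduled belief propagation
#'
#' Computes, for one hidden factor, the forward message into every time
#' step: the normalised predictive distribution
#' `mu_fwd(tau) = B (mu_fwd(tau-1) * mu_A(tau-1)) / c_tau`, with
#' `mu_fwd(1) = D`.  The retained per-step log-normalisers sum to the log
#' evidence contributed by this factor's observations.
#'
#' @param model an [mp_model()].
#' @param obs an [mp_obs()]; `NA` entries are treated as uninformative.
#' @param factor index of the hidden factor.
#' @return A list with `mu_fwd` (`m x T` matrix of normalised messages) and
#'   `log_norm` (length-`T` vector of log-normalisers).
#' @export
forward_messages <- function(model, obs = NULL, factor = 1L) {
  if (is.null(obs)) obs <- empty_obs(model)
  obs <- validate_obs(model, obs)
  fac <- model$factors[[factor]]
  Tn <- model$T
  L <- factor_likelihood(model, obs, factor)
  mu <- matrix(0, fac$m, Tn)
  logc <- numeric(Tn)
  mu[, 1] <- fac$D
  for (tau in seq_len(Tn)) {
    post <- mu[, tau] * L[, tau]
    c_tau <- sum(post)
    if (c_tau == 0)
      stop(sprintf("impossible observation sequence: zero forward mass at time step %d (factor %d)",
                   tau, factor))
    logc[tau] <- log(c_tau)
    if (tau < Tn) mu[, tau + 1] <- fac$B %*% (post / c_tau)
  }
  list(mu_fwd = mu, log_norm = logc)
}

#' Backward messages of scheduled belief propagation
#'
#' Mirror of [forward_messages()]: `mu_bwd(T)` is the all-ones vector (no
#' future evidence) and `mu_bwd(tau) = t(B) (mu_bwd(tau+1) * mu_A(tau+1))`,
#' normalised at every step.  Note that the plain transpose is used here
#' (sum-product form); the reversed transition matrix of
#' [reverse_transition()] belongs to the marginal scheme only.
#'
#' @inheritParams forward_messages
#' @return An `m x T` matrix of normalised backward messages.
#' @export
backward_messages <- function(model, obs = NULL, factor = 1L) {
  if (is.null(obs)) obs <- empty_obs(model)
  obs <- validate_obs(model, obs)
  fac <- model$factors[[factor]]
  Tn <- model$T
  L <- factor_likelihood(model, obs, factor)
  mu <- matrix(0, fac$m, Tn)
  mu[, Tn] <- rep(1, fac$m)
  if (Tn > 1) for (tau in (Tn - 1):1) {
    v <- crossprod(fac$B, mu[, tau + 1] * L[, tau + 1])
    s <- sum(v)
    if (s == 0)
      stop(sprintf("impossible observation sequence: zero backward mass at time step %d (factor %d)",
                   tau, factor))
    mu[, tau] <- v / s
  }
  mu
}

#' Exact posterior marginals by scheduled sum-product message passing
#'
#' One forward sweep and one backward sweep per factor (sufficient on this
#' acyclic chain), then the normalised triple product of likelihood, forward
#' and backward messages at every time step.  Exact for this model class.
#'
#' @inheritParams forward_messages
#' @param pairwise if `TRUE`, also return the pairwise posterior marginals
#'   of temporally adjacent states (see [pairwise_marginals()]).
#' @return An object of class `mp_marginals`: a list of `m_f x T` matrices
#'   of posterior probabilities, one per factor, with attributes
#'   `log_evidence` (nats) and, if requested, `pairwise`.
#' @export
exact_marginals <- function(model, obs = NULL, pairwise = FALSE) {
  if (is.null(obs)) obs <- empty_obs(model)
  Q <- vector("list", length(model$factors))
  qp <- vector("list", length(model$factors))
  logev <- 0
  for (f in seq_along(model$factors)) {
    fwd <- forward_messages(model, obs, f)
    bwd <- backward_messages(model, obs, f)
    L <- factor_likelihood(model, obs, f)
    raw <- L * fwd$mu_fwd * bwd
    Q[[f]] <- sweep(raw, 2, colSums(raw), "/")
    logev <- logev + sum(fwd$log_norm)
    if (pairwise) qp[[f]] <- .pairwise_from_messages(model, f, L, fwd$mu_fwd, bwd)
  }
  structure(Q, class = "mp_marginals", log_evidence = logev,
            pairwise = if (pairwise) qp else NULL)
}

# q_pair[i, j, tau-1] = Q(s_{tau-1} = i, s_tau = j | all observations)
.pairwise_from_messages <- function(model, f, L, mu_fwd, mu_bwd) {
  fac <- model$factors[[f]]
  Tn <- model$T
  if (Tn < 2) return(array(0, c(fac$m, fac$m, 0)))
  qp <- array(0, c(fac$m, fac$m, Tn - 1))
  for (tau in 2:Tn) {
    left <- mu_fwd[, tau - 1] * L[, tau - 1]      # filtered past, unnormalised
    right <- L[, tau] * mu_bwd[, tau]             # evidence from tau onwards
    P <- outer(left, right) * t(fac$B)            # [i, j] with B[j, i]
    qp[, , tau - 1] <- P / sum(P)
  }
  qp
}

#' Pairwise posterior marginals of adjacent states
#'
#' Joint posterior tables `Q(s_{tau-1}, s_tau)` for every adjacent pair,
#' built from the forward filtered distribution, the transition matrix, and
#' the backward evidence.  Marginalising either argument recovers the
#' corresponding singleton marginal exactly; these tables are the pairwise
#' component of the Bethe posterior family.
#'
#' @inheritParams forward_messages
#' @return An `m x m x (T-1)` array per factor (as a list), entry
#'   `[i, j, tau-1]` holding `Q(s_{tau-1} = i, s_tau = j)`.
#' @export
pairwise_marginals <- function(model, obs = NULL) {
  if (is.null(obs)) obs <- empty_obs(model)
  attr(exact_marginals(model, obs, pairwise = TRUE), "pairwise")
}

#' Log evidence of an observation sequence
#'
#' `ln P(o)` in nats, summed over the per-step forward normalisers of every
#' factor (factors without observing modalities contribute zero).  An
#' impossible sequence (the model assigns it probability zero) is reported
#' as `-Inf`.
#'
#' @inheritParams forward_messages
#' @return A scalar, or `-Inf` for an impossible sequence.
#' @export
log_evidence <- function(model, obs = NULL) {
  if (is.null(obs)) obs <- empty_obs(model)
  tryCatch(attr(exact_marginals(model, obs), "log_evidence"),
           error = function(e) {
             if (grepl("impossible observation sequence", conditionMessage(e)))
               -Inf else stop(e)
           })
}

#' Brute-force posterior by enumeration of state sequences
#'
#' The independent oracle: enumerates every state sequence of each factor,
#' scores its joint probability with the observations directly from the
#' model definition, and normalises.  Exponential in the horizon, guarded at
#' `prod(m_f^T) <= 1e7`; use [exact_marginals()] beyond that.
#'
#' @inheritParams forward_messages
#' @return A list with `marginals` (list of `m x T` matrices), `pairwise`
#'   (list of `m x m x (T-1)` arrays), and `log_evidence` (nats).
#' @export
brute_force_posterior <- function(model, obs = NULL) {
  if (is.null(obs)) obs <- empty_obs(model)
  obs <- validate_obs(model, obs)
  sz <- prod(vapply(model$factors, function(f) as.numeric(f$m)^model$T, 0))
  if (sz > 1e7)
    stop("state space too large to enumerate (> 1e7 sequences): use exact_marginals() instead")
  Tn <- model$T
  marg <- vector("list", length(model$factors))
  pair <- vector("list", length(model$factors))
  logev <- 0
  for (f in seq_along(model$factors)) {
    fac <- model$factors[[f]]
    L <- factor_likelihood(model, obs, f)
    seqs <- as.matrix(expand.grid(rep(list(seq_len(fac$m)), Tn)))
    w <- fac$D[seqs[, 1]] * L[seqs[, 1], 1]
    if (Tn > 1) for (tau in 2:Tn) {
      w <- w * fac$B[cbind(seqs[, tau], seqs[, tau - 1])] * L[seqs[, tau], tau]
    }
    Z <- sum(w)
    if (Z == 0)
      stop(sprintf("impossible observation sequence (factor %d)", f))
    logev <- logev + log(Z)
    w <- w / Z
    marg[[f]] <- vapply(seq_len(Tn), function(tau)
      vapply(seq_len(fac$m), function(i) sum(w[seqs[, tau] == i]), 0),
      numeric(fac$m))
    marg[[f]] <- matrix(marg[[f]], fac$m, Tn)
    qp <- array(0, c(fac$m, fac$m, max(0, Tn - 1)))
    if (Tn > 1) for (tau in 2:Tn) {
      for (i in seq_len(fac$m)) for (j in seq_len(fac$m)) {
        qp[i, j, tau - 1] <- sum(w[seqs[, tau - 1] == i & seqs[, tau] == j])
      }
    }
    pair[[f]] <- qp
  }
  list(marginals = structure(marg, class = "mp_marginals", log_evidence = logev),
       pairwise = pair, log_evidence = logev)
}
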