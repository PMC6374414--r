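# The three message passing schemes as continuous-time gradient descents
# with neuronal semantics: membrane potentials v (log-space belief
# parameters), firing rates s = softmax(v) (posterior expectations) and
# prediction-error units eps = gauge-fixed log-target - v.  The dynamics
# v' = eps descend the scheme's free-energy landscape; all time steps and
# factors are updated in parallel (Jacobi style) by explicit Euler.

#' Integration settings for the neuronal dynamics
#'
#' @param step_size explicit-Euler step (integration time units).
#' @param max_time maximum integration time before the run is flagged as
#'   non-converged.
#' @param tol convergence tolerance on the largest absolute prediction
#'   error.
#' @param record_every record a belief snapshot every this many Euler steps.
#' @param alpha corrective exponent of the marginal scheme's messages
#'   (default 1/2); the log of the within-expectation message is multiplied
#'   by `alpha`, attenuating its precision.  `alpha = 1` recovers the
#'   unattenuated within-log-expectation variant.
#' @param msg_tau time constant of the belief-propagation message
#'   populations.  The default (`msg_tau = step_size`) solves the messages
#'   algebraically at every Euler step — the adiabatic limit in which the
#'   fast message populations are enslaved by the marginals.  Larger values
#'   relax the messages as an explicit fast process with rate
#'   `step_size / msg_tau` per step (neural-mass-style experiments).
#' @return A list of class `mp_control`.
#' @export
mp_control <- function(step_size = 0.1, max_time = 200, tol = 1e-6,
                       record_every = 10L, alpha = 0.5,
                       msg_tau = step_size) {
  stopifnot(step_size > 0, max_time > 0, tol > 0, record_every >= 1,
            alpha >= 0, msg_tau > 0)
  structure(list(step_size = step_size, max_time = max_time, tol = tol,
                 record_every = as.integer(record_every), alpha = alpha,
                 msg_tau = msg_tau),
            class = "mp_control")
}

# per-factor constants reused at every integration step
.factor_env <- function(model, obs, f) {
  fac <- model$factors[[f]]
  L <- factor_likelihood(model, obs, f)
  list(m = fac$m, B = fac$B, Bdag = reverse_transition(fac$B),
       lnB = flog(fac$B), lnD = flog(fac$D), D = fac$D,
       L = L, lnL = flog(L))
}

# ---- log-target maps (vectorised over tau; column tau of the returned
# matrix is the log of the unnormalised target posterior at that step) ----

vmp_target <- function(fe, S, Tn) {
  past <- if (Tn > 1) cbind(fe$lnD, fe$lnB %*% S[, -Tn, drop = FALSE])
          else matrix(fe$lnD, fe$m, 1)
  fut <- if (Tn > 1) cbind(crossprod(fe$lnB, S[, -1, drop = FALSE]), 0)
         else matrix(0, fe$m, 1)
  fe$lnL + past + fut
}

mmp_target <- function(fe, S, Tn, alpha) {
  past <- if (Tn > 1)
    cbind(alpha * fe$lnD, alpha * flog(fe$B %*% S[, -Tn, drop = FALSE]))
  else matrix(alpha * fe$lnD, fe$m, 1)
  fut <- if (Tn > 1)
    cbind(alpha * flog(fe$Bdag %*% S[, -1, drop = FALSE]), 0)
  else matrix(0, fe$m, 1)
  fe$lnL + past + fut
}

# Algebraic message construction.  `Mf` / `Mb` hold the incoming forward /
# backward message at every edge (time step).  The outgoing message of an
# edge is its marginal with the incoming opposite-direction message divided
# out (the descending inhibitory loop) and the ascending likelihood message
# divided out (the "starred" inhibitory connection); crossing the
# transition factor re-multiplies the likelihood and applies B (forward) or
# t(B) (backward).  Net effect: the incoming forward message at tau is
# B (s_{tau-1} / Mb_{tau-1}), and symmetrically backward.  The lesioned
# variant cuts the starred subtraction from the forward out-message, so the
# ascending message crosses the factor twice and is overcounted in the
# marginal downstream.
bp_message_targets <- function(fe, S, Mf, Mb, Tn, lesion) {
  ratio_cols <- function(num, den) {
    R <- exp(flog(num) - flog(den))
    sweep(R, 2, colSums(R), "/")
  }
  Mf_t <- matrix(fe$D, fe$m, Tn)
  if (Tn > 1) {
    out_f <- ratio_cols(if (lesion) S * fe$L else S, Mb)
    fwd <- fe$B %*% out_f[, -Tn, drop = FALSE]
    Mf_t[, -1] <- sweep(fwd, 2, colSums(fwd), "/")
  }
  Mb_t <- matrix(1 / fe$m, fe$m, Tn)
  if (Tn > 1) {
    out_b <- ratio_cols(S, Mf)
    bwd <- crossprod(fe$B, out_b[, -1, drop = FALSE])
    Mb_t[, -Tn] <- sweep(bwd, 2, colSums(bwd), "/")
  }
  list(Mf = Mf_t, Mb = Mb_t)
}

bp_target <- function(fe, Mf, Mb, Tn) {
  fe$lnL + flog(Mf) + flog(Mb)
}

#' Infer hidden states of a discrete HMM
#'
#' The central fitting function.  Runs one of three neuronal message
#' passing schemes as a continuous-time gradient descent (or its discrete
#' fixed-point iteration), or scheduled sum-product belief propagation
#' (`scheme = "exact"`), and returns the posterior beliefs over hidden
#' states at every time step.
#'
#' * `"BP"` — belief propagation with message populations coupled to the
#'   marginals: messages are reconstructed from the current beliefs
#'   (dividing out the likelihood message and the companion message) and
#'   relax on a fast time scale, while the marginal populations descend the
#'   Bethe free-energy landscape.  Exact at convergence on this model
#'   class.
#' * `"VMP"` — variational message passing: messages are expectations of
#'   log-transition probabilities under the neighbouring marginals
#'   (mean-field coordinate dynamics).
#' * `"MMP"` — marginal message passing: messages are logs of expectations
#'   (as in belief propagation) of the transition matrix and its
#'   time-reversal under the neighbouring marginals, attenuated by the
#'   corrective exponent `alpha` (default 1/2) to curb overconfidence.
#' * `"exact"` — scheduled sum-product sweeps, no dynamics.
#'
#' The dynamics evolve membrane potentials `v' = eps` with prediction error
#' `eps = target - v` (target mean-centred per time step, fixing the
#' softmax gauge), beliefs `s = softmax(v)`, explicit Euler with the given
#' step size, all time steps and factors updated in parallel.  Integration
#' stops when the largest `|eps|` falls below `control$tol`;
#' non-convergence at `max_time` is flagged in the returned object, not an
#' error.  The run is fully deterministic given its inputs.
#'
#' @param model an [mp_model()].
#' @param obs an [mp_obs()], or `NULL` for a fully unobserved sequence.
#' @param scheme `"BP"`, `"VMP"`, `"MMP"` or `"exact"`.
#' @param control an [mp_control()] list of integration settings.
#' @param init `NULL` for uniform initial beliefs (`v = 0`), or a previous
#'   `mp_fit` to warm-start from (beliefs persist, as when successive
#'   outcomes arrive within a trial).
#' @param lesion if `TRUE` (BP only), cut the inhibitory connection that
#'   subtracts the ascending likelihood message from the forward message,
#'   so the ascending message is counted twice ("circular inference").
#' @param engine `"ode"` for the Euler-integrated gradient descent,
#'   `"map"` for direct (parallel) fixed-point iteration of the target map.
#'   Both converge to the same beliefs; the map is faster, the ode is the
#'   neuronal process model.
#' @return An object of class `mp_fit`; see Details.  Key elements:
#'   `marginals` (list of `m x T` belief matrices, one per factor), `v`,
#'   `eps`, `trajectory` (recorded belief snapshots and the cumulative L1
#'   path length of belief updating), `converged`, `n_steps`.
#' @examples
#' mod <- benchmark_model(T_steps = 6)
#' obs <- simulate(mod, seed = 1)
#' fit <- mp_infer(mod, obs, scheme = "MMP")
#' coef(fit)[[1]]
#' @export
mp_infer <- function(model, obs = NULL, scheme = c("BP", "VMP", "MMP", "exact"),
                     control = mp_control(), init = NULL, lesion = FALSE,
                     engine = c("ode", "map")) {
  scheme <- match.arg(scheme)
  engine <- match.arg(engine)
  if (is.null(obs)) obs <- empty_obs(model)
  obs <- validate_obs(model, obs)
  if (lesion && scheme != "BP")
    stop("the overcounting lesion is defined only for the BP circuit")
  if (scheme == "exact") {
    Q <- exact_marginals(model, obs, pairwise = TRUE)
    fit <- structure(
      list(model = model, obs = obs, scheme = scheme, control = control,
           engine = "scheduled", lesion = FALSE,
           marginals = structure(unclass(Q), class = "mp_marginals"),
           pairwise = attr(Q, "pairwise"),
           log_evidence = attr(Q, "log_evidence"),
           v = lapply(unclass(Q), function(M) sweep(flog(M), 2, colMeans(flog(M)))),
           eps = lapply(unclass(Q), function(M) M * 0),
           trajectory = NULL, converged = TRUE, n_steps = 0L),
      class = "mp_fit")
    return(fit)
  }

  Tn <- model$T
  nf <- length(model$factors)
  fes <- lapply(seq_len(nf), function(f) .factor_env(model, obs, f))
  dt <- control$step_size
  lam <- min(1, dt / control$msg_tau)
  n_max <- as.integer(ceiling(control$max_time / dt))

  # state: membrane potentials, firing rates, message populations
  V <- lapply(fes, function(fe) matrix(0, fe$m, Tn))
  if (!is.null(init)) {
    vi <- if (inherits(init, "mp_fit")) init$v else init
    stopifnot(length(vi) == nf)
    V <- lapply(seq_len(nf), function(f)
      sweep(vi[[f]], 2, colMeans(vi[[f]])))
  }
  S <- lapply(V, softmax)
  Mf <- Mb <- NULL
  if (scheme == "BP") {
    Mf <- lapply(fes, function(fe) {
      M <- matrix(1 / fe$m, fe$m, Tn); M[, 1] <- fe$D; M
    })
    Mb <- lapply(fes, function(fe) matrix(1 / fe$m, fe$m, Tn))
    if (!is.null(init) && inherits(init, "mp_fit") &&
        identical(init$scheme, "BP") && !is.null(init$msg_fwd)) {
      Mf <- init$msg_fwd
      Mb <- init$msg_bwd
    }
  }

  rec_times <- 0
  rec_s <- list(S)
  path <- numeric(n_max)
  eps <- V
  converged <- FALSE
  step <- 0L
  while (step < n_max) {
    step <- step + 1L
    max_eps <- 0
    dpath <- 0
    for (f in seq_len(nf)) {
      fe <- fes[[f]]
      if (scheme == "BP") {
        mt <- bp_message_targets(fe, S[[f]], Mf[[f]], Mb[[f]], Tn, lesion)
        Mf[[f]] <- Mf[[f]] + lam * (mt$Mf - Mf[[f]])
        Mb[[f]] <- Mb[[f]] + lam * (mt$Mb - Mb[[f]])
        tg <- bp_target(fe, Mf[[f]], Mb[[f]], Tn)
      } else if (scheme == "VMP") {
        tg <- vmp_target(fe, S[[f]], Tn)
      } else {
        tg <- mmp_target(fe, S[[f]], Tn, control$alpha)
      }
      tg <- sweep(tg, 2, colMeans(tg))
      e <- tg - V[[f]]
      eps[[f]] <- e
      max_eps <- max(max_eps, max(abs(e)))
      Vn <- if (engine == "ode") V[[f]] + dt * e else tg
      Sn <- softmax(Vn)
      dpath <- dpath + sum(abs(Sn - S[[f]]))
      V[[f]] <- Vn
      S[[f]] <- Sn
    }
    path[step] <- dpath
    if (step %% control$record_every == 0L) {
      rec_times <- c(rec_times, step * dt)
      rec_s[[length(rec_s) + 1L]] <- S
    }
    if (max_eps < control$tol) { converged <- TRUE; break }
  }
  if (rec_times[length(rec_times)] < step * dt) {
    rec_times <- c(rec_times, step * dt)
    rec_s[[length(rec_s) + 1L]] <- S
  }

  structure(
    list(model = model, obs = obs, scheme = scheme, control = control,
         engine = engine, lesion = lesion,
         marginals = structure(S, class = "mp_marginals"),
         v = V, eps = eps, msg_fwd = Mf, msg_bwd = Mb,
         trajectory = list(time = rec_times, s = rec_s,
                           path_length = cumsum(path[seq_len(step)]),
                           step_time = seq_len(step) * dt),
         converged = converged, n_steps = step),
    class = "mp_fit")
}

#' Pairwise marginals implied by a converged BP fit
#'
#' Reconstructs the adjacent-pair posterior tables from the message
#' populations of a belief-propagation fit (or returns the exact tables for
#' `scheme = "exact"`), in the same form as [pairwise_marginals()].
#'
#' @param fit an `mp_fit` with `scheme` `"BP"` or `"exact"`.
#' @return A list (one per factor) of `m x m x (T-1)` arrays.
#' @export
pairwise_from_fit <- function(fit) {
  if (identical(fit$scheme, "exact")) return(fit$pairwise)
  if (!identical(fit$scheme, "BP"))
    stop("pairwise marginals are defined for BP or exact fits only")
  model <- fit$model
  lapply(seq_along(model$factors), function(f) {
    L <- factor_likelihood(model, fit$obs, f)
    .pairwise_from_messages(model, f, L, fit$msg_fwd[[f]], fit$msg_bwd[[f]])
  })
}
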