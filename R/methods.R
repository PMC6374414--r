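# S3 methods for mp_fit and mp_marginals

#' @export
print.mp_fit <- function(x, ...) {
  cat("Message passing fit: scheme =", x$scheme,
      if (x$lesion) "(lesioned)", "\n")
  cat("  factors:", length(x$model$factors), " horizon T =", x$model$T, "\n")
  if (!identical(x$scheme, "exact")) {
    cat("  engine =", x$engine, ", steps =", x$n_steps,
        ", converged =", x$converged, "\n")
  } else {
    cat("  log evidence =", format(x$log_evidence, digits = 6), "nats\n")
  }
  invisible(x)
}

#' @export
summary.mp_fit <- function(object, ...) {
  H <- entropy_profile(object$marginals)
  out <- list(scheme = object$scheme, converged = object$converged,
              n_steps = object$n_steps, entropy = H,
              map_states = lapply(object$marginals, function(M)
                apply(M, 2, which.max)))
  class(out) <- "summary.mp_fit"
  out
}

#' @export
print.summary.mp_fit <- function(x, ...) {
  cat("Scheme:", x$scheme, " converged:", x$converged,
      " steps:", x$n_steps, "\n")
  cat("Posterior entropy (nats) per factor x time step:\n")
  print(round(x$entropy, 3))
  cat("MAP state sequence per factor:\n")
  for (f in seq_along(x$map_states))
    cat("  factor", f, ":", x$map_states[[f]], "\n")
  invisible(x)
}

#' Posterior marginals of a fit
#'
#' @param object an `mp_fit`.
#' @param ... unused.
#' @return A list of `m x T` matrices of posterior probabilities (class
#'   `mp_marginals`), one per hidden factor.
#' @export
coef.mp_fit <- function(object, ...) object$marginals

#' @export
fitted.mp_fit <- function(object, ...) object$marginals

#' Prediction errors of a fit
#'
#' The final prediction-error unit activities: the gauge-fixed difference
#' between the log-target and the membrane potentials.  At a fixed point
#' these vanish (up to the softmax's additive gauge).
#'
#' @param object an `mp_fit`.
#' @param ... unused.
#' @return A list of `m x T` matrices, one per factor.
#' @export
residuals.mp_fit <- function(object, ...) object$eps

#' Log evidence (or its free-energy bound) of a fit
#'
#' For `scheme = "exact"` this is `ln P(o)`.  For `"VMP"` it is the negative
#' variational free energy (an evidence lower bound), for `"BP"` the
#' negative Bethe free energy evaluated with the fit's pairwise marginals
#' (exact at convergence on this model class).  For `"MMP"` the negative
#' sum of per-step marginal free energies is returned; this is a local
#' objective, not a global evidence bound.
#'
#' @param object an `mp_fit`.
#' @param ... unused.
#' @export
logLik.mp_fit <- function(object, ...) {
  val <- switch(object$scheme,
    exact = object$log_evidence,
    VMP = -variational_free_energy(object$model, object$obs, object$marginals),
    BP = -bethe_free_energy(object$model, object$obs, object$marginals,
                            pairwise_from_fit(object)),
    MMP = -sum(marginal_free_energies(object$model, object$obs,
                                      object$marginals)$F_marginal))
  structure(val, df = NA_integer_, class = "logLik")
}

#' Plot belief updating
#'
#' For a dynamic fit, plots the time course of every belief (the sufficient
#' statistics of each posterior marginal) over integration time — one line
#' per factor, time step and level.  For an exact fit, plots the final
#' marginals as grey-scale images per factor (darkest = probability one).
#'
#' @param x an `mp_fit`.
#' @param which `"trajectory"` or `"marginals"`.
#' @param ... passed to [graphics::matplot()] / [graphics::image()].
#' @export
plot.mp_fit <- function(x, which = c("trajectory", "marginals"), ...) {
  which <- match.arg(which)
  if (which == "trajectory" && !is.null(x$trajectory)) {
    tr <- x$trajectory
    flat <- t(vapply(tr$s, function(snap) unlist(snap),
                     numeric(length(unlist(tr$s[[1]])))))
    graphics::matplot(tr$time, flat, type = "l", lty = 1,
                      xlab = "integration time", ylab = "belief",
                      main = paste0(x$scheme, ": belief updating"), ...)
  } else {
    nf <- length(x$marginals)
    op <- graphics::par(mfrow = c(nf, 1))
    on.exit(graphics::par(op))
    for (f in seq_len(nf)) {
      M <- x$marginals[[f]]
      graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M),
                      col = grey(seq(1, 0, length.out = 64)),
                      xlab = "time step", ylab = "level",
                      main = paste0(x$scheme, ": factor ", f), ...)
    }
  }
  invisible(x)
}

#' @importFrom grDevices grey
#' @importFrom stats coef fitted residuals simulate
NULL
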