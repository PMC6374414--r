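#' Construct a discrete hidden Markov model
#'
#' Defines the generative model used throughout the package: one or more
#' independent hidden factors, each a first-order Markov chain over a finite
#' number of levels, and one or more outcome modalities, each generated from a
#' single hidden factor at every time step.
#'
#' All probability matrices follow the column-stochastic convention: the
#' column indexes the conditioning variable.  `B[[f]][i, j]` is the
#' probability that factor `f` moves to level `i` at time `tau + 1` given
#' level `j` at time `tau`; `A[[g]][i, j]` is the probability of outcome `i`
#' of modality `g` given level `j` of its target factor; `D[[f]][i]` is the
#' prior probability that factor `f` starts in level `i`.  Time is indexed
#' `1..T` (closed).
#'
#' @param B transition matrix (column-stochastic), or a list of one matrix per
#'   hidden factor.
#' @param D initial-state prior vector, or a list of one vector per factor.
#' @param A likelihood matrix (outcomes x levels, column-stochastic), or a
#'   list of one matrix per outcome modality.  May be `NULL` for a model with
#'   no modalities (a bare Markov chain).
#' @param A_factor integer vector assigning each modality to the hidden
#'   factor it observes (defaults to factor 1 for every modality).
#' @param T_steps horizon: number of time steps represented.
#' @param validate if `TRUE` (default) the model is checked by
#'   [validate_model()] before being returned.
#'
#' @return An object of class `mp_model`: a list with elements `factors`
#'   (each with `m`, `B`, `D`), `modalities` (each with `O`, `A`, `factor`)
#'   and `T`.
#'
#' @examples
#' m <- mp_model(B = diag(2), D = c(1, 0), A = diag(2), T_steps = 3)
#' print(m)
#' @seealso [benchmark_model()], [random_model()], [mp_infer()]
#' @export
mp_model <- function(B, D, A = NULL, A_factor = NULL, T_steps = 1,
                     validate = TRUE) {
  if (is.matrix(B)) B <- list(B)
  if (is.numeric(D) && !is.list(D)) D <- list(D)
  if (!is.null(A) && is.matrix(A)) A <- list(A)
  if (is.null(A)) A <- list()
  if (is.null(A_factor)) A_factor <- rep(1L, length(A))
  if (length(A_factor) != length(A))
    stop("`A_factor` must assign one factor index per modality")
  factors <- mapply(function(b, d) {
    list(m = length(d), B = unname(as.matrix(b)), D = unname(as.numeric(d)))
  }, B, D, SIMPLIFY = FALSE)
  modalities <- mapply(function(a, f) {
    list(O = nrow(a), A = unname(as.matrix(a)), factor = as.integer(f))
  }, A, A_factor, SIMPLIFY = FALSE)
  model <- structure(
    list(factors = factors, modalities = modalities, T = as.integer(T_steps)),
    class = "mp_model")
  if (validate) validate_model(model) else model
}

#' @export
print.mp_model <- function(x, ...) {
  m <- vapply(x$factors, function(f) f$m, integer(1))
  cat("Hidden Markov model (", length(x$factors), " factor",
      if (length(x$factors) != 1) "s", ", T = ", x$T, ")\n", sep = "")
  cat("  factor levels:", paste(m, collapse = ", "), "\n")
  if (length(x$modalities)) {
    for (g in seq_along(x$modalities)) {
      mod <- x$modalities[[g]]
      cat("  modality ", g, ": ", mod$O, " outcomes <- factor ", mod$factor,
          "\n", sep = "")
    }
  } else cat("  no outcome modalities\n")
  invisible(x)
}

# stochasticity tolerance used when loading/validating models
.mp_stoch_tol <- 1e-10

#' Validate a model specification
#'
#' Checks that every transition matrix, likelihood matrix and initial prior
#' is column-stochastic (columns summing to one within `1e-10`, entries
#' non-negative), that the horizon is at least one, and that every modality
#' points at an existing hidden factor.  Columns within tolerance of one are
#' renormalised exactly; larger deviations are an error naming the offending
#' factor or modality and column.
#'
#' @param model an [mp_model()].
#' @return The validated (possibly renormalised) model, invisibly unchanged
#'   in structure.
#' @export
validate_model <- function(model) {
  if (!inherits(model, "mp_model")) stop("`model` must be an mp_model")
  if (length(model$factors) < 1L) stop("model has no hidden factors")
  if (is.na(model$T) || model$T < 1L) stop("horizon T must be >= 1")
  for (f in seq_along(model$factors)) {
    fac <- model$factors[[f]]
    m <- fac$m
    if (!is.matrix(fac$B) || any(dim(fac$B) != c(m, m)))
      stop(sprintf("factor %d: B must be %d x %d", f, m, m))
    model$factors[[f]]$B <- .check_stochastic(fac$B, sprintf("factor %d transition matrix B", f))
    model$factors[[f]]$D <- drop(.check_stochastic(matrix(fac$D, ncol = 1),
                                                   sprintf("factor %d initial prior D", f)))
  }
  for (g in seq_along(model$modalities)) {
    mod <- model$modalities[[g]]
    if (mod$factor < 1L || mod$factor > length(model$factors))
      stop(sprintf("modality %d: target factor %d does not exist", g, mod$factor))
    m <- model$factors[[mod$factor]]$m
    if (!is.matrix(mod$A) || ncol(mod$A) != m)
      stop(sprintf("modality %d: A must have %d columns (levels of factor %d)",
                   g, m, mod$factor))
    model$modalities[[g]]$A <- .check_stochastic(mod$A, sprintf("modality %d likelihood matrix A", g))
  }
  model
}

.check_stochastic <- function(M, what) {
  if (any(M < 0))
    stop(sprintf("%s: negative entry in column %d", what,
                 which(apply(M < 0, 2, any))[1]))
  cs <- colSums(M)
  bad <- which(abs(cs - 1) > .mp_stoch_tol)
  if (length(bad))
    stop(sprintf("%s: column %d sums to %.6g, not 1", what, bad[1], cs[bad[1]]))
  sweep(M, 2, cs, "/")
}

#' Reverse-time transition matrix
#'
#' Bayes-inverts a column-stochastic transition matrix under a flat prior on
#' the earlier state: the transpose of `B` with its columns normalised,
#' `Bdag[i, j] = B[j, i] / sum_k B[j, k]`.  The result maps a belief about
#' the later state to a distribution over the earlier state, so that the
#' chain can be run from the future to the past while conserving probability
#' mass.
#'
#' If some row `j` of `B` is all zero (level `j` is unreachable as a
#' successor), the corresponding column of the reversal is undefined; it is
#' filled with the uniform distribution and a warning is emitted.
#'
#' @param B a column-stochastic square matrix.
#' @return A column-stochastic matrix of the same dimension.
#' @examples
#' reverse_transition(matrix(c(0.9, 0.1, 0.3, 0.7), 2))
#' @export
reverse_transition <- function(B) {
  rs <- rowSums(B)
  zero <- rs == 0
  if (any(zero)) {
    warning(sprintf("all-zero row(s) %s in B: filling reversed column(s) with the uniform distribution",
                    paste(which(zero), collapse = ", ")))
    rs[zero] <- 1
  }
  Bdag <- t(B / rs)
  if (any(zero)) Bdag[, zero] <- 1 / nrow(B)
  Bdag
}

#' Likelihood message for one outcome
#'
#' Returns the likelihood of each hidden level given an observed outcome:
#' row `o` of the likelihood matrix `A`.  An unobserved outcome (`NA`)
#' yields the all-ones vector, the uninformative message that leaves any
#' product of messages unchanged up to normalisation.
#'
#' @param A likelihood matrix (outcomes x levels).
#' @param o outcome index in `1..nrow(A)`, or `NA` for "not yet observed".
#' @param modality,tau optional indices used only to make error messages
#'   informative.
#' @return A non-negative vector of length `ncol(A)`.
#' @export
likelihood_message <- function(A, o, modality = NA, tau = NA) {
  if (is.na(o)) return(rep(1, ncol(A)))
  o <- as.integer(o)
  if (o < 1L || o > nrow(A))
    stop(sprintf("outcome index %d out of range 1..%d (modality %s, time step %s)",
                 o, nrow(A), as.character(modality), as.character(tau)))
  A[o, ]
}

#' Construct an observation record
#'
#' Holds outcome indices per modality per time step, with `NA` marking
#' outcomes that have not (yet) been observed, and optionally the true
#' generating states (used when scoring inferred states against the ground
#' truth of a simulation).
#'
#' @param outcomes integer matrix with `T` rows and one column per modality
#'   (`NA` allowed), or a vector for a single modality.
#' @param true_states optional integer matrix with `T` rows and one column
#'   per hidden factor.
#' @return An object of class `mp_obs`.
#' @export
mp_obs <- function(outcomes, true_states = NULL) {
  if (!is.matrix(outcomes)) outcomes <- matrix(outcomes, ncol = 1)
  storage.mode(outcomes) <- "integer"
  if (!is.null(true_states)) {
    if (!is.matrix(true_states)) true_states <- matrix(true_states, ncol = 1)
    storage.mode(true_states) <- "integer"
    if (nrow(true_states) != nrow(outcomes))
      stop("true_states must have one row per time step")
  }
  structure(list(outcomes = unname(outcomes),
                 true_states = if (is.null(true_states)) NULL else unname(true_states)),
            class = "mp_obs")
}

#' @export
print.mp_obs <- function(x, ...) {
  cat("Observation record: T =", nrow(x$outcomes), "steps,",
      ncol(x$outcomes), "modality(ies),",
      sum(is.na(x$outcomes)), "unobserved entries\n")
  if (!is.null(x$true_states)) cat("  true states recorded for",
                                   ncol(x$true_states), "factor(s)\n")
  invisible(x)
}

# check an observation record against a model; returns the record
validate_obs <- function(model, obs) {
  G <- length(model$modalities)
  if (ncol(obs$outcomes) != G)
    stop(sprintf("observation record has %d modality columns, model has %d",
                 ncol(obs$outcomes), G))
  if (nrow(obs$outcomes) != model$T)
    stop(sprintf("observation record has %d time steps, model horizon is %d",
                 nrow(obs$outcomes), model$T))
  for (g in seq_len(G)) {
    o <- obs$outcomes[, g]
    bad <- which(!is.na(o) & (o < 1L | o > model$modalities[[g]]$O))
    if (length(bad))
      stop(sprintf("outcome index %d out of range 1..%d (modality %d, time step %d)",
                   o[bad[1]], model$modalities[[g]]$O, g, bad[1]))
  }
  obs
}

# empty (fully unobserved) record for a model
empty_obs <- function(model) {
  mp_obs(matrix(NA_integer_, model$T, max(1L, length(model$modalities)))[,
         seq_len(length(model$modalities)), drop = FALSE])
}

# linear-domain likelihood messages for one factor: m x T matrix, the product
# over observing modalities of the selected likelihood rows (ones where
# unobserved).  Unnormalised so products remain interpretable as joint terms.
factor_likelihood <- function(model, obs, f) {
  m <- model$factors[[f]]$m
  L <- matrix(1, m, model$T)
  for (g in seq_along(model$modalities)) {
    mod <- model$modalities[[g]]
    if (mod$factor != f) next
    for (tau in seq_len(model$T)) {
      L[, tau] <- L[, tau] *
        likelihood_message(mod$A, obs$outcomes[tau, g], modality = g, tau = tau)
    }
  }
  L
}
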