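# Numerical floor for logarithms: tolerates structural zeros in A, B, D
# (deterministic priors have exact zeros).
.mp_floor <- 1e-16

flog <- function(x) log(x + .mp_floor)

#' Softmax (normalised exponential)
#'
#' `softmax(v)_i = exp(v_i) / sum_j exp(v_j)`, computed with max-subtraction
#' for numerical stability.  Invariant to adding a constant to `v` (the
#' additive gauge of log-space belief parameters).  For a matrix, the
#' softmax is applied to each column.
#'
#' @param v a numeric vector, or a matrix whose columns are transformed
#'   independently.
#' @return A probability vector (or column-stochastic matrix) of the same
#'   shape as `v`.
#' @examples
#' softmax(c(log(2), 0))  # (2/3, 1/3)
#' @export
softmax <- function(v) {
  if (is.matrix(v)) {
    e <- exp(sweep(v, 2, apply(v, 2, max)))
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(v - max(v))
    e / sum(e)
  }
}

# Shannon entropy in nats, 0 log 0 = 0
entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# KL divergence in nats; terms with p = 0 contribute 0, p > 0 against q = 0
# yields +Inf (flagged explicitly by the infinite return value)
kl_div <- function(p, q) {
  i <- p > 0
  if (any(q[i] == 0)) return(Inf)
  sum(p[i] * (log(p[i]) - log(q[i])))
}

# normalise a non-negative vector to sum 1
norm1 <- function(x) x / sum(x)

# run code with a temporary RNG seed, restoring global RNG state afterwards
# (explicit seed threading; no hidden global state is left behind)
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# coerce beliefs to a list of m x T matrices (one per factor)
as_marginals <- function(Q) {
  if (inherits(Q, "mp_fit")) return(Q$marginals)
  if (inherits(Q, "mp_marginals")) return(unclass(Q))
  if (is.matrix(Q)) return(list(Q))
  if (is.list(Q)) return(Q)
  stop("cannot interpret `Q` as posterior marginals")
}
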