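# Plain-text interchange formats: model specifications as YAML,
# observation sequences and belief tables as delimited text.

#' Write / read a model specification file
#'
#' The model file is YAML with keys `T`, `convention`, `factors` (each with
#' `levels`, `B`, `D`) and `modalities` (each with `outcomes`, `A`,
#' `factor`).  Matrices are stored row-major (a list of rows).  The
#' `convention` field declares how the stored matrices are oriented:
#' `column_stochastic` (the package's internal convention, written by
#' default) or `row_stochastic`, in which case matrices are transposed on
#' load.  Externally supplied models (for exact reproduction of published
#' simulations) can be dropped in through this reader.
#'
#' @param model an [mp_model()].
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns a
#'   validated [mp_model()].
#' @export
write_model <- function(model, path) {
  spec <- list(
    convention = "column_stochastic",
    T = model$T,
    factors = lapply(model$factors, function(f)
      list(levels = f$m,
           B = lapply(seq_len(nrow(f$B)), function(i) as.numeric(f$B[i, ])),
           D = as.numeric(f$D))),
    modalities = lapply(model$modalities, function(g)
      list(outcomes = g$O,
           A = lapply(seq_len(nrow(g$A)), function(i) as.numeric(g$A[i, ])),
           factor = g$factor)))
  yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  spec <- yaml::read_yaml(path)
  conv <- spec$convention
  if (is.null(conv)) conv <- "column_stochastic"
  if (!conv %in% c("column_stochastic", "row_stochastic"))
    stop(sprintf("unknown matrix convention '%s' in %s", conv, path))
  orient <- function(M) if (conv == "row_stochastic") t(M) else M
  as_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
  B <- lapply(spec$factors, function(f) orient(as_mat(f$B)))
  D <- lapply(spec$factors, function(f) as.numeric(f$D))
  mods <- spec$modalities
  if (is.null(mods)) mods <- list()
  A <- lapply(mods, function(g) orient(as_mat(g$A)))
  A_factor <- vapply(mods, function(g) as.integer(g$factor), integer(1))
  mp_model(B = B, D = D, A = if (length(A)) A else NULL,
           A_factor = if (length(A)) A_factor else NULL,
           T_steps = spec$T)
}

#' Write / read an observation file
#'
#' Tab-delimited text, one row per time step: one column per modality
#' (`o1`, `o2`, ...; 1-based outcome indices, `.` for a not-yet-observed
#' entry) and, when present, one column per hidden factor of true
#' generating states (`s1`, `s2`, ...).
#'
#' @param obs an [mp_obs()].
#' @param path file path.
#' @return `write_observations` returns `path` invisibly;
#'   `read_observations` returns an [mp_obs()].
#' @export
write_observations <- function(obs, path) {
  O <- obs$outcomes
  df <- as.data.frame(O)
  names(df) <- paste0("o", seq_len(ncol(O)))
  if (!is.null(obs$true_states)) {
    ts <- as.data.frame(obs$true_states)
    names(ts) <- paste0("s", seq_len(ncol(ts)))
    df <- cbind(df, ts)
  }
  for (j in seq_along(df)) df[[j]] <- ifelse(is.na(df[[j]]), ".", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = ".", colClasses = "integer")
  o_cols <- grep("^o[0-9]+$", names(df))
  s_cols <- grep("^s[0-9]+$", names(df))
  if (!length(o_cols)) stop(sprintf("no outcome columns (o1, o2, ...) in %s", path))
  mp_obs(as.matrix(df[o_cols]),
         true_states = if (length(s_cols)) as.matrix(df[s_cols]) else NULL)
}

#' Export posterior marginals as a long table
#'
#' @param Q marginals (list of `m x T` matrices or an `mp_fit`).
#' @param path optional file; if given, written as tab-delimited text.
#' @return A data frame with columns `factor`, `tau`, `state`,
#'   `probability` (invisibly if `path` is given).
#' @export
export_marginals <- function(Q, path = NULL) {
  Q <- as_marginals(Q)
  df <- do.call(rbind, lapply(seq_along(Q), function(f) {
    M <- Q[[f]]
    data.frame(factor = f,
               tau = rep(seq_len(ncol(M)), each = nrow(M)),
               state = rep(seq_len(nrow(M)), ncol(M)),
               probability = as.numeric(M))
  }))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Export a belief-updating trajectory
#'
#' Writes the recorded belief snapshots of a dynamic fit as a long
#' tab-delimited table (columns `time`, `factor`, `tau`, `state`,
#' `s_value`) and, optionally, a YAML sidecar with the run metadata
#' (scheme, integration settings, convergence).
#'
#' @param fit a dynamic `mp_fit`.
#' @param path file path for the table.
#' @param meta_path optional path for the YAML sidecar.
#' @return The data frame, invisibly.
#' @export
export_trajectory <- function(fit, path, meta_path = NULL) {
  if (is.null(fit$trajectory)) stop("fit has no recorded trajectory")
  tr <- fit$trajectory
  df <- do.call(rbind, lapply(seq_along(tr$time), function(k) {
    snap <- tr$s[[k]]
    do.call(rbind, lapply(seq_along(snap), function(f) {
      M <- snap[[f]]
      data.frame(time = tr$time[k], factor = f,
                 tau = rep(seq_len(ncol(M)), each = nrow(M)),
                 state = rep(seq_len(nrow(M)), ncol(M)),
                 s_value = as.numeric(M))
    }))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    yaml::write_yaml(list(scheme = fit$scheme, engine = fit$engine,
                          lesion = fit$lesion,
                          control = unclass(fit$control),
                          converged = fit$converged,
                          n_steps = fit$n_steps), meta_path)
  }
  invisible(df)
}
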