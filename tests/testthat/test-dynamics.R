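test_that("softmax evaluates the normalised exponential with gauge invariance", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(rep(-17.3, 5)), rep(0.2, 5))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  v <- c(0.3, -1.2, 2.5)
  expect_equal(softmax(v + 100), softmax(v))
  M <- cbind(c(0, 0), c(log(3), 0))
  expect_equal(softmax(M), cbind(c(0.5, 0.5), c(0.75, 0.25)))
})

test_that("gauge invariance: shifting membrane potentials leaves dynamics of s unchanged", {
  mod <- random_model(levels = 3, T_steps = 4, seed = 31)
  obs <- simulate(mod, seed = 32)
  base <- mp_infer(mod, obs, scheme = "VMP",
                   control = mp_control(max_time = 5, tol = 1e-12))
  shifted_init <- list(base$v[[1]] * 0 + 7)   # constant columns, uniform s
  shifted <- mp_infer(mod, obs, scheme = "VMP", init = shifted_init,
                      control = mp_control(max_time = 5, tol = 1e-12))
  expect_equal(shifted$marginals[[1]], base$marginals[[1]], tolerance = 1e-12)
})

test_that("BP gradient network converges to the enumeration-oracle marginals", {
  for (k in 1:12) {
    mod <- random_model(levels = sample(2:3, 1), T_steps = sample(2:6, 1),
                        seed = 1000 + k)
    obs <- simulate(mod, seed = 2000 + k)
    fit <- mp_infer(mod, obs, scheme = "BP")
    expect_true(fit$converged)
    bf <- brute_force_posterior(mod, obs)
    expect_lt(max(kl_marginals(bf$marginals, fit)$per_tau), 1e-6)
  }
})

test_that("converged BP message populations match the scheduled sum-product messages", {
  mod <- random_model(levels = c(3, 2), T_steps = 5, seed = 51)
  obs <- simulate(mod, seed = 52)
  fit <- mp_infer(mod, obs, scheme = "BP",
                  control = mp_control(tol = 1e-9, max_time = 500))
  for (f in 1:2) {
    fw <- forward_messages(mod, obs, f)$mu_fwd
    bw <- backward_messages(mod, obs, f)
    # proportional per column (population activities are normalised)
    for (tau in 1:5) {
      expect_equal(fit$msg_fwd[[f]][, tau], fw[, tau] / sum(fw[, tau]),
                   tolerance = 1e-6)
      expect_equal(fit$msg_bwd[[f]][, tau], bw[, tau] / sum(bw[, tau]),
                   tolerance = 1e-6)
    }
  }
  # T = 1: the forward message is the prior itself
  s1 <- mp_model(B = diag(2), D = c(0.3, 0.7), A = diag(2), T_steps = 1)
  f1 <- mp_infer(s1, mp_obs(matrix(2L, 1, 1)), scheme = "BP")
  expect_equal(f1$msg_fwd[[1]][, 1], c(0.3, 0.7))
})

test_that("VMP fixed point equals an independent mean-field coordinate ascent", {
  for (k in 1:6) {
    mod <- random_model(levels = 2, T_steps = 3, seed = 60 + k)
    obs <- simulate(mod, seed = 70 + k)
    fit <- mp_infer(mod, obs, scheme = "VMP",
                    control = mp_control(tol = 1e-10, max_time = 1000))
    oracle <- coordinate_ascent_oracle(mod, obs)
    expect_lt(max(abs(fit$marginals[[1]] - oracle[[1]])), 1e-6)
  }
})

test_that("ODE integration and direct fixed-point iteration agree for every scheme", {
  for (k in 1:4) {
    mod <- random_model(levels = 3, T_steps = 5, seed = 80 + k)
    obs <- simulate(mod, seed = 90 + k)
    for (sch in c("BP", "VMP", "MMP")) {
      fo <- mp_infer(mod, obs, scheme = sch,
                     control = mp_control(tol = 1e-9, max_time = 1000))
      fm <- mp_infer(mod, obs, scheme = sch, engine = "map",
                     control = mp_control(tol = 1e-9, max_time = 1000))
      expect_lt(abs(kl_marginals(fo, fm)$total), 1e-8)
    }
  }
})

test_that("MMP with deterministic transitions matches BP; attenuation raises entropy", {
  # deterministic chain: the halved log message still selects the same
  # support after the softmax on the floored logs
  d <- deterministic_chain(2, 4)
  obs <- mp_obs(matrix(forced_path(2, 4), ncol = 1))
  fb <- mp_infer(d, obs, scheme = "BP")
  fm <- mp_infer(d, obs, scheme = "MMP")
  expect_lt(max(kl_marginals(fb, fm)$per_tau), 1e-8)

  # attenuation exponent: alpha = 1/2 gives beliefs at least as uncertain
  # as the unattenuated alpha = 1 variant
  for (k in 1:5) {
    mod <- random_model(levels = 3, T_steps = 5, seed = 110 + k)
    o <- simulate(mod, seed = 120 + k)
    h_half <- mean(entropy_profile(mp_infer(mod, o, scheme = "MMP")))
    h_one <- mean(entropy_profile(mp_infer(mod, o, scheme = "MMP",
                                           control = mp_control(alpha = 1))))
    expect_gte(h_half, h_one - 1e-8)
  }
})

test_that("uniform models settle at uniform beliefs for every scheme", {
  u <- uniform_model(3, 3, 4)
  o <- simulate(u, seed = 5)
  for (sch in c("BP", "VMP", "MMP")) {
    fit <- mp_infer(u, o, scheme = sch)
    expect_true(fit$converged)
    expect_equal(fit$marginals[[1]], matrix(1 / 3, 3, 4), tolerance = 1e-9)
  }
})

test_that("identical inputs give bitwise-identical trajectories", {
  mod <- benchmark_model(T_steps = 6)
  obs <- simulate(mod, seed = 14)
  f1 <- mp_infer(mod, obs, scheme = "MMP")
  f2 <- mp_infer(mod, obs, scheme = "MMP")
  expect_identical(f1$trajectory, f2$trajectory)
  expect_identical(f1$marginals, f2$marginals)
})

test_that("non-convergence is flagged in the trajectory, not raised", {
  mod <- benchmark_model(T_steps = 8)
  obs <- simulate(mod, seed = 15)
  fit <- mp_infer(mod, obs, scheme = "BP",
                  control = mp_control(max_time = 0.5))
  expect_false(fit$converged)
  expect_s3_class(fit, "mp_fit")
})

test_that("the overcounting lesion doubles past likelihoods exactly", {
  expect_error(mp_infer(benchmark_model(T_steps = 3), scheme = "VMP", lesion = TRUE),
               "only for the BP circuit")

  # uniform likelihood: the ascending message is uninformative, no effect
  u <- mp_model(B = sticky_matrix(3, 0.7), D = c(1, 0, 0),
                A = matrix(1 / 3, 3, 3), T_steps = 5)
  ou <- simulate(u, seed = 16)
  expect_equal(mp_infer(u, ou, scheme = "BP", lesion = TRUE)$marginals,
               mp_infer(u, ou, scheme = "BP")$marginals, tolerance = 1e-9)

  # oracle identity: lesioned beliefs = current likelihood x forward filter
  # run with squared past likelihoods x standard backward messages
  for (k in 1:5) {
    mod <- random_model(levels = 3, T_steps = 5, seed = 130 + k,
                        concentration = 2)
    o <- simulate(mod, seed = 140 + k)
    fl <- mp_infer(mod, o, scheme = "BP", lesion = TRUE,
                   control = mp_control(tol = 1e-9, max_time = 500))
    L <- neuralmp:::factor_likelihood(mod, o, 1)
    fac <- mod$factors[[1]]
    Fm <- matrix(0, 3, 5)
    Fm[, 1] <- fac$D
    for (tau in 2:5) Fm[, tau] <- fac$B %*% (Fm[, tau - 1] * L[, tau - 1]^2)
    q <- L * Fm * backward_messages(mod, o, 1)
    q <- sweep(q, 2, colSums(q), "/")
    expect_lt(max(abs(q - fl$marginals[[1]])), 1e-6)
  }

  # consistent evidence is over-weighted: more mass on the supported state
  m <- mp_model(B = sticky_matrix(3, 0.7), D = rep(1 / 3, 3),
                A = sticky_matrix(3, 0.8), T_steps = 8)
  o <- mp_obs(matrix(rep(2L, 8), ncol = 1))
  fi <- mp_infer(m, o, scheme = "BP")
  fl <- mp_infer(m, o, scheme = "BP", lesion = TRUE)
  expect_gt(coef(fl)[[1]][2, 8], coef(fi)[[1]][2, 8])
})

test_that("fit methods expose beliefs, errors and evidence coherently", {
  mod <- benchmark_model(T_steps = 5)
  obs <- simulate(mod, seed = 17)
  fit <- mp_infer(mod, obs, scheme = "BP",
                  control = mp_control(tol = 1e-8, max_time = 500))
  expect_identical(coef(fit), fit$marginals)
  expect_lt(max(abs(residuals(fit)[[1]])), 1e-7)
  ex <- mp_infer(mod, obs, scheme = "exact")
  # Bethe bound of the converged BP fit equals the exact log evidence
  expect_equal(as.numeric(logLik(fit)), as.numeric(logLik(ex)),
               tolerance = 1e-5)
  expect_output(print(fit), "scheme = BP")
  expect_output(print(summary(fit)), "Posterior entropy")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_invisible(plot(ex, which = "marginals"))
})
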