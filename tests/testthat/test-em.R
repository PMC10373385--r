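test_that("initialization starts from OLS with strictly positive variances", {
  inst <- random_instance(J = 4, Tn = 3, K = 2, seed = 3)
  d <- inst$design
  y0 <- as.numeric(d$X %*% inst$beta)  # noiseless
  init <- initialize_params(y0, d)
  expect_equal(init$beta, inst$beta, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(init$vc$sigma0_sq, 1e-6)  # absolute floor when none supplied
  expect_true(init$vc$sigma0_sq > 0 && all(init$vc$sigma_k_sq > 0))

  # response orthogonal to the design column space -> zero coefficients
  qx <- qr(d$X)
  resid_space <- qr.resid(qx, rnorm(d$N))
  init2 <- initialize_params(resid_space, d)
  expect_equal(init2$beta, rep(0, d$P), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("E-step moments equal generic Gaussian conditioning", {
  for (seed in 1:6) {
    inst <- random_instance(J = 2, Tn = 2, K = 1, seed = seed)
    if (seed > 3) inst <- random_instance(J = 3, Tn = 3, K = 2, seed = seed)
    d <- inst$design
    post <- e_step(inst$y, d, inst$beta, inst$vc)
    oracle <- dense_conditional(inst$y, d, inst$beta, inst$vc)
    expect_equal(post$mu_p, oracle$mu, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(post$Sigma_p), unname(oracle$Sigma),
                 tolerance = 1e-8)
    # expected residual and random-effect moments from the dense pieces
    r <- as.numeric(inst$y - d$X %*% inst$beta)
    ssr_oracle <- sum(diag(d$A %*% oracle$Sigma %*% t(d$A))) +
      sum((as.numeric(d$A %*% oracle$mu) - r)^2)
    expect_equal(post$expected_ssr, ssr_oracle, tolerance = 1e-8)
    uku_oracle <- sapply(seq_len(d$K), function(k) {
      idx <- (k - 1) * d$J + seq_len(d$J)
      sum(diag(oracle$Sigma[idx, idx, drop = FALSE])) +
        sum(oracle$mu[idx]^2)
    })
    expect_equal(post$expected_uku, uku_oracle, tolerance = 1e-8)
  }
})

test_that("E-step degenerates correctly without random-effect variance", {
  inst <- random_instance(J = 3, Tn = 3, K = 2, seed = 4)
  d <- inst$design
  vc0 <- variance_components(2, rep(0, d$K))
  post <- e_step(inst$y, d, inst$beta, vc0)
  expect_equal(post$mu_p, rep(0, d$Q), ignore_attr = TRUE)
  expect_equal(unname(post$Sigma_p), matrix(0, d$Q, d$Q))
  expect_equal(post$expected_ssr,
               sum((inst$y - d$X %*% inst$beta)^2), tolerance = 1e-10)

  # exact mean: posterior mean vanishes, only the trace term remains
  y0 <- as.numeric(d$X %*% inst$beta)
  post0 <- e_step(y0, d, inst$beta, inst$vc)
  expect_equal(post0$mu_p, rep(0, d$Q), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(post0$expected_ssr, post0$tr_ASpA, tolerance = 1e-10)
})

test_that("M-step reproduces the closed-form updates", {
  inst <- random_instance(J = 3, Tn = 3, K = 2, seed = 5)
  d <- inst$design
  post <- e_step(inst$y, d, inst$beta, inst$vc)
  upd <- m_step(inst$y, d, post)
  # direct evaluation of the printed formulas
  beta_direct <- solve(crossprod(d$X),
                       crossprod(d$X, inst$y - d$A %*% post$mu_p))[, 1]
  expect_equal(upd$beta, beta_direct, tolerance = 1e-10, ignore_attr = TRUE)
  ssr_new <- post$tr_ASpA +
    sum((inst$y - d$X %*% beta_direct - d$A %*% post$mu_p)^2)
  expect_equal(upd$vc$sigma0_sq, ssr_new / d$N, tolerance = 1e-10)
  expect_equal(upd$vc$sigma_k_sq, post$expected_uku / d$J,
               tolerance = 1e-10)

  # zero posterior mean -> the coefficient update is plain OLS
  post$mu_p[] <- 0
  post$Amu[] <- 0
  upd0 <- m_step(inst$y, d, post)
  expect_equal(upd0$beta, qr.coef(qr(d$X), inst$y), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("EM recovers noiseless data and ascends monotonically", {
  inst <- random_instance(J = 6, Tn = 3, K = 2, seed = 6)
  d <- inst$design
  y0 <- as.numeric(d$X %*% inst$beta)
  fit <- ctlmm(y0, d)
  expect_equal(unname(coef(fit)), inst$beta, tolerance = 1e-5)
  # residual variance sits at its (scale-relative) floor
  expect_lte(fit$vc$sigma0_sq, 1e-6 * var(y0) * (1 + 1e-6))
  expect_true(fit$boundary)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))

  # noisy data: ascent property on both engines
  fitc <- ctlmm(inst$y, d, ctlmm_control(max_iter = 500))
  fitr <- ctlmm(inst$y, d, ctlmm_control(max_iter = 500), engine = "R")
  expect_true(all(diff(fitc$loglik_trace) >= -1e-8))
  expect_true(all(diff(fitr$loglik_trace) >= -1e-8))
})

test_that("compiled and reference engines run the identical algorithm", {
  for (seed in c(7, 8)) {
    inst <- random_instance(J = 5, Tn = 3, K = 2, seed = seed)
    ctrl <- ctlmm_control(max_iter = 40, accelerate = FALSE)
    fc <- ctlmm(inst$y, inst$design, ctrl)
    fr <- ctlmm(inst$y, inst$design, ctrl, engine = "R")
    expect_equal(fc$loglik_trace, fr$loglik_trace, tolerance = 1e-9)
    expect_equal(coef(fc), coef(fr), tolerance = 1e-9)
    expect_equal(fc$vc$sigma_k_sq, fr$vc$sigma_k_sq, tolerance = 1e-9)
    expect_equal(fc$mu_p, fr$mu_p, tolerance = 1e-8)
  }
})

test_that("accelerated EM reaches at least the plain-map likelihood", {
  inst <- random_instance(J = 6, Tn = 3, K = 3, seed = 11)
  acc <- ctlmm(inst$y, inst$design, ctlmm_control(tol = 1e-9, max_iter = 300))
  plain <- ctlmm(inst$y, inst$design,
                 ctlmm_control(tol = 1e-9, max_iter = 5000,
                               accelerate = FALSE))
  expect_gte(acc$loglik, plain$loglik - 1e-4)
  expect_true(all(diff(acc$loglik_trace) >= -1e-8))
})

test_that("EM fixed point attains the numerical-MLE likelihood", {
  for (seed in 1:5) {
    inst <- random_instance(J = 4, Tn = 3, K = 2, seed = 20 + seed)
    fit <- ctlmm(inst$y, inst$design,
                 ctlmm_control(tol = 1e-10, max_iter = 1000))
    oracle <- numerical_mle(inst$y, inst$design,
                            starts = list(phi_from_fit(fit),
                                          rep(0, inst$design$P + 1 +
                                                inst$design$K)))
    expect_gte(fit$loglik, oracle$loglik - 1e-4)
    expect_equal(fit$loglik,
                 dense_loglik(inst$y, inst$design, coef(fit), fit$vc),
                 tolerance = 1e-8)
  }
})

test_that("vanishing between-subject variance reduces the fit to OLS", {
  inst <- random_instance(J = 12, Tn = 3, K = 2, seed = 30)
  d <- inst$design
  set.seed(31)
  y <- as.numeric(d$X %*% inst$beta) + rnorm(d$N, 0, 0.01)  # no subject effect
  fit <- ctlmm(y, d, ctlmm_control(tol = 1e-9, max_iter = 2000))
  ols <- qr.coef(qr(d$X), y)
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 0.01)
  expect_true(all(fit$vc$sigma_k_sq < 0.01))
})

test_that("panel fitting equals independent per-gene fits in any order", {
  inst <- random_instance(J = 4, Tn = 3, K = 2, seed = 40)
  d <- inst$design
  set.seed(41)
  Y <- rbind(g1 = gaussian_gene(d, inst$beta, inst$vc),
             g2 = gaussian_gene(d, inst$beta * 0.5, inst$vc))
  pf <- ctlmm_panel(Y, d)
  f1 <- ctlmm(Y[1, ], d)
  expect_equal(coef(pf$fits$g1), coef(f1))
  pf_shuf <- ctlmm_panel(Y[c(2, 1), ], d)
  expect_equal(coef(pf_shuf$fits$g1), coef(pf$fits$g1))
  expect_length(pf$errors, 0)

  # per-gene failures are collected, not fatal
  Y_bad <- rbind(Y, g3 = c(NA, Y[1, -1]))
  pf_bad <- ctlmm_panel(Y_bad, d)
  expect_named(pf_bad$errors, "g3")
  expect_null(pf_bad$fits$g3)
  expect_equal(coef(pf_bad$fits$g1), coef(f1))
})

test_that("model fit methods are coherent", {
  inst <- random_instance(J = 4, Tn = 3, K = 2, seed = 50)
  fit <- ctlmm(inst$y, inst$design)
  expect_equal(fitted(fit) + residuals(fit), inst$y)
  expect_s3_class(summary(fit), "summary.ctlmm")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), inst$design$P + inst$design$K + 1L)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(inst$design$N, 2L))
  expect_output(print(fit), "mixed-effect model")
})
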