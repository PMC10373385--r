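test_that("two-level Dirichlet proportions have the right structure", {
  cfg <- sim_config(G = 1, J_per_group = 150, K = 6)
  pr <- simulate_proportions(cfg, seed = 1)
  expect_equal(rowSums(pr$theta), rep(1, nrow(pr$theta)), tolerance = 1e-12)
  expect_true(all(pr$theta >= 0))
  # Monte-Carlo mean of control proportions ~ alpha_C / sum(alpha_C)
  ctrl_rows <- which(rep(pr$groups, each = cfg$T_points) == 0)
  alpha_c <- cfg$dirichlet_alpha_control
  expect_equal(colMeans(pr$theta[ctrl_rows, ]), alpha_c / sum(alpha_c),
               tolerance = 0.05, ignore_attr = TRUE)

  # huge within-subject precision: time points nearly identical
  cfg2 <- sim_config(G = 1, J_per_group = 3, K = 3, xi_subject = 1e7)
  pr2 <- simulate_proportions(cfg2, seed = 2)
  for (j in 1:6) {
    rows <- (j - 1) * 3 + 1:3
    expect_lt(max(apply(pr2$theta[rows, ], 2, sd)), 1e-3)
  }
  expect_error(simulate_proportions(sim_config(K = 2, xi_group = -1,
                                               J_per_group = 2)),
               "positive")
})

test_that("gene-level parameter draws honor mean, shift, and covariance", {
  cfg <- sim_config(G = 400, J_per_group = 6, K = 3, lfc = 1.5,
                    mean_log = c(3, 4, 5), mean_cov = cs_cov(3, 0.5, 0.5),
                    disp_log = rep(-1, 3), disp_cov = cs_cov(3, 0.25, 0.5))
  de <- matrix(FALSE, 400, 3)
  de[1:200, 2] <- TRUE
  gp <- simulate_gene_params(cfg, de = de, seed = 3)
  case <- 7:12
  # DE genes: case subjects shifted by the LFC in the flagged coordinate only
  expect_equal(mean(gp$M_log[1:200, case, 2]), 4 + 1.5, tolerance = 0.05)
  expect_equal(mean(gp$M_log[1:200, 1:6, 2]), 4, tolerance = 0.05)
  expect_equal(mean(gp$M_log[201:400, case, 2]), 4, tolerance = 0.05)
  # empirical covariance of the draws matches the target
  draws <- apply(gp$M_log[201:400, , ], 3, as.numeric)
  expect_equal(unname(cov(draws)), unname(cs_cov(3, 0.5, 0.5)),
               tolerance = 0.05)

  cfg0 <- sim_config(G = 5, J_per_group = 2, K = 2, mean_cov = cs_cov(2, 0, 0),
                     disp_cov = cs_cov(2, 0, 0), mean_log = c(2, 3))
  gp0 <- simulate_gene_params(cfg0, seed = 4)
  expect_equal(max(abs(sweep(gp0$M_log, 3, c(2, 3)))), 0, tolerance = 1e-12)
})

test_that("Gamma references have mean M and variance M^2 exp(Phi)", {
  set.seed(5)
  M <- matrix(50, 2000, 2)
  Phi <- matrix(c(-1, -2), 2000, 2, byrow = TRUE)
  lam <- simulate_reference(M, Phi)
  expect_true(all(lam >= 0))
  expect_equal(colMeans(lam), c(50, 50), tolerance = 0.1 * 50)
  expect_equal(apply(lam, 2, var), 50^2 * exp(c(-1, -2)), tolerance = 0.2 *
                 50^2 * exp(-1))
  # vanishing overdispersion concentrates at the mean
  lam0 <- simulate_reference(matrix(50, 500, 1), matrix(-15, 500, 1))
  expect_lt(max(abs(lam0 - 50)), 1)
  expect_error(simulate_reference(matrix(-1, 1, 1), matrix(0, 1, 1)),
               "positive")
})

test_that("slope shifts redraw references around shifted means", {
  groups <- c(0, 0, 1, 1)
  M <- matrix(100, 4, 2)
  Phi <- matrix(-8, 4, 2)
  sh <- list(control = c(0, 0, 0), case = c(0, 20, 40))
  set.seed(6)
  lam <- apply_slope_shift(M, Phi, sh, groups)
  expect_equal(dim(lam), c(4, 2, 3))
  # tiny overdispersion: draws sit near the shifted means
  expect_equal(unname(lam[1, 1, ]), c(100, 100, 100), tolerance = 5)
  expect_equal(unname(lam[3, 1, ]), c(100, 120, 140), tolerance = 5)
  expect_error(apply_slope_shift(M, Phi, list(control = c(0, -200, 0),
                                              case = c(0, 0, 0)), groups),
               "nonpositive")
})

test_that("mixing conserves the proportion-weighted mean", {
  lam <- array(c(10, 30, 20, 40), c(1, 2, 2))  # gene x subject x cell type
  theta <- rbind(c(0.25, 0.75), c(0.5, 0.5))
  mo <- mix_and_observe(lam, theta, subj = c(1, 2), observe = FALSE)
  expect_equal(as.numeric(mo$mean), c(0.25 * 10 + 0.75 * 20,
                                      0.5 * 30 + 0.5 * 40))
  # K = 1 reduces to the reference itself
  lam1 <- array(c(7, 9), c(1, 2, 1))
  mo1 <- mix_and_observe(lam1, matrix(1, 2, 1), subj = c(1, 2),
                         observe = FALSE)
  expect_equal(as.numeric(mo1$mean), c(7, 9))
  # Poisson draws are nonnegative integers with the right mean
  set.seed(7)
  lam_big <- array(200, c(1, 1, 1))
  mo2 <- mix_and_observe(lam_big, matrix(1, 1, 1), subj = 1)
  expect_true(mo2$counts >= 0 && mo2$counts == round(mo2$counts))
  ys <- replicate(300, mix_and_observe(lam_big, matrix(1, 1, 1),
                                       subj = 1)$counts[1, 1])
  expect_equal(mean(ys), 200, tolerance = 5)
})

test_that("the full generator is deterministic with per-gene substreams", {
  cfg <- sim_config(G = 12, J_per_group = 4, K = 3)
  s1 <- simulate_dataset(cfg, seed = 42)
  s2 <- simulate_dataset(cfg, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$lambda, s2$truth$lambda)

  # growing G leaves earlier genes' draws untouched (fixed DE design)
  cfg_a <- sim_config(G = 12, J_per_group = 4, K = 3, de_fraction = 0,
                      de_cell_types = integer(0))
  cfg_b <- sim_config(G = 20, J_per_group = 4, K = 3, de_fraction = 0,
                      de_cell_types = integer(0))
  sa <- simulate_dataset(cfg_a, seed = 42)
  sb <- simulate_dataset(cfg_b, seed = 42)
  expect_identical(unname(sa$truth$M), unname(sb$truth$M[1:12, , ]))
  expect_identical(unname(sa$counts), unname(sb$counts[1:12, ]))

  # counts are overdispersed relative to Poisson around the mixture mean
  cfg_od <- sim_config(G = 200, J_per_group = 10, K = 2, mean_log = c(4, 5),
                       de_fraction = 0, de_cell_types = integer(0))
  sod <- simulate_dataset(cfg_od, seed = 9)
  vm <- sapply(1:200, function(g) {
    y <- sod$counts[g, ]
    c(var(y), mean(y))
  })
  expect_gt(median(vm[1, ] / vm[2, ]), 2)
})

test_that("DE design fractions match the configuration", {
  sim <- simulate_dataset(sim_config(G = 200, J_per_group = 3), seed = 8)
  de <- sim$truth$de
  expect_equal(unname(colSums(de)), c(20, 20, 20, 20, 0, 0))
  # disjoint assignment
  expect_true(all(rowSums(de) <= 1))
})

test_that("Dirichlet fitting recovers known parameters", {
  alpha <- c(8.85, 6.49, 5.98, 5.28, 4.22, 3.85)
  set.seed(10)
  x <- matrix(rgamma(1e5 * 6, shape = rep(alpha, each = 1e5)), 1e5, 6)
  x <- x / rowSums(x)
  ahat <- fit_dirichlet(x)
  expect_equal(ahat, alpha, tolerance = 0.05, ignore_attr = TRUE)

  # exchangeable columns give (near) equal concentrations
  set.seed(11)
  y <- matrix(rgamma(4e4 * 2, 3), 4e4, 2)
  y <- y / rowSums(y)
  ahat2 <- fit_dirichlet(y)
  expect_equal(ahat2[1], ahat2[2], tolerance = 0.05 * ahat2[1])
  expect_warning(fit_dirichlet(rbind(c(0, 1), c(0.5, 0.5))), "clipped")
})

test_that("surrogate deconvolution recovers the truth without noise", {
  # cell-type-informative profiles (independent per-gene variation) make the
  # composition identifiable; tiny Gamma overdispersion isolates the NNLS step
  cfg <- sim_config(G = 60, J_per_group = 6, K = 3, mean_log = c(5, 5, 5),
                    mean_cov = cs_cov(3, 1.2, 0), disp_log = rep(-8, 3),
                    disp_cov = cs_cov(3, 0.01, 0), de_fraction = 0,
                    de_cell_types = integer(0))
  sim <- simulate_dataset(cfg, seed = 12)
  est <- perturb_proportions(sim, noise_sd = 0, n_markers = 60, seed = 1)
  expect_equal(rowSums(est), rep(1, nrow(est)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # noiseless panels: estimated compositions track the truth closely
  expect_lt(mean(abs(est - sim$proportions)), 0.02)
  # panel noise degrades the estimate
  est_noisy <- perturb_proportions(sim, noise_sd = 0.5, n_markers = 60,
                                   seed = 1)
  expect_gt(mean(abs(est_noisy - sim$proportions)),
            mean(abs(est - sim$proportions)))
})

test_that("NNLS solutions match brute-force active-set enumeration", {
  set.seed(13)
  for (i in 1:10) {
    A <- matrix(runif(6, 0.1, 2), 3, 2)
    b <- as.numeric(A %*% runif(2, -0.5, 1.5)) + rnorm(3, 0, 0.2)
    x_pkg <- pracma::lsqnonneg(A, b)$x
    expect_equal(x_pkg, brute_nnls(A, b), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("null configuration keeps groups exchangeable", {
  cfg <- sim_config(G = 150, J_per_group = 12, K = 3, lfc = 0,
                    de_fraction = 0, de_cell_types = integer(0))
  sim <- simulate_dataset(cfg, seed = 14)
  grp <- sim$meta$group
  # per-gene subject reference means have the same distribution in both arms
  m_ctr <- as.numeric(sim$truth$M[, sim$truth$groups == 0, ])
  m_cas <- as.numeric(sim$truth$M[, sim$truth$groups == 1, ])
  expect_gt(suppressWarnings(ks.test(log(m_ctr), log(m_cas)))$p.value, 1e-3)
})
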