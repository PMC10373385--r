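#' Configuration for the longitudinal bulk count simulator
#'
#' Defines one simulated study: two groups of subjects measured at `T` time
#' points, cell-type composition drawn from a two-level Dirichlet (between-
#' subject, then within-subject), per-gene per-subject log-scale mean and
#' overdispersion drawn from correlated multivariate normals, pure-cell
#' references drawn from a Gamma with mean `M` and variance `M^2 exp(Phi)`,
#' bulk mixtures formed as proportion-weighted sums, and observed counts
#' drawn from a Poisson around the mixture mean.
#'
#' @param G number of genes.
#' @param J_per_group subjects per group (controls and cases are balanced).
#' @param T_points repeated measures per subject (default 3).
#' @param K number of cell types (default 6).
#' @param dirichlet_alpha_control,dirichlet_alpha_case Dirichlet parameters
#'   whose normalized values give the expected group compositions. Defaults
#'   (for K = 6): controls `(8.85, 6.49, 5.98, 5.28, 4.22, 3.85)`, cases
#'   `(1.90, 2.25, 2.10, 5.72, 7.33, 15.37)`; for other K a flat `rep(5, K)`.
#' @param xi_group between-subject Dirichlet precision (default 30).
#' @param xi_subject within-subject (between-time-point) precision
#'   (default 100).
#' @param mean_log length-K log-scale mean expression per cell type
#'   (default evenly spaced over \[2, 8\]).
#' @param mean_cov K x K covariance of the log-mean draws (default
#'   compound-symmetric, sd 0.5, correlation 0.5).
#' @param disp_log length-K log-scale overdispersion means (default -1).
#' @param disp_cov K x K covariance of the overdispersion draws (default
#'   compound-symmetric, sd 0.25, correlation 0.5).
#' @param de_fraction fraction of genes flagged DE in each designated cell
#'   type (default 0.10).
#' @param de_cell_types cell types carrying DE genes (default the first 4 of
#'   6, leaving 2 cell types DE-free); DE gene sets are disjoint across cell
#'   types.
#' @param lfc log fold change added to the case-group log-mean in the
#'   flagged cell type (default 1; the study grid is
#'   0, 0.5, 0.75, 1.0, 1.25, 1.5).
#' @param slope_shifts optional list with numeric elements `control` and
#'   `case`, each of length `T_points` with first entry 0: additive
#'   (count-scale) shifts of the reference mean at each time point, fixed by
#'   group. The `control` shift is the temporal trend shared by everyone;
#'   case subjects follow the `case` shift in a gene's DE-flagged cell types
#'   (a differential change rate there) and the `control` shift elsewhere.
#'   `NULL` (default) simulates the static scenario.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(G = 1000L, J_per_group = 25L, T_points = 3L, K = 6L,
                       dirichlet_alpha_control = NULL,
                       dirichlet_alpha_case = NULL,
                       xi_group = 30, xi_subject = 100,
                       mean_log = seq(2, 8, length.out = K),
                       mean_cov = cs_cov(K, 0.5, 0.5),
                       disp_log = rep(-1, K),
                       disp_cov = cs_cov(K, 0.25, 0.5),
                       de_fraction = 0.10,
                       de_cell_types = seq_len(min(4L, K)),
                       lfc = 1,
                       slope_shifts = NULL) {
  if (is.null(dirichlet_alpha_control)) {
    dirichlet_alpha_control <- if (K == 6L) {
      c(8.85, 6.49, 5.98, 5.28, 4.22, 3.85)
    } else rep(5, K)
  }
  if (is.null(dirichlet_alpha_case)) {
    dirichlet_alpha_case <- if (K == 6L) {
      c(1.90, 2.25, 2.10, 5.72, 7.33, 15.37)
    } else rep(5, K)
  }
  stopifnot(G >= 1, J_per_group >= 1, T_points >= 1, K >= 1)
  if (any(dirichlet_alpha_control <= 0) || any(dirichlet_alpha_case <= 0)) {
    stop("Dirichlet parameters must be strictly positive")
  }
  if (length(dirichlet_alpha_control) != K ||
      length(dirichlet_alpha_case) != K) {
    stop("Dirichlet parameter vectors must have length K = ", K)
  }
  if (xi_group <= 0 || xi_subject <= 0) {
    stop("Dirichlet precisions xi must be positive")
  }
  stopifnot(length(mean_log) == K, length(disp_log) == K)
  check_psd(mean_cov, K, "mean_cov")
  check_psd(disp_cov, K, "disp_cov")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  if (length(de_cell_types) &&
      (any(de_cell_types < 1) || any(de_cell_types > K))) {
    stop("de_cell_types must index 1..K")
  }
  n_de <- round(de_fraction * G)
  if (n_de * length(de_cell_types) > G) {
    stop("disjoint DE assignment needs de_fraction * length(de_cell_types) <= 1")
  }
  if (!is.null(slope_shifts)) {
    if (!is.list(slope_shifts) ||
        !all(c("control", "case") %in% names(slope_shifts))) {
      stop("slope_shifts must be a list with elements 'control' and 'case'")
    }
    for (gname in c("control", "case")) {
      s <- slope_shifts[[gname]]
      if (length(s) != T_points || s[1] != 0) {
        stop("slope_shifts$", gname, " must have length T_points with first",
             " entry 0")
      }
    }
  }
  structure(list(G = as.integer(G), J_per_group = as.integer(J_per_group),
                 T_points = as.integer(T_points), K = as.integer(K),
                 dirichlet_alpha_control = dirichlet_alpha_control,
                 dirichlet_alpha_case = dirichlet_alpha_case,
                 xi_group = xi_group, xi_subject = xi_subject,
                 mean_log = mean_log, mean_cov = mean_cov,
                 disp_log = disp_log, disp_cov = disp_cov,
                 de_fraction = de_fraction,
                 de_cell_types = as.integer(de_cell_types),
                 lfc = lfc, slope_shifts = slope_shifts),
            class = "sim_config")
}

#' Compound-symmetric covariance matrix
#'
#' @param K dimension.
#' @param sd common standard deviation.
#' @param rho common correlation.
#' @export
cs_cov <- function(K, sd = 1, rho = 0.5) {
  m <- matrix(rho * sd^2, K, K)
  diag(m) <- sd^2
  m
}

check_psd <- function(S, K, name) {
  if (!is.matrix(S) || nrow(S) != K || ncol(S) != K ||
      max(abs(S - t(S))) > 1e-8) {
    stop(name, " must be a symmetric ", K, "x", K, " matrix")
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(name, " is not positive semi-definite")
  }
  invisible(TRUE)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}

# Deterministic per-gene RNG substream: changing G never perturbs the draws
# of earlier genes.
gene_seed <- function(seed, g) {
  as.integer((as.numeric(seed) %% 2147483647 * 1000003 + g * 7919) %%
               2147483629 + 1)
}

#' Simulate two-level Dirichlet cell-type proportions
#'
#' Subject-level mean compositions are drawn from
#' `Dir(xi_group * alpha_Z / sum(alpha_Z))` for the subject's group Z, then
#' each time point's composition from `Dir(xi_subject * theta_bar_j)`.
#'
#' @param cfg a [sim_config()].
#' @param groups optional 0/1 vector of subject group flags (default
#'   `J_per_group` controls followed by `J_per_group` cases).
#' @param seed optional seed (`NULL` uses the current RNG state).
#' @return list with `theta` (N x K sample compositions, samples ordered
#'   subject-major by time), `theta_subject` (J x K subject means), `groups`.
#' @export
simulate_proportions <- function(cfg, groups = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groups)) {
    groups <- rep(c(0, 1), each = cfg$J_per_group)
  }
  J <- length(groups)
  K <- cfg$K
  mean_c <- cfg$dirichlet_alpha_control / sum(cfg$dirichlet_alpha_control)
  mean_d <- cfg$dirichlet_alpha_case / sum(cfg$dirichlet_alpha_case)
  theta_subject <- matrix(NA_real_, J, K)
  for (j in seq_len(J)) {
    base <- if (groups[j] == 1) mean_d else mean_c
    theta_subject[j, ] <- rdirichlet(1L, cfg$xi_group * base)
  }
  theta <- matrix(NA_real_, J * cfg$T_points, K)
  for (j in seq_len(J)) {
    rows <- (j - 1L) * cfg$T_points + seq_len(cfg$T_points)
    theta[rows, ] <- rdirichlet(cfg$T_points,
                                cfg$xi_subject * theta_subject[j, ])
  }
  list(theta = theta, theta_subject = theta_subject, groups = groups)
}

#' Simulate per-gene, per-subject mean and overdispersion parameters
#'
#' Draws the log-scale mean vector `M_log[g, j, ]` from
#' `MVN(mean_log (+ lfc shift for DE cell types in cases), mean_cov)` and the
#' overdispersion vector `Phi[g, j, ]` from `MVN(disp_log, disp_cov)`,
#' independently across genes and subjects.
#'
#' @param cfg a [sim_config()].
#' @param groups 0/1 subject group flags.
#' @param de logical G x K matrix of DE flags (default none).
#' @param seed optional seed.
#' @return list with arrays `M_log` and `Phi` (G x J x K).
#' @export
simulate_gene_params <- function(cfg, groups = NULL, de = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groups)) groups <- rep(c(0, 1), each = cfg$J_per_group)
  J <- length(groups)
  K <- cfg$K
  G <- cfg$G
  if (is.null(de)) de <- matrix(FALSE, G, K)
  R_m <- chol_psd(cfg$mean_cov)
  R_p <- chol_psd(cfg$disp_cov)
  M_log <- array(NA_real_, c(G, J, K))
  Phi <- array(NA_real_, c(G, J, K))
  case <- groups == 1
  for (g in seq_len(G)) {
    mu <- matrix(cfg$mean_log, J, K, byrow = TRUE)
    if (any(de[g, ])) {
      for (k in which(de[g, ])) mu[case, k] <- mu[case, k] + cfg$lfc
    }
    M_log[g, , ] <- mu + matrix(stats::rnorm(J * K), J, K) %*% R_m
    Phi[g, , ] <- matrix(cfg$disp_log, J, K, byrow = TRUE) +
      matrix(stats::rnorm(J * K), J, K) %*% R_p
  }
  list(M_log = M_log, Phi = Phi)
}

# Cholesky factor tolerant of a PSD (possibly singular) covariance.
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  t(ev$vectors %*% (sqrt(lam) * t(ev$vectors)))
}

#' Draw pure-cell reference expression from the Gamma biological model
#'
#' `lambda ~ Gamma(shape = exp(-Phi), scale = M * exp(Phi))`, so that
#' `E[lambda] = M` and `Var[lambda] = M^2 exp(Phi)`: `M` is the (natural
#' scale) mean expression and `Phi` the log-scale biological overdispersion.
#'
#' @param M array of positive mean expression values (natural scale; log
#'   scale draws must be exponentiated first).
#' @param Phi array of overdispersion values, same shape as `M`.
#' @return array of nonnegative reference values, same shape as `M`.
#' @export
simulate_reference <- function(M, Phi) {
  if (any(M <= 0)) stop("reference means M must be strictly positive")
  if (!identical(dim(M), dim(Phi)) && length(M) != length(Phi)) {
    stop("M and Phi must have the same shape")
  }
  out <- stats::rgamma(length(M), shape = exp(-as.numeric(Phi)),
                       scale = as.numeric(M) * exp(as.numeric(Phi)))
  array(out, dim = if (is.null(dim(M))) length(M) else dim(M))
}

#' Apply group-wise temporal shifts to the reference means
#'
#' Shifts the per-subject mean `M` to `M + shift[group, t]` at every time
#' point (`shift = 0` at t = 1) and redraws the Gamma reference at each time
#' point, yielding time-varying references with a group-fixed change rate.
#'
#' @param M J x K matrix (or G x J x K array) of natural-scale means.
#' @param Phi matching overdispersion values.
#' @param slope_shifts list with `control` and `case` shift vectors of length
#'   T (first entry 0).
#' @param groups 0/1 subject group flags (length J).
#' @return array with a trailing time dimension (`dim(M) x T`) of reference
#'   draws.
#' @export
apply_slope_shift <- function(M, Phi, slope_shifts, groups) {
  Tn <- length(slope_shifts$control)
  dM <- if (is.null(dim(M))) c(length(M)) else dim(M)
  jdim <- if (length(dM) == 3L) 2L else 1L
  if (dM[jdim] != length(groups)) {
    stop("subject dimension of M does not match length(groups)")
  }
  out <- array(NA_real_, c(dM, Tn))
  flat <- array(as.numeric(M), dM)
  shift_of <- function(t) {
    ifelse(groups == 1, slope_shifts$case[t], slope_shifts$control[t])
  }
  for (t in seq_len(Tn)) {
    s <- shift_of(t)
    Mt <- if (length(dM) == 3L) {
      sweep(flat, 2L, s, `+`)
    } else flat + s
    if (any(Mt <= 0)) {
      stop("slope shift at time ", t, " makes a reference mean nonpositive")
    }
    idx <- slice.index(out, length(dM) + 1L) == t
    out[idx] <- simulate_reference(Mt, Phi)
  }
  out
}

#' Mix references by cell-type proportions and observe Poisson counts
#'
#' The mixture mean of gene g in sample (j, t) is the proportion-weighted sum
#' of that subject's references, `sum_k lambda[g, j, k(, t)] * theta[i, k]`;
#' observed counts are independent Poisson draws around it.
#'
#' @param lambda G x J x K (static) or G x J x K x T (slope scenario) array
#'   of references.
#' @param theta N x K sample composition matrix.
#' @param subj length-N subject index per sample.
#' @param time_index length-N time index per sample (needed for 4-d lambda).
#' @param observe draw Poisson counts (`TRUE`) or return the mixture means.
#' @return list with `counts` (G x N integer matrix) and `mean` (G x N
#'   mixture means).
#' @export
mix_and_observe <- function(lambda, theta, subj, time_index = NULL,
                            observe = TRUE) {
  dl <- dim(lambda)
  G <- dl[1]
  N <- nrow(theta)
  mu <- matrix(NA_real_, G, N)
  for (i in seq_len(N)) {
    lam_i <- if (length(dl) == 4L) {
      lambda[, subj[i], , time_index[i], drop = TRUE]
    } else {
      lambda[, subj[i], , drop = TRUE]
    }
    lam_i <- matrix(lam_i, G, dl[3])
    mu[, i] <- lam_i %*% theta[i, ]
  }
  if (any(mu < 0)) stop("negative mixture mean; invalid references")
  counts <- if (observe) {
    matrix(stats::rpois(G * N, as.numeric(mu)), G, N)
  } else NULL
  list(counts = counts, mean = mu)
}

#' Generate a full synthetic longitudinal bulk study with ground truth
#'
#' Composes the whole generative pipeline — two-level Dirichlet proportions,
#' per-gene MVN mean/overdispersion (with the log-fold-change applied to the
#' case group in the DE-flagged cell types), Gamma references (with optional
#' group-wise temporal shifts), proportion-weighted mixing, Poisson
#' observation — and retains every intermediate truth. Fully reproducible
#' from the seed, with per-gene RNG substreams.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return object of class `"sim_dataset"`: `counts` (G x N), `meta` (sample
#'   table with `sample_id`, `subject_id`, `time`, `group`), `proportions`
#'   (N x K true compositions), and `truth` (subject-level compositions,
#'   reference arrays `lambda`, natural-scale means `M`, overdispersions
#'   `Phi`, logical DE flag matrix `de`, mixture means, config, seed).
#' @examples
#' sim <- simulate_dataset(sim_config(G = 20, J_per_group = 5), seed = 1)
#' dim(sim$counts)
#' colSums(sim$truth$de)
#' @export
simulate_dataset <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- as.integer(seed)
  set.seed(seed)
  G <- cfg$G; K <- cfg$K; Tn <- cfg$T_points
  J <- 2L * cfg$J_per_group
  groups <- rep(c(0, 1), each = cfg$J_per_group)
  subjects <- sprintf("S%03d", seq_len(J))
  meta <- data.frame(
    sample_id = paste0(rep(subjects, each = Tn), "_t", rep(seq_len(Tn), J)),
    subject_id = rep(subjects, each = Tn),
    time = rep(seq_len(Tn), J),
    group = rep(groups, each = Tn),
    stringsAsFactors = FALSE)
  subj <- rep(seq_len(J), each = Tn)

  pr <- simulate_proportions(cfg, groups)
  theta <- pr$theta
  cts <- paste0("ct", seq_len(K))
  dimnames(theta) <- list(meta$sample_id, cts)

  # disjoint DE gene sets across the designated cell types
  de <- matrix(FALSE, G, K, dimnames = list(NULL, cts))
  n_de <- round(cfg$de_fraction * G)
  if (n_de > 0 && length(cfg$de_cell_types) > 0) {
    pool <- sample(G, n_de * length(cfg$de_cell_types))
    for (i in seq_along(cfg$de_cell_types)) {
      de[pool[(i - 1L) * n_de + seq_len(n_de)], cfg$de_cell_types[i]] <- TRUE
    }
  }

  R_m <- chol_psd(cfg$mean_cov)
  R_p <- chol_psd(cfg$disp_cov)
  slope <- !is.null(cfg$slope_shifts)
  lambda <- if (slope) array(NA_real_, c(G, J, K, Tn))
            else array(NA_real_, c(G, J, K))
  M_all <- array(NA_real_, c(G, J, K))
  Phi_all <- array(NA_real_, c(G, J, K))
  counts <- matrix(NA_integer_, G, J * Tn)
  case <- groups == 1

  for (g in seq_len(G)) {
    set.seed(gene_seed(seed, g))
    mu <- matrix(cfg$mean_log, J, K, byrow = TRUE)
    for (k in which(de[g, ])) mu[case, k] <- mu[case, k] + cfg$lfc
    M_log <- mu + matrix(stats::rnorm(J * K), J, K) %*% R_m
    Phi <- matrix(cfg$disp_log, J, K, byrow = TRUE) +
      matrix(stats::rnorm(J * K), J, K) %*% R_p
    M <- exp(M_log)
    M_all[g, , ] <- M
    Phi_all[g, , ] <- Phi
    if (slope) {
      # shared temporal shift for everyone; the case-group shift applies only
      # to case subjects in this gene's DE-flagged cell types (differential
      # change rate in those cell types alone)
      lam_g <- array(NA_real_, c(J, K, Tn))
      for (t in seq_len(Tn)) {
        sh <- matrix(cfg$slope_shifts$control[t], J, K)
        if (any(de[g, ])) {
          sh[case, de[g, ]] <- cfg$slope_shifts$case[t]
        }
        Mt <- M + sh
        if (any(Mt <= 0)) {
          stop("slope shift at time ", t,
               " makes a reference mean nonpositive")
        }
        lam_g[, , t] <- simulate_reference(Mt, Phi)
      }
      lambda[g, , , ] <- lam_g
      for (j in seq_len(J)) for (t in seq_len(Tn)) {
        i <- (j - 1L) * Tn + t
        mu_i <- sum(lam_g[j, , t] * theta[i, ])
        counts[g, i] <- stats::rpois(1L, mu_i)
      }
    } else {
      lam_g <- simulate_reference(M, Phi)
      lambda[g, , ] <- lam_g
      for (j in seq_len(J)) for (t in seq_len(Tn)) {
        i <- (j - 1L) * Tn + t
        counts[g, i] <- stats::rpois(1L, sum(lam_g[j, ] * theta[i, ]))
      }
    }
  }
  genes <- sprintf("g%05d", seq_len(G))
  dimnames(counts) <- list(genes, meta$sample_id)

  structure(list(counts = counts, meta = meta, proportions = theta,
                 truth = list(theta_subject = pr$theta_subject,
                              lambda = lambda, M = M_all, Phi = Phi_all,
                              de = de, groups = groups, subj = subj,
                              config = cfg, seed = seed)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$truth$config
  cat("Simulated longitudinal bulk study: G =", nrow(x$counts),
      "genes, J =", 2 * cfg$J_per_group, "subjects x T =", cfg$T_points,
      "time points, K =", cfg$K, "cell types\n")
  cat("  DE design: fraction", cfg$de_fraction, "per cell type in",
      length(cfg$de_cell_types), "cell type(s), LFC =", cfg$lfc,
      if (!is.null(cfg$slope_shifts)) "(slope scenario)" else "", "\n")
  invisible(x)
}

#' Maximum-likelihood fit of a Dirichlet distribution
#'
#' Estimates the concentration parameters of a Dirichlet from composition
#' samples by the standard fixed-point iteration on the digamma equations,
#' started from moment matching.
#'
#' @param x matrix of compositions, samples as rows (rows sum to 1).
#'   Boundary entries (0 or 1) are clipped to 1e-6 with a warning and the
#'   rows renormalized.
#' @param tol convergence tolerance on the parameter change.
#' @param max_iter iteration cap.
#' @return numeric vector of fitted alpha (fitted mean is
#'   `alpha / sum(alpha)`).
#' @export
fit_dirichlet <- function(x, tol = 1e-10, max_iter = 1000L) {
  x <- as.matrix(x)
  if (any(x <= 0 | x >= 1)) {
    warning("boundary composition values clipped at 1e-6")
    x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
    x <- x / rowSums(x)
  }
  m <- colMeans(x)
  v <- apply(x, 2L, stats::var)
  v <- pmax(v, 1e-12)
  s <- stats::median((m * (1 - m)) / v - 1)
  if (!is.finite(s) || s <= 0) s <- 1
  alpha <- m * s
  logp <- colMeans(log(x))
  for (iter in seq_len(max_iter)) {
    alpha_new <- inv_digamma(digamma(sum(alpha)) + logp)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  alpha
}

# Newton inversion of the digamma function.
inv_digamma <- function(y) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y - digamma(1)))
  for (i in 1:8) x <- x - (digamma(x) - y) / trigamma(x)
  x
}

#' Surrogate estimated proportions via noisy-panel deconvolution
#'
#' Emulates an external signature-based deconvolution step: adds Gaussian
#' noise to the true reference panels, selects marker genes by
#' cross-cell-type coefficient of variation of the (noisy) average
#' signature, solves a nonnegative least squares fit of each bulk sample on
#' its subject's noisy marker panel, and renormalizes each solution to a
#' composition.
#'
#' @param sim a [simulate_dataset()] result.
#' @param noise_sd noise level relative to the reference scale (default 0.1).
#' @param n_markers number of marker genes (default 200).
#' @param seed optional seed for the noise draw.
#' @return N x K matrix of estimated compositions (rows sum to 1).
#' @export
perturb_proportions <- function(sim, noise_sd = 0.1, n_markers = 200L,
                                seed = NULL) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!is.null(seed)) set.seed(seed)
  lam <- sim$truth$lambda
  slope <- length(dim(lam)) == 4L
  scale <- mean(lam)
  noisy <- lam + array(stats::rnorm(length(lam), sd = noise_sd * scale),
                       dim(lam))
  noisy <- pmax(noisy, 0)
  sig <- apply(noisy, c(1, 3), mean)  # gene x cell-type average signature
  cv <- apply(sig, 1L, function(r) {
    m <- mean(r)
    if (m <= 0) 0 else stats::sd(r) / m
  })
  n_markers <- min(n_markers, nrow(sig))
  markers <- order(cv, decreasing = TRUE)[seq_len(n_markers)]
  if (qr(sig[markers, , drop = FALSE])$rank < ncol(sig)) {
    stop("marker signature is rank deficient; increase n_markers")
  }
  Y <- sim$counts[markers, , drop = FALSE]
  N <- ncol(Y)
  K <- dim(lam)[3]
  Tn <- sim$truth$config$T_points
  est <- matrix(NA_real_, N, K)
  for (i in seq_len(N)) {
    j <- sim$truth$subj[i]
    S <- if (slope) {
      t_i <- sim$meta$time[i]
      matrix(noisy[markers, j, , t_i], length(markers), K)
    } else {
      matrix(noisy[markers, j, ], length(markers), K)
    }
    x <- pracma::lsqnonneg(S, Y[, i])$x
    if (sum(x) <= 0) x <- rep(1 / K, K)
    est[i, ] <- x / sum(x)
  }
  dimnames(est) <- dimnames(sim$proportions)
  est
}
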