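# Independent oracles: dense linear algebra and brute-force definitions used
# to validate the structured (subject-block) implementations.

# dense marginal covariance straight from the definition
dense_V <- function(design, vc) {
  Su <- diag(rep(vc$sigma_k_sq, each = design$J), design$Q)
  design$A %*% Su %*% t(design$A) + vc$sigma0_sq * diag(design$N)
}

# multivariate normal log-density via dense solve/determinant
dense_loglik <- function(y, design, beta, vc) {
  V <- dense_V(design, vc)
  r <- as.numeric(y - design$X %*% beta)
  -0.5 * (design$N * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            sum(r * solve(V, r)))
}

# generic Gaussian conditioning of the joint (y, u) distribution
dense_conditional <- function(y, design, beta, vc) {
  Su <- diag(rep(vc$sigma_k_sq, each = design$J), design$Q)
  V <- dense_V(design, vc)
  SAt <- Su %*% t(design$A)
  r <- as.numeric(y - design$X %*% beta)
  list(mu = as.numeric(SAt %*% solve(V, r)),
       Sigma = Su - SAt %*% solve(V, t(SAt)))
}

# direct numerical maximization of the marginal likelihood over
# (beta, log sigma0^2, log sigma_k^2), used as the MLE oracle
numerical_mle <- function(y, design, starts = list()) {
  P <- design$P; K <- design$K
  obj <- function(phi) {
    ll <- tryCatch({
      vc <- variance_components(exp(phi[P + 1]),
                                exp(phi[P + 1 + seq_len(K)]))
      dense_loglik(y, design, phi[seq_len(P)], vc)
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e12 else -ll
  }
  best <- NULL
  for (s in starts) {
    o <- optim(s, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    o2 <- optim(o$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    cand <- if (o2$value < o$value) o2 else o
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  list(loglik = -best$value, par = best$par)
}

phi_from_fit <- function(fit) {
  c(fit$coefficients, log(fit$vc$sigma0_sq), log(fit$vc$sigma_k_sq))
}

# draw one gene from the Gaussian mixed model itself
gaussian_gene <- function(design, beta, vc) {
  u <- rnorm(design$Q, 0, sqrt(rep(vc$sigma_k_sq, each = design$J)))
  as.numeric(design$X %*% beta + design$A %*% u +
               rnorm(design$N, 0, sqrt(vc$sigma0_sq)))
}

# small random model instance on the simplex design
random_instance <- function(J = 4, Tn = 3, K = 2, seed = 1) {
  set.seed(seed)
  meta <- data.frame(
    sample_id = paste0("s", seq_len(J * Tn)),
    subject_id = rep(paste0("sub", seq_len(J)), each = Tn),
    time = rep(seq_len(Tn), J),
    group = rep(rep(c(0, 1), length.out = J), each = Tn))
  th <- matrix(rgamma(J * Tn * K, 2), J * Tn, K)
  th <- th / rowSums(th)
  colnames(th) <- paste0("ct", seq_len(K))
  design <- ct_design(meta, th)
  beta <- c(runif(K, 5, 15), runif(K, -2, 2))
  vc <- variance_components(runif(1, 0.5, 2), runif(K, 0.5, 3))
  y <- gaussian_gene(design, beta, vc)
  list(design = design, beta = beta, vc = vc, y = y, meta = meta, theta = th)
}

# brute-force AUC: all positive-negative pairs, ties get half credit
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force BH step-up
brute_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# brute-force one-sample KS statistic against Uniform[0,1]
brute_ks_D <- function(x) {
  x <- sort(x)
  n <- length(x)
  max(pmax(abs(seq_len(n) / n - x), abs((seq_len(n) - 1) / n - x)))
}

# brute-force NNLS by active-set enumeration (small K only)
brute_nnls <- function(A, b) {
  K <- ncol(A)
  best <- NULL
  for (m in 0:(2^K - 1)) {
    S <- which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0)
    x <- rep(0, K)
    if (length(S) > 0) {
      As <- A[, S, drop = FALSE]
      xs <- tryCatch(solve(crossprod(As), crossprod(As, b)),
                     error = function(e) NULL)
      if (is.null(xs) || any(xs < 0)) next
      x[S] <- xs
    }
    rss <- sum((b - A %*% x)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(x = x, rss = rss)
  }
  best$x
}
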