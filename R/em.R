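#' Control parameters for the EM fit
#'
#' @param tol relative change in marginal log-likelihood below which the EM
#'   iteration stops. Default `1e-6`.
#' @param max_iter maximum number of EM iterations. Default 200.
#' @param floor lower bound applied to every variance component to keep the
#'   marginal covariance invertible. Default `1e-8`. A variance sitting at
#'   the floor at convergence is reported through the `boundary` flag.
#' @param floor_rel scale-relative lower bound on the residual variance:
#'   `sigma0^2` is floored at `max(floor, floor_rel * var(y))` (default
#'   `1e-6`). A residual variance collapsing to an absolute floor far below
#'   the data scale makes the marginal covariance numerically singular; the
#'   relative floor keeps it invertible at every data scale while adding
#'   negligible variance (one millionth of the response variance).
#' @param accelerate wrap the EM map in squared extrapolation (SQUAREM-type)
#'   with a monotonicity safeguard (default TRUE; only the compiled engine
#'   accelerates — the pure-R engine always runs the plain map). The
#'   accelerated and plain iterations share the same fixed points; the
#'   safeguard rejects any extrapolated step that would decrease the
#'   likelihood, so the ascent property is preserved.
#' @return list of class `"ctlmm_control"`.
#' @export
ctlmm_control <- function(tol = 1e-6, max_iter = 200L, floor = 1e-8,
                          floor_rel = 1e-6, accelerate = TRUE) {
  stopifnot(tol > 0, max_iter >= 1, floor > 0, floor_rel >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter), floor = floor,
                 floor_rel = floor_rel, accelerate = isTRUE(accelerate)),
            class = "ctlmm_control")
}

#' Starting values for the EM iteration
#'
#' Ordinary least squares of `y` on the fixed-effect design supplies the
#' initial coefficients; the OLS residual variance is split evenly between
#' the residual component (half) and the K random-effect components (half,
#' divided by K). All variances are floored.
#'
#' @param y numeric response vector.
#' @param design a [ct_design()].
#' @param floor variance floor for the random-effect components.
#' @param floor_s0 variance floor for the residual component (defaults to
#'   `floor`).
#' @return list with elements `beta`, `vc`.
#' @export
initialize_params <- function(y, design, floor = 1e-8, floor_s0 = floor) {
  X <- design$X
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("fixed-effect design is rank deficient (rank ", qr_x$rank,
            " < ", ncol(X), "); using a ridge-stabilized start")
    XtX <- crossprod(X)
    diag(XtX) <- diag(XtX) + 1e-6 * mean(diag(XtX))
    beta0 <- solve(XtX, crossprod(X, y))[, 1L]
  } else {
    beta0 <- qr.coef(qr_x, y)
  }
  res <- y - X %*% beta0
  s2 <- sum(res^2) / max(1, length(y) - ncol(X))
  vc <- variance_components(max(s2 / 2, floor_s0),
                            rep(max(s2 / 2 / design$K, floor), design$K))
  list(beta = as.numeric(beta0), vc = vc)
}

#' Posterior moments of the random effects (E-step)
#'
#' Conditioning the joint Gaussian of (y, u) on the observed y gives
#' `mu_p = Sigma_u A' V^-1 (y - X beta)` and
#' `Sigma_p = Sigma_u - Sigma_u A' V^-1 A Sigma_u`. Also returns the
#' expectations feeding the M-step: `expected_ssr = E[s's | y]` with
#' `s = A u + X beta - y`, and `expected_uku[k] = E[u_k' u_k | y]` per cell
#' type.
#'
#' @param y numeric response.
#' @param design a [ct_design()].
#' @param beta current fixed effects.
#' @param vc current [variance_components()].
#' @param keep_cov return the full Q x Q `Sigma_p` (subject-block-diagonal
#'   under subject grouping); set `FALSE` to skip its assembly.
#' @return list with `mu_p`, `Sigma_p` (or `NULL`), `expected_ssr`,
#'   `expected_uku`, and `tr_ASpA` (the trace term of `expected_ssr`).
#' @export
e_step <- function(y, design, beta, vc, keep_cov = TRUE) {
  J <- design$J; K <- design$K; Q <- design$Q
  r <- as.numeric(y - design$X %*% beta)
  sk <- vc$sigma_k_sq
  mu_p <- numeric(Q)
  Sigma_p <- if (keep_cov) matrix(0, Q, Q) else NULL
  tr_ASpA <- 0
  uku <- numeric(K)
  Amu <- numeric(design$N)
  for (j in seq_len(J)) {
    rows <- which(design$subj == j)
    Th <- design$theta[rows, , drop = FALSE]
    Vj <- Th %*% (sk * t(Th))
    diag(Vj) <- diag(Vj) + vc$sigma0_sq
    ch <- chol(Vj)
    w <- backsolve(ch, r[rows], transpose = TRUE)
    vinv_r <- backsolve(ch, w)
    muj <- sk * as.numeric(crossprod(Th, vinv_r))
    W <- backsolve(ch, Th, transpose = TRUE)
    Spj <- diag(sk, K) - tcrossprod(sk) * crossprod(W)
    idx <- (seq_len(K) - 1L) * J + j
    mu_p[idx] <- muj
    if (keep_cov) Sigma_p[idx, idx] <- Spj
    tr_ASpA <- tr_ASpA + sum((Th %*% Spj) * Th)
    uku <- uku + diag(Spj) + muj^2
    Amu[rows] <- Th %*% muj
  }
  expected_ssr <- tr_ASpA + sum((Amu - r)^2)
  list(mu_p = mu_p, Sigma_p = Sigma_p, expected_ssr = expected_ssr,
       expected_uku = uku, tr_ASpA = tr_ASpA, Amu = Amu)
}

#' Closed-form parameter updates (M-step)
#'
#' Updates the fixed effects by generalized least squares against the
#' posterior-mean-adjusted response, `beta = (X'X)^-1 X' (y - A mu_p)`, then
#' the variance components `sigma0^2 = E[s's|y]/N` (with the residual term of
#' `E[s's|y]` evaluated at the updated beta, the joint maximizer of the
#' expected complete-data log-likelihood) and `sigma_k^2 = E[u_k'u_k|y]/J`.
#'
#' @param y numeric response.
#' @param design a [ct_design()].
#' @param post output of [e_step()].
#' @param floor variance floor for the random-effect components.
#' @param floor_s0 variance floor for the residual component (defaults to
#'   `floor`).
#' @return list with updated `beta` and `vc`.
#' @export
m_step <- function(y, design, post, floor = 1e-8, floor_s0 = floor) {
  X <- design$X
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[seq(qx$rank + 1L, ncol(X))]
    stop("fixed-effect design is rank deficient; collinear or empty",
         " column(s): ", paste(colnames(X)[drop_idx], collapse = ", "))
  }
  beta <- qr.coef(qx, y - post$Amu)
  res <- y - X %*% beta - post$Amu
  ssr <- post$tr_ASpA + sum(res^2)
  vc <- variance_components(max(ssr / design$N, floor_s0),
                            pmax(post$expected_uku / design$J, floor))
  list(beta = beta, vc = vc)
}

# Pure-R EM loop mirroring src/em.cpp; reference implementation used for
# cross-validation of the compiled path.
fit_em_r <- function(y, design, control, init) {
  if (is.null(control$floor_s0)) control$floor_s0 <- control$floor
  beta <- init$beta
  vc <- init$vc
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  post <- NULL
  for (iter in seq_len(control$max_iter)) {
    post <- e_step(y, design, beta, vc, keep_cov = FALSE)
    ll <- marginal_loglik(y, design, beta, vc)
    if (!is.finite(ll)) {
      stop("non-finite marginal log-likelihood at EM iteration ", iter)
    }
    trace <- c(trace, ll)
    n_iter <- iter
    if (iter > 1L &&
        abs(ll - trace[iter - 1L]) < control$tol *
          (abs(trace[iter - 1L]) + 1e-8)) {
      converged <- TRUE
      break
    }
    upd <- m_step(y, design, post, floor = control$floor,
                  floor_s0 = control$floor_s0)
    beta <- upd$beta
    vc <- upd$vc
  }
  post <- e_step(y, design, beta, vc, keep_cov = FALSE)
  ll_final <- marginal_loglik(y, design, beta, vc)
  if (!converged || abs(ll_final - trace[length(trace)]) > 1e-12) {
    trace <- c(trace, ll_final)
  }
  list(beta = beta, sigma0_sq = vc$sigma0_sq, sigma_k_sq = vc$sigma_k_sq,
       mu_p = post$mu_p, loglik = ll_final, loglik_trace = trace,
       converged = converged, n_iter = n_iter,
       boundary = vc$sigma0_sq <= control$floor_s0 * (1 + 1e-6) ||
         any(vc$sigma_k_sq <= control$floor * (1 + 1e-6)))
}

#' Fit the cell-type mixed-effect deconvolution model for one gene
#'
#' Maximum-likelihood estimation of the model
#' \deqn{y = X\beta + A u + \varepsilon,\quad
#'   u \sim N(0, \Sigma_u),\ \varepsilon \sim N(0, \sigma_0^2 I)}
#' by expectation-maximization, where the fixed effects carry per-cell-type
#' baseline expression and group (and optionally covariate-slope and
#' group-by-covariate) contrasts weighted by cell-type proportions, and the
#' random effects are per-subject, per-cell-type deviations from the group
#' mean shared across that subject's repeated samples.
#'
#' @param y numeric length-N vector: one gene's expression across all samples
#'   (raw or normalized counts; any roughly Gaussian measurement works,
#'   including methylation values).
#' @param design a [ct_design()].
#' @param control a [ctlmm_control()].
#' @param init optional warm start: list with `beta` and `vc`
#'   ([variance_components()]); defaults to [initialize_params()].
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation); both run the identical algorithm.
#' @return object of class `"ctlmm"` with components `coefficients`, `vc`,
#'   `mu_p` (posterior random-effect means, cell-type-major), `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`, `boundary`, `design`, `y`.
#' @seealso [subject_panel()], [group_panel()], [csde()], [ct_design()]
#' @examples
#' sim <- simulate_dataset(sim_config(G = 1, J_per_group = 10, K = 2), seed = 1)
#' d <- ct_design(sim$meta, sim$proportions)
#' fit <- ctlmm(sim$counts[1, ], d)
#' fit
#' @export
ctlmm <- function(y, design, control = ctlmm_control(), init = NULL,
                  engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(design, "ct_design"))
  y <- as.numeric(y)
  if (length(y) != design$N) {
    stop("y has length ", length(y), " but the design has N = ", design$N,
         " samples")
  }
  if (any(!is.finite(y))) stop("y must be finite")
  floor_s0 <- max(control$floor, control$floor_rel * stats::var(y))
  control$floor_s0 <- floor_s0
  if (is.null(init)) {
    init <- initialize_params(y, design, control$floor, floor_s0)
  }
  init$vc$sigma0_sq <- max(init$vc$sigma0_sq, floor_s0)
  res <- if (engine == "cpp") {
    em_fit_cpp(y, design$X, design$theta, as.integer(design$subj), design$J,
               init$beta, init$vc$sigma0_sq, init$vc$sigma_k_sq,
               control$tol, control$max_iter, control$floor, floor_s0,
               control$accelerate)
  } else {
    fit_em_r(y, design, control, init)
  }
  beta <- as.numeric(res$beta)
  names(beta) <- colnames(design$X)
  mu_p <- as.numeric(res$mu)
  if (is.null(mu_p)) mu_p <- as.numeric(res$mu_p)
  names(mu_p) <- colnames(design$A)
  structure(list(coefficients = beta,
                 vc = variance_components(res$sigma0_sq,
                                          as.numeric(res$sigma_k_sq)),
                 mu_p = mu_p,
                 loglik = res$loglik,
                 loglik_trace = as.numeric(res$loglik_trace),
                 converged = isTRUE(res$converged),
                 n_iter = as.integer(res$n_iter),
                 boundary = isTRUE(res$boundary),
                 design = design, y = y, control = control,
                 engine = engine, call = match.call()),
            class = "ctlmm")
}

#' Fit the model gene-by-gene across an expression matrix
#'
#' All genes share one design; each gene is fitted independently from its own
#' OLS start (results are identical to separate [ctlmm()] calls and invariant
#' to gene order). Per-gene failures are collected, not fatal.
#'
#' @param Y numeric G x N matrix, genes as rows, samples as columns.
#' @param design a [ct_design()].
#' @param control a [ctlmm_control()].
#' @param engine see [ctlmm()].
#' @return object of class `"ctlmm_panel"`: list with `fits` (named list of
#'   `ctlmm` objects, `NULL` where a gene failed), `errors` (named character
#'   vector of failure messages), and the shared `design`.
#' @export
ctlmm_panel <- function(Y, design, control = ctlmm_control(),
                        engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  Y <- as.matrix(Y)
  if (ncol(Y) != design$N) {
    stop("expression matrix has ", ncol(Y), " columns but design has N = ",
         design$N)
  }
  genes <- rownames(Y)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(Y)))
  fits <- vector("list", nrow(Y))
  names(fits) <- genes
  errors <- character(0)
  for (g in seq_len(nrow(Y))) {
    fits[[g]] <- tryCatch(ctlmm(Y[g, ], design, control, engine = engine),
                          error = function(e) {
                            errors[[genes[g]]] <<- conditionMessage(e)
                            NULL
                          })
  }
  structure(list(fits = fits, errors = errors, design = design),
            class = "ctlmm_panel")
}

#' @export
print.ctlmm_panel <- function(x, ...) {
  ok <- sum(!vapply(x$fits, is.null, logical(1)))
  cat("ctlmm panel:", length(x$fits), "genes (", ok, "fitted,",
      length(x$errors), "failed )\n")
  invisible(x)
}

#' @export
print.ctlmm <- function(x, digits = 4, ...) {
  cat("Cell-type mixed-effect model (", x$design$model, " model), fit by EM\n",
      sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = digits),
      " iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat("Variance components: sigma0^2 =",
      format(x$vc$sigma0_sq, digits = digits), "\n  sigma_k^2:",
      paste(format(x$vc$sigma_k_sq, digits = digits), collapse = " "), "\n")
  if (x$boundary) cat("Note: a variance component is at the floor.\n")
  invisible(x)
}

#' @export
summary.ctlmm <- function(object, ...) {
  d <- object$design
  K <- d$K
  sp <- subject_panel(object)
  structure(list(fit = object,
                 cell_types = d$cell_types,
                 baseline = object$coefficients[d$xmap$block == "base"],
                 group_effect = object$coefficients[d$xmap$block == "group"],
                 vc = object$vc,
                 panel_range = range(sp$panel),
                 N = d$N, J = d$J, K = K),
            class = "summary.ctlmm")
}

#' @export
print.summary.ctlmm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  tab <- cbind(baseline = x$baseline, group = x$group_effect,
               sigma_k_sq = x$vc$sigma_k_sq)
  rownames(tab) <- x$cell_types
  cat("\nPer-cell-type effects:\n")
  print(round(tab, digits))
  cat("\nRecovered subject panel range: [",
      format(x$panel_range[1], digits = digits), ", ",
      format(x$panel_range[2], digits = digits), "]\n", sep = "")
  invisible(x)
}

#' @export
coef.ctlmm <- function(object, ...) object$coefficients

#' @export
logLik.ctlmm <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- length(object$coefficients) +
    length(object$vc$sigma_k_sq) + 1L
  attr(val, "nobs") <- object$design$N
  class(val) <- "logLik"
  val
}

#' @export
fitted.ctlmm <- function(object, ...) {
  d <- object$design
  as.numeric(d$X %*% object$coefficients + d$A %*% object$mu_p)
}

#' @export
residuals.ctlmm <- function(object, ...) object$y - fitted(object)

#' Predict from a fitted cell-type mixed model
#'
#' @param object a [ctlmm()] fit.
#' @param type `"panel"` for the individual-specific reference panel (see
#'   [subject_panel()]), `"group_panel"` for the two-row group-mean panel, or
#'   `"response"` for the fitted per-sample bulk values.
#' @param ... unused.
#' @export
predict.ctlmm <- function(object, type = c("panel", "group_panel", "response"),
                          ...) {
  type <- match.arg(type)
  switch(type,
         panel = subject_panel(object)$panel,
         group_panel = group_panel(object),
         response = fitted(object))
}

#' @export
simulate.ctlmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$design
  mean_fixed <- as.numeric(d$X %*% object$coefficients)
  out <- replicate(nsim, {
    u <- stats::rnorm(d$Q, 0, sqrt(sigma_u_diag(object$vc, d$J)))
    mean_fixed + as.numeric(d$A %*% u) +
      stats::rnorm(d$N, 0, sqrt(object$vc$sigma0_sq))
  })
  as.data.frame(out)
}

#' @export
plot.ctlmm <- function(x, ...) {
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b", pch = 16,
       xlab = "EM iteration", ylab = "marginal log-likelihood",
       main = "EM ascent", ...)
  invisible(x)
}
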