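#' Construct fixed- and random-effect design matrices for the deconvolution model
#'
#' Builds the design pair (X, A) of the cell-type mixed-effect regression
#' from a sample table and a sample-by-cell-type proportion matrix. The
#' fixed-effect matrix `X` carries, per cell type, a baseline column (the
#' proportions themselves) and a group-offset column (proportions multiplied
#' by the binary group flag); under the slope model each covariate
#' additionally contributes a slope block and a group-interaction block. The
#' random-effect matrix `A` has one column per (subject, cell type): that
#' subject's proportions for that cell type placed in its own rows, zeros
#' elsewhere, ordered cell-type-major then subject.
#'
#' @param meta data.frame with columns `sample_id`, `subject_id`, `time`
#'   (integer index of the repeated measure), `group` (0/1, constant within
#'   subject), plus any covariate columns.
#' @param proportions numeric matrix, samples x cell types, rows aligned with
#'   `meta` and summing to 1. Column names label the cell types.
#' @param model `"mean"` for the group-offset model or `"slope"` to add
#'   per-cell-type covariate slopes and group-by-covariate interactions.
#' @param covariates character vector of covariate column names in `meta`
#'   (required for the slope model; typically time or age). Covariates are
#'   mean-centered before entering the design; the centering constants are
#'   stored in the result.
#'
#' @return An object of class `"ct_design"`: a list with the design matrices
#'   `X` (N x P) and `A` (N x Q, Q = J*K), their column maps `xmap` and
#'   `amap`, the aligned proportion matrix `theta`, per-sample subject index
#'   `subj`, per-subject group flags `z_subject`, dimensions `N`, `J`, `K`,
#'   `P`, `Q`, the model kind, and covariate centering constants.
#' @examples
#' meta <- data.frame(sample_id = c("s1", "s2"), subject_id = "a",
#'                    time = 1:2, group = 1)
#' th <- rbind(c(0.3, 0.7), c(0.4, 0.6))
#' colnames(th) <- c("ct1", "ct2")
#' d <- ct_design(meta, th)
#' d$X
#' @export
ct_design <- function(meta, proportions, model = c("mean", "slope"),
                      covariates = NULL) {
  model <- match.arg(model)
  required <- c("sample_id", "subject_id", "time", "group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  proportions <- as.matrix(proportions)
  if (nrow(proportions) != nrow(meta)) {
    stop("proportion matrix has ", nrow(proportions),
         " rows but the sample table has ", nrow(meta),
         "; rows must align one sample per row")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata")
  }
  if (any(!is.finite(proportions)) || any(proportions < 0) ||
      any(proportions > 1 + 1e-8)) {
    stop("proportions must be finite and within [0, 1]")
  }
  rs <- rowSums(proportions)
  if (any(abs(rs - 1) > 1e-6)) {
    bad <- which(abs(rs - 1) > 1e-6)[1L]
    stop("proportion row ", bad, " sums to ", format(rs[bad]),
         "; rows must sum to 1 (tolerance 1e-6)")
  }
  # benign float drift: renormalize silently
  proportions <- proportions / rs
  if (any(colSums(proportions) == 0)) {
    zero_ct <- which(colSums(proportions) == 0)
    stop("cell type column(s) ", paste(zero_ct, collapse = ", "),
         " are identically zero; drop degenerate cell types before fitting")
  }
  K <- ncol(proportions)
  cts <- colnames(proportions)
  if (is.null(cts)) cts <- paste0("ct", seq_len(K))

  subjects <- unique(as.character(meta$subject_id))
  J <- length(subjects)
  subj <- match(as.character(meta$subject_id), subjects)
  N <- nrow(meta)

  grp <- as.numeric(meta$group)
  if (!all(grp %in% c(0, 1))) stop("group must be a binary 0/1 flag")
  z_subject <- vapply(seq_len(J), function(j) {
    zj <- unique(grp[subj == j])
    if (length(zj) != 1L) {
      stop("subject '", subjects[j], "' has non-constant group flag")
    }
    zj
  }, numeric(1))
  z_sample <- z_subject[subj]

  if (model == "slope") {
    if (is.null(covariates) || length(covariates) == 0L) {
      stop("the slope model requires at least one covariate (e.g. time or age)")
    }
    missing_cov <- setdiff(covariates, names(meta))
    if (length(missing_cov) > 0L) {
      stop("covariate column(s) not found in metadata: ",
           paste(missing_cov, collapse = ", "))
    }
    C <- as.matrix(meta[, covariates, drop = FALSE])
    storage.mode(C) <- "double"
    centers <- colMeans(C)
    C <- sweep(C, 2L, centers)
  } else {
    covariates <- character(0)
    C <- NULL
    centers <- numeric(0)
  }
  p <- length(covariates)

  base_block <- proportions
  colnames(base_block) <- paste0("base.", cts)
  group_block <- proportions * z_sample
  colnames(group_block) <- paste0("group.", cts)
  xmap <- data.frame(block = c(rep("base", K), rep("group", K)),
                     cell_type = c(cts, cts),
                     covariate = NA_character_,
                     stringsAsFactors = FALSE)
  if (model == "slope") {
    slope_block <- do.call(cbind, lapply(seq_len(p), function(i) {
      b <- proportions * C[, i]
      colnames(b) <- paste0("slope.", covariates[i], ".", cts)
      b
    }))
    inter_block <- do.call(cbind, lapply(seq_len(p), function(i) {
      b <- proportions * (C[, i] * z_sample)
      colnames(b) <- paste0("inter.", covariates[i], ".", cts)
      b
    }))
    X <- cbind(base_block, slope_block, group_block, inter_block)
    xmap <- data.frame(
      block = c(rep("base", K), rep("slope", K * p),
                rep("group", K), rep("inter", K * p)),
      cell_type = c(cts, rep(cts, p), cts, rep(cts, p)),
      covariate = c(rep(NA_character_, K), rep(covariates, each = K),
                    rep(NA_character_, K), rep(covariates, each = K)),
      stringsAsFactors = FALSE)
  } else {
    X <- cbind(base_block, group_block)
  }

  Q <- J * K
  A <- matrix(0, N, Q)
  amap <- data.frame(subject = rep(subjects, K),
                     cell_type = rep(cts, each = J),
                     stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    for (j in seq_len(J)) {
      rows <- which(subj == j)
      A[rows, (k - 1L) * J + j] <- proportions[rows, k]
    }
  }
  colnames(A) <- paste0(amap$cell_type, ".", amap$subject)

  structure(list(X = X, A = A, xmap = xmap, amap = amap,
                 theta = proportions, subj = subj, subjects = subjects,
                 z_subject = z_subject, cell_types = cts,
                 N = N, J = J, K = K, P = ncol(X), Q = Q,
                 model = model, covariates = covariates, centers = centers,
                 sample_id = as.character(meta$sample_id),
                 meta = meta),
            class = "ct_design")
}

#' @export
print.ct_design <- function(x, ...) {
  cat("Cell-type mixed-model design (", x$model, " model)\n", sep = "")
  cat("  samples N =", x$N, " subjects J =", x$J, " cell types K =", x$K, "\n")
  cat("  fixed effects P =", x$P, " random effects Q =", x$Q, "\n")
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "),
        "(mean-centered)\n")
  }
  invisible(x)
}

#' Variance components of the mixed model
#'
#' Container for the residual variance and the per-cell-type between-subject
#' random-effect variances that define the marginal covariance
#' V = A Sigma_u A' + sigma0^2 I, with Sigma_u block-diagonal
#' diag(sigma_1^2 I_J, ..., sigma_K^2 I_J).
#'
#' @param sigma0_sq residual variance, nonnegative scalar.
#' @param sigma_k_sq length-K vector of random-effect variances, nonnegative.
#' @return list of class `"variance_components"`.
#' @export
variance_components <- function(sigma0_sq, sigma_k_sq) {
  if (length(sigma0_sq) != 1L || !is.finite(sigma0_sq) || sigma0_sq < 0) {
    stop("sigma0_sq must be a single nonnegative number")
  }
  if (any(!is.finite(sigma_k_sq)) || any(sigma_k_sq < 0)) {
    stop("sigma_k_sq must be nonnegative")
  }
  structure(list(sigma0_sq = as.numeric(sigma0_sq),
                 sigma_k_sq = as.numeric(sigma_k_sq)),
            class = "variance_components")
}

# Sigma_u as a Q-vector of diagonal entries in the cell-type-major order of A.
sigma_u_diag <- function(vc, J) rep(vc$sigma_k_sq, each = J)

#' Marginal covariance of the observations
#'
#' Computes V = A Sigma_u A' + sigma0^2 I for a fitted or hypothesized set of
#' variance components. V is block-diagonal by subject because each column of
#' A touches a single subject's rows.
#'
#' @param vc a [variance_components()] object.
#' @param design a [ct_design()] object (or a plain matrix `A`, in which case
#'   the dense product is formed directly).
#' @return N x N symmetric positive semi-definite matrix.
#' @export
marginal_covariance <- function(vc, design) {
  A <- if (inherits(design, "ct_design")) design$A else as.matrix(design)
  J <- if (inherits(design, "ct_design")) design$J else {
    if (ncol(A) %% length(vc$sigma_k_sq) != 0)
      stop("cannot infer J from A; pass a ct_design")
    ncol(A) / length(vc$sigma_k_sq)
  }
  d <- sigma_u_diag(vc, J)
  V <- A %*% (d * t(A))
  diag(V) <- diag(V) + vc$sigma0_sq
  V
}

#' Marginal Gaussian log-likelihood of the mixed model
#'
#' Evaluates
#' \deqn{L(\beta,\sigma) = -\tfrac12\{N\ln(2\pi) + \ln|V| +
#'   (y - X\beta)' V^{-1} (y - X\beta)\}}
#' with V = A Sigma_u A' + sigma0^2 I, using the subject-block structure of V
#' (each subject contributes an independent T_j x T_j block).
#'
#' @param y numeric length-N response (one gene across all samples).
#' @param design a [ct_design()].
#' @param beta fixed-effect coefficient vector of length P.
#' @param vc a [variance_components()].
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(y, design, beta, vc) {
  stopifnot(inherits(design, "ct_design"))
  if (length(y) != design$N) stop("y has wrong length")
  if (length(beta) != design$P) stop("beta has wrong length")
  r <- as.numeric(y - design$X %*% beta)
  D <- vc$sigma_k_sq
  quad <- 0
  logdet <- 0
  for (j in seq_len(design$J)) {
    rows <- which(design$subj == j)
    Th <- design$theta[rows, , drop = FALSE]
    Vj <- Th %*% (D * t(Th))
    diag(Vj) <- diag(Vj) + vc$sigma0_sq
    ch <- tryCatch(chol(Vj), error = function(e) {
      stop("marginal covariance block for subject ", design$subjects[j],
           " is singular (sigma0_sq = ", vc$sigma0_sq, ")")
    })
    w <- backsolve(ch, r[rows], transpose = TRUE)
    quad <- quad + sum(w^2)
    logdet <- logdet + 2 * sum(log(diag(ch)))
  }
  -0.5 * (design$N * log(2 * pi) + logdet + quad)
}
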