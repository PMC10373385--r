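#' Likelihood-ratio test for cell-type-specific differential expression
#'
#' Fits the full model and the nested reduced model (the tested fixed-effect
#' column(s) removed from X) by EM and forms
#' \deqn{\Lambda = 2\,(L(\hat\beta,\hat\sigma) - L(\tilde\beta,\tilde\sigma))}
#' from the two maximized marginal log-likelihoods, referred to a chi-square
#' with degrees of freedom equal to the number of constrained coefficients.
#' Test kinds: `"mean"` tests the group offset `beta_k` in the mean model;
#' `"adjusted_mean"` tests the age-independent group offset in the slope
#' model; `"slope"` tests the group-by-covariate interaction (differential
#' change rate); `"joint"` tests all K group offsets at once (df = K).
#'
#' @param y numeric response for one gene.
#' @param design a [ct_design()] matching the test kind (`mean` model for
#'   `"mean"`/`"joint"`, `slope` model otherwise).
#' @param kind one of `"mean"`, `"slope"`, `"adjusted_mean"`, `"joint"`.
#' @param cell_index which cell type to test (ignored for `"joint"`).
#' @param control a [ctlmm_control()].
#' @param full_fit optional pre-computed full-model [ctlmm()] fit to reuse
#'   when several cell types are tested on one gene.
#' @param engine see [ctlmm()].
#' @return list with `statistic` (clipped at 0), `df`, `p_value`,
#'   `converged`, `flag` (non-`NA` when either fit failed to converge, in
#'   which case `p_value` is `NA`), and the two fits.
#' @export
lrt_test <- function(y, design, kind = c("mean", "slope", "adjusted_mean",
                                         "joint"),
                     cell_index = 1L, control = ctlmm_control(),
                     full_fit = NULL, engine = c("cpp", "R")) {
  kind <- match.arg(kind)
  engine <- match.arg(engine)
  drop_cols <- tested_columns(design, kind, cell_index)
  if (is.null(full_fit)) {
    full_fit <- ctlmm(y, design, control, engine = engine)
  }
  reduced_design <- drop_design_columns(design, drop_cols)
  init <- list(beta = full_fit$coefficients[-drop_cols],
               vc = full_fit$vc)
  reduced_fit <- ctlmm(y, reduced_design, control, init = init,
                       engine = engine)
  stat_raw <- 2 * (full_fit$loglik - reduced_fit$loglik)
  stat <- max(0, stat_raw)
  converged <- full_fit$converged && reduced_fit$converged
  flag <- NA_character_
  if (!converged) flag <- "non-convergent fit"
  if (converged && stat_raw < -1e-4) flag <- "negative LRT beyond tolerance"
  df <- length(drop_cols)
  p <- if (converged) stats::pchisq(stat, df = df, lower.tail = FALSE)
       else NA_real_
  list(statistic = stat, df = df, p_value = p,
       converged = converged, flag = flag,
       full_fit = full_fit, reduced_fit = reduced_fit)
}

# Columns of X constrained to zero under H0 for a given test kind.
tested_columns <- function(design, kind, cell_index) {
  xm <- design$xmap
  ct <- design$cell_types
  if (kind %in% c("mean", "adjusted_mean", "joint") &&
      kind != "joint" &&
      (cell_index < 1L || cell_index > design$K)) {
    stop("cell_index out of range 1..", design$K)
  }
  cols <- switch(kind,
    mean = {
      if (design$model != "mean") {
        stop("the mean test requires a design built with model = \"mean\"")
      }
      which(xm$block == "group" & xm$cell_type == ct[cell_index])
    },
    joint = {
      if (design$model != "mean") {
        stop("the joint test requires a design built with model = \"mean\"")
      }
      which(xm$block == "group")
    },
    adjusted_mean = {
      if (design$model != "slope") {
        stop("the adjusted-mean test requires a design built with model = \"slope\"")
      }
      which(xm$block == "group" & xm$cell_type == ct[cell_index])
    },
    slope = {
      if (design$model != "slope") {
        stop("the slope test requires a design built with model = \"slope\"")
      }
      which(xm$block == "inter" & xm$cell_type == ct[cell_index])
    })
  if (length(cols) == 0L) stop("no testable column found for kind ", kind)
  cols
}

# Reduced design: same random effects, X with the tested columns removed.
drop_design_columns <- function(design, cols) {
  out <- design
  out$X <- design$X[, -cols, drop = FALSE]
  out$xmap <- design$xmap[-cols, , drop = FALSE]
  out$P <- ncol(out$X)
  out
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up FDR control; missing p-values are excluded from the family and
#' propagate as missing q-values.
#'
#' @param p_values numeric vector in \[0, 1\] (NA allowed).
#' @param level target FDR (default 0.1).
#' @return list with `q_values` and logical `reject` (`q <= level`).
#' @export
bh_adjust <- function(p_values, level = 0.1) {
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= level)
}

#' Screen all genes for cell-type-specific differential expression
#'
#' Runs the likelihood-ratio test for every gene and every requested cell
#' type, reusing one full-model fit per gene across cell types, and applies
#' Benjamini-Hochberg correction within each cell type across genes (each
#' cell type is its own testing family).
#'
#' @param Y numeric G x N expression matrix (genes x samples), or a
#'   `bulk_study` / `sim_dataset` object.
#' @param design a [ct_design()] (required when `Y` is a matrix; otherwise
#'   built from the object's metadata and proportions).
#' @param kind test kind, see [lrt_test()].
#' @param cell_types integer indices of cell types to test (default all;
#'   ignored for `"joint"`).
#' @param fdr target FDR for the rejection flags (default 0.1).
#' @param control a [ctlmm_control()].
#' @param covariates covariate names for the slope-model kinds when the
#'   design is built internally (default `"time"`).
#' @param engine see [ctlmm()].
#' @return data.frame of class `"csde_result"` with columns `gene_id`,
#'   `cell_type`, `test`, `statistic`, `df`, `p`, `q`, `reject`, `flag`.
#' @examples
#' sim <- simulate_dataset(sim_config(G = 5, J_per_group = 8, K = 2,
#'                                    dirichlet_alpha_control = c(6, 4),
#'                                    dirichlet_alpha_case = c(4, 6),
#'                                    de_cell_types = 1), seed = 7)
#' res <- csde(sim, kind = "mean")
#' head(res)
#' @export
csde <- function(Y, design = NULL,
                 kind = c("mean", "slope", "adjusted_mean", "joint"),
                 cell_types = NULL, fdr = 0.1, control = ctlmm_control(),
                 covariates = "time", engine = c("cpp", "R")) {
  kind <- match.arg(kind)
  engine <- match.arg(engine)
  model <- if (kind %in% c("mean", "joint")) "mean" else "slope"
  if (inherits(Y, "sim_dataset") || inherits(Y, "bulk_study")) {
    obj <- Y
    meta <- obj$meta
    props <- obj$proportions
    Y <- if (inherits(obj, "sim_dataset")) obj$counts else obj$expression
    if (is.null(design)) {
      design <- ct_design(meta, props, model = model,
                          covariates = if (model == "slope") covariates)
    }
  }
  if (is.null(design)) stop("a ct_design is required when Y is a matrix")
  if (design$model != model) {
    stop("design model '", design$model, "' does not match test kind '",
         kind, "'")
  }
  Y <- as.matrix(Y)
  genes <- rownames(Y)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(Y)))
  if (kind == "joint") {
    cell_types <- NA_integer_
  } else if (is.null(cell_types)) {
    cell_types <- seq_len(design$K)
  }
  rows <- vector("list", nrow(Y) * length(cell_types))
  ri <- 0L
  for (g in seq_len(nrow(Y))) {
    y <- Y[g, ]
    full_fit <- tryCatch(ctlmm(y, design, control, engine = engine),
                         error = function(e) e)
    for (ci in cell_types) {
      ri <- ri + 1L
      if (inherits(full_fit, "error")) {
        rows[[ri]] <- data.frame(
          gene_id = genes[g],
          cell_type = if (kind == "joint") "all" else design$cell_types[ci],
          test = kind, statistic = NA_real_, df = NA_integer_, p = NA_real_,
          flag = conditionMessage(full_fit), stringsAsFactors = FALSE)
        next
      }
      lt <- tryCatch(
        lrt_test(y, design, kind, cell_index = ci, control = control,
                 full_fit = full_fit, engine = engine),
        error = function(e) e)
      rows[[ri]] <- if (inherits(lt, "error")) {
        data.frame(gene_id = genes[g],
                   cell_type = if (kind == "joint") "all"
                               else design$cell_types[ci],
                   test = kind, statistic = NA_real_, df = NA_integer_,
                   p = NA_real_, flag = conditionMessage(lt),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(gene_id = genes[g],
                   cell_type = if (kind == "joint") "all"
                               else design$cell_types[ci],
                   test = kind, statistic = lt$statistic, df = lt$df,
                   p = lt$p_value, flag = lt$flag, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$reject <- FALSE
  for (ct in unique(out$cell_type)) {
    sel <- out$cell_type == ct
    adj <- bh_adjust(out$p[sel], level = fdr)
    out$q[sel] <- adj$q_values
    out$reject[sel] <- adj$reject
  }
  out <- out[, c("gene_id", "cell_type", "test", "statistic", "df",
                 "p", "q", "reject", "flag")]
  class(out) <- c("csde_result", "data.frame")
  attr(out, "fdr") <- fdr
  out
}

#' Write a csDE result table to TSV
#'
#' @param x a `csde_result` (or any data.frame).
#' @param path output file path.
#' @export
write_csde <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
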