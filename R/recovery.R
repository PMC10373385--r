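#' Recover the individual-specific reference panel from a fit
#'
#' The recovered reference expression of subject j in cell type k is the sum
#' of the estimated cell-type baseline, the group offset for that subject's
#' group, and the subject's posterior-mean random effect:
#' `max(0, m_k + beta_k * z_j + u_jk)`. Negative values are truncated at
#' zero (estimation itself is unconstrained). For the slope model the panel
#' is reported at the centered-covariate reference point, where slope and
#' interaction terms vanish.
#'
#' @param fit a [ctlmm()] object.
#' @param allow_unconverged set `TRUE` to recover from a non-converged fit.
#' @return list of class `"subject_panel"`: `panel` (J x K matrix, subjects
#'   by cell types), `n_truncated` (entries clipped at zero), `model`.
#' @export
subject_panel <- function(fit, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "ctlmm"))
  if (!fit$converged && !allow_unconverged) {
    stop("fit did not converge; pass allow_unconverged = TRUE to override")
  }
  d <- fit$design
  m <- fit$coefficients[d$xmap$block == "base"]
  b <- fit$coefficients[d$xmap$block == "group"]
  u <- matrix(fit$mu_p, nrow = d$J, ncol = d$K)  # cell-type-major columns
  raw <- matrix(m, d$J, d$K, byrow = TRUE) +
    outer(d$z_subject, b) + u
  panel <- pmax(raw, 0)
  dimnames(panel) <- list(d$subjects, d$cell_types)
  structure(list(panel = panel, n_truncated = sum(raw < 0),
                 model = d$model),
            class = "subject_panel")
}

#' @export
print.subject_panel <- function(x, ...) {
  cat("Individual-specific reference panel:", nrow(x$panel), "subjects x",
      ncol(x$panel), "cell types (", x$n_truncated,
      "entries truncated at 0 )\n")
  print(utils::head(x$panel))
  invisible(x)
}

#' Group-mean reference panel (fixed-panel baseline)
#'
#' The two-row panel holding one reference per group: controls get the
#' baseline `m_k`, cases `m_k + beta_k`, truncated at zero. This is the
#' fixed-reference comparator used when benchmarking subject-level recovery.
#'
#' @param fit a [ctlmm()] object.
#' @return 2 x K matrix with rows `control` and `case`.
#' @export
group_panel <- function(fit) {
  stopifnot(inherits(fit, "ctlmm"))
  d <- fit$design
  m <- fit$coefficients[d$xmap$block == "base"]
  b <- fit$coefficients[d$xmap$block == "group"]
  out <- pmax(rbind(control = m, case = m + b), 0)
  colnames(out) <- d$cell_types
  out
}

#' Normalized mean squared error against a known truth
#'
#' `sum((estimate - truth)^2) / sum((truth - mean(truth))^2)`: squared error
#' normalized by the truth's centered sum of squares, so that predicting the
#' grand mean of the truth scores exactly 1.
#'
#' @param estimate,truth numeric arrays of identical shape.
#' @return scalar NMSE (>= 0).
#' @export
nmse <- function(estimate, truth) {
  estimate <- as.numeric(estimate)
  truth <- as.numeric(truth)
  if (length(estimate) != length(truth)) {
    stop("estimate and truth must have the same number of entries")
  }
  denom <- sum((truth - mean(truth))^2)
  if (denom <= .Machine$double.eps * length(truth)) {
    stop("truth is (numerically) constant; NMSE is undefined")
  }
  sum((estimate - truth)^2) / denom
}
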