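#' True discovery rate among top-ranked calls
#'
#' For each cutoff n in `top_grid`, the fraction of the n top-ranked items
#' that are truly positive (precision among the top n).
#'
#' @param ranking character (or integer) vector of item ids, best first.
#' @param truth vector of truly positive item ids.
#' @param top_grid cutoffs (default `seq(10, 200, by = 10)`); cutoffs beyond
#'   the ranking length are truncated to it.
#' @return data.frame with columns `n` and `tdr`.
#' @export
tdr_curve <- function(ranking, truth, top_grid = seq(10L, 200L, by = 10L)) {
  if (length(ranking) == 0L) stop("empty ranking")
  truncated <- any(top_grid > length(ranking))
  top_grid <- unique(pmin(top_grid, length(ranking)))
  hits <- cumsum(ranking %in% truth)
  out <- data.frame(n = top_grid, tdr = hits[top_grid] / top_grid)
  if (truncated) attr(out, "note") <- "top_grid truncated to ranking length"
  out
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive scores above a random
#' negative, with ties counted 1/2 (exact rank/concordance formula).
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels logical (or 0/1) truth per item; both classes must occur.
#' @return list with `auc` and `curve` (data.frame `fpr`, `tpr` over all
#'   score thresholds).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to form a ROC curve")
  }
  r <- rank(scores)  # midranks: ties get 1/2 credit
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

#' Sensitivity and false discovery rate of a rejection set
#'
#' `sensitivity = TP / #true` (NA when nothing is true) and
#' `FDR = FP / max(1, #rejections)` (so an empty rejection set has FDR 0).
#'
#' @param rejected logical vector of rejections.
#' @param truth logical vector of ground-truth positives, same length.
#' @return named numeric vector `c(sensitivity, fdr)`.
#' @export
sensitivity_fdr <- function(rejected, truth) {
  rejected <- as.logical(rejected)
  truth <- as.logical(truth)
  if (length(rejected) != length(truth)) stop("length mismatch")
  tp <- sum(rejected & truth)
  fp <- sum(rejected & !truth)
  sens <- if (sum(truth) == 0L) NA_real_ else tp / sum(truth)
  c(sensitivity = sens, fdr = fp / max(1L, sum(rejected)))
}

#' Kolmogorov-Smirnov test of p-value uniformity
#'
#' One-sample KS statistic of the empirical CDF against Uniform\[0, 1\].
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return list with `D` (sup deviation) and `p` (KS p-value).
#' @export
ks_uniformity <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values supplied")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  kt <- suppressWarnings(stats::ks.test(p_values, "punif"))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Rank genes for precision/ROC summaries
#'
#' Deterministic ranking of a csDE result: ascending p-value, ties broken by
#' descending LRT statistic, then by gene id.
#'
#' @param res a [csde()] result (one cell type's rows, typically).
#' @return the rows of `res` in rank order.
#' @export
rank_genes <- function(res) {
  res[order(res$p, -res$statistic, res$gene_id), , drop = FALSE]
}

#' Run the simulation study grid
#'
#' For every combination of log fold change and sample size, generates
#' `replicates` synthetic datasets, screens them for cell-type-specific
#' differential expression, optionally recovers reference panels, and
#' tabulates sensitivity, empirical FDR (at the BH level), AUC, and median
#' panel NMSE per replicate.
#'
#' @param lfc_grid numeric vector of log fold changes.
#' @param j_grid integer vector of subjects per group.
#' @param replicates datasets per scenario (default 20).
#' @param seed base seed; replicate r of scenario s uses a deterministic
#'   derived seed.
#' @param cfg_base a [sim_config()] supplying all other settings.
#' @param fdr BH level (default 0.1).
#' @param use_perturbed use surrogate estimated proportions instead of the
#'   truth.
#' @param panel_nmse also compute the median per-gene subject-panel NMSE
#'   (slower; default FALSE).
#' @param control,engine passed to the fitting routines.
#' @return data.frame with one row per scenario x replicate and columns
#'   `lfc`, `J`, `replicate`, `sensitivity`, `fdr`, `auc`, `nmse`
#'   (NA when not computed).
#' @export
run_scenario_grid <- function(lfc_grid, j_grid, replicates = 20L, seed = 1L,
                              cfg_base = sim_config(), fdr = 0.1,
                              use_perturbed = FALSE, panel_nmse = FALSE,
                              control = ctlmm_control(),
                              engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  out <- list()
  sidx <- 0L
  for (lfc in lfc_grid) for (J in j_grid) {
    sidx <- sidx + 1L
    for (r in seq_len(replicates)) {
      cfg <- cfg_base
      cfg$lfc <- lfc
      cfg$J_per_group <- as.integer(J)
      rep_seed <- gene_seed(seed, sidx * 10000L + r)
      sim <- simulate_dataset(cfg, seed = rep_seed)
      props <- if (use_perturbed) {
        perturb_proportions(sim, seed = rep_seed)
      } else sim$proportions
      design <- ct_design(sim$meta, props, model = "mean")
      res <- csde(sim$counts, design, kind = "mean", fdr = fdr,
                  control = control, engine = engine)
      truth_flags <- as.logical(sim$truth$de[cbind(
        match(res$gene_id, rownames(sim$counts)),
        match(res$cell_type, colnames(sim$truth$de)))])
      sf <- sensitivity_fdr(res$reject, truth_flags)
      auc <- if (any(truth_flags) && !all(truth_flags)) {
        stat <- ifelse(is.na(res$statistic), 0, res$statistic)
        roc_auc(stat, truth_flags)$auc
      } else NA_real_
      nm <- NA_real_
      if (panel_nmse) {
        nm <- median_panel_nmse(sim, design, control, engine)
      }
      out[[length(out) + 1L]] <- data.frame(
        lfc = lfc, J = J, replicate = r,
        sensitivity = sf[["sensitivity"]], fdr = sf[["fdr"]], auc = auc,
        nmse = nm)
    }
  }
  do.call(rbind, out)
}

# Median across genes of the per-gene subject-panel NMSE against the true
# references.
median_panel_nmse <- function(sim, design, control = ctlmm_control(),
                              engine = "cpp", genes = NULL,
                              panel_fun = subject_panel) {
  lam <- sim$truth$lambda
  if (length(dim(lam)) == 4L) lam <- apply(lam, c(1, 2, 3), mean)
  if (is.null(genes)) genes <- seq_len(nrow(sim$counts))
  vals <- vapply(genes, function(g) {
    fit <- tryCatch(ctlmm(sim$counts[g, ], design, control, engine = engine),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    est <- if (identical(panel_fun, subject_panel)) {
      subject_panel(fit, allow_unconverged = TRUE)$panel
    } else {
      gp <- group_panel(fit)
      gp[sim$truth$groups + 1L, , drop = FALSE]
    }
    tryCatch(nmse(est, lam[g, , ]), error = function(e) NA_real_)
  }, numeric(1))
  stats::median(vals, na.rm = TRUE)
}
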