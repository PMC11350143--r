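#' Hierarchical correlation score
#'
#' For each (dataset, cell type), the correlation between predicted and
#' ground-truth values across that dataset's samples is computed; these
#' correlations are averaged over cell types to give a per-dataset score,
#' and the per-dataset scores are averaged over datasets to give the
#' aggregate score. Cell types with undefined correlation (zero variance)
#' are recorded as missing and excluded from the cell-type mean, with a
#' count reported.
#'
#' @param predictions a `prediction_table`.
#' @param design an `admixture_design` with a `dataset` column in its meta.
#' @param metric `"pearson"` or `"spearman"`.
#' @param cell_types scored cell types (default: all predicted types that
#'   appear in the design, cancer excluded).
#' @return list with `score` (aggregate), `per_dataset`, `per_cell_type`
#'   (dataset x cell-type matrix of correlations), `n_undefined` and
#'   `metric`.
#' @export
hierarchical_score <- function(predictions, design,
                               metric = c("pearson", "spearman"),
                               cell_types = NULL) {
  metric <- match.arg(metric)
  truth <- design$proportions
  pred <- predictions$values
  stopifnot(nrow(pred) == nrow(truth))
  if (is.null(cell_types)) {
    cell_types <- setdiff(intersect(colnames(pred), colnames(truth)),
                          grep("^cancer", colnames(truth), value = TRUE))
  }
  missing <- setdiff(cell_types, colnames(pred))
  if (length(missing)) {
    stop("predictions do not cover scored cell types: ",
         paste(missing, collapse = ", "))
  }
  datasets <- unique(design$meta$dataset)
  per_ct <- matrix(NA_real_, nrow = length(datasets), ncol = length(cell_types),
                   dimnames = list(datasets, cell_types))
  for (d in datasets) {
    idx <- which(design$meta$dataset == d)
    if (length(idx) < 3) stop("dataset '", d, "' has fewer than 3 samples")
    for (ct in cell_types) {
      x <- pred[idx, ct]
      y <- truth[idx, ct]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined, stays NA
      per_ct[d, ct] <- stats::cor(x, y, method = metric)
    }
  }
  per_dataset <- rowMeans(per_ct, na.rm = TRUE)
  list(score = mean(per_dataset), per_dataset = per_dataset,
       per_cell_type = per_ct, n_undefined = sum(is.na(per_ct)),
       metric = metric)
}

#' Bootstrap Bayes-factor comparison of two methods
#'
#' Per bootstrap iteration, sample indices are resampled with replacement
#' separately within each dataset (one shared draw applied to both methods
#' and the truth, so the comparison is paired), the hierarchical Pearson
#' score of each method is recomputed, and the Bayes factor is
#' `K = #(S_a > S_b) / #(S_b > S_a)`. `K > threshold` (default 3) declares
#' a significant difference. With a zero denominator, `K` is `Inf` when the
#' numerator is positive and 1 (a tie) when both counts are zero.
#'
#' @param pred_a,pred_b `prediction_table`s for the two methods.
#' @param design an `admixture_design`.
#' @param n_boot number of bootstrap samples (default 1000).
#' @param seed optional integer seed.
#' @param metric correlation metric for the per-bootstrap scores.
#' @param threshold significance threshold on `K`.
#' @param cell_types scored cell types (see [hierarchical_score()]).
#' @return list with `K`, `wins_a`, `wins_b`, `ties`, `significant`,
#'   `scores_a`, `scores_b`.
#' @export
bootstrap_compare <- function(pred_a, pred_b, design, n_boot = 1000,
                              seed = NULL, metric = "pearson",
                              threshold = 3, cell_types = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  datasets <- unique(design$meta$dataset)
  idx_by_ds <- lapply(datasets, function(d) which(design$meta$dataset == d))
  scores_a <- scores_b <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_ds, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }))
    boot_design <- design
    boot_design$proportions <- design$proportions[take, , drop = FALSE]
    boot_design$meta <- design$meta[take, , drop = FALSE]
    pa <- pred_a; pa$values <- pred_a$values[take, , drop = FALSE]
    pb <- pred_b; pb$values <- pred_b$values[take, , drop = FALSE]
    scores_a[i] <- hierarchical_score(pa, boot_design, metric,
                                      cell_types = cell_types)$score
    scores_b[i] <- hierarchical_score(pb, boot_design, metric,
                                      cell_types = cell_types)$score
  }
  wins_a <- sum(scores_a > scores_b)
  wins_b <- sum(scores_b > scores_a)
  K <- if (wins_b == 0) {
    if (wins_a == 0) 1 else Inf
  } else {
    wins_a / wins_b
  }
  list(K = K, wins_a = wins_a, wins_b = wins_b,
       ties = n_boot - wins_a - wins_b,
       significant = K > threshold,
       scores_a = scores_a, scores_b = scores_b)
}

#' Rank methods by the two-stage score
#'
#' Methods are ordered by the primary Pearson-based aggregate score.
#' Methods statistically tied with the top performer (bootstrap Bayes
#' factor `K <= threshold`) are re-ordered among themselves by the
#' secondary Spearman-based score.
#'
#' @param predictions named list of `prediction_table`s.
#' @param design an `admixture_design`.
#' @param n_boot bootstrap samples for the tie assessment.
#' @param seed optional integer seed.
#' @param threshold Bayes-factor significance threshold.
#' @param cell_types scored cell types.
#' @return data.frame with method, pearson and spearman scores, tie flag
#'   and final rank, ordered by rank.
#' @export
rank_methods <- function(predictions, design, n_boot = 1000, seed = NULL,
                         threshold = 3, cell_types = NULL) {
  stopifnot(length(predictions) >= 1)
  methods <- names(predictions)
  r <- vapply(predictions, function(p)
    hierarchical_score(p, design, "pearson", cell_types)$score, numeric(1))
  rho <- vapply(predictions, function(p)
    hierarchical_score(p, design, "spearman", cell_types)$score, numeric(1))
  ord <- order(-r)
  tied <- rep(FALSE, length(methods))
  names(tied) <- methods
  tied[ord[1]] <- TRUE
  if (length(methods) > 1) {
    top <- ord[1]
    for (j in ord[-1]) {
      cmp <- bootstrap_compare(predictions[[top]], predictions[[j]], design,
                               n_boot = n_boot, seed = seed,
                               threshold = threshold, cell_types = cell_types)
      tied[j] <- !cmp$significant
    }
  }
  # re-order the top tie group by the secondary Spearman score
  final <- ord
  grp_idx <- ord[tied[ord]]
  if (length(grp_idx) > 1) {
    reordered <- grp_idx[order(-rho[grp_idx])]
    final[tied[ord]] <- reordered
  }
  out <- data.frame(method = methods[final],
                    pearson = unname(r[final]),
                    spearman = unname(rho[final]),
                    tied_with_top = unname(tied[final]),
                    rank = seq_along(final),
                    stringsAsFactors = FALSE)
  out
}

#' Within-sample (cross-cell type) metrics
#'
#' For every sample, the Pearson and Spearman correlation and the RMSE of
#' predicted versus true values across cell types; summaries are the
#' medians across samples. Score-scale prediction tables are rejected,
#' since raw scores are not comparable across cell types. Constant
#' prediction vectors yield missing correlations.
#'
#' @param predictions a `prediction_table` with scale `"normalized"`,
#'   `"fraction"` or `"proportion"`.
#' @param design an `admixture_design`.
#' @param cell_types cell types to compare (default: shared, non-cancer).
#' @return list with `per_sample` (data.frame: sample, pearson, spearman,
#'   rmse) and `summary` (medians).
#' @export
within_sample_metrics <- function(predictions, design, cell_types = NULL) {
  if (predictions$output_scale == "score") {
    stop("score-scale predictions are not comparable across cell types")
  }
  truth <- design$proportions
  pred <- predictions$values
  if (is.null(cell_types)) {
    cell_types <- setdiff(intersect(colnames(pred), colnames(truth)),
                          grep("^cancer", colnames(truth), value = TRUE))
  }
  P <- pred[, cell_types, drop = FALSE]
  Tm <- truth[, cell_types, drop = FALSE]
  per_sample <- data.frame(
    sample = rownames(Tm) %||% seq_len(nrow(Tm)),
    pearson = NA_real_, spearman = NA_real_, rmse = NA_real_)
  for (i in seq_len(nrow(Tm))) {
    x <- P[i, ]; y <- Tm[i, ]
    per_sample$rmse[i] <- sqrt(mean((x - y)^2))
    if (stats::sd(x) > 0 && stats::sd(y) > 0) {
      per_sample$pearson[i] <- stats::cor(x, y)
      per_sample$spearman[i] <- stats::cor(x, y, method = "spearman")
    }
  }
  list(per_sample = per_sample,
       summary = c(pearson = stats::median(per_sample$pearson, na.rm = TRUE),
                   spearman = stats::median(per_sample$spearman, na.rm = TRUE),
                   rmse = stats::median(per_sample$rmse, na.rm = TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Statistical ties on a within-sample metric
#'
#' Fits a linear model of the per-sample metric on method identity with the
#' top-ranked method as the reference level; methods whose coefficient
#' t-statistic p-value exceeds `alpha` are considered tied with the top
#' performer.
#'
#' @param metric_table data.frame with columns `method`, `sample`, `value`
#'   (per-sample metric values for every method).
#' @param top_method reference method name.
#' @param alpha tie threshold on the coefficient p-value (default 0.05).
#' @return character vector: the top method plus all methods tied with it.
#' @export
tie_test_within_sample <- function(metric_table, top_method, alpha = 0.05) {
  stopifnot(all(c("method", "value") %in% names(metric_table)))
  methods <- unique(metric_table$method)
  if (length(methods) < 2) stop("need at least 2 methods")
  if (sum(stats::complete.cases(metric_table$value)) < 2) {
    stop("need at least 2 samples")
  }
  metric_table$method <- stats::relevel(factor(metric_table$method),
                                        ref = top_method)
  fit <- stats::lm(value ~ method, data = metric_table)
  coefs <- summary(fit)$coefficients
  rows <- grep("^method", rownames(coefs), value = TRUE)
  p <- coefs[rows, "Pr(>|t|)"]
  names(p) <- sub("^method", "", rows)
  c(top_method, names(p)[p > alpha])
}

#' Consensus-rank ensemble prediction
#'
#' Per cell type, samples are ranked within each method (average ranks for
#' ties, larger prediction = larger rank) and the ensemble value is the
#' mean rank across methods. The output is a score-scale prediction table.
#'
#' @param prediction_tables named list of `prediction_table`s over common
#'   samples and cell types.
#' @return A `prediction_table` (method `"consensus"`, scale `"score"`).
#' @export
consensus_rank <- function(prediction_tables) {
  stopifnot(length(prediction_tables) >= 1)
  first <- prediction_tables[[1]]$values
  cts <- colnames(first)
  acc <- matrix(0, nrow = nrow(first), ncol = ncol(first),
                dimnames = dimnames(first))
  for (p in prediction_tables) {
    v <- p$values[, cts, drop = FALSE]
    stopifnot(nrow(v) == nrow(first))
    acc <- acc + apply(v, 2, rank)
  }
  prediction_table(acc / length(prediction_tables), "consensus", "score")
}

#' Cross-dataset effects on per-dataset correlations
#'
#' Per cell type, each method's per-dataset Pearson correlations are
#' centered by subtracting the method's mean across datasets; an ANOVA
#' `response ~ 0 + dataset` then estimates a per-dataset coefficient (the
#' mean centered correlation). One-sided lower-tail p-values test whether a
#' dataset's performance is below the method average, adjusted across all
#' (dataset, cell type) tests with Holm-Bonferroni; 95% confidence
#' intervals accompany the coefficients.
#'
#' @param per_dataset_correlations data.frame with columns `method`,
#'   `dataset`, `cell_type`, `r`.
#' @return data.frame with one row per (cell type, dataset): coefficient,
#'   raw and adjusted one-sided p, and the 95% CI.
#' @export
cross_dataset_effects <- function(per_dataset_correlations) {
  df <- per_dataset_correlations
  stopifnot(all(c("method", "dataset", "cell_type", "r") %in% names(df)))
  if (length(unique(df$dataset)) < 2) stop("need at least 2 datasets")
  out <- list()
  for (ct in unique(df$cell_type)) {
    sub <- df[df$cell_type == ct & !is.na(df$r), ]
    if (length(unique(sub$method)) < 2) {
      stop("cell type '", ct, "' has fewer than 2 methods")
    }
    centered <- stats::ave(sub$r, sub$method, FUN = mean)
    sub$centered <- sub$r - centered
    counts <- table(sub$dataset)
    singletons <- names(counts)[counts < 2]
    if (length(singletons)) {
      warning("datasets with a single observation excluded for '", ct, "': ",
              paste(singletons, collapse = ", "))
      sub <- sub[!(sub$dataset %in% singletons), ]
    }
    fit <- stats::lm(centered ~ 0 + dataset, data = sub)
    # a perfect fit (zero residual variance) is a legitimate degenerate case
    sm <- suppressWarnings(summary(fit)$coefficients)
    ci <- suppressWarnings(stats::confint(fit))
    tval <- sm[, "t value"]
    tval[is.nan(tval)] <- 0  # zero coefficient with zero residual variance
    res <- data.frame(cell_type = ct,
                      dataset = sub("^dataset", "", rownames(sm)),
                      coefficient = sm[, "Estimate"],
                      p_raw = stats::pt(tval,
                                        df = fit$df.residual, lower.tail = TRUE),
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
    out[[ct]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "holm")
  res
}
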