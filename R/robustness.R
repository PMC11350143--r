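#' Min-max normalized spillover matrix
#'
#' For predictions on the purified-sample panel, each cell type's
#' predictions are min-max normalized across the purified samples:
#' `(pred - min) / (max - min)`. Degenerate cell types (min equal to max,
#' e.g. a constant predictor) are set to 0 and flagged.
#'
#' @param predictions a `prediction_table` on the purified panel.
#' @param panel_design the purified panel's `admixture_design` (its meta
#'   must carry `purified_type`).
#' @return list of class `spillover_matrix` with `normalized` (sample x
#'   cell type), `purified_type` per sample, and `degenerate` flags.
#' @export
spillover_matrix <- function(predictions, panel_design) {
  vals <- predictions$values
  if (!nrow(vals)) stop("empty purified panel")
  rng <- apply(vals, 2, range)
  span <- rng[2, ] - rng[1, ]
  degenerate <- span <= 0
  norm <- sweep(vals, 2, rng[1, ], "-")
  norm <- sweep(norm, 2, ifelse(degenerate, 1, span), "/")
  norm[, degenerate] <- 0
  structure(list(normalized = norm,
                 purified_type = panel_design$meta$purified_type,
                 degenerate = degenerate,
                 method = predictions$method),
            class = "spillover_matrix")
}

#' Per cell-type spillover summary
#'
#' Spillover into cell type `X` is the normalized prediction for `X`
#' averaged over samples purified for any other type `Y != X`. When a
#' hierarchy is supplied, fine- and coarse-level spillovers are averaged
#' for cell types present in both panels.
#'
#' @param matrix a `spillover_matrix` (or a list of them, one per
#'   granularity, to average across sub-Challenges).
#' @param hierarchy optional [cell_type_hierarchy()].
#' @return named numeric vector of per-cell-type spillover.
#' @export
spillover_summary <- function(matrix, hierarchy = NULL) {
  one <- function(m) {
    norm <- m$normalized
    vapply(colnames(norm), function(ct) {
      off <- m$purified_type != ct
      if (!any(off)) return(NA_real_)
      mean(norm[off, ct])
    }, numeric(1))
  }
  if (inherits(matrix, "spillover_matrix")) return(one(matrix))
  # list of matrices (e.g. coarse + fine sub-Challenges): average shared types
  sums <- list()
  for (m in matrix) {
    s <- one(m)
    for (ct in names(s)) {
      sums[[ct]] <- c(sums[[ct]], s[[ct]])
    }
  }
  vapply(sums, function(v) mean(v, na.rm = TRUE), numeric(1))
}

#' Limit of detection from a spike-in series
#'
#' For each spike-in level `s > 0`, the method's predictions for the target
#' type at level `s` are compared with the baseline (0% spike-in)
#' predictions by a two-sided Wilcoxon rank-sum test. The limit of
#' detection is the least level `s` such that every level at and above `s`
#' is significant at `alpha` (raw, uncorrected); `NA` ("undetected") if no
#' such level exists.
#'
#' @param predictions a `prediction_table` on the spike-in series columns.
#' @param series the `series` data.frame from [make_spikein_series()] (or
#'   the full series object).
#' @param target target cell type column of the predictions.
#' @param alpha raw p-value cutoff (default 0.01).
#' @return list with `lod` (fraction or `NA`), `per_level` data.frame
#'   (level, p, significant) and `alpha`.
#' @export
limit_of_detection <- function(predictions, series, target = NULL, alpha = 0.01) {
  if (is.list(series) && !is.data.frame(series)) {
    if (is.null(target) && !is.null(series$target)) target <- series$target
    series <- series$series
  }
  if (is.null(target)) stop("target cell type must be given")
  vals <- predictions$values
  stopifnot(target %in% colnames(vals))
  x <- vals[series$column, target]
  levels <- sort(unique(series$level))
  if (levels[1] != 0) stop("baseline (0% spike-in) level missing")
  baseline <- x[series$level == 0]
  lv <- levels[-1]
  p <- vapply(lv, function(s) {
    at <- x[series$level == s]
    suppressWarnings(stats::wilcox.test(at, baseline, exact = NULL)$p.value)
  }, numeric(1))
  sig <- p < alpha
  # least level from which significance holds at every level upward
  lod <- NA_real_
  run <- rev(cumprod(rev(sig)))  # 1 where all levels >= this one significant
  if (any(run == 1)) lod <- lv[which(run == 1)[1]]
  list(lod = lod,
       per_level = data.frame(level = lv, p = p, significant = sig),
       alpha = alpha, target = target)
}
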