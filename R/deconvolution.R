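#' Prediction tables
#'
#' All deconvolution methods return a `prediction_table`: a sample x
#' cell-type matrix of values plus a method name and an output-scale tag.
#' The tag gates which downstream metrics apply: `"score"` outputs are only
#' comparable across samples within a cell type; `"normalized"`,
#' `"fraction"` and `"proportion"` outputs can also be compared across cell
#' types within a sample.
#'
#' @param values sample x cell-type numeric matrix.
#' @param method method name.
#' @param output_scale one of `"score"`, `"normalized"`, `"fraction"`,
#'   `"proportion"`.
#' @return A `prediction_table`.
#' @export
prediction_table <- function(values, method,
                             output_scale = c("score", "normalized",
                                              "fraction", "proportion")) {
  output_scale <- match.arg(output_scale)
  values <- as.matrix(values)
  if (output_scale %in% c("fraction", "proportion") && any(values < -1e-9)) {
    stop("negative entries in a ", output_scale, "-scale prediction table")
  }
  if (output_scale == "proportion" &&
      any(rowSums(values) > 1 + 1e-6)) {
    stop("proportion-scale rows must sum to at most 1")
  }
  structure(list(values = values, method = method, output_scale = output_scale),
            class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, ...) {
  cat("prediction_table '", x$method, "' (", x$output_scale, "): ",
      nrow(x$values), " samples x ", ncol(x$values), " cell types\n", sep = "")
  invisible(x)
}

#' Build a signature matrix and marker sets from purified profiles
#'
#' Per cell type, genes are ranked by the fold change of their mean linear
#' expression in that type over their mean in all other types; up to
#' `markers_per_type` genes with fold change at least `min_fold` are kept.
#' The specificity filter drops genes qualifying for more than one type.
#' Signature entries are the per-type mean linear expression of the
#' selected markers.
#'
#' @param profiles a `profile_library`.
#' @param markers_per_type maximum markers per cell type.
#' @param min_fold minimum own/other mean fold change.
#' @param specificity_filter drop genes qualifying for several types.
#' @param types cell types to include (default: all non-cancer types).
#' @return list with `signature` (marker x type matrix) and `marker_sets`
#'   (per-type character vectors).
#' @export
build_signature <- function(profiles, markers_per_type = 20, min_fold = 2,
                            specificity_filter = TRUE,
                            types = setdiff(unique(profiles$sample_meta$cell_type),
                                            grep("^cancer", unique(profiles$sample_meta$cell_type),
                                                 value = TRUE))) {
  if (length(types) < 2) stop("need at least 2 cell types")
  meta <- profiles$sample_meta
  type_mean <- vapply(types, function(ct) {
    rowMeans(profiles$tpm[, meta$sample_id[meta$cell_type == ct], drop = FALSE])
  }, numeric(length(profiles$genes)))
  eps <- 1e-8
  qualifies <- matrix(FALSE, nrow = nrow(type_mean), ncol = length(types),
                      dimnames = dimnames(type_mean))
  fold <- qualifies + 0
  for (j in seq_along(types)) {
    other <- rowMeans(type_mean[, -j, drop = FALSE])
    fold[, j] <- (type_mean[, j] + eps) / (other + eps)
    qualifies[, j] <- fold[, j] >= min_fold
  }
  if (specificity_filter) {
    qualifies[rowSums(qualifies) > 1L, ] <- FALSE
  }
  marker_sets <- lapply(seq_along(types), function(j) {
    cand <- which(qualifies[, j])
    if (!length(cand)) {
      stop("no gene passes the marker criteria for type '", types[j], "'")
    }
    cand <- cand[order(fold[cand, j], decreasing = TRUE)]
    rownames(type_mean)[cand[seq_len(min(length(cand), markers_per_type))]]
  })
  names(marker_sets) <- types
  markers <- unique(unlist(marker_sets))
  signature <- type_mean[markers, , drop = FALSE]
  list(signature = signature, marker_sets = marker_sets)
}

.check_admixture <- function(admixture) {
  if (inherits(admixture, "admixture_dataset")) admixture$expression
  else as.matrix(admixture)
}

#' Marker-summary (enrichment) deconvolution
#'
#' Scores cell type `c` in a sample as the mean (or sum) of the sample's
#' linear expression over the type's marker genes. Scores are comparable
#' across samples within a cell type only.
#'
#' @param admixture an `admixture_dataset` or gene x sample matrix (linear
#'   space).
#' @param marker_sets per-type marker gene lists.
#' @param reducer `"mean"` or `"sum"`.
#' @return A `prediction_table` with `output_scale = "score"`.
#' @export
deconvolve_marker_summary <- function(admixture, marker_sets,
                                      reducer = c("mean", "sum")) {
  reducer <- match.arg(reducer)
  expr <- .check_admixture(admixture)
  fn <- if (reducer == "mean") colMeans else colSums
  vals <- vapply(names(marker_sets), function(ct) {
    mk <- marker_sets[[ct]]
    present <- intersect(mk, rownames(expr))
    if (!length(present)) stop("no markers of '", ct, "' in the admixture genes")
    if (length(present) < length(mk)) {
      warning(length(mk) - length(present), " markers of '", ct,
              "' absent from the admixture; dropped")
    }
    fn(expr[present, , drop = FALSE])
  }, numeric(ncol(expr)))
  if (ncol(expr) == 1L) vals <- matrix(vals, nrow = 1,
                                       dimnames = list(colnames(expr), names(marker_sets)))
  prediction_table(vals, paste0("marker_", reducer), "score")
}

#' Constrained (weighted) least-squares deconvolution
#'
#' Per sample solves `argmin_b sum_m w_m (a_m - s_m . b)^2` subject to
#' `b >= 0` and `sum(b) <= 1`. Unit weights give the plain constrained
#' least-squares variant; supplied per-marker weights give the weighted
#' variant. The sum constraint is enforced through a slack population and a
#' heavily weighted equality row solved with non-negative least squares.
#'
#' @param admixture an `admixture_dataset` or gene x sample matrix.
#' @param signature marker x cell-type signature matrix.
#' @param weights optional per-marker weights `w_m`.
#' @return A `prediction_table` with `output_scale = "proportion"`.
#' @export
deconvolve_cls <- function(admixture, signature, weights = NULL) {
  expr <- .check_admixture(admixture)
  S <- as.matrix(signature)
  if (qr(S)$rank < ncol(S)) {
    warning("signature columns are not linearly independent")
  }
  markers <- intersect(rownames(S), rownames(expr))
  if (length(markers) < ncol(S)) stop("fewer usable markers than cell types")
  S <- S[markers, , drop = FALSE]
  A <- expr[markers, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, length(markers)) else {
    stopifnot(length(weights) == length(markers) || !is.null(names(weights)))
    if (!is.null(names(weights))) weights[markers] else weights
  }
  sw <- sqrt(w)
  k <- ncol(S)
  # sum constraint through a slack population plus a heavily weighted
  # equality row; the weight steps down if the active-set solver stalls
  solve_one <- function(y) {
    for (mufac in c(1e3, 1e2, 10)) {
      mu <- mufac * max(abs(S) * sw)
      D <- rbind(cbind(S * sw, 0), c(rep(mu, k), mu))
      fit <- tryCatch(pracma::lsqnonneg(D, c(y, mu)), error = function(e) NULL)
      if (!is.null(fit)) return(fit$x[seq_len(k)])
    }
    stop("constrained least-squares solver did not converge")
  }
  vals <- t(vapply(seq_len(ncol(A)), function(j) solve_one(A[, j] * sw),
                   numeric(k)))
  dimnames(vals) <- list(colnames(A), colnames(S))
  vals[vals < 0] <- 0
  vals <- vals / pmax(1, rowSums(vals))  # guard against slack round-off
  prediction_table(vals, if (is.null(weights)) "cls" else "wcls", "proportion")
}

#' nu-SVR deconvolution
#'
#' Per sample, the admixture over the signature markers and the signature
#' entries (vectorized) are each scaled to zero mean and unit variance; a
#' linear nu-support-vector regression of the scaled admixture on the
#' scaled signature columns is fitted for each `nu` in `nu_grid`, the fit
#' with the lowest root-mean-square residual is kept, and negative
#' coefficients are clipped to zero.
#'
#' @param admixture an `admixture_dataset` or gene x sample matrix.
#' @param signature marker x cell-type signature matrix.
#' @param nu_grid candidate `nu` values.
#' @param cost SVR cost parameter `C`.
#' @return A `prediction_table` with `output_scale = "fraction"`.
#' @export
deconvolve_nusvr <- function(admixture, signature,
                             nu_grid = c(0.25, 0.5, 0.75), cost = 1) {
  expr <- .check_admixture(admixture)
  S <- as.matrix(signature)
  markers <- intersect(rownames(S), rownames(expr))
  if (length(markers) < 2) stop("need at least 2 markers")
  S <- S[markers, , drop = FALSE]
  Sz <- (S - mean(S)) / stats::sd(S)
  A <- expr[markers, , drop = FALSE]
  k <- ncol(S)
  vals <- t(vapply(seq_len(ncol(A)), function(j) {
    a <- A[, j]
    if (stats::sd(a) == 0) {
      stop("admixture column ", colnames(A)[j],
           " is constant over the markers")
    }
    az <- (a - mean(a)) / stats::sd(a)
    best <- NULL
    best_rmse <- Inf
    for (nu in nu_grid) {
      fit <- e1071::svm(x = Sz, y = az, type = "nu-regression",
                        kernel = "linear", nu = nu, cost = cost, scale = FALSE)
      beta <- drop(t(fit$coefs) %*% fit$SV)
      rmse <- sqrt(mean((az - stats::predict(fit, Sz))^2))
      if (rmse < best_rmse) {
        best_rmse <- rmse
        best <- beta
      }
    }
    pmax(best, 0)
  }, numeric(k)))
  dimnames(vals) <- list(colnames(A), colnames(S))
  prediction_table(vals, "nusvr", "fraction")
}

#' Huber robust-regression deconvolution
#'
#' Iteratively reweighted least squares with Huber weights
#' (`w(e) = 1` if `|e| < k`, else `k/|e|`) of the admixture on the
#' signature columns, as in robust linear modeling; negative coefficients
#' are clipped to zero on output.
#'
#' @param admixture an `admixture_dataset` or gene x sample matrix.
#' @param signature marker x cell-type signature matrix.
#' @param k Huber tuning constant (in residual scale units).
#' @param maxit maximum IRLS iterations.
#' @return A `prediction_table` with `output_scale = "fraction"`.
#' @export
deconvolve_huber <- function(admixture, signature, k = 1.345, maxit = 100) {
  expr <- .check_admixture(admixture)
  S <- as.matrix(signature)
  markers <- intersect(rownames(S), rownames(expr))
  S <- S[markers, , drop = FALSE]
  A <- expr[markers, , drop = FALSE]
  vals <- t(vapply(seq_len(ncol(A)), function(j) {
    y <- A[, j]
    ols <- qr.coef(qr(S), y)
    resid <- y - drop(S %*% ols)
    if (max(abs(resid)) < 1e-8 * max(abs(y), 1)) {
      return(unname(ols))  # exact fit: Huber weights are all 1
    }
    fit <- MASS::rlm(x = S, y = y, psi = MASS::psi.huber, k = k,
                     maxit = maxit)
    if (!fit$converged) {
      stop("Huber IRLS did not converge within ", maxit, " iterations")
    }
    unname(fit$coefficients)
  }, numeric(ncol(S))))
  dimnames(vals) <- list(colnames(A), colnames(S))
  vals[vals < 0] <- 0
  prediction_table(vals, "huber", "fraction")
}

#' Oracle method: predictions equal the ground truth
#'
#' Perfect predictor used by harness self-tests: its hierarchical score is
#' 1, its spillover 0 and its limit of detection the smallest nonzero grid
#' level.
#'
#' @param design an `admixture_design`.
#' @param types optional subset/order of cell types to report.
#' @return A `prediction_table` with `output_scale = "proportion"`.
#' @export
oracle_method <- function(design, types = colnames(design$proportions)) {
  prediction_table(design$proportions[, types, drop = FALSE],
                   "oracle", "proportion")
}
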