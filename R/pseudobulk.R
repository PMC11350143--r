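#' Pseudo-bulk admixtures from a single-cell fixture
#'
#' Per patient, cells are mapped into panel types via `type_map` (unmapped
#' annotations are dropped) and the ground-truth proportions are the mapped
#' cell-count frequencies. Raw gene counts are summed over cells sharing an
#' annotation within a patient, each (patient, type) profile is normalized
#' to the maximum pair total, and the pseudo-bulk sample is the
#' frequency-weighted sum of the normalized per-type profiles, finally
#' scaled to counts per million.
#'
#' Quality control: the normalized (patient, type) profiles restricted to
#' `qc_genes` are embedded in two dimensions (first two principal components
#' of the log1p-CPM profiles by default; any function returning an n x 2
#' matrix can be plugged in) and a profile whose `k_neighbors` nearest
#' neighbors' majority annotation differs from its own flags the patient,
#' which is then excluded.
#'
#' @param fixture a `single_cell_fixture`.
#' @param type_map named character vector mapping fixture annotations to
#'   panel types; annotations absent from it are dropped. `NULL` keeps
#'   annotations as-is.
#' @param qc_genes genes used for the QC embedding (default: all).
#' @param k_neighbors neighborhood size for the QC majority vote.
#' @param embed function(matrix) -> n x 2 embedding; default PCA.
#' @param run_qc set `FALSE` to skip QC (e.g. too few profiles).
#' @return An `admixture_dataset` (scale `"cpm"`, one column per retained
#'   patient) with extra fields `flagged` (patient/type pairs failing QC)
#'   and `excluded_patients`.
#' @export
pseudobulk_from_sc <- function(fixture, type_map = NULL,
                               qc_genes = NULL, k_neighbors = 10,
                               embed = NULL, run_qc = TRUE) {
  meta <- fixture$cell_meta
  ann <- meta$cell_type
  if (!is.null(type_map)) {
    mapped <- type_map[ann]
    keep <- !is.na(mapped)
    meta <- meta[keep, , drop = FALSE]
    meta$cell_type <- unname(mapped[keep])
  }
  if (!nrow(meta)) stop("no cells left after type mapping")
  dropped <- setdiff(unique(fixture$cell_meta$patient), unique(meta$patient))
  if (length(dropped)) {
    warning("patients with zero mapped cells excluded: ",
            paste(dropped, collapse = ", "))
  }
  counts <- fixture$counts[, meta$cell_id, drop = FALSE]

  # sum raw counts over cells sharing (patient, type)
  grp <- paste(meta$patient, meta$cell_type, sep = "\r")
  grp_levels <- unique(grp)
  agg <- vapply(grp_levels, function(g) {
    rowSums(counts[, grp == g, drop = FALSE])
  }, numeric(nrow(counts)))
  grp_meta <- data.frame(
    patient = sub("\r.*", "", grp_levels),
    cell_type = sub(".*\r", "", grp_levels),
    n_cells = as.vector(table(grp)[grp_levels]),
    stringsAsFactors = FALSE)

  # normalize every (patient, type) profile to the maximum pair total
  totals <- colSums(agg)
  norm <- sweep(agg, 2, max(totals) / totals, "*")

  flagged <- grp_meta[0, ]
  if (run_qc && ncol(norm) > k_neighbors) {
    sub <- if (is.null(qc_genes)) norm else norm[intersect(qc_genes, rownames(norm)), , drop = FALSE]
    logcpm <- log1p(sweep(sub, 2, 1e6 / colSums(sub), "*"))
    emb <- if (is.null(embed)) {
      stats::prcomp(t(logcpm), rank. = 2)$x[, 1:2, drop = FALSE]
    } else {
      embed(t(logcpm))
    }
    d <- as.matrix(stats::dist(emb))
    diag(d) <- Inf
    bad <- vapply(seq_len(ncol(norm)), function(i) {
      nn <- order(d[i, ])[seq_len(k_neighbors)]
      votes <- table(grp_meta$cell_type[nn])
      names(votes)[which.max(votes)] != grp_meta$cell_type[i]
    }, logical(1))
    flagged <- grp_meta[bad, , drop = FALSE]
  }
  excluded <- unique(flagged$patient)
  keep_grp <- !(grp_meta$patient %in% excluded)
  if (!any(keep_grp)) stop("all patients excluded by QC")

  patients <- unique(grp_meta$patient[keep_grp])
  types <- sort(unique(grp_meta$cell_type[keep_grp]))
  props <- matrix(0, nrow = length(patients), ncol = length(types),
                  dimnames = list(patients, types))
  expr <- matrix(0, nrow = nrow(norm), ncol = length(patients),
                 dimnames = list(rownames(norm), patients))
  for (pt in patients) {
    rows <- which(grp_meta$patient == pt & keep_grp)
    freq <- grp_meta$n_cells[rows] / sum(grp_meta$n_cells[rows])
    props[pt, grp_meta$cell_type[rows]] <- freq
    expr[, pt] <- norm[, rows, drop = FALSE] %*% freq
  }
  expr <- sweep(expr, 2, 1e6 / colSums(expr), "*")  # CPM
  dmeta <- data.frame(dataset = "pseudobulk", cancer_type = NA_character_,
                      batch = "sc", origin = "pseudobulk",
                      design_class = "pseudobulk", stringsAsFactors = FALSE)
  dmeta <- dmeta[rep(1, length(patients)), , drop = FALSE]
  design <- admixture_design(props, dmeta, granularity = "fine")
  out <- structure(list(expression = expr, design = design, scale = "cpm",
                        flagged = flagged, excluded_patients = excluded),
                   class = "admixture_dataset")
  out
}
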