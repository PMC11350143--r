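#' Cell-type hierarchy for the deconvolution panel
#'
#' Defines the mapping between the fine-grained panel (14 immune and stromal
#' sub-populations) and the coarse-grained panel (8 major populations), plus
#' the cancer cell types used as the non-scored "contaminating" compartment.
#'
#' @param fine_types character vector of fine-grained population names.
#' @param coarse_of named character vector mapping each fine type to its
#'   coarse parent.
#' @param cancer_types character vector of cancer cell-type names. Cancer is
#'   excluded from both scored panels.
#' @return An object of class `cell_type_hierarchy` with fields `fine_types`,
#'   `coarse_types`, `coarse_of`, `cancer_types` and `levels` (a named factor
#'   tagging every node as `"coarse"`, `"fine"` or `"non_immune"`).
#' @export
cell_type_hierarchy <- function(fine_types, coarse_of, cancer_types = character()) {
  stopifnot(is.character(fine_types), length(fine_types) >= 1)
  if (!all(fine_types %in% names(coarse_of))) {
    stop("every fine type must map to exactly one coarse type; missing: ",
         paste(setdiff(fine_types, names(coarse_of)), collapse = ", "))
  }
  coarse_of <- coarse_of[fine_types]
  coarse_types <- unique(unname(coarse_of))
  non_immune <- c("endothelial", "fibroblast")
  levels <- c(
    stats::setNames(rep("coarse", length(coarse_types)), coarse_types),
    stats::setNames(
      ifelse(fine_types %in% non_immune, "non_immune", "fine"), fine_types)
  )
  structure(
    list(fine_types = fine_types,
         coarse_types = coarse_types,
         coarse_of = coarse_of,
         cancer_types = cancer_types,
         levels = levels),
    class = "cell_type_hierarchy")
}

#' Default benchmark hierarchy
#'
#' The 14 fine-grained populations of the fine-grained panel (memory/naive B,
#' memory/naive/regulatory CD4 T, memory/naive CD8 T, NK, neutrophils,
#' monocytes, macrophages, myeloid dendritic cells, endothelial cells and
#' fibroblasts), their aggregation into 8 coarse populations, and the two
#' cancer cell lines (breast and colorectal) used as admixture backbone.
#'
#' @return A `cell_type_hierarchy`.
#' @export
default_hierarchy <- function() {
  coarse_of <- c(
    memory_B       = "B_cells",
    naive_B        = "B_cells",
    memory_CD4_T   = "CD4_T_cells",
    naive_CD4_T    = "CD4_T_cells",
    Treg           = "CD4_T_cells",
    memory_CD8_T   = "CD8_T_cells",
    naive_CD8_T    = "CD8_T_cells",
    NK             = "NK_cells",
    neutrophil     = "neutrophils",
    monocyte       = "monocytic_lineage",
    macrophage     = "monocytic_lineage",
    dendritic      = "monocytic_lineage",
    endothelial    = "endothelial",
    fibroblast     = "fibroblast")
  cell_type_hierarchy(
    fine_types = names(coarse_of),
    coarse_of = coarse_of,
    cancer_types = c("cancer_BRCA", "cancer_CRC"))
}

#' Admixture panels derived from a hierarchy
#'
#' The in silico mixing panel excludes memory B cells (no purified material
#' was modelled for them); the in vitro-style design panel retains all 14
#' fine types.
#'
#' @param hierarchy a `cell_type_hierarchy`.
#' @param kind `"in_silico"` or `"in_vitro"`.
#' @return character vector of non-cancer fine types to mix over.
#' @export
admixture_panel <- function(hierarchy, kind = c("in_silico", "in_vitro")) {
  kind <- match.arg(kind)
  types <- hierarchy$fine_types
  if (kind == "in_silico") types <- setdiff(types, "memory_B")
  types
}

#' @export
print.cell_type_hierarchy <- function(x, ...) {
  cat("cell_type_hierarchy:", length(x$fine_types), "fine types,",
      length(x$coarse_types), "coarse types,",
      length(x$cancer_types), "cancer types\n")
  invisible(x)
}

#' Aggregate a fine-grained proportion matrix to coarse populations
#'
#' Coarse proportions are the sums of their fine-grained children; row sums
#' are preserved exactly.
#'
#' @param props admixture x fine-type proportion matrix (may include cancer
#'   columns, which are carried through unchanged).
#' @param hierarchy a `cell_type_hierarchy`.
#' @return admixture x coarse-type matrix (cancer columns last).
#' @export
aggregate_to_coarse <- function(props, hierarchy) {
  fine_cols <- intersect(colnames(props), hierarchy$fine_types)
  missing <- setdiff(fine_cols, names(hierarchy$coarse_of))
  if (length(missing)) {
    stop("fine types missing from hierarchy: ", paste(missing, collapse = ", "))
  }
  groups <- hierarchy$coarse_of[fine_cols]
  coarse <- vapply(hierarchy$coarse_types, function(ct) {
    cols <- fine_cols[groups == ct]
    if (length(cols) == 1L) props[, cols] else rowSums(props[, cols, drop = FALSE])
  }, numeric(nrow(props)))
  if (nrow(props) == 1L) coarse <- matrix(coarse, nrow = 1,
                                          dimnames = list(rownames(props), hierarchy$coarse_types))
  extra <- setdiff(colnames(props), hierarchy$fine_types)
  if (length(extra)) coarse <- cbind(coarse, props[, extra, drop = FALSE])
  rownames(coarse) <- rownames(props)
  coarse
}
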