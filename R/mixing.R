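#' Pick one representative purified profile per (cell type, batch)
#'
#' A mixture column uses the replicate profile whose batch matches the
#' design's batch label; the first replicate wins ties.
#' @noRd
.profile_for <- function(profiles, cell_type, batch) {
  meta <- profiles$sample_meta
  hit <- which(meta$cell_type == cell_type & meta$batch == batch)
  if (!length(hit)) hit <- which(meta$cell_type == cell_type)
  if (!length(hit)) stop("no purified profile for cell type '", cell_type, "'")
  hit[1L]
}

#' Mix purified TPM profiles into admixture expression
#'
#' Each admixture column is the proportion-weighted sum of the purified TPM
#' profiles (linear space), with the representative profile of each cell
#' type matched to the admixture's batch label.
#'
#' @param profiles a `profile_library`.
#' @param design an `admixture_design` (fine-grained, cell types must have
#'   profiles).
#' @return An `admixture_dataset`: list with `expression` (gene x
#'   admixture), `design`, and `scale = "tpm"`.
#' @export
mix_tpm <- function(profiles, design) {
  .mix(profiles, design, profiles$tpm, "tpm")
}

#' Mix purified count profiles into pseudo-count admixture expression
#'
#' Purified counts are first rescaled to pseudo-counts on a common scale:
#' each sample's counts are divided by its total and multiplied by the
#' median across samples of the per-sample totals. Admixtures are then
#' proportion-weighted sums of pseudo-counts.
#'
#' @inheritParams mix_tpm
#' @return An `admixture_dataset` with `scale = "counts"`.
#' @export
mix_counts <- function(profiles, design) {
  totals <- colSums(profiles$counts)
  if (any(totals == 0)) {
    stop("zero-total purified sample: ",
         paste(colnames(profiles$counts)[totals == 0], collapse = ", "))
  }
  pseudo <- sweep(profiles$counts, 2, stats::median(totals) / totals, "*")
  .mix(profiles, design, pseudo, "counts")
}

.mix <- function(profiles, design, mat, scale) {
  pr <- design$proportions
  batches <- design$meta$batch
  if (is.null(batches)) batches <- rep("batch1", nrow(pr))
  expr <- matrix(0, nrow = nrow(mat), ncol = nrow(pr),
                 dimnames = list(rownames(mat), rownames(pr)))
  used_types <- colnames(pr)[colSums(pr) > 0]
  for (ct in used_types) {
    for (b in unique(batches)) {
      in_b <- batches == b & pr[, ct] > 0
      if (!any(in_b)) next
      prof <- mat[, .profile_for(profiles, ct, b)]
      expr[, in_b] <- expr[, in_b, drop = FALSE] +
        outer(prof, pr[in_b, ct])
    }
  }
  structure(list(expression = expr, design = design, scale = scale),
            class = "admixture_dataset")
}

#' @export
print.admixture_dataset <- function(x, ...) {
  cat("admixture_dataset (", x$scale, "):", nrow(x$expression), "genes x",
      ncol(x$expression), "admixtures\n")
  invisible(x)
}

#' The spike-in level grid
#'
#' 0 to 0.1 percent in steps of 0.01 percent, 0.1 to 1 percent in steps of
#' 0.1 percent, 1 to 20 percent in steps of 1 percent, and 20 to 40 percent
#' in steps of 2 percent, with shared endpoints counted once.
#'
#' @return numeric vector of 49 spike-in fractions, starting at 0.
#' @export
spikein_levels <- function() {
  lv <- c(seq(0, 0.001, by = 1e-4),
          seq(0.001, 0.01, by = 1e-3),
          seq(0.01, 0.2, by = 0.01),
          seq(0.2, 0.4, by = 0.02))
  sort(unique(round(lv, 10)))
}

#' Build a spike-in series for one target cell type
#'
#' The target type is computationally spiked in at each grid level `s` into
#' unconstrained background admixtures of all other panel types (cancer
#' excluded) summing to `1 - s`. The same `n_reps` backgrounds (broken
#' stick, step 0.001, no extremal diversification, half per vendor-like
#' batch) are reused across all levels by renaming the fixed-`s` slot. For a
#' coarse-grained target, the fixed parental proportion is split across its
#' `m` fine sub-populations by a flat Dirichlet with all parameters `1/m`.
#'
#' @param profiles a `profile_library`.
#' @param cell_type target type: a fine panel type or a coarse population.
#' @param hierarchy a [cell_type_hierarchy()].
#' @param n_reps background replicates per level (default 10).
#' @param step broken-stick grid step for backgrounds.
#' @param seed optional integer seed.
#' @return list with `series` (data.frame: level, replicate, column id),
#'   `design` (fine-grained `admixture_design`) and `dataset` (the mixed
#'   TPM `admixture_dataset`).
#' @export
make_spikein_series <- function(profiles, cell_type, hierarchy,
                                n_reps = 10, step = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- admixture_panel(hierarchy, "in_silico")
  coarse_target <- cell_type %in% hierarchy$coarse_types &&
    !(cell_type %in% panel)
  target_fine <- if (coarse_target) {
    intersect(panel, names(hierarchy$coarse_of)[hierarchy$coarse_of == cell_type])
  } else {
    if (!cell_type %in% panel) stop("unknown cell type '", cell_type, "'")
    cell_type
  }
  background <- setdiff(panel, target_fine)
  levels <- spikein_levels()

  # n_reps reusable backgrounds over the non-target types, summing to 1
  bg <- broken_stick(length(background),
                     proportion_constraint(step = step),
                     n_candidates = n_reps)
  colnames(bg) <- background
  batches <- rep(c("batch1", "batch2"), length.out = n_reps)

  n_rows <- length(levels) * n_reps
  cols <- c(target_fine, background)
  props <- matrix(0, nrow = n_rows, ncol = length(cols),
                  dimnames = list(NULL, cols))
  series <- data.frame(level = rep(levels, each = n_reps),
                       replicate = rep(seq_len(n_reps), length(levels)))
  series$column = sprintf("spike_%s_L%02d_r%02d", cell_type,
                          rep(seq_along(levels), each = n_reps),
                          series$replicate)
  rownames(props) <- series$column
  for (i in seq_len(n_rows)) {
    s <- series$level[i]
    r <- series$replicate[i]
    props[i, background] <- bg[r, ] * (1 - s)
    if (s > 0) {
      if (coarse_target) {
        m <- length(target_fine)
        split <- .rdirichlet(1, rep(1 / m, m))
        props[i, target_fine] <- s * split / sum(split)
      } else {
        props[i, target_fine] <- s
      }
    }
  }
  meta <- data.frame(dataset = "spikein", cancer_type = NA_character_,
                     batch = batches[series$replicate],
                     origin = "in_silico", design_class = "unconstrained",
                     level = series$level, replicate = series$replicate,
                     stringsAsFactors = FALSE)
  design <- admixture_design(props, meta, granularity = "fine")
  list(series = series, design = design,
       dataset = mix_tpm(profiles, design),
       target = cell_type, levels = levels, n_reps = n_reps)
}

# flat Dirichlet draws via normalized gammas
.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  drop(x / rowSums(x))
}

#' Purified-sample panel for spillover assessment
#'
#' One admixture column per purified (non-cancer) sample; the design rows
#' are one-hot, so each column equals the corresponding purified profile.
#'
#' @param profiles a `profile_library`.
#' @param types cell types to include (default: all non-cancer types).
#' @return An `admixture_dataset` whose design rows are one-hot.
#' @export
make_purified_panel <- function(profiles,
                                types = setdiff(unique(profiles$sample_meta$cell_type),
                                                grep("^cancer", unique(profiles$sample_meta$cell_type),
                                                     value = TRUE))) {
  meta <- profiles$sample_meta
  keep <- meta$cell_type %in% types
  meta <- meta[keep, , drop = FALSE]
  props <- matrix(0, nrow = nrow(meta), ncol = length(types),
                  dimnames = list(meta$sample_id, types))
  props[cbind(seq_len(nrow(meta)), match(meta$cell_type, types))] <- 1
  dmeta <- data.frame(dataset = "purified", cancer_type = NA_character_,
                      batch = meta$batch, origin = "in_silico",
                      design_class = "purified", purified_type = meta$cell_type,
                      stringsAsFactors = FALSE)
  design <- admixture_design(props, dmeta, granularity = "fine")
  expr <- profiles$tpm[, meta$sample_id, drop = FALSE]
  colnames(expr) <- rownames(props)
  structure(list(expression = expr, design = design, scale = "tpm"),
            class = "admixture_dataset")
}
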