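#' Configuration for the synthetic profile generator
#'
#' The generator emulates purified bulk RNA-seq profiles: log-normal baseline
#' gene means shared across cell types, a set of planted marker genes per
#' type whose expected linear expression is up-regulated by a constant fold
#' change, multiplicative gamma noise per replicate, and a multiplicative
#' per-gene log-normal batch factor shared within each of two vendor-like
#' batches.
#'
#' @param n_genes number of genes.
#' @param markers_per_type planted marker genes per cell type.
#' @param marker_fold_change linear-scale up-regulation of a type's markers
#'   in that type relative to all other types.
#' @param baseline_dispersion coefficient of variation of the per-replicate
#'   multiplicative gamma noise (0 = noiseless replicates).
#' @param batch_effect_sd standard deviation (log scale) of the per-gene
#'   batch factor (0 = no batch effect).
#' @param library_size_range length-2 numeric, uniform sampling range of the
#'   per-sample total read count.
#' @param n_replicates replicates per cell type (spread across the two
#'   batches).
#' @param seed integer seed fixing all downstream randomness.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1200,
                             markers_per_type = 20,
                             marker_fold_change = 8,
                             baseline_dispersion = 0.15,
                             batch_effect_sd = 0.1,
                             library_size_range = c(8e5, 1.2e6),
                             n_replicates = 2,
                             seed = 1L) {
  stopifnot(n_genes >= 1, markers_per_type >= 1, marker_fold_change > 0,
            baseline_dispersion >= 0, batch_effect_sd >= 0,
            length(library_size_range) == 2, all(library_size_range > 0),
            diff(library_size_range) >= 0, n_replicates >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold_change = marker_fold_change,
                 baseline_dispersion = baseline_dispersion,
                 batch_effect_sd = batch_effect_sd,
                 library_size_range = library_size_range,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# multiplicative mean-1 gamma noise; cv = 0 collapses to 1
.gamma_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rgamma(n, shape = 1 / cv^2, rate = 1 / cv^2)
}

# per-type expected linear expression, markers planted on disjoint gene blocks
.expectation_profiles <- function(config, types) {
  n_types <- length(types)
  needed <- config$markers_per_type * n_types
  if (needed > config$n_genes) {
    stop("markers_per_type x number of types (", needed,
         ") exceeds n_genes (", config$n_genes, ")")
  }
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  base <- stats::rlnorm(config$n_genes, meanlog = log(50), sdlog = 1.2)
  expectation <- matrix(base, nrow = config$n_genes, ncol = n_types,
                        dimnames = list(genes, types))
  marker_sets <- vector("list", n_types)
  names(marker_sets) <- types
  for (i in seq_len(n_types)) {
    idx <- ((i - 1) * config$markers_per_type + 1):(i * config$markers_per_type)
    expectation[idx, i] <- expectation[idx, i] * config$marker_fold_change
    marker_sets[[i]] <- genes[idx]
  }
  list(genes = genes, expectation = expectation, marker_sets = marker_sets)
}

#' Generate a purified profile library
#'
#' Emits replicate purified TPM and count profiles for every fine-grained
#' type in the hierarchy plus the cancer types. Counts are derived by
#' scaling each sample's noisy relative expression to a sampled library size
#' and rounding; TPM is then defined as counts per column scaled to 1e6, so
#' the count/TPM consistency identity holds by construction.
#'
#' @param config a [synthetic_config()].
#' @param hierarchy a [cell_type_hierarchy()].
#' @return A `profile_library` list with fields `genes`, `tpm`, `counts`,
#'   `sample_meta` (cell_type, batch, replicate) and `marker_sets` (the
#'   planted ground-truth markers, used by harness self-consistency tests).
#' @export
generate_profiles <- function(config, hierarchy) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(hierarchy, "cell_type_hierarchy"))
  set.seed(config$seed)
  types <- c(hierarchy$fine_types, hierarchy$cancer_types)
  prof <- .expectation_profiles(config, types)

  batches <- c("batch1", "batch2")
  batch_factor <- vapply(batches, function(b) {
    if (config$batch_effect_sd <= 0) rep(1, config$n_genes)
    else stats::rlnorm(config$n_genes, meanlog = 0, sdlog = config$batch_effect_sd)
  }, numeric(config$n_genes))

  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      cell_type = types, stringsAsFactors = FALSE)
  meta$batch <- batches[(meta$replicate - 1L) %% 2L + 1L]
  meta$sample_id <- sprintf("%s_rep%d", meta$cell_type, meta$replicate)
  meta <- meta[, c("sample_id", "cell_type", "batch", "replicate")]

  counts <- matrix(0L, nrow = config$n_genes, ncol = nrow(meta),
                   dimnames = list(prof$genes, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    mu <- prof$expectation[, meta$cell_type[s]] * batch_factor[, meta$batch[s]]
    x <- mu * .gamma_noise(config$n_genes, config$baseline_dispersion)
    lib <- stats::runif(1, config$library_size_range[1], config$library_size_range[2])
    counts[, s] <- as.integer(round(x / sum(x) * lib))
  }
  tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6

  structure(list(genes = prof$genes, tpm = tpm, counts = counts,
                 sample_meta = meta, marker_sets = prof$marker_sets,
                 config = config),
            class = "profile_library")
}

#' @export
print.profile_library <- function(x, ...) {
  cat("profile_library:", length(x$genes), "genes x", ncol(x$tpm), "samples (",
      length(unique(x$sample_meta$cell_type)), "cell types )\n")
  invisible(x)
}

#' Generate a synthetic single-cell count fixture
#'
#' Draws per-cell counts from the same per-type expectation profiles used for
#' the bulk generator, with per-cell multiplicative gamma noise and
#' library-size variation. Optionally injects a "mislabeled cluster": for one
#' patient, a block of cells drawn from `mislabel$true_type` but annotated as
#' `mislabel$labeled_type`, used to exercise the pseudo-bulk k-NN QC.
#'
#' @param config a [synthetic_config()].
#' @param hierarchy a [cell_type_hierarchy()].
#' @param n_patients number of patients.
#' @param cells_per_type_range length-2 integer range; the number of cells
#'   per (patient, type) is sampled uniformly from it.
#' @param cell_types types to simulate (default: the in silico panel).
#' @param cell_library_range per-cell total count sampling range.
#' @param mislabel `NULL`, or a list with `patient`, `true_type`,
#'   `labeled_type` and `n_cells`.
#' @param seed integer seed.
#' @return A `single_cell_fixture` list with `counts` (gene x cell) and
#'   `cell_meta` (cell_id, patient, cell_type, true_type).
#' @export
generate_single_cell <- function(config, hierarchy,
                                 n_patients = 4,
                                 cells_per_type_range = c(30L, 80L),
                                 cell_types = admixture_panel(hierarchy, "in_silico"),
                                 cell_library_range = c(2000, 6000),
                                 mislabel = NULL,
                                 seed = config$seed) {
  stopifnot(n_patients >= 1)
  if (length(cells_per_type_range) != 2 || any(cells_per_type_range < 1)) {
    stop("cells_per_type_range must be two positive integers")
  }
  set.seed(seed)
  all_types <- c(hierarchy$fine_types, hierarchy$cancer_types)
  stopifnot(all(cell_types %in% all_types))
  prof <- .expectation_profiles(config, all_types)

  patients <- sprintf("patient_%02d", seq_len(n_patients))
  blocks <- expand.grid(cell_type = cell_types, patient = patients,
                        stringsAsFactors = FALSE)
  blocks$n_cells <- if (diff(cells_per_type_range) == 0) {
    rep(cells_per_type_range[1], nrow(blocks))
  } else {
    sample(seq(cells_per_type_range[1], cells_per_type_range[2]),
           nrow(blocks), replace = TRUE)
  }
  blocks$true_type <- blocks$cell_type
  if (!is.null(mislabel)) {
    stopifnot(all(c("patient", "true_type", "labeled_type", "n_cells") %in%
                    names(mislabel)))
    blocks <- rbind(blocks, data.frame(
      cell_type = mislabel$labeled_type, patient = mislabel$patient,
      n_cells = mislabel$n_cells, true_type = mislabel$true_type))
  }

  n_cells_total <- sum(blocks$n_cells)
  counts <- matrix(0L, nrow = config$n_genes, ncol = n_cells_total,
                   dimnames = list(prof$genes, NULL))
  meta <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n_cells_total)),
                     patient = rep(blocks$patient, blocks$n_cells),
                     cell_type = rep(blocks$cell_type, blocks$n_cells),
                     true_type = rep(blocks$true_type, blocks$n_cells),
                     stringsAsFactors = FALSE)
  colnames(counts) <- meta$cell_id
  for (i in seq_len(n_cells_total)) {
    mu <- prof$expectation[, meta$true_type[i]]
    x <- mu * .gamma_noise(config$n_genes, config$baseline_dispersion)
    lib <- stats::runif(1, cell_library_range[1], cell_library_range[2])
    counts[, i] <- as.integer(round(x / sum(x) * lib))
  }
  structure(list(counts = counts, cell_meta = meta),
            class = "single_cell_fixture")
}

#' @export
print.single_cell_fixture <- function(x, ...) {
  cat("single_cell_fixture:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells,", length(unique(x$cell_meta$patient)), "patients\n")
  invisible(x)
}
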