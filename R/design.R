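#' Admixture design containers
#'
#' An `admixture_design` holds a ground-truth proportion matrix (admixture x
#' cell type, cancer columns included) together with per-admixture metadata:
#' dataset label, cancer type, vendor-like batch, design class
#' (unconstrained or biological), origin (in vitro-style or in silico-style)
#' and granularity.
#'
#' @param proportions admixture x cell-type matrix.
#' @param meta data.frame with one row per admixture.
#' @param granularity `"fine"` or `"coarse"`.
#' @return An `admixture_design`.
#' @export
admixture_design <- function(proportions, meta, granularity = "fine") {
  stopifnot(is.matrix(proportions), nrow(proportions) == nrow(meta))
  if (is.null(rownames(proportions))) {
    rownames(proportions) <- sprintf("admix_%03d", seq_len(nrow(proportions)))
  }
  meta$admixture_id <- rownames(proportions)
  obj <- structure(list(proportions = proportions, meta = meta,
                        granularity = granularity),
                   class = "admixture_design")
  validate_admixture_design(obj)
  obj
}

#' Validate an admixture design
#'
#' Checks non-negativity and that every row sums to one (cancer included)
#' within `tol`.
#'
#' @param design an `admixture_design`.
#' @param tol numeric tolerance (default 1e-9).
#' @return `design`, invisibly; errors describe the first violation.
#' @export
validate_admixture_design <- function(design, tol = 1e-9) {
  pr <- design$proportions
  if (any(pr < -tol)) stop("negative proportions in design")
  rs <- rowSums(pr)
  if (any(abs(rs - 1) > tol)) {
    stop("row sums differ from 1 by up to ", signif(max(abs(rs - 1)), 3))
  }
  invisible(design)
}

#' @export
print.admixture_design <- function(x, ...) {
  cat("admixture_design:", nrow(x$proportions), "admixtures x",
      ncol(x$proportions), "cell types (", x$granularity, "grained )\n")
  if (!is.null(x$meta$dataset)) {
    print(table(x$meta$dataset))
  }
  invisible(x)
}

#' Coarsen a fine-grained admixture design
#'
#' Coarse proportions are sums over fine children; cancer columns and row
#' sums are preserved exactly.
#'
#' @param design a fine-grained `admixture_design`.
#' @param hierarchy a [cell_type_hierarchy()].
#' @return A coarse-grained `admixture_design`.
#' @export
coarsen <- function(design, hierarchy) {
  if (design$granularity != "fine") stop("design is not fine-grained")
  props <- aggregate_to_coarse(design$proportions, hierarchy)
  admixture_design(props, design$meta, granularity = "coarse")
}

.default_pairs <- function() {
  matrix(c("monocyte",     "dendritic",
           "macrophage",   "monocyte",
           "dendritic",    "macrophage",
           "naive_CD4_T",  "memory_CD4_T",
           "memory_CD4_T", "naive_CD4_T",
           "naive_CD8_T",  "memory_CD8_T",
           "memory_CD8_T", "naive_CD8_T",
           "naive_B",      "memory_B",
           "memory_B",     "naive_B",
           "Treg",         "naive_CD4_T",
           "naive_CD4_T",  "Treg"),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("signal", "decoy")))
}

#' Generate and select signal/decoy unconstrained candidate designs
#'
#' For every combination of a cancer-proportion range and a (signal, decoy)
#' cell-type pair, draws `n_per_cell` broken-stick candidates in which the
#' signal type is bounded in `[0.2, 0.35]`, the decoy is excluded (exactly
#' 0), every other non-cancer type lies in `[0.01, 0.5]` and the cancer
#' proportion lies in the given range. Final selection then rotates through
#' the pairs, each round adding (from that pair's pooled candidates) the
#' design that maximizes its minimal squared distance to those already
#' selected; the very first pick is the candidate of the first pair farthest
#' from its pool mean.
#'
#' @param panel_types non-cancer cell types of the design panel.
#' @param n_select number of designs to select (`NULL` = return candidates
#'   only).
#' @param pairs two-column character matrix of (signal, decoy) pairs.
#' @param cancer_ranges list of length-2 numeric cancer proportion ranges.
#' @param n_per_cell candidates per (range x pair) combination.
#' @param signal_range,other_range signal and background per-type bounds.
#' @param step grid step for the broken stick.
#' @param seed optional integer seed.
#' @return list with `candidates` (matrix over `c("cancer", panel_types)`),
#'   `candidate_meta` (pair/range per candidate) and, when `n_select` is
#'   given, `selected` (row indices in selection order).
#' @export
design_signal_decoy <- function(panel_types,
                                n_select = NULL,
                                pairs = .default_pairs(),
                                cancer_ranges = list(c(0.2, 0.3), c(0.4, 0.5), c(0.6, 0.7)),
                                n_per_cell = 1000,
                                signal_range = c(0.2, 0.35),
                                other_range = c(0.01, 0.5),
                                step = 0.01,
                                seed = NULL) {
  stopifnot(all(pairs %in% panel_types))
  if (!is.null(seed)) set.seed(seed)
  cols <- c("cancer", panel_types)
  pools <- list()
  meta <- list()
  for (pi in seq_len(nrow(pairs))) {
    signal <- pairs[pi, "signal"]
    decoy <- pairs[pi, "decoy"]
    stick_types <- c(signal, setdiff(panel_types, c(signal, decoy)))
    min_c <- c(signal_range[1], rep(other_range[1], length(stick_types) - 1L))
    max_c <- c(signal_range[2], rep(other_range[2], length(stick_types) - 1L))
    for (ri in seq_along(cancer_ranges)) {
      rng <- cancer_ranges[[ri]]
      # cancer takes the fixed (n+1)st slot: drawn on the step grid within
      # its range, the stick partitions the remaining 1 - cancer; grid
      # values leaving less than the non-cancer minima are unattainable
      cancer_vals <- seq(rng[1], rng[2], by = step)
      feasible <- 1 - cancer_vals >= sum(min_c) - 1e-12
      if (!any(feasible)) {
        stop("infeasible combination: cancer range [", rng[1], ", ", rng[2],
             "] leaves less than the non-cancer minima for pair ",
             signal, "/", decoy)
      }
      cancer_vals <- cancer_vals[feasible]
      cc <- cancer_vals[sample.int(length(cancer_vals), n_per_cell,
                                   replace = TRUE)]
      full <- matrix(0, nrow = n_per_cell, ncol = length(cols),
                     dimnames = list(NULL, cols))
      full[, "cancer"] <- cc
      for (v in unique(cc)) {
        take <- which(cc == v)
        cand <- broken_stick(length(stick_types),
                             proportion_constraint(min_c, max_c,
                                                   step = step, p = 1 - v),
                             n_candidates = length(take))
        full[take, stick_types] <- cand
      }
      pools[[length(pools) + 1L]] <- full
      meta[[length(meta) + 1L]] <- data.frame(
        pair = pi, signal = signal, decoy = decoy,
        cancer_min = rng[1], cancer_max = rng[2],
        stringsAsFactors = FALSE)
    }
  }
  candidates <- do.call(rbind, pools)
  candidate_meta <- do.call(rbind, lapply(seq_along(meta), function(i) {
    cbind(meta[[i]][rep(1, nrow(pools[[i]])), , drop = FALSE], row.names = NULL)
  }))
  out <- list(candidates = candidates, candidate_meta = candidate_meta)
  if (is.null(n_select)) return(out)

  n_pairs <- nrow(pairs)
  selected <- integer(0)
  min_d2 <- rep(Inf, nrow(candidates))
  start_round <- 1L
  if (n_pairs == 1L && n_select >= 2L) {
    # both opening rounds draw from the same pool: take its extremal pair
    first_two <- select_extremal(candidates, 2)
    selected <- first_two
    min_d2 <- pmin(rowSums(sweep(candidates, 2, candidates[first_two[1], ])^2),
                   rowSums(sweep(candidates, 2, candidates[first_two[2], ])^2))
    min_d2[selected] <- -Inf
    start_round <- 3L
  }
  for (round in seq(start_round, length.out = n_select - start_round + 1L)) {
    pair_idx <- (round - 1L) %% n_pairs + 1L
    in_pool <- which(candidate_meta$pair == pair_idx)
    in_pool <- setdiff(in_pool, selected)
    if (!length(in_pool)) stop("candidate pool for pair ", pair_idx, " exhausted")
    if (!length(selected)) {
      ctr <- colMeans(candidates[in_pool, , drop = FALSE])
      score <- rowSums(sweep(candidates[in_pool, , drop = FALSE], 2, ctr)^2)
    } else {
      score <- min_d2[in_pool]
    }
    pick <- in_pool[which.max(score)]
    selected <- c(selected, pick)
    d2_new <- rowSums(sweep(candidates, 2, candidates[pick, ])^2)
    min_d2 <- pmin(min_d2, d2_new)
  }
  out$selected <- selected
  out
}

#' Biologically constrained admixtures via hit-and-run sampling
#'
#' In silico style (`fixed_cancer = NULL`): the polytope spans the cancer
#' compartment and the panel jointly (row sums 1); candidates are drawn in
#' `n_batches` independent chains and each batch contributes its
#' `per_batch_select` mutually most-distant samples. In vitro style
#' (`fixed_cancer` a vector of cancer proportions): per admixture the cancer
#' proportion is pinned and one thinned sample is drawn over the panel
#' summing to `1 - cancer`.
#'
#' @param model a `constraint_model` (leaf `cancer` plus panel leaves).
#' @param panel_types non-cancer cell types.
#' @param n_admixtures number of admixtures to return (in silico style).
#' @param n_batches number of independent MCMC batches (in silico style).
#' @param fixed_cancer optional numeric vector of per-admixture cancer
#'   proportions (in vitro style).
#' @param settings a [sampler_settings()].
#' @return matrix over `c("cancer", panel_types)`, one row per admixture.
#' @export
biological_admixtures <- function(model, panel_types,
                                  n_admixtures = 20, n_batches = 5,
                                  fixed_cancer = NULL,
                                  settings = sampler_settings()) {
  cols <- c("cancer", panel_types)
  if (is.null(fixed_cancer)) {
    per_batch <- n_admixtures / n_batches
    stopifnot(per_batch == round(per_batch))
    rows <- lapply(seq_len(n_batches), function(b) {
      samples <- hit_and_run_sample(model, cols, p = 1, settings = settings)
      samples[select_extremal(samples, per_batch), , drop = FALSE]
    })
    out <- do.call(rbind, rows)
  } else {
    bounds <- flatten_model(model, cols)
    out <- t(vapply(fixed_cancer, function(cc) {
      x <- hit_and_run_sample(bounds[bounds$population != "cancer", ],
                              panel_types, p = 1 - cc, n_samples = 1,
                              settings = settings)
      c(cc, drop(x))
    }, numeric(length(cols))))
    colnames(out) <- cols
  }
  out
}

#' Assemble the full eight-dataset challenge layout
#'
#' Emits the complete validation design: four in vitro-style datasets (DS1 -
#' DS4; per dataset 15 biological admixtures with a fixed cancer proportion
#' drawn from the 0.20 - 0.80 grid in 0.01 steps, plus 9 unconstrained
#' signal/decoy admixtures from a rotating extremal selection of 36), and
#' four in silico-style datasets (AA, AB, AE, AF; per dataset 15
#' unconstrained admixtures at step 0.001 and 20 biological admixtures taken
#' as the 4 most distant of each of 5 MCMC batches). Datasets alternate
#' breast (BRCA) and colorectal (CRC) cancer backbones across two
#' vendor-like batches.
#'
#' @param seed integer seed governing all randomness.
#' @param hierarchy a [cell_type_hierarchy()].
#' @param model a `constraint_model`; default [default_biological_model()].
#' @param n_signal_decoy_candidates candidates per (range x pair) pool.
#' @return A fine-grained `admixture_design` of 96 in vitro-style plus 140
#'   in silico-style admixtures.
#' @export
assemble_challenge_layout <- function(seed = 1L,
                                      hierarchy = default_hierarchy(),
                                      model = default_biological_model(),
                                      n_signal_decoy_candidates = 1000) {
  set.seed(seed)
  vitro_panel <- admixture_panel(hierarchy, "in_vitro")
  silico_panel <- admixture_panel(hierarchy, "in_silico")
  all_cols <- c(hierarchy$fine_types, hierarchy$cancer_types)

  ds_info <- data.frame(
    dataset = c("DS1", "DS2", "DS3", "DS4", "AA", "AB", "AE", "AF"),
    cancer_type = c("cancer_BRCA", "cancer_CRC", "cancer_BRCA", "cancer_CRC",
                    "cancer_BRCA", "cancer_CRC", "cancer_BRCA", "cancer_CRC"),
    batch = c("batch1", "batch1", "batch2", "batch2",
              "batch1", "batch1", "batch2", "batch2"),
    origin = rep(c("in_vitro", "in_silico"), each = 4),
    stringsAsFactors = FALSE)

  rows <- list()
  meta <- list()
  add <- function(props_named, dataset, class) {
    info <- ds_info[ds_info$dataset == dataset, ]
    full <- matrix(0, nrow = nrow(props_named), ncol = length(all_cols),
                   dimnames = list(NULL, all_cols))
    nm <- colnames(props_named)
    nm[nm == "cancer"] <- info$cancer_type
    full[, nm] <- props_named
    rows[[length(rows) + 1L]] <<- full
    meta[[length(meta) + 1L]] <<- data.frame(
      dataset = dataset, cancer_type = info$cancer_type, batch = info$batch,
      origin = info$origin, design_class = class,
      stringsAsFactors = FALSE)[rep(1, nrow(full)), , drop = FALSE]
  }

  # --- in vitro style: 60 biological + 36 signal/decoy unconstrained ------
  cancer_grid <- seq(0.2, 0.8, by = 0.01)
  for (ds in c("DS1", "DS2", "DS3", "DS4")) {
    fixed <- cancer_grid[sample.int(length(cancer_grid), 15)]
    bio <- biological_admixtures(model, vitro_panel, fixed_cancer = fixed)
    add(bio, ds, "biological")
  }
  sd <- design_signal_decoy(vitro_panel, n_select = 36,
                            n_per_cell = n_signal_decoy_candidates)
  picked <- sd$candidates[sd$selected, , drop = FALSE]
  for (i in seq_len(4)) {
    ds <- c("DS1", "DS2", "DS3", "DS4")[i]
    idx <- seq(i, 36, by = 4)
    add(picked[idx, , drop = FALSE], ds, "unconstrained")
  }

  # --- in silico style: 15 unconstrained + 20 biological per dataset ------
  for (ds in c("AA", "AB", "AE", "AF")) {
    n_pop <- length(silico_panel) + 1L
    unc <- broken_stick(n_pop, proportion_constraint(step = 0.001),
                        n_candidates = 15)
    colnames(unc) <- c("cancer", silico_panel)
    add(unc, ds, "unconstrained")
    bio <- biological_admixtures(model, silico_panel,
                                 n_admixtures = 20, n_batches = 5)
    add(bio, ds, "biological")
  }

  props <- do.call(rbind, rows)
  m <- do.call(rbind, meta)
  rownames(props) <- sprintf("%s_%s_%02d", m$dataset,
                             ifelse(m$design_class == "biological", "bio", "unc"),
                             stats::ave(seq_len(nrow(m)),
                                        paste(m$dataset, m$design_class),
                                        FUN = seq_along))
  admixture_design(props, m, granularity = "fine")
}
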