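#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers
#' and whose header names the samples. Rows sharing a gene identifier are
#' summed (as when transcript-level values are aggregated to genes).
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop("malformed numeric cell in ", path, " at row ", bad[1] + 1L,
           " (gene '", raw[[1]][bad[1]], "'), column '", samples[j], "'")
    }
    mat[, j] <- num
  }
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    mat <- rowsum(mat, group = genes, reorder = FALSE)
  } else {
    rownames(mat) <- genes
  }
  mat
}

#' Write a gene x sample expression matrix as TSV
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output path.
#' @param id_column name of the first (gene identifier) column.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an admixture design (proportions + metadata) as TSV
#'
#' @param design an `admixture_design`.
#' @param path output path; metadata goes to `<path>.meta.tsv`.
#' @export
write_design <- function(design, path) {
  df <- data.frame(admixture_id = rownames(design$proportions),
                   design$proportions, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(design$meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a prediction table as TSV with a method/scale header block
#'
#' @param predictions a `prediction_table`.
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# method: ", predictions$method),
               paste0("# output_scale: ", predictions$output_scale)), con)
  df <- data.frame(sample = rownames(predictions$values),
                   predictions$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# rolling polynomial hash over the serialized object, for provenance stamps
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^44
  sprintf("%.0f", h)
}

#' Pipeline run configuration
#'
#' One master seed deterministically derives every stage seed. The default
#' problem sizes are reduced relative to the full challenge layout so that
#' an end-to-end run stays interactive; `use_full_layout = TRUE` switches
#' the design stage to [assemble_challenge_layout()].
#'
#' @param out_dir run directory for artifacts.
#' @param seed master seed.
#' @param synthetic a [synthetic_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param methods deconvolution methods to run.
#' @param n_boot bootstrap samples for method ranking.
#' @param alpha limit-of-detection p-value cutoff.
#' @param spikein_targets cell types to run spike-in series for (empty =
#'   skip the sensitivity stage).
#' @param spikein_reps replicates per spike-in level.
#' @param use_full_layout use the complete eight-dataset design.
#' @param n_unconstrained,n_biological per-dataset design sizes when not
#'   using the full layout.
#' @param stages named logical vector toggling pipeline stages; a disabled
#'   stage reads its cached artifact from `out_dir`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("admixbench_run_"),
                       seed = 1L,
                       synthetic = synthetic_config(),
                       methods = c("cls", "huber", "nusvr",
                                   "marker_mean", "marker_sum"),
                       n_boot = 100,
                       alpha = 0.01,
                       spikein_targets = character(),
                       spikein_reps = 10,
                       use_full_layout = FALSE,
                       n_unconstrained = 6,
                       n_biological = 4,
                       stages = c(profiles = TRUE, design = TRUE, mix = TRUE,
                                  deconvolve = TRUE, score = TRUE,
                                  spillover = TRUE, lod = TRUE)) {
  seed <- as.integer(seed)
  stage_names <- c("profiles", "design", "mix", "deconvolve", "score",
                   "spillover", "lod")
  stage_seeds <- stats::setNames(
    (seed * 1000L + seq_along(stage_names) * 7L) %% .Machine$integer.max,
    stage_names)
  structure(list(out_dir = out_dir, seed = seed, stage_seeds = stage_seeds,
                 synthetic = synthetic, methods = methods, n_boot = n_boot,
                 alpha = alpha, spikein_targets = spikein_targets,
                 spikein_reps = spikein_reps,
                 use_full_layout = use_full_layout,
                 n_unconstrained = n_unconstrained,
                 n_biological = n_biological,
                 stages = stages),
            class = "run_config")
}

.reduced_layout <- function(config, hierarchy, model) {
  set.seed(config$stage_seeds[["design"]])
  panel <- admixture_panel(hierarchy, "in_silico")
  ds_info <- data.frame(dataset = c("AA", "AB", "AE", "AF"),
                        cancer_type = c("cancer_BRCA", "cancer_CRC",
                                        "cancer_BRCA", "cancer_CRC"),
                        batch = c("batch1", "batch1", "batch2", "batch2"),
                        stringsAsFactors = FALSE)
  rows <- list(); meta <- list()
  all_cols <- c(hierarchy$fine_types, hierarchy$cancer_types)
  for (i in seq_len(nrow(ds_info))) {
    unc <- broken_stick(length(panel) + 1L,
                        proportion_constraint(step = 0.001),
                        n_candidates = config$n_unconstrained)
    colnames(unc) <- c("cancer", panel)
    bio <- biological_admixtures(model, panel,
                                 n_admixtures = config$n_biological,
                                 n_batches = 1,
                                 settings = sampler_settings(N = 200 * length(panel)^2,
                                                             thin = 50))
    block <- rbind(unc, bio[, colnames(unc), drop = FALSE])
    full <- matrix(0, nrow = nrow(block), ncol = length(all_cols),
                   dimnames = list(NULL, all_cols))
    nm <- colnames(block)
    nm[nm == "cancer"] <- ds_info$cancer_type[i]
    full[, nm] <- block
    rows[[i]] <- full
    meta[[i]] <- data.frame(dataset = ds_info$dataset[i],
                            cancer_type = ds_info$cancer_type[i],
                            batch = ds_info$batch[i], origin = "in_silico",
                            design_class = rep(c("unconstrained", "biological"),
                                               c(config$n_unconstrained,
                                                 config$n_biological)),
                            stringsAsFactors = FALSE)
  }
  props <- do.call(rbind, rows)
  m <- do.call(rbind, meta)
  rownames(props) <- sprintf("%s_%02d", m$dataset,
                             stats::ave(seq_len(nrow(m)), m$dataset, FUN = seq_along))
  admixture_design(props, m, granularity = "fine")
}

.run_method <- function(method, dataset, sig) {
  switch(method,
         cls = deconvolve_cls(dataset, sig$signature),
         wcls = deconvolve_cls(dataset, sig$signature,
                               weights = stats::setNames(rep(1, nrow(sig$signature)),
                                                         rownames(sig$signature))),
         huber = deconvolve_huber(dataset, sig$signature),
         nusvr = deconvolve_nusvr(dataset, sig$signature),
         marker_mean = deconvolve_marker_summary(dataset, sig$marker_sets, "mean"),
         marker_sum = deconvolve_marker_summary(dataset, sig$marker_sets, "sum"),
         stop("unknown method '", method, "'"))
}

#' Run the full benchmarking pipeline
#'
#' Executes simulate -> design -> mix -> deconvolve -> score -> spillover ->
#' lod, writing TSV artifacts, stage caches and a provenance log (seed and
#' configuration hash) into `config$out_dir`. Re-running with the same
#' configuration reproduces all numeric outputs exactly; stages toggled off
#' read their cached artifacts.
#'
#' @param config a [run_config()].
#' @param hierarchy a [cell_type_hierarchy()].
#' @param model a `constraint_model`.
#' @return list with `profiles`, `design`, `datasets`, `predictions`,
#'   `ranking`, `spillover`, `lod` and `provenance`.
#' @export
run_pipeline <- function(config, hierarchy = default_hierarchy(),
                         model = default_biological_model()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  cache <- function(name) file.path(config$out_dir, paste0(name, ".rds"))
  stage <- function(name, fn) {
    if (isTRUE(config$stages[[name]])) {
      value <- fn()
      saveRDS(value, cache(name))
      value
    } else {
      if (!file.exists(cache(name))) {
        stop("stage '", name, "': disabled but no cached artifact in ",
             config$out_dir)
      }
      readRDS(cache(name))
    }
  }

  profiles <- stage("profiles", function() {
    cfg <- config$synthetic
    cfg$seed <- config$stage_seeds[["profiles"]]
    generate_profiles(cfg, hierarchy)
  })
  write_expression_matrix(profiles$tpm, file.path(config$out_dir, "purified_tpm.tsv"))
  utils::write.table(profiles$sample_meta,
                     file.path(config$out_dir, "purified_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  design <- stage("design", function() {
    if (config$use_full_layout) {
      assemble_challenge_layout(config$stage_seeds[["design"]],
                                hierarchy = hierarchy, model = model)
    } else {
      .reduced_layout(config, hierarchy, model)
    }
  })
  write_design(design, file.path(config$out_dir, "design.tsv"))

  datasets <- stage("mix", function() {
    list(tpm = mix_tpm(profiles, design),
         counts = mix_counts(profiles, design))
  })
  write_expression_matrix(datasets$tpm$expression,
                          file.path(config$out_dir, "admixture_tpm.tsv"))

  sig <- build_signature(profiles)
  predictions <- stage("deconvolve", function() {
    stats::setNames(lapply(config$methods, .run_method,
                           dataset = datasets$tpm, sig = sig),
                    config$methods)
  })
  for (m in names(predictions)) {
    write_predictions(predictions[[m]],
                      file.path(config$out_dir, paste0("pred_", m, ".tsv")))
  }

  ranking <- stage("score", function() {
    rank_methods(predictions, design, n_boot = config$n_boot,
                 seed = config$stage_seeds[["score"]])
  })
  utils::write.table(cbind(config_hash = hash, ranking),
                     file.path(config$out_dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  spill <- stage("spillover", function() {
    panel <- make_purified_panel(profiles)
    res <- lapply(config$methods, function(m) {
      sp <- spillover_matrix(.run_method(m, panel, sig), panel$design)
      spillover_summary(sp)
    })
    stats::setNames(res, config$methods)
  })

  lod <- stage("lod", function() {
    if (!length(config$spikein_targets)) return(NULL)
    res <- lapply(config$spikein_targets, function(tg) {
      series <- make_spikein_series(profiles, tg, hierarchy,
                                    n_reps = config$spikein_reps,
                                    seed = config$stage_seeds[["lod"]])
      per_method <- lapply(config$methods, function(m) {
        limit_of_detection(.run_method(m, series$dataset, sig), series,
                           alpha = config$alpha)$lod
      })
      stats::setNames(unlist(per_method), config$methods)
    })
    stats::setNames(res, config$spikein_targets)
  })

  provenance <- data.frame(seed = config$seed, config_hash = hash,
                           package_version = as.character(utils::packageVersion("admixbench")),
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  utils::write.table(provenance, file.path(config$out_dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(profiles = profiles, design = design, datasets = datasets,
       predictions = predictions, ranking = ranking, spillover = spill,
       lod = lod, provenance = provenance)
}
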