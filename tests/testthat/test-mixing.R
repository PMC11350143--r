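one_hot_design <- function(types, hot, batch = "batch1") {
  props <- matrix(0, nrow = 1, ncol = length(types),
                  dimnames = list("adm1", types))
  props[1, hot] <- 1
  admixture_design(props, data.frame(dataset = "D", batch = batch))
}

test_that("a one-hot design reproduces the matching purified profile", {
  pl <- tiny_profiles()
  h <- tiny_hierarchy()
  types <- c(h$fine_types, h$cancer_types)
  ds <- mix_tpm(pl, one_hot_design(types, "B", batch = "batch1"))
  rep_id <- pl$sample_meta$sample_id[pl$sample_meta$cell_type == "B" &
                                       pl$sample_meta$batch == "batch1"][1]
  expect_equal(unname(ds$expression[, 1]), unname(pl$tpm[, rep_id]))
})

test_that("mixing matches an independent per-gene accumulation loop", {
  mx <- tiny_mixture(n = 4)
  pl <- tiny_profiles()
  pr <- mx$design$proportions
  for (s in seq_len(nrow(pr))) {
    batch <- mx$design$meta$batch[s]
    manual <- numeric(length(pl$genes))
    for (ct in colnames(pr)) {
      if (pr[s, ct] == 0) next
      meta <- pl$sample_meta
      hit <- which(meta$cell_type == ct & meta$batch == batch)[1]
      for (g in seq_along(manual)) {
        manual[g] <- manual[g] + pr[s, ct] * pl$tpm[g, hit]
      }
    }
    expect_equal(unname(mx$dataset$expression[, s]), manual, tolerance = 1e-10)
  }
})

test_that("mixing is linear in the design", {
  pl <- tiny_profiles()
  h <- tiny_hierarchy()
  types <- c(h$fine_types, h$cancer_types)
  set.seed(2)
  p1 <- broken_stick(length(types), n_candidates = 1)
  p2 <- broken_stick(length(types), n_candidates = 1)
  alpha <- 0.3
  mk <- function(p) {
    colnames(p) <- types
    mix_tpm(pl, admixture_design(p, data.frame(dataset = "D", batch = "batch1")))
  }
  blended <- mk(alpha * p1 + (1 - alpha) * p2)$expression
  expect_equal(blended,
               alpha * mk(p1)$expression + (1 - alpha) * mk(p2)$expression,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pseudo-count scaling follows the median library-size rule", {
  pl <- tiny_profiles()
  # equal library sizes: pseudo-counts equal raw counts
  pl_eq <- pl
  pl_eq$counts <- matrix(5L, nrow = 4, ncol = ncol(pl$counts),
                         dimnames = list(paste0("g", 1:4),
                                         colnames(pl$counts)))
  pl_eq$tpm <- sweep(pl_eq$counts, 2, colSums(pl_eq$counts), "/") * 1e6
  pl_eq$genes <- rownames(pl_eq$counts)
  h <- tiny_hierarchy()
  types <- c(h$fine_types, h$cancer_types)
  d <- one_hot_design(types, "naive_T")
  ds <- mix_counts(pl_eq, d)
  rep_id <- pl$sample_meta$sample_id[pl$sample_meta$cell_type == "naive_T" &
                                       pl$sample_meta$batch == "batch1"][1]
  expect_equal(unname(ds$expression[, 1]), unname(pl_eq$counts[, rep_id]))

  # two samples with totals 100 and 300: scale factors 2 and 2/3 (median 200)
  counts <- cbind(s1 = c(60L, 40L), s2 = c(100L, 200L))
  rownames(counts) <- c("g1", "g2")
  totals <- colSums(counts)
  expect_equal(unname(totals), c(100, 300))
  med <- median(totals)
  expect_equal(unname(med / totals), c(2, 2 / 3))
  pseudo <- sweep(counts, 2, med / totals, "*")
  expect_equal(unname(colSums(pseudo)), c(200, 200))
})

test_that("zero-total purified samples are rejected", {
  pl <- tiny_profiles()
  pl$counts[, 1] <- 0L
  mx <- tiny_mixture(n = 3)
  expect_error(mix_counts(pl, mx$design), "zero-total")
})

test_that("the spike-in grid holds the four stated ranges", {
  lv <- spikein_levels()
  expect_equal(lv[1], 0)
  expect_true(all(diff(lv) > 0))
  # segment steps: 0.01% / 0.1% / 1% / 2%
  expect_equal(unique(round(diff(lv[lv <= 0.001]), 10)), 1e-4)
  expect_equal(unique(round(diff(lv[lv >= 0.001 & lv <= 0.01]), 10)), 1e-3)
  expect_equal(unique(round(diff(lv[lv >= 0.01 & lv <= 0.2]), 10)), 1e-2)
  expect_equal(unique(round(diff(lv[lv >= 0.2]), 10)), 2e-2)
  expect_equal(max(lv), 0.4)
})

test_that("spike-in series reuse backgrounds and keep truth monotone", {
  pl <- tiny_profiles()
  h <- tiny_hierarchy()
  ser <- make_spikein_series(pl, "B", h, n_reps = 4, seed = 12)
  pr <- ser$design$proportions
  expect_equal(nrow(pr), 49 * 4)
  # each level has exactly n_reps admixtures
  expect_true(all(table(ser$series$level) == 4))
  # target truth strictly increases along the grid for each replicate
  for (r in 1:4) {
    tr <- pr[ser$series$replicate == r, "B"]
    expect_true(all(diff(tr[order(ser$series$level[ser$series$replicate == r])]) > 0))
  }
  # background composition is shared across levels (renamed fixed slot)
  bg <- pr[, setdiff(colnames(pr), "B")]
  rel <- bg / rowSums(bg)
  r1 <- rel[ser$series$replicate == 1, ]
  expect_true(all(abs(sweep(r1, 2, r1[1, ])) < 1e-9))
  expect_error(make_spikein_series(pl, "no_such_type", h), "unknown cell type")
})

test_that("coarse spike-in targets split across children and sum exactly", {
  pl <- default_profiles()
  h <- default_hierarchy()
  ser <- make_spikein_series(pl, "CD8_T_cells", h, n_reps = 2, seed = 5)
  pr <- ser$design$proportions
  kids <- c("memory_CD8_T", "naive_CD8_T")
  lv <- ser$series$level
  expect_equal(unname(rowSums(pr[, kids])), lv, tolerance = 1e-12)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
})

test_that("the purified panel is one-hot and reproduces profiles", {
  pl <- tiny_profiles()
  panel <- make_purified_panel(pl)
  pr <- panel$design$proportions
  expect_equal(nrow(pr), sum(!grepl("^cancer", pl$sample_meta$cell_type)))
  expect_true(all(rowSums(pr) == 1))
  expect_true(all(pr %in% c(0, 1)))
  for (i in seq_len(nrow(pr))) {
    sample_id <- pl$sample_meta$sample_id[match(rownames(pr)[i],
                                                pl$sample_meta$sample_id)]
    expect_equal(unname(panel$expression[, i]), unname(pl$tpm[, sample_id]))
  }
})
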