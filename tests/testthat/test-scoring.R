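toy_table <- function(values, datasets, types = colnames(values)) {
  design <- admixture_design(values, data.frame(dataset = datasets),
                             granularity = "fine")
  design
}

test_that("perfect and anti-perfect predictions score 1 and -1", {
  mx <- tiny_mixture(n = 8)
  orc <- oracle_method(mx$design)
  expect_equal(hierarchical_score(orc, mx$design, "pearson")$score, 1)
  expect_equal(hierarchical_score(orc, mx$design, "spearman")$score, 1)
  anti <- orc
  anti$values <- -anti$values + 1
  anti <- prediction_table(anti$values, "anti", "fraction")
  expect_equal(hierarchical_score(anti, mx$design, "pearson")$score, -1)
})

test_that("the hierarchical score is a mean of means, not a pooled r", {
  set.seed(5)
  truth <- matrix(runif(24), nrow = 12,
                  dimnames = list(paste0("s", 1:12), c("ctA", "ctB")))
  truth <- cbind(truth / rowSums(truth) * 0.6, other = 0.4)
  pred <- truth[, 1:2] + matrix(rnorm(24, sd = 0.1), nrow = 12)
  datasets <- rep(c("D1", "D2"), each = 6)
  design <- admixture_design(truth, data.frame(dataset = datasets))
  pt <- prediction_table(pred, "m", "normalized")
  got <- hierarchical_score(pt, design, "pearson",
                            cell_types = c("ctA", "ctB"))
  # scalar-loop oracle
  rs <- c()
  for (d in c("D1", "D2")) {
    per_ct <- c()
    for (ct in c("ctA", "ctB")) {
      i <- datasets == d
      per_ct <- c(per_ct, cor(pred[i, ct], truth[i, ct]))
    }
    rs <- c(rs, mean(per_ct))
  }
  expect_equal(got$score, mean(rs))
  pooled <- cor(as.vector(pred), as.vector(truth[, 1:2]))
  expect_false(isTRUE(all.equal(got$score, pooled)))
})

test_that("undefined correlations are excluded with a count", {
  mx <- tiny_mixture(n = 8)
  pred <- oracle_method(mx$design)
  pred$values[, "B"] <- 0.5  # constant prediction: undefined correlation
  pt <- prediction_table(pred$values, "m", "fraction")
  got <- hierarchical_score(pt, mx$design, "pearson")
  expect_equal(got$n_undefined, length(unique(mx$design$meta$dataset)))
  expect_equal(got$score, 1)  # remaining cell types are perfect
})

test_that("Bayes factors detect dominance and respect reciprocity", {
  mx <- tiny_mixture(n = 16)
  orc <- oracle_method(mx$design)
  set.seed(77)
  noise <- prediction_table(
    matrix(runif(length(orc$values)), nrow = nrow(orc$values),
           dimnames = dimnames(orc$values)), "noise", "fraction")
  cmp <- bootstrap_compare(orc, noise, mx$design, n_boot = 100, seed = 1)
  expect_gt(cmp$K, 3)
  expect_true(cmp$significant)
  # identical methods tie with K = 1 by convention
  cmp_same <- bootstrap_compare(orc, orc, mx$design, n_boot = 50, seed = 2)
  expect_equal(cmp_same$K, 1)
  expect_equal(cmp_same$ties, 50)
  # reciprocity when both counts are positive
  mid <- orc
  mid$values <- 0.5 * orc$values +
    0.5 * matrix(runif(length(orc$values)), nrow = nrow(orc$values))
  cmp_ab <- bootstrap_compare(orc, mid, mx$design, n_boot = 200, seed = 3)
  cmp_ba <- bootstrap_compare(mid, orc, mx$design, n_boot = 200, seed = 3)
  if (cmp_ab$wins_a > 0 && cmp_ab$wins_b > 0) {
    expect_equal(cmp_ab$K * cmp_ba$K, 1, tolerance = 1e-12)
  }
})

test_that("the bootstrap matches an independent duplicate loop exactly", {
  mx <- tiny_mixture(n = 10)
  orc <- oracle_method(mx$design)
  set.seed(55)
  other <- prediction_table(
    orc$values + matrix(rnorm(length(orc$values), sd = 0.15),
                        nrow = nrow(orc$values),
                        dimnames = dimnames(orc$values)), "b", "normalized")
  got <- bootstrap_compare(orc, other, mx$design, n_boot = 50, seed = 99)
  # independent re-implementation of the resampling loop
  datasets <- mx$design$meta$dataset
  cts <- setdiff(colnames(orc$values), "cancer_X")
  set.seed(99)
  wins_a <- wins_b <- 0
  for (i in 1:50) {
    take <- c()
    for (d in unique(datasets)) {
      ix <- which(datasets == d)
      take <- c(take, ix[sample.int(length(ix), length(ix), replace = TRUE)])
    }
    score_of <- function(vals) {
      per_ds <- c()
      for (d in unique(datasets)) {
        sel <- take[datasets[take] == d]
        per_ct <- c()
        for (ct in cts) {
          tv <- mx$design$proportions[sel, ct]
          pv <- vals[sel, ct]
          if (sd(tv) == 0 || sd(pv) == 0) next
          per_ct <- c(per_ct, cor(pv, tv))
        }
        per_ds <- c(per_ds, mean(per_ct))
      }
      mean(per_ds)
    }
    sa <- score_of(orc$values); sb <- score_of(other$values)
    if (sa > sb) wins_a <- wins_a + 1
    if (sb > sa) wins_b <- wins_b + 1
  }
  expect_equal(got$wins_a, wins_a)
  expect_equal(got$wins_b, wins_b)
  expect_equal(got$K, wins_a / wins_b)
})

test_that("ranking applies the two-stage tie rule", {
  mx <- tiny_mixture(n = 12)
  orc <- oracle_method(mx$design)
  single <- rank_methods(list(only = orc), mx$design, n_boot = 10, seed = 1)
  expect_equal(single$rank, 1)

  set.seed(8)
  noise <- prediction_table(
    matrix(runif(length(orc$values)), nrow = nrow(orc$values),
           dimnames = dimnames(orc$values)), "noise", "fraction")
  two <- rank_methods(list(good = orc, bad = noise), mx$design,
                      n_boot = 100, seed = 2)
  expect_equal(two$method, c("good", "bad"))
  expect_false(two$tied_with_top[two$method == "bad"])

  # a monotone transform of the oracle ties on Pearson bootstrap draws in
  # most resamples and keeps its Spearman score at 1
  warped <- prediction_table(orc$values^1.05, "warped", "fraction")
  three <- rank_methods(list(oracle = orc, warped = warped, noise = noise),
                        mx$design, n_boot = 100, seed = 3)
  expect_equal(sort(three$method[1:2]), c("oracle", "warped"))
  expect_equal(three$method[3], "noise")
})

test_that("within-sample metrics follow the stated formulas", {
  mx <- tiny_mixture(n = 6)
  orc <- oracle_method(mx$design)
  got <- within_sample_metrics(orc, mx$design)
  expect_equal(got$summary[["pearson"]], 1)
  expect_equal(got$summary[["rmse"]], 0)

  truth <- matrix(c(0.2, 0.3, 0.5), nrow = 1,
                  dimnames = list("s1", c("a", "b", "c")))
  pred <- matrix(c(0.3, 0.3, 0.4), nrow = 1,
                 dimnames = list("s1", c("a", "b", "c")))
  design <- admixture_design(truth, data.frame(dataset = "D"))
  pt <- prediction_table(pred, "m", "proportion")
  got2 <- within_sample_metrics(pt, design)
  expect_equal(got2$per_sample$rmse, sqrt(0.02 / 3))

  const <- prediction_table(matrix(0.33, 1, 3,
                                   dimnames = dimnames(pred)), "c", "fraction")
  got3 <- within_sample_metrics(const, design)
  expect_true(is.na(got3$per_sample$pearson))

  score_pt <- prediction_table(pred, "s", "score")
  expect_error(within_sample_metrics(score_pt, design), "not comparable")
})

test_that("within-sample ties reproduce closed-form OLS t statistics", {
  set.seed(12)
  n <- 30
  tab <- data.frame(
    method = rep(c("top", "close", "far"), each = n),
    sample = rep(seq_len(n), 3),
    value = c(rnorm(n, 0.8, 0.05), rnorm(n, 0.79, 0.05), rnorm(n, 0.4, 0.05)))
  tied <- tie_test_within_sample(tab, "top")
  expect_true("close" %in% tied)
  expect_false("far" %in% tied)
  # closed-form oracle: per-coefficient t statistics from the design algebra
  y <- tab$value
  X <- cbind(1, tab$method == "close", tab$method == "far")
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - 3)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df = length(y) - 3, lower.tail = FALSE)
  expect_equal("close" %in% tied, p[2] > 0.05)
  expect_equal("far" %in% tied, p[3] > 0.05)

  # two identical methods tie with p = 1
  tab2 <- tab[tab$method != "far", ]
  tab2$value[tab2$method == "close"] <- tab2$value[tab2$method == "top"]
  expect_true("close" %in% tie_test_within_sample(tab2, "top"))
})

test_that("consensus ranks average individual rankings", {
  v1 <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(paste0("s", 1:3), "A"))
  v2 <- matrix(c(3, 2, 1), ncol = 1, dimnames = list(paste0("s", 1:3), "A"))
  ens <- consensus_rank(list(prediction_table(v1, "m1", "score"),
                             prediction_table(v2, "m2", "score")))
  expect_equal(unname(ens$values[, "A"]), c(2, 2, 2))

  # consensus of identical methods preserves their ordering
  same <- consensus_rank(list(prediction_table(v1, "m1", "score"),
                              prediction_table(v1, "m2", "score")))
  expect_equal(order(same$values[, "A"]), order(v1[, "A"]))

  # two agreeing methods outvote one dissenter
  set.seed(3)
  truth <- runif(5)
  good <- matrix(truth + rnorm(5, sd = 0.01), ncol = 1,
                 dimnames = list(paste0("s", 1:5), "A"))
  good2 <- matrix(truth + rnorm(5, sd = 0.01), ncol = 1,
                  dimnames = list(paste0("s", 1:5), "A"))
  bad <- matrix(rev(truth), ncol = 1, dimnames = list(paste0("s", 1:5), "A"))
  ens3 <- consensus_rank(list(prediction_table(good, "g", "score"),
                              prediction_table(good2, "h", "score"),
                              prediction_table(bad, "b", "score")))
  r_ens <- cor(ens3$values[, "A"], truth, method = "spearman")
  r_bad <- cor(bad[, "A"], truth, method = "spearman")
  expect_gte(r_ens, r_bad)
})

test_that("cross-dataset effects center, test one-sided and adjust", {
  df <- expand.grid(method = c("m1", "m2", "m3"),
                    dataset = c("D1", "D2"),
                    cell_type = "ct", stringsAsFactors = FALSE)
  df$r <- 0.8
  got <- cross_dataset_effects(df)
  expect_equal(got$coefficient, c(0, 0))
  expect_equal(got$p_raw, c(0.5, 0.5))

  # one dataset uniformly offset by -0.1: coefficients -0.05 / +0.05
  df2 <- df
  df2$r[df2$dataset == "D2"] <- 0.7
  got2 <- cross_dataset_effects(df2)
  expect_equal(got2$coefficient[got2$dataset == "D2"], -0.05)
  expect_equal(got2$coefficient[got2$dataset == "D1"], 0.05)
  expect_lt(got2$p_raw[got2$dataset == "D2"], 0.5)
  # Holm adjustment never lowers a p-value
  expect_true(all(got2$p_adjusted >= got2$p_raw - 1e-15))
})
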