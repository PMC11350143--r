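test_that("disjointly expressed genes become exactly the markers", {
  genes <- paste0("g", 1:6)
  types <- c("A", "B", "C")
  tpm <- matrix(0, nrow = 6, ncol = 6,
                dimnames = list(genes, paste0(rep(types, each = 2), "_r",
                                              rep(1:2, 3))))
  tpm[1:2, 1:2] <- 100; tpm[3:4, 3:4] <- 200; tpm[5:6, 5:6] <- 300
  pl <- list(genes = genes, tpm = tpm,
             sample_meta = data.frame(sample_id = colnames(tpm),
                                      cell_type = rep(types, each = 2),
                                      batch = "batch1", replicate = rep(1:2, 3)))
  sig <- build_signature(pl, markers_per_type = 5, types = types)
  expect_setequal(sig$marker_sets$A, c("g1", "g2"))
  expect_setequal(sig$marker_sets$B, c("g3", "g4"))
  expect_setequal(sig$marker_sets$C, c("g5", "g6"))
  # diagonal-blocked signature: zero expression off the own-type block
  expect_equal(unname(sig$signature[c("g1", "g2"), c("B", "C")]),
               matrix(0, 2, 2))
})

test_that("a gene expressed equally in two types is dropped by specificity", {
  genes <- paste0("g", 1:4)
  tpm <- rbind(g1 = c(100, 100, 100, 0),   # equally high in A and B
               g2 = c(80, 80, 0, 0),
               g3 = c(0, 0, 100, 0),
               g4 = c(0, 0, 0, 200))
  colnames(tpm) <- c("A_r1", "A_r2", "B_r1", "C_r1")
  pl <- list(genes = genes, tpm = tpm,
             sample_meta = data.frame(sample_id = colnames(tpm),
                                      cell_type = c("A", "A", "B", "C"),
                                      batch = "batch1",
                                      replicate = c(1, 2, 1, 1)))
  # g1 qualifies for both A and B, so the specificity filter drops it
  sig <- build_signature(pl, markers_per_type = 5, min_fold = 2,
                         types = c("A", "B", "C"))
  expect_false("g1" %in% sig$marker_sets$A)
  expect_false("g1" %in% sig$marker_sets$B)
})

test_that("planted markers are recovered from the synthetic library", {
  pl <- default_profiles()
  sig <- default_signature()
  planted <- pl$marker_sets[names(sig$marker_sets)]
  hit_rate <- mean(vapply(names(planted), function(ct) {
    mean(planted[[ct]] %in% sig$marker_sets[[ct]])
  }, numeric(1)))
  expect_gte(hit_rate, 0.9)
})

test_that("marker summaries follow the stated arithmetic", {
  expr <- matrix(c(2, 4, 6, 0, 0, 0), ncol = 2,
                 dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  ms <- list(A = c("g1", "g2", "g3"))
  mean_pred <- deconvolve_marker_summary(expr, ms, "mean")
  sum_pred <- deconvolve_marker_summary(expr, ms, "sum")
  expect_equal(unname(mean_pred$values["s1", "A"]), 4)
  expect_equal(unname(sum_pred$values["s1", "A"]), 12)
  expect_equal(unname(mean_pred$values["s2", "A"]), 0)
  expect_equal(mean_pred$output_scale, "score")
  # degree-1 homogeneity in the admixture
  expect_equal(deconvolve_marker_summary(3 * expr, ms, "mean")$values,
               3 * mean_pred$values)
  expect_error(deconvolve_marker_summary(expr, list(B = "absent")),
               "no markers")
  expect_warning(deconvolve_marker_summary(expr, list(A = c("g1", "zz"))),
                 "dropped")
})

test_that("constrained least squares solves the identity KKT case", {
  S <- diag(2)
  rownames(S) <- c("m1", "m2"); colnames(S) <- c("A", "B")
  a <- matrix(c(0.3, 0.7), ncol = 1, dimnames = list(c("m1", "m2"), "s1"))
  fit <- deconvolve_cls(a, S)
  expect_equal(unname(fit$values[1, ]), c(0.3, 0.7), tolerance = 1e-8)
  expect_equal(fit$output_scale, "proportion")
})

test_that("noiseless feasible mixtures are recovered to 1e-6", {
  sig <- default_signature()$signature
  set.seed(31)
  k <- ncol(sig)
  beta <- matrix(runif(5 * k, 0.01, 0.1), nrow = 5)
  beta <- beta / rowSums(beta) * runif(5, 0.6, 0.95)  # strictly inside
  a <- sig %*% t(beta)
  colnames(a) <- paste0("s", 1:5)
  fit <- deconvolve_cls(a, sig)
  expect_equal(unname(fit$values), beta, tolerance = 1e-6)
  hub <- deconvolve_huber(a, sig)
  expect_equal(unname(hub$values), beta, tolerance = 1e-6)
})

test_that("an infeasible scale is projected onto the sum-one boundary", {
  sig <- default_signature()$signature[, 1:2]
  beta_big <- c(1.4, 0.8)  # unconstrained optimum sums over 1
  a <- matrix(sig %*% beta_big, ncol = 1,
              dimnames = list(rownames(sig), "s1"))
  fit <- deconvolve_cls(a, sig)
  expect_equal(sum(fit$values), 1, tolerance = 1e-6)
  # fine grid search over the constrained simplex as oracle
  grid <- seq(0, 1, by = 0.002)
  best <- c(NA, NA); best_val <- Inf
  for (b1 in grid) {
    b2 <- pmin(1 - b1, grid)
    loss <- colSums((matrix(a, nrow(sig), length(b2)) -
                       outer(sig[, 1], rep(b1, length(b2))) -
                       outer(sig[, 2], b2))^2)
    j <- which.min(loss)
    if (loss[j] < best_val) { best_val <- loss[j]; best <- c(b1, b2[j]) }
  }
  expect_equal(unname(fit$values[1, ]), best, tolerance = 5e-3)
})

test_that("nu-SVR clips negatives and identifies a pure column", {
  sig <- default_signature()$signature
  # a pure column: the admixture is exactly one signature column
  a <- matrix(sig[, 3], ncol = 1, dimnames = list(rownames(sig), "s1"))
  fit <- deconvolve_nusvr(a, sig)
  expect_true(all(fit$values >= 0))
  expect_equal(unname(which.max(fit$values[1, ])), 3)
  expect_equal(fit$output_scale, "fraction")
  const <- matrix(1, nrow = nrow(sig), ncol = 1,
                  dimnames = list(rownames(sig), "s1"))
  expect_error(deconvolve_nusvr(const, sig), "constant")
})

test_that("Huber equals least squares without outliers and resists one", {
  set.seed(7)
  S <- matrix(rexp(40), nrow = 20,
              dimnames = list(paste0("m", 1:20), c("A", "B")))
  beta <- c(0.4, 0.3)
  a_clean <- S %*% beta
  colnames(a_clean) <- "s1"
  hub <- deconvolve_huber(a_clean, S)
  ols <- qr.solve(S, a_clean)
  expect_equal(unname(hub$values[1, ]), unname(drop(ols)), tolerance = 1e-6)

  a_out <- a_clean
  a_out[5, 1] <- a_out[5, 1] + 50  # gross corruption of one marker
  hub_o <- deconvolve_huber(a_out, S)
  ols_o <- pmax(qr.solve(S, a_out), 0)
  err_h <- sum((hub_o$values[1, ] - beta)^2)
  err_o <- sum((ols_o - beta)^2)
  expect_lt(err_h, err_o)

  # k -> infinity reduces Huber to ordinary least squares
  hub_inf <- deconvolve_huber(a_out, S, k = 1e6)
  expect_equal(unname(hub_inf$values[1, ]), unname(pmax(drop(qr.solve(S, a_out)), 0)),
               tolerance = 1e-6)
})

test_that("all solvers track truth on noiseless synthetic mixtures", {
  h <- default_hierarchy()
  pl <- cached("noiseless_profiles",
               generate_profiles(synthetic_config(baseline_dispersion = 0,
                                                  batch_effect_sd = 0,
                                                  library_size_range = c(1e6, 1e6),
                                                  seed = 13), h))
  sig <- cached("noiseless_signature", build_signature(pl))
  panel <- admixture_panel(h, "in_silico")
  set.seed(41)
  props <- broken_stick(length(panel) + 1, proportion_constraint(step = 0.001),
                        n_candidates = 15)
  colnames(props) <- c("cancer_BRCA", panel)
  meta <- data.frame(dataset = "D1", batch = "batch1")[rep(1, nrow(props)), ]
  design <- admixture_design(props, meta)
  ds <- mix_tpm(pl, design)

  check_r <- function(pred, threshold) {
    r <- vapply(panel, function(ct) {
      cor(pred$values[, ct], props[, ct])
    }, numeric(1))
    expect_true(all(r >= threshold), info = paste(pred$method, "min r =",
                                                  round(min(r), 3)))
  }
  check_r(deconvolve_marker_summary(ds, sig$marker_sets, "mean"), 0.95)
  check_r(deconvolve_cls(ds, sig$signature), 0.99)
  check_r(deconvolve_huber(ds, sig$signature), 0.99)
  check_r(deconvolve_nusvr(ds, sig$signature), 0.95)
})

test_that("the oracle method reproduces the design", {
  mx <- tiny_mixture(n = 6)
  orc <- oracle_method(mx$design)
  expect_equal(orc$values, mx$design$proportions)
  expect_equal(orc$output_scale, "proportion")
})
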