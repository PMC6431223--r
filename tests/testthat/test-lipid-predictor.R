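# small handmade lipid matrices for the normalization/merge layer
mk_series <- function(values, classes, series = 1L) {
  n <- nrow(values)
  samples <- data.frame(
    sample_id = paste0("g", seq_len(n), "_s", series),
    genotype = paste0("g", seq_len(n)), series = series,
    replicate = 1L, inheritance_class = classes)
  rownames(values) <- samples$sample_id
  lipid_matrix(values, samples,
               data.frame(lipid_id = colnames(values),
                          lipid_class = rep("PC", ncol(values))))
}

test_that("normalization log-transforms and centers on class-1 medians", {
  v <- matrix(c(exp(1), exp(1), exp(1), 5), ncol = 1,
              dimnames = list(NULL, "lipA"))
  m <- mk_series(v, classes = c(1L, 1L, 1L, 3L))
  nm <- normalize_series(m)
  expect_true(nm$normalized)
  # class-1 values e, e, e all become 0; the class-3 value becomes log(5) - 1
  expect_equal(unname(nm$values[1:3, 1]), rep(0, 3))
  expect_equal(unname(nm$values[4, 1]), log(5) - 1)
  expect_error(normalize_series(nm), "already normalized")
})

test_that("after normalization every class-1 per-series median is zero", {
  lip <- simulate_lipidome(n_genotypes = 8, n_lipids = 30, n_shared = 20,
                           seed = 12)
  for (nm in lapply(lip$series, normalize_series)) {
    ref <- nm$samples$inheritance_class == 1L
    med <- apply(nm$values[ref, , drop = FALSE], 2, median, na.rm = TRUE)
    expect_equal(unname(med), rep(0, ncol(nm$values)), tolerance = 1e-12)
  }
})

test_that("normalization rejects nonpositive levels and missing references", {
  v <- matrix(c(1, -2, 3, 4), ncol = 1, dimnames = list(NULL, "lipA"))
  m <- mk_series(v, classes = c(1L, 1L, 2L, 3L))
  expect_error(normalize_series(m), "nonpositive level.*lipA")
  v2 <- matrix(1:4, ncol = 1, dimnames = list(NULL, "lipA"))
  m2 <- mk_series(v2, classes = c(2L, 2L, 3L, 3L))
  expect_error(normalize_series(m2), "no inheritance-class-1")
})

test_that("merging keeps exactly the lipid intersection", {
  mk <- function(lipids, series) {
    v <- matrix(exp(seq_len(4 * length(lipids))), nrow = 4,
                dimnames = list(NULL, lipids))
    normalize_series(mk_series(v, classes = c(1L, 1L, 2L, 3L),
                               series = series))
  }
  same <- merge_series(list(mk(c("A", "B"), 1), mk(c("A", "B"), 2)))
  expect_equal(colnames(same$values), c("A", "B"))
  expect_length(attr(same, "dropped"), 0)

  mixed <- merge_series(list(mk(c("A", "B", "C"), 1), mk(c("A", "B"), 2),
                             mk("B", 3)))
  expect_equal(colnames(mixed$values), "B")
  expect_setequal(attr(mixed, "dropped"), c("A", "C"))
  expect_equal(nrow(mixed$values), 12)

  expect_error(merge_series(list(mk("A", 1), mk("B", 2))),
               "no lipid")
  expect_error(merge_series(list(mk("A", 1))), "at least 2")
})

test_that("constructed per-series dropout leaves the planted shared set", {
  lip <- simulate_lipidome(n_lipids = 184, n_shared = 102, seed = 3)
  merged <- merge_series(lapply(lip$series, normalize_series))
  expect_equal(ncol(merged$values), 102)
  expect_length(attr(merged, "dropped"), 82)
  # by construction no retained lipid has missing values in any series
  expect_false(anyNA(merged$values))
})

test_that("the L1 limit gives the intercept-only null model exactly", {
  lip <- simulate_lipidome(n_genotypes = 8, n_lipids = 30, n_shared = 20,
                           seed = 7)
  merged <- merge_series(lapply(lip$series, normalize_series))
  cfg <- lasso_config(n_runs = 1, seed = 5)
  run <- lasso_cv_run(merged, cfg, 1, lambda = Inf)
  expect_true(all(run$coefficients == 0))
  train_mean <- mean(as.numeric(
    merged$samples$inheritance_class[
      !merged$samples$genotype %in% run$holdout_genotypes]))
  expect_equal(unique(run$predicted), train_mean, tolerance = 1e-12)
  # at the data-derived maximal penalty of the path all coefficients are 0
  x <- merged$values
  y <- as.numeric(merged$samples$inheritance_class)
  fit <- glmnet::glmnet(x, y, alpha = 1)
  expect_true(all(abs(coef(fit, s = fit$lambda[1])[-1]) < 1e-12))
})

test_that("the unpenalized solution matches least squares on a reduced instance", {
  set.seed(19)
  n <- 60; p <- 5
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("l", 1:p)))
  beta <- c(2, -1, 0, 0.5, 0)
  y <- drop(x %*% beta) + rnorm(n, 0, 0.1)
  fit <- glmnet::glmnet(x, y, alpha = 1, lambda = c(0.5, 0.1, 0),
                        thresh = 1e-14)
  cf <- coef(fit, s = 0, exact = TRUE, x = x, y = y, thresh = 1e-14)
  ls <- coef(lm(y ~ x))
  expect_equal(as.vector(cf), unname(ls), tolerance = 1e-6)
})

test_that("a planted noiseless predictor yields near-perfect cvR", {
  set.seed(29)
  n_geno <- 12
  classes <- rep(1:4, each = 3)
  reps <- 4
  samples <- data.frame(
    sample_id = paste0("g", rep(seq_len(n_geno), each = reps), "_r",
                       rep(seq_len(reps), n_geno)),
    genotype = paste0("g", rep(seq_len(n_geno), each = reps)),
    series = 1L, replicate = rep(seq_len(reps), n_geno),
    inheritance_class = rep(classes, each = reps))
  x1 <- samples$inheritance_class / 2            # y = 2 * x1 exactly
  noise <- matrix(rnorm(nrow(samples) * 20), nrow(samples))
  vals <- cbind(x1, noise)
  colnames(vals) <- paste0("lip", 1:21)
  rownames(vals) <- samples$sample_id
  m <- lipid_matrix(vals, samples,
                    data.frame(lipid_id = colnames(vals),
                               lipid_class = "PC"), normalized = TRUE)
  rr <- run_repeated_lasso(m, lasso_config(n_runs = 10, seed = 3))
  expect_gte(median(rr$cvR, na.rm = TRUE), 0.99)
  sel <- select_predictive(rr)
  expect_true(sel$predictive[sel$lipid_id == "lip1"])
  expect_lte(sum(sel$predictive), 3)
})

test_that("cvR is flagged undefined when the held-out classes are constant", {
  lip <- simulate_lipidome(n_genotypes = 8, n_lipids = 30, n_shared = 20,
                           seed = 31)
  merged <- merge_series(lapply(lip$series, normalize_series))
  cfg <- lasso_config(n_runs = 1, seed = 1)
  # force a holdout of two genotypes with the same class by searching seeds
  found <- FALSE
  for (i in 1:50) {
    run <- lasso_cv_run(merged, lasso_config(n_runs = 1, seed = i), 1)
    cls <- unique(merged$samples$inheritance_class[
      merged$samples$genotype %in% run$holdout_genotypes])
    if (length(cls) == 1L) {
      expect_false(run$cvR_defined)
      expect_true(is.na(run$cvR))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("repeated runs are bit-reproducible given the seed", {
  lip <- simulate_lipidome(n_genotypes = 8, n_lipids = 30, n_shared = 20,
                           seed = 8)
  merged <- merge_series(lapply(lip$series, normalize_series))
  cfg <- lasso_config(n_runs = 5, seed = 17)
  r1 <- run_repeated_lasso(merged, cfg)
  r2 <- run_repeated_lasso(merged, cfg)
  expect_identical(r1$cvR, r2$cvR)
  expect_identical(lapply(r1$runs, `[[`, "coefficients"),
                   lapply(r2$runs, `[[`, "coefficients"))
})

test_that("predictive selection applies the 1-SD avgW threshold strictly", {
  mk_run <- function(cf) structure(list(coefficients = cf), class = "lasso_run")
  zero <- setNames(rep(0, 102), paste0("lip", 1:102))
  sel0 <- select_predictive(list(mk_run(zero), mk_run(zero)))
  expect_equal(sum(sel0$predictive), 0)  # threshold 0, strict inequality

  one <- zero
  one["lip1"] <- 10
  sel1 <- select_predictive(list(mk_run(one)))
  expect_equal(sel1$lipid_id[sel1$predictive], "lip1")
  expect_equal(attr(sel1, "threshold"), sd(c(10, rep(0, 101))))

  # signed means distinguish direction; mean_abs vs abs_mean rules differ
  # when signs flip across runs
  flip <- list(mk_run(one), mk_run(-one))
  expect_equal(select_predictive(flip, rule = "mean_abs")$avgW[1], 10)
  expect_equal(select_predictive(flip, rule = "abs_mean")$avgW[1], 0)
  expect_equal(select_predictive(flip)$mean_coefficient[1], 0)
})

test_that("class enrichment reproduces the hypergeometric odds structure", {
  report <- data.frame(
    lipid_id = paste0("lip", 1:100),
    avgW = 0, mean_coefficient = 0,
    predictive = c(rep(TRUE, 4), rep(FALSE, 16),   # class A: 4/20
                   rep(TRUE, 16), rep(FALSE, 64))) # class B: 16/80
  classes <- setNames(rep(c("A", "B"), c(20, 80)), report$lipid_id)
  en <- class_enrichment(report, classes)
  # representation proportional to the overall predictive fraction: OR = 1
  expect_equal(en$odds_ratio[en$lipid_class == "A"], 1, tolerance = 1e-6)
  expect_equal(en$p_value[en$lipid_class == "A"], 1)

  # all 5 class-C lipids predictive among 10 predictive of 100 total
  report2 <- data.frame(
    lipid_id = paste0("lip", 1:100), avgW = 0, mean_coefficient = 0,
    predictive = c(rep(TRUE, 5), rep(TRUE, 5), rep(FALSE, 90)))
  classes2 <- setNames(c(rep("C", 5), rep("D", 95)), report2$lipid_id)
  en2 <- class_enrichment(report2, classes2)
  expect_equal(en2$p_value[en2$lipid_class == "C"],
               oracle_fisher_p(matrix(c(5, 5, 0, 90), 2, byrow = TRUE)),
               tolerance = 1e-12)

  # empty predictive set: every p = 1
  report3 <- report
  report3$predictive <- FALSE
  en3 <- class_enrichment(report3, classes)
  expect_true(all(en3$p_value == 1))

  expect_error(class_enrichment(report, classes[1:50]), "without class")
})

test_that("long-format CSV round-trips into per-series matrices", {
  lip <- simulate_lipidome(n_genotypes = 6, n_replicates = 2, n_lipids = 12,
                           n_shared = 8, n_planted = 2, seed = 41)
  long <- do.call(rbind, lapply(lip$series, function(m) {
    idx <- expand.grid(i = seq_len(nrow(m$values)),
                       j = seq_len(ncol(m$values)))
    data.frame(m$samples[idx$i, ],
               lipid_id = m$lipids$lipid_id[idx$j],
               lipid_class = m$lipids$lipid_class[idx$j],
               level = m$values[cbind(idx$i, idx$j)])
  }))
  back <- read_lipid_long(long)
  expect_equal(length(back), 3)
  for (s in names(back)) {
    orig <- lip$series[[paste0("series_", s)]]
    b <- back[[s]]
    expect_equal(b$values[rownames(orig$values), colnames(orig$values)],
                 orig$values)
  }
})
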