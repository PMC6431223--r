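# Prediction of inheritance strength from lipid levels: per-series
# normalization (log + median-centering on class-1 genotypes), cross-series
# merging to the shared lipid set, repeated leave-two-genotypes-out LASSO
# with inner 1-SE penalty selection, cvR summaries, predictive-lipid
# ranking by average absolute coefficient, and lipid-class enrichment.

#' Construct a lipid level matrix
#'
#' @param values numeric matrix, samples x lipids; rownames are sample ids,
#'   colnames lipid ids. Raw levels must be strictly positive.
#' @param samples `data.frame` with columns `sample_id`, `genotype`,
#'   `series`, `replicate`, `inheritance_class` (ordinal 1..5), one row per
#'   matrix row.
#' @param lipids `data.frame` with columns `lipid_id`, `lipid_class`
#'   (MGDG, DGDG, SQDG, PG, PC, PI, PE, FA, TAG, CoQ, chlorophyll,
#'   pheophytin), one row per matrix column.
#' @param normalized whether values are already log median-centered.
#' @return object of class `lipid_matrix`.
#' @export
lipid_matrix <- function(values, samples, lipids, normalized = FALSE) {
  stopifnot(is.matrix(values))
  if (nrow(values) != nrow(samples))
    stop("values rows and samples rows differ")
  if (ncol(values) != nrow(lipids))
    stop("values columns and lipids rows differ")
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  if (is.null(colnames(values))) colnames(values) <- lipids$lipid_id
  need_s <- c("sample_id", "genotype", "series", "replicate",
              "inheritance_class")
  if (!all(need_s %in% names(samples)))
    stop("samples need columns: ", paste(need_s, collapse = ", "))
  need_l <- c("lipid_id", "lipid_class")
  if (!all(need_l %in% names(lipids)))
    stop("lipids need columns: ", paste(need_l, collapse = ", "))
  structure(list(values = values, samples = samples, lipids = lipids,
                 normalized = isTRUE(normalized)),
            class = "lipid_matrix")
}

#' @export
print.lipid_matrix <- function(x, ...) {
  cat("lipid_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "lipids,", length(unique(x$samples$genotype)), "genotypes,",
      length(unique(x$samples$series)), "series",
      if (x$normalized) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' Read a long-format lipidomics CSV into per-series matrices
#'
#' @param data path to a CSV, or a `data.frame`, with columns `sample_id`,
#'   `genotype`, `series`, `replicate`, `inheritance_class`, `lipid_id`,
#'   `lipid_class`, `level`.
#' @return named list of raw single-series [lipid_matrix()] objects.
#' @export
read_lipid_long <- function(data) {
  if (is.character(data)) data <- read.table(data, sep = ",", header = TRUE)
  lapply(split(data, data$series), function(d) {
    wide <- stats::reshape(d[c("sample_id", "lipid_id", "level")],
                           idvar = "sample_id", timevar = "lipid_id",
                           direction = "wide")
    vals <- as.matrix(wide[, -1L, drop = FALSE])
    colnames(vals) <- sub("^level\\.", "", colnames(vals))
    rownames(vals) <- wide$sample_id
    smp <- unique(d[c("sample_id", "genotype", "series", "replicate",
                      "inheritance_class")])
    smp <- smp[match(rownames(vals), smp$sample_id), ]
    lip <- unique(d[c("lipid_id", "lipid_class")])
    lip <- lip[match(colnames(vals), lip$lipid_id), ]
    lipid_matrix(vals, smp, lip)
  })
}

#' Normalize lipid levels within each experimental series
#'
#' Per series and per lipid, all levels are log-transformed and the median
#' over that series' inheritance-class-1 samples is subtracted, so class-1
#' genotypes serve as the common reference across series (their per-series
#' median becomes 0 for every lipid).
#'
#' @param matrix a raw `lipid_matrix` (one or several series).
#' @return the normalized `lipid_matrix` (`normalized = TRUE`).
#' @export
normalize_series <- function(matrix) {
  stopifnot(inherits(matrix, "lipid_matrix"))
  if (matrix$normalized) stop("matrix is already normalized")
  vals <- matrix$values
  bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive level for sample '", rownames(vals)[bad[1L, 1L]],
         "', lipid '", colnames(vals)[bad[1L, 2L]], "'")
  lv <- log(vals)
  for (s in unique(matrix$samples$series)) {
    in_series <- matrix$samples$series == s
    ref <- in_series & matrix$samples$inheritance_class == 1L
    if (!any(ref))
      stop("series '", s, "' has no inheritance-class-1 genotype")
    med <- apply(lv[ref, , drop = FALSE], 2L, median, na.rm = TRUE)
    lv[in_series, ] <- sweep(lv[in_series, , drop = FALSE], 2L, med)
  }
  out <- matrix
  out$values <- lv
  out$normalized <- TRUE
  out
}

#' Merge normalized series on their shared lipid set
#'
#' Row-concatenates the series, restricted to lipids measured in every
#' series; lipids missing from any series are dropped (and reported in the
#' `dropped` attribute).
#'
#' @param matrices list (>= 2) of normalized `lipid_matrix` objects.
#' @return one normalized `lipid_matrix` over the lipid intersection.
#' @export
merge_series <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("need at least 2 series to merge")
  if (!all(vapply(matrices, function(m)
    inherits(m, "lipid_matrix") && m$normalized, logical(1L))))
    stop("all series must be normalized lipid_matrix objects")
  measured <- lapply(matrices, function(m)
    colnames(m$values)[colSums(!is.na(m$values)) == nrow(m$values)])
  shared <- Reduce(intersect, measured)
  if (!length(shared)) stop("no lipid is measured in every series")
  all_lipids <- unique(unlist(lapply(matrices,
                                     function(m) colnames(m$values))))
  vals <- do.call(rbind, lapply(matrices, function(m)
    m$values[, shared, drop = FALSE]))
  samples <- do.call(rbind, lapply(matrices, function(m) m$samples))
  rownames(samples) <- NULL
  lipids <- do.call(rbind, lapply(matrices, function(m) m$lipids))
  lipids <- unique(lipids)
  lipids <- lipids[match(shared, lipids$lipid_id), ]
  if (anyDuplicated(lipids$lipid_id))
    stop("inconsistent lipid-class assignment across series")
  out <- lipid_matrix(vals, samples, lipids, normalized = TRUE)
  attr(out, "dropped") <- setdiff(all_lipids, shared)
  out
}

#' LASSO cross-validation configuration
#'
#' @param n_runs number of repeated cross-validation runs (default 100).
#' @param holdout genotypes held out per run (default 2, drawn without
#'   replacement).
#' @param nfolds inner cross-validation folds for the penalty path
#'   (default 10).
#' @param seed master seed; each run derives its own sub-seed from it.
#' @return list of class `lasso_config` (mixing parameter alpha fixed at 1 =
#'   pure L1; penalty chosen by the inner-CV 1-SE rule, Gaussian response).
#' @export
lasso_config <- function(n_runs = 100L, holdout = 2L, nfolds = 10L,
                         seed = 1L) {
  structure(list(n_runs = as.integer(n_runs), holdout = as.integer(holdout),
                 nfolds = as.integer(nfolds), seed = as.integer(seed),
                 alpha = 1),
            class = "lasso_config")
}

.run_seed <- function(config, run_index) {
  (as.integer(config$seed) * 1009L + as.integer(run_index)) %% 2147483647L
}

#' One leave-two-genotypes-out LASSO run
#'
#' Holds out all replicate samples of `config$holdout` seeded-random
#' genotypes; on the remaining samples fits an L1-penalized (alpha = 1)
#' linear regression of the ordinal inheritance class (treated as a Gaussian
#' response) on the lipid levels, with the penalty chosen by inner k-fold
#' cross-validation at the 1-SE rule; predicts the held-out samples. cvR is
#' the Pearson correlation between actual and predicted strengths over all
#' held-out replicate samples (pooled; correlation over two genotype means
#' would be degenerate). If the held-out actuals (or predictions) are
#' constant, cvR is flagged undefined and the run is kept.
#'
#' @param matrix a merged, normalized `lipid_matrix` with >= 4 genotypes.
#' @param config a [lasso_config()].
#' @param run_index run number (1-based), which fixes the run's sub-seed.
#' @param lambda optional fixed penalty overriding the inner-CV choice
#'   (e.g. `Inf` for the intercept-only null model).
#' @return list of class `lasso_run`: `run_index`, `holdout_genotypes`,
#'   `lambda`, `intercept`, `coefficients` (named by lipid), `actual`,
#'   `predicted`, `cvR`, `cvR_defined`.
#' @export
lasso_cv_run <- function(matrix, config, run_index, lambda = NULL) {
  stopifnot(inherits(matrix, "lipid_matrix"), inherits(config, "lasso_config"))
  if (!matrix$normalized) stop("matrix must be normalized and merged")
  genotypes <- unique(matrix$samples$genotype)
  if (length(genotypes) < 4L) stop("need at least 4 genotypes")
  set.seed(.run_seed(config, run_index))
  held <- sample(genotypes, config$holdout)
  test <- matrix$samples$genotype %in% held
  x_train <- matrix$values[!test, , drop = FALSE]
  y_train <- as.numeric(matrix$samples$inheritance_class[!test])
  x_test <- matrix$values[test, , drop = FALSE]
  y_test <- as.numeric(matrix$samples$inheritance_class[test])
  foldid <- sample(rep(seq_len(config$nfolds),
                       length.out = length(y_train)))
  if (is.null(lambda)) {
    cvfit <- glmnet::cv.glmnet(x_train, y_train, alpha = config$alpha,
                               family = "gaussian", foldid = foldid)
    s <- cvfit$lambda.1se
    cf <- as.vector(coef(cvfit, s = "lambda.1se"))
    pred <- as.vector(predict(cvfit, newx = x_test, s = "lambda.1se"))
  } else {
    fit <- glmnet::glmnet(x_train, y_train, alpha = config$alpha,
                          family = "gaussian")
    s <- lambda
    if (is.infinite(lambda)) {
      # the L1 limit: all coefficients zero, prediction = training mean
      cf <- c(mean(y_train), rep(0, ncol(x_train)))
      pred <- rep(mean(y_train), nrow(x_test))
    } else {
      cf <- as.vector(coef(fit, s = s, exact = FALSE))
      pred <- as.vector(predict(fit, newx = x_test, s = s, exact = FALSE))
    }
  }
  defined <- sd(y_test) > 0 && sd(pred) > 0
  structure(
    list(run_index = run_index, holdout_genotypes = held, lambda = s,
         intercept = cf[1L],
         coefficients = setNames(cf[-1L], colnames(matrix$values)),
         actual = y_test, predicted = pred,
         cvR = if (defined) cor(y_test, pred) else NA_real_,
         cvR_defined = defined),
    class = "lasso_run")
}

#' Repeated leave-two-genotypes-out LASSO
#'
#' Runs [lasso_cv_run()] `config$n_runs` times (independent seeded holdouts
#' and fold assignments; bit-reproducible given the config seed) and
#' summarizes the cvR distribution.
#'
#' @param matrix a merged, normalized `lipid_matrix`.
#' @param config a [lasso_config()].
#' @return list of class `lasso_runs`: `runs` (list of `lasso_run`), `cvR`
#'   (numeric vector, NA where undefined), `cvR_histogram` (counts in bins
#'   of width 0.1 over `[-1, 1]`).
#' @export
run_repeated_lasso <- function(matrix, config) {
  runs <- lapply(seq_len(config$n_runs), function(i)
    lasso_cv_run(matrix, config, i))
  cvR <- vapply(runs, function(r) r$cvR, numeric(1L))
  breaks <- seq(-1, 1, by = 0.1)
  h <- table(cut(cvR[!is.na(cvR)], breaks = breaks, include.lowest = TRUE))
  structure(list(runs = runs, cvR = cvR, cvR_histogram = h,
                 config = config),
            class = "lasso_runs")
}

#' @export
print.lasso_runs <- function(x, ...) {
  cat("lasso_runs:", length(x$runs), "runs; cvR median =",
      signif(median(x$cvR, na.rm = TRUE), 3L), "(",
      sum(is.na(x$cvR)), "undefined )\n")
  invisible(x)
}

#' Rank lipids by their average LASSO weight
#'
#' Scores every lipid by avgW, its average coefficient magnitude across
#' runs, and flags it predictive when avgW exceeds one standard deviation of
#' the avgW values of all lipids (strict inequality). The signed mean
#' coefficient indicates whether the lipid correlates positively or
#' negatively with inheritance strength. `rule = "mean_abs"` (default)
#' averages absolute per-run coefficients; `"abs_mean"` takes the absolute
#' value of the mean coefficient.
#'
#' @param results a `lasso_runs` object (or list of `lasso_run`).
#' @param rule avgW definition, `"mean_abs"` or `"abs_mean"`.
#' @return `data.frame` (`lipid_id`, `avgW`, `mean_coefficient`,
#'   `predictive`) with the threshold in attribute `threshold`.
#' @export
select_predictive <- function(results, rule = c("mean_abs", "abs_mean")) {
  rule <- match.arg(rule)
  runs <- if (inherits(results, "lasso_runs")) results$runs else results
  if (!length(runs)) stop("no runs")
  cf <- vapply(runs, function(r) r$coefficients,
               numeric(length(runs[[1L]]$coefficients)))
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L,
                                     dimnames = list(names(runs[[1L]]$coefficients)))
  avgW <- switch(rule,
                 mean_abs = rowMeans(abs(cf)),
                 abs_mean = abs(rowMeans(cf)))
  threshold <- sd(avgW)
  out <- data.frame(lipid_id = rownames(cf), avgW = unname(avgW),
                    mean_coefficient = unname(rowMeans(cf)),
                    predictive = unname(avgW > threshold),
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- rule
  out
}

#' Lipid-class enrichment among predictive lipids
#'
#' For every lipid class, a two-sided Fisher's exact test on the 2x2 table
#' (predictive vs not x in-class vs not), reporting the raw p-value and the
#' odds ratio (no multiple-testing correction; classes absent from the
#' merged set are skipped with a warning).
#'
#' @param report output of [select_predictive()].
#' @param lipid_classes named character vector mapping every lipid id in the
#'   report to its class, or a `data.frame` with `lipid_id`, `lipid_class`.
#' @return `data.frame` (`lipid_class`, `n_class`, `n_predictive_in_class`,
#'   `odds_ratio`, `p_value`).
#' @export
class_enrichment <- function(report, lipid_classes) {
  if (is.data.frame(lipid_classes))
    lipid_classes <- setNames(lipid_classes$lipid_class,
                              lipid_classes$lipid_id)
  cls <- lipid_classes[report$lipid_id]
  if (anyNA(cls))
    stop("lipids without class assignment: ",
         paste(report$lipid_id[is.na(cls)], collapse = ", "))
  pred <- report$predictive
  rows <- lapply(unique(cls), function(k) {
    inc <- cls == k
    tab <- matrix(c(sum(pred & inc), sum(pred & !inc),
                    sum(!pred & inc), sum(!pred & !inc)),
                  nrow = 2L, byrow = TRUE)
    ft <- fisher.test(tab, alternative = "two.sided")
    data.frame(lipid_class = k, n_class = sum(inc),
               n_predictive_in_class = sum(pred & inc),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
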