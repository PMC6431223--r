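# Transmission-genetics and assay statistics: percent-biparental progeny
# from seedling counts, season-pooled Fisher's exact tests against the
# reference line, Kruskal-Wallis omnibus tests with rank-based post hocs,
# and the carboxylase (ACCase) activity arithmetic.

.validate_cross_counts <- function(counts) {
  need <- c("line_id", "season", "n_variegated", "n_total")
  if (!all(need %in% names(counts)))
    stop("cross counts need columns: ", paste(need, collapse = ", "))
  if (any(counts$n_total <= 0)) stop("n_total must be positive")
  if (any(counts$n_variegated < 0) ||
      any(counts$n_variegated > counts$n_total))
    stop("n_variegated must lie in [0, n_total]")
  if (any(counts$n_variegated != round(counts$n_variegated)) ||
      any(counts$n_total != round(counts$n_total)))
    stop("counts must be integral")
  counts
}

#' Percent biparental progeny per line
#'
#' The fraction of variegated (heteroplasmic) seedlings among all seedlings
#' scored, `100 * sum(variegated) / sum(total)` — per season and pooled over
#' seasons (pooling sums counts, i.e. weights seasons by their totals).
#'
#' @param counts `data.frame` with columns `line_id`, `season`,
#'   `n_variegated`, `n_total` (one row per cross per season).
#' @return list with `per_season` (`line_id`, `season`, `percent`) and
#'   `pooled` (`line_id`, `n_variegated`, `n_total`, `percent`).
#' @export
biparental_percent <- function(counts) {
  counts <- .validate_cross_counts(counts)
  per_season <- aggregate(cbind(n_variegated, n_total) ~ line_id + season,
                          data = counts, FUN = sum)
  per_season$percent <- 100 * per_season$n_variegated / per_season$n_total
  pooled <- aggregate(cbind(n_variegated, n_total) ~ line_id,
                      data = counts, FUN = sum)
  pooled$percent <- 100 * pooled$n_variegated / pooled$n_total
  list(per_season = per_season[order(per_season$line_id, per_season$season), ],
       pooled = pooled[order(pooled$line_id), ])
}

#' Fisher's exact test of a line against the reference line
#'
#' Counts are pooled over seasons for each line, then a two-sided Fisher's
#' exact test is run on the 2x2 table (variegated vs not x line vs
#' reference). The odds ratio is the conditional maximum-likelihood estimate
#' reported by [stats::fisher.test()].
#'
#' @param line_counts,reference_counts either `data.frame`s of cross counts
#'   (as in [biparental_percent()]; summed internally) or length-2 vectors
#'   `c(n_variegated, n_total)`.
#' @return list with `odds_ratio`, `p_value` and the pooled 2x2 `table`.
#' @export
fisher_vs_reference <- function(line_counts, reference_counts) {
  pool <- function(x) {
    if (is.data.frame(x)) {
      x <- .validate_cross_counts(x)
      c(sum(x$n_variegated), sum(x$n_total))
    } else {
      x <- as.numeric(x)
      if (length(x) != 2L || x[2L] <= 0 || x[1L] < 0 || x[1L] > x[2L])
        stop("counts must be c(n_variegated, n_total) with 0 <= v <= t")
      x
    }
  }
  a <- pool(line_counts)
  b <- pool(reference_counts)
  tab <- matrix(as.numeric(c(a[1L], a[2L] - a[1L], b[1L], b[2L] - b[1L])),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("line", "reference"),
                                c("variegated", "not_variegated")))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("degenerate 2x2 table: zero margin")
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Kruskal-Wallis one-way ANOVA on ranks
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom, via [stats::kruskal.test()]. Used as the omnibus test across
#' lines for paternal-plastome transmission fractions.
#'
#' @param groups list (length >= 2) of numeric vectors, one per line.
#' @return list with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L) {
    # every observation tied: the tie-corrected statistic degenerates to 0
    return(list(H = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Pairwise rank tests of each line against the reference
#'
#' Post hoc for the Kruskal-Wallis omnibus: two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test of every line against the reference line, with
#' Benjamini-Hochberg adjustment across lines.
#'
#' @param groups named list of numeric vectors.
#' @param reference name of the reference group.
#' @return `data.frame` (`line_id`, `p_value`, `p_adj`).
#' @export
pairwise_vs_reference <- function(groups, reference) {
  if (!reference %in% names(groups))
    stop("reference group '", reference, "' not found")
  others <- setdiff(names(groups), reference)
  p <- vapply(others, function(g)
    suppressWarnings(stats::wilcox.test(groups[[g]], groups[[reference]],
                                        alternative = "two.sided"))$p.value,
    numeric(1L))
  data.frame(line_id = others, p_value = p,
             p_adj = p.adjust(p, method = "BH"), row.names = NULL)
}

#' Chloroplast concentration from counting-chamber counts
#'
#' `chloroplasts per ml = 10 * average count per B square / (4e-6)`.
#'
#' @param avg_count_per_b_square mean chloroplast count per B square
#'   (>= 0).
#' @return chloroplasts per milliliter.
#' @export
chloroplast_concentration <- function(avg_count_per_b_square) {
  if (any(avg_count_per_b_square < 0)) stop("count must be >= 0")
  10 * avg_count_per_b_square / (4e-6)
}

#' ACCase activity of one sample
#'
#' Acetyl-CoA-dependent 14C fixation rate: total dpm divided by the
#' incubation time, averaged over technical replicates, minus the same
#' quantity for the minus-acetyl-CoA control, normalized by chloroplast
#' count (replicates are averaged before control subtraction).
#'
#' @param total_dpm numeric vector of fixed radioactivity (dpm) for the
#'   technical replicates.
#' @param control_dpm dpm of the matching negative control(s).
#' @param chloroplasts_per_ml chloroplast concentration of the suspension
#'   (> 0), e.g. from [chloroplast_concentration()].
#' @param incubation_minutes incubation time (default 20 min).
#' @return net rate in dpm/min per chloroplast.
#' @export
accase_activity <- function(total_dpm, control_dpm, chloroplasts_per_ml,
                            incubation_minutes = 20) {
  if (missing(control_dpm) || is.null(control_dpm) || !length(control_dpm))
    stop("negative control (minus acetyl-CoA) is required")
  if (any(total_dpm < 0) || any(control_dpm < 0)) stop("dpm must be >= 0")
  if (chloroplasts_per_ml <= 0) stop("chloroplast count must be > 0")
  if (incubation_minutes <= 0) stop("incubation time must be > 0")
  rate <- mean(total_dpm / incubation_minutes)
  control_rate <- mean(control_dpm / incubation_minutes)
  (rate - control_rate) / chloroplasts_per_ml
}

#' Relative ACCase activities with paired t tests
#'
#' Expresses each line's activity relative to the reference line within each
#' experiment, then tests, per line, whether the ratios differ from 1 across
#' experiments (two-tailed paired t test, equivalent to a one-sample t test
#' of the per-experiment ratios against 1), followed by Benjamini-Hochberg
#' adjustment across lines. Lines with zero ratio variance across
#' experiments are flagged (`p = NA`) rather than given p = 0.
#'
#' @param rates `data.frame` with columns `line_id`, `experiment`, `rate`.
#' @param reference_line reference `line_id`, present in every experiment.
#' @return `data.frame` (`line_id`, `mean_relative`, `n_experiments`,
#'   `p_value`, `p_adj`).
#' @export
relative_activity_tests <- function(rates, reference_line) {
  need <- c("line_id", "experiment", "rate")
  if (!all(need %in% names(rates)))
    stop("rates need columns: ", paste(need, collapse = ", "))
  experiments <- unique(rates$experiment)
  ref <- rates[rates$line_id == reference_line, ]
  if (!all(experiments %in% ref$experiment))
    stop("reference line '", reference_line,
         "' missing from some experiments")
  ref_rate <- setNames(ref$rate, ref$experiment)
  others <- setdiff(unique(rates$line_id), reference_line)
  rows <- lapply(others, function(l) {
    sub <- rates[rates$line_id == l, ]
    rel <- sub$rate / ref_rate[as.character(sub$experiment)]
    p <- if (length(rel) >= 2L && sd(rel) > 0)
      t.test(rel, mu = 1, alternative = "two.sided")$p.value
    else NA_real_
    data.frame(line_id = l, mean_relative = mean(rel),
               n_experiments = length(rel), p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adj[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out
}
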