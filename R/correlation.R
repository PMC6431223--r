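# Window-wise correlation of sequence divergence with inheritance strength,
# Benjamini-Hochberg adjustment over the collapsed-window family, and a
# phylogenetic generalized least squares variant.

#' Construct a phenotype table
#'
#' One inheritance-strength value per sample. `direction` records the series
#' convention: in crosses where the white tester plastome is paternal (the
#' I-chi type), a *low* percent-biparental value means a *strong* maternal
#' plastome; the reciprocal (IV-delta type) cross reverses this. The pipeline
#' never flips signs silently; the label is echoed in outputs so the sign of
#' a correlation stays interpretable.
#'
#' @param sample_id character vector of sample ids (unique).
#' @param value numeric inheritance strength (percent biparental progeny in
#'   `[0, 100]`, or an ordinal class).
#' @param series optional label of the cross series the values come from.
#' @param direction `"low_is_strong"` or `"high_is_strong"`.
#' @return `data.frame` with columns `sample_id`, `value`, `series` and
#'   attribute `direction`.
#' @export
phenotype_table <- function(sample_id, value,
                            series = NA_character_,
                            direction = c("low_is_strong", "high_is_strong")) {
  direction <- match.arg(direction)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (!is.numeric(value) || anyNA(value))
    stop("phenotype values must be numeric and non-missing")
  out <- data.frame(sample_id = as.character(sample_id), value = value,
                    series = series, stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  out
}

.phenotype_for <- function(phenotype, sample_ids) {
  if (!all(c("sample_id", "value") %in% names(phenotype)))
    stop("phenotype needs columns sample_id and value")
  missing <- setdiff(sample_ids, phenotype$sample_id)
  if (length(missing))
    stop("phenotype missing samples: ", paste(missing, collapse = ", "))
  phenotype$value[match(sample_ids, phenotype$sample_id)]
}

# -- exact Spearman permutation machinery (small n) ---------------------------

.perm_cache <- new.env(parent = emptyenv())

.all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  gen <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], gen(v[-i]))))
  }
  p <- gen(seq_len(n))
  .perm_cache[[key]] <- p
  p
}

# Two-sided exact permutation p-value for Spearman's rho of one predictor row
# against y: the fraction of permutations of y whose |rho| >= |observed|.
# Mid-ranks make this valid under ties.
.spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  P <- .all_perms(n)
  rxc <- rx - mean(rx)
  ssx <- sum(rxc^2)
  ryc <- ry - mean(ry)
  ssy <- sum(ryc^2)
  if (ssx == 0 || ssy == 0) return(NA_real_)
  RY <- matrix(ryc[P], nrow = nrow(P))
  rho_perm <- as.vector(RY %*% rxc) / sqrt(ssx * ssy)
  rho_obs <- sum(rxc * ryc) / sqrt(ssx * ssy)
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

# Row-wise Pearson r of X (rows = windows) against y, with two-sided
# t-approximation p-values. Zero-variance rows come back NA.
.row_pearson <- function(X, y) {
  n <- length(y)
  Xc <- X - rowMeans(X)
  yc <- y - mean(y)
  ssx <- rowSums(Xc^2)
  ssy <- sum(yc^2)
  r <- as.vector(Xc %*% yc) / sqrt(ssx * ssy)
  r[ssx == 0 | ssy == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  df <- n - 2L
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  near1 <- ok & abs(r) >= 1 - 1e-15
  mid <- ok & !near1
  tstat <- r[mid] * sqrt(df / (1 - r[mid]^2))
  p[mid] <- 2 * pt(-abs(tstat), df)
  p[near1] <- 0
  list(r = r, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, preserving input order.
#' Thin validating wrapper around [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

.correlate_rows <- function(X, y, method, exact_max_n = 8L) {
  n <- length(y)
  out <- data.frame(row.names = seq_len(nrow(X)))
  if (method %in% c("pearson", "both")) {
    pe <- .row_pearson(X, y)
    out$r_pearson <- pe$r
    out$p_pearson <- pe$p
  }
  if (method %in% c("spearman", "both")) {
    RX <- t(apply(X, 1L, rank))
    if (nrow(X) == 1L) RX <- matrix(RX, nrow = 1L)
    ry <- rank(y)
    sp <- .row_pearson(RX, ry)
    out$r_spearman <- sp$r
    if (n <= exact_max_n) {
      out$p_spearman <- vapply(seq_len(nrow(RX)), function(i) {
        if (is.na(sp$r[i])) return(NA_real_)
        .spearman_exact_p(RX[i, ], ry)
      }, numeric(1L))
    } else {
      out$p_spearman <- sp$p
    }
  }
  out
}

#' Correlate window divergence with inheritance strength
#'
#' For every (typically collapsed) window, correlates the per-sample change
#' counts with the phenotype. Pearson p-values use the two-sided
#' t-approximation; Spearman p-values are exact permutation values for
#' `n <= 8` samples (full enumeration, mid-ranks under ties) and
#' t-approximate otherwise. Windows with zero count variance are flagged
#' undefined and excluded from the Benjamini-Hochberg family, which is
#' applied separately per metric.
#'
#' @param matrix a `divergence_matrix` (collapse with [collapse_windows()]
#'   first to shrink the testing family, as the mapping procedure does).
#' @param phenotype a [phenotype_table()] covering all matrix samples.
#' @param method `"pearson"`, `"spearman"` or `"both"`.
#' @return `data.frame` (one row per window): coordinates, `n_members`
#'   (collapsed run length), per-metric `r`, `p`, `p_adj`, and `defined`.
#'   Attribute `direction` echoes the phenotype convention.
#' @export
correlate_windows <- function(matrix, phenotype,
                              method = c("both", "pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "divergence_matrix"))
  y <- .phenotype_for(phenotype, matrix$sample_ids)
  if (length(y) < 3L) stop("need at least 3 samples to correlate")
  res <- .correlate_rows(matrix$counts, y, method)
  track <- cbind(matrix$windows,
                 n_members = if (isTRUE(matrix$collapsed))
                   lengths(matrix$collapse_map) else 1L,
                 res)
  for (m in intersect(c("pearson", "spearman"),
                      if (method == "both") c("pearson", "spearman") else method)) {
    pcol <- paste0("p_", m)
    acol <- paste0("p_adj_", m)
    track[[acol]] <- NA_real_
    ok <- !is.na(track[[pcol]])
    # exact zeros (|r| = 1) are kept in the family at the smallest
    # representable p so BH stays within its (0, 1] domain
    pv <- pmax(track[[pcol]][ok], .Machine$double.xmin)
    if (any(ok)) track[[acol]][ok] <- bh_adjust(pv)
  }
  rcols <- grep("^r_", names(track), value = TRUE)
  track$defined <- stats::complete.cases(track[, rcols, drop = FALSE])
  attr(track, "direction") <- attr(phenotype, "direction")
  track
}

#' Correlate a single reference region with inheritance strength
#'
#' Counts changes over one user-chosen interval (a candidate locus such as
#' the accD 5' coding region or the ycf2 promoter/5'-UTR) and correlates them
#' with the phenotype, as [correlate_windows()] does for grid windows.
#'
#' @param alignment a [plastome_alignment()].
#' @param phenotype a [phenotype_table()].
#' @param interval `c(start, end)` in ungapped reference coordinates.
#' @param method `"pearson"`, `"spearman"` or `"both"`.
#' @return one-row `data.frame` with the interval, per-sample counts as an
#'   attribute `counts`, r and p per metric, and `defined`.
#' @export
region_correlation <- function(alignment, phenotype, interval,
                               method = c("both", "pearson", "spearman")) {
  method <- match.arg(method)
  samples <- setdiff(names(alignment$seqs), alignment$reference_id)
  counts <- vapply(samples, function(s)
    count_changes(alignment, s, interval), integer(1L))
  y <- .phenotype_for(phenotype, samples)
  if (length(y) < 3L) stop("need at least 3 samples to correlate")
  res <- .correlate_rows(matrix(counts, nrow = 1L), y, method)
  out <- cbind(data.frame(start = interval[1L], end = interval[2L]), res)
  rcols <- grep("^r_", names(out), value = TRUE)
  out$defined <- all(!is.na(out[, rcols]))
  attr(out, "counts") <- setNames(counts, samples)
  attr(out, "direction") <- attr(phenotype, "direction")
  out
}

# -- PGLS ---------------------------------------------------------------------

.tree_covariance <- function(tree, sample_ids, lambda = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!setequal(tree$tip.label, sample_ids))
    stop("tree tips and phenotype samples must match; offending: ",
         paste(c(setdiff(tree$tip.label, sample_ids),
                 setdiff(sample_ids, tree$tip.label)), collapse = ", "))
  V <- ape::vcv(tree)
  V <- V[sample_ids, sample_ids]
  if (!is.null(lambda)) {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
    d <- diag(V)
    V <- lambda * V
    diag(V) <- d
  }
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) {
    # a zero-length cherry makes two tips perfectly correlated
    for (i in seq_len(nrow(V) - 1L)) for (j in (i + 1L):nrow(V)) {
      if (isTRUE(all.equal(V[i, i], V[i, j])) &&
          isTRUE(all.equal(V[j, j], V[i, j])))
        stop("singular phylogenetic covariance: zero-length cherry joining '",
             sample_ids[i], "' and '", sample_ids[j], "'")
    }
    stop("singular phylogenetic covariance")
  }
  list(V = V, U = U)
}

# GLS fit of y on [1, x] with covariance V = t(U) %*% U: whiten both sides by
# solve(t(U), .) and run ordinary least squares on the transformed data.
.gls_slope <- function(x, y, U) {
  n <- length(y)
  X <- cbind(1, x)
  Xw <- forwardsolve(t(U), X)
  yw <- forwardsolve(t(U), y)
  XtX <- crossprod(Xw)
  if (abs(det(XtX)) < 1e-12 * max(1, abs(XtX[2L, 2L])))
    return(c(slope = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_))
  XtXi <- solve(XtX)
  beta <- XtXi %*% crossprod(Xw, yw)
  resid <- yw - Xw %*% beta
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * XtXi[2L, 2L])
  tval <- beta[2L] / se
  c(slope = beta[2L], se = se, t = tval, p = 2 * pt(-abs(tval), df))
}

#' Phylogenetic generalized least squares over windows
#'
#' Regresses the phenotype on per-window change counts under a
#' Brownian-motion tip covariance derived from the supplied tree (optionally
#' scaled by a user-fixed Pagel's lambda; no likelihood optimization). On a
#' star tree with equal branch lengths the covariance is proportional to the
#' identity and the fit reduces to ordinary least squares. Reports the window
#' slope with a two-sided Wald p-value (t distribution, n - 2 df),
#' Benjamini-Hochberg adjusted across defined windows.
#'
#' @param matrix a `divergence_matrix`.
#' @param phenotype a [phenotype_table()]; needs >= 4 samples.
#' @param tree an `ape::phylo` tree whose tips match the matrix samples.
#' @param lambda optional fixed Pagel's lambda in `[0, 1]` scaling the
#'   off-diagonal covariance (default `NULL` = pure Brownian motion).
#' @return `data.frame` per window: coordinates, `pgls_slope`, `pgls_se`,
#'   `pgls_t`, `pgls_p`, `pgls_p_adj`, `defined` (zero-variance predictor
#'   windows are flagged and excluded from adjustment).
#' @export
pgls_windows <- function(matrix, phenotype, tree, lambda = NULL) {
  stopifnot(inherits(matrix, "divergence_matrix"))
  y <- .phenotype_for(phenotype, matrix$sample_ids)
  if (length(y) < 4L) stop("need at least 4 samples for PGLS")
  cv <- .tree_covariance(tree, matrix$sample_ids, lambda)
  X <- matrix$counts
  fits <- t(vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    if (stats::var(x) == 0)
      return(c(slope = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_))
    .gls_slope(x, y, cv$U)
  }, c(slope = 0, se = 0, t = 0, p = 0)))
  track <- cbind(matrix$windows,
                 pgls_slope = fits[, "slope"], pgls_se = fits[, "se"],
                 pgls_t = fits[, "t"], pgls_p = fits[, "p"])
  track$pgls_p_adj <- NA_real_
  ok <- !is.na(track$pgls_p)
  if (any(ok))
    track$pgls_p_adj[ok] <- bh_adjust(pmax(track$pgls_p[ok],
                                           .Machine$double.xmin))
  track$defined <- ok
  attr(track, "direction") <- attr(phenotype, "direction")
  track
}

#' Write a correlation track as TSV
#'
#' @param track output of [correlate_windows()] or [pgls_windows()],
#'   optionally with a `features` column from [intersect_annotations()].
#' @param path output TSV path.
#' @export
write_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
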