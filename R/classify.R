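# Classification of plastomes into inheritance-strength classes from
# transmission frequencies: PAM + average silhouette width to choose k,
# seeded k-means to assign classes, and a label-permutation swap rate to
# compare clusterings across runs.

.profiles_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (all(c("sample_id", "series", "frequency") %in% names(profiles))) {
      # long format: one row per sample x cross series
      wide <- stats::reshape(
        profiles[c("sample_id", "series", "frequency")],
        idvar = "sample_id", timevar = "series", direction = "wide")
      m <- as.matrix(wide[, -1L, drop = FALSE])
      rownames(m) <- wide$sample_id
      colnames(m) <- sub("^frequency\\.", "", colnames(m))
    } else {
      m <- as.matrix(profiles)
    }
  } else {
    m <- as.matrix(profiles)
  }
  if (anyNA(m)) stop("transmission profiles contain missing values")
  if (is.null(rownames(m))) rownames(m) <- paste0("sample_", seq_len(nrow(m)))
  m
}

#' Estimate the number of inheritance-strength classes
#'
#' Partitioning-around-medoids clustering for each candidate k, scored by the
#' average silhouette width; the estimate is the argmax. This reproduces the
#' documented default criterion of the `pamk` approach, after which k-means
#' is run with the chosen k ([kmeans_classify()]).
#'
#' @param profiles transmission frequencies: samples x series matrix, or a
#'   long `data.frame` with columns `sample_id`, `series`, `frequency`
#'   (percent variegated progeny, in `[0, 100]`).
#' @param k_range candidate cluster counts (default `2:10`, truncated to
#'   `n - 1`).
#' @param standardize scale columns to unit variance first (default `FALSE`;
#'   both cross series share percentage units).
#' @return list with `k_opt` and `silhouette_by_k` (named numeric).
#' @export
estimate_k <- function(profiles, k_range = 2:10, standardize = FALSE) {
  m <- .profiles_matrix(profiles)
  if (standardize) m <- scale(m)
  n <- nrow(m)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range))
    stop("need at least min(k_range) + 1 samples")
  sil <- vapply(k_range, function(k) {
    cluster::pam(m, k = k, metric = "euclidean")$silinfo$avg.width
  }, numeric(1L))
  names(sil) <- k_range
  list(k_opt = k_range[which.max(sil)], silhouette_by_k = sil)
}

#' Classify samples into inheritance-strength classes by k-means
#'
#' Seeded k-means (Lloyd iterations, `n_restarts` random initializations,
#' Euclidean distance) on transmission-frequency profiles. Classes are
#' relabelled `1..k` by ascending mean weakness so class 1 is the strongest:
#' with `strong = "low"` (the convention when the white tester plastome is
#' paternal, so few variegated progeny = assertive maternal plastome) class 1
#' has the lowest mean frequency; `strong = "high"` reverses this.
#'
#' @param profiles as in [estimate_k()].
#' @param k number of classes (>= 2; the data-driven k from [estimate_k()]
#'   or a user-forced value).
#' @param n_restarts random restarts (default 100).
#' @param seed integer seed making the run deterministic.
#' @param strong whether low or high frequencies indicate strong plastomes.
#' @param standardize scale columns first (default `FALSE`).
#' @return object of class `class_model`: `k`, `centers`, `assignment`
#'   (named integer vector), `distance_to_center`, `withinss_total`.
#' @export
kmeans_classify <- function(profiles, k, n_restarts = 100L, seed = 1L,
                            strong = c("low", "high"), standardize = FALSE) {
  strong <- match.arg(strong)
  m <- .profiles_matrix(profiles)
  if (standardize) m <- scale(m)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(m) - 1L) stop("k must be <= n - 1")
  n_distinct <- nrow(unique(m))
  if (k > n_distinct)
    stop("k (", k, ") exceeds the number of distinct profiles (",
         n_distinct, ")")
  set.seed(seed)
  # Lloyd restarts can start from an initialization that empties a cluster;
  # the restart machinery keeps the best non-degenerate solution, so that
  # particular warning is noise
  fit <- withCallingHandlers(
    kmeans(m, centers = k, nstart = n_restarts,
           iter.max = 100L, algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(unique(fit$cluster)) < k)
    stop("k-means produced fewer than k non-empty clusters")
  # relabel so class index is monotone in weakness
  center_mean <- rowMeans(fit$centers)
  ord <- order(if (strong == "low") center_mean else -center_mean)
  relabel <- match(seq_len(k), ord)
  assignment <- setNames(relabel[fit$cluster], rownames(m))
  centers <- fit$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  d2c <- sqrt(rowSums((m - centers[assignment, , drop = FALSE])^2))
  structure(
    list(k = k, centers = centers, assignment = assignment,
         distance_to_center = setNames(d2c, rownames(m)),
         withinss_total = fit$tot.withinss, seed = seed),
    class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat("class_model: k =", x$k, ", n =", length(x$assignment),
      ", total within-SS =", signif(x$withinss_total, 5L), "\n")
  print(table(class = x$assignment))
  invisible(x)
}

#' Swap rate between two clusterings
#'
#' Minimal fraction of samples whose class labels differ between two models,
#' minimized over all label permutations (exhaustive assignment matching).
#' Zero iff the two clusterings are label-permutation-equivalent; used to
#' assess k-means stability across seeds.
#'
#' @param model_a,model_b `class_model` objects (or bare label vectors named
#'   by sample) over the same samples with the same k.
#' @return fraction in `[0, 1]`.
#' @export
swap_rate <- function(model_a, model_b) {
  la <- if (inherits(model_a, "class_model")) model_a$assignment else model_a
  lb <- if (inherits(model_b, "class_model")) model_b$assignment else model_b
  if (!setequal(names(la), names(lb)))
    stop("models must cover the same samples")
  lb <- lb[names(la)]
  ka <- length(unique(la)); kb <- length(unique(lb))
  k <- max(la, lb)
  if (ka != kb) stop("cluster counts differ (", ka, " vs ", kb, ")")
  if (k > 8L) stop("exhaustive label matching supports k <= 8")
  n <- length(la)
  agree <- table(factor(la, levels = seq_len(k)),
                 factor(lb, levels = seq_len(k)))
  perms <- .all_perms(k)
  best <- max(vapply(seq_len(nrow(perms)), function(i)
    sum(agree[cbind(seq_len(k), perms[i, ])]), numeric(1L)))
  1 - best / n
}

#' Write a classification as CSV (+ JSON model summary)
#'
#' @param model a `class_model`.
#' @param path CSV path (`sample_id`, `class`, `distance_to_center`).
#' @param json_path optional JSON path for `k`, `centers`,
#'   `silhouette_by_k`.
#' @param silhouette_by_k optional named vector from [estimate_k()].
#' @export
write_class_model <- function(model, path, json_path = NULL,
                              silhouette_by_k = NULL) {
  df <- data.frame(sample_id = names(model$assignment),
                   class = unname(model$assignment),
                   distance_to_center = unname(model$distance_to_center))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(k = model$k,
           centers = as.data.frame(model$centers),
           silhouette_by_k = as.list(silhouette_by_k)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
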