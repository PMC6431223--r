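# Aligned plastome sets, sliding-window grids and per-window divergence counts.
#
# Coordinates are 1-based inclusive throughout; BED I/O converts from/to
# 0-based half-open at the boundary. Change counting is per alignment column
# (an n-bp indel counts n), and insertion columns (gap in the reference) are
# assigned to the reference position immediately 5' of the insertion run so
# that windows are defined purely on reference coordinates.

#' Construct an aligned plastome set
#'
#' Holds equal-length aligned sequences with a designated reference and
#' (optionally) gene annotations in ungapped reference coordinates.
#'
#' @param seqs named character vector of aligned sequences over
#'   `{A,C,G,T, IUPAC ambiguity codes, -}`; names are sample ids.
#' @param reference_id name of the reference sample; must occur exactly once.
#' @param annotations optional `data.frame` with columns `feature`, `start`,
#'   `end` (1-based inclusive, ungapped reference coordinates) and optionally
#'   `strand` (carried as metadata only; counting ignores strand).
#' @return an object of class `plastome_alignment` with elements `seqs`,
#'   `reference_id`, `annotations` and `reference_length` (ungapped).
#' @export
plastome_alignment <- function(seqs, reference_id, annotations = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must be uniquely named by sample id")
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("all aligned sequences must have identical length")
  if (!reference_id %in% names(seqs))
    stop("reference_id '", reference_id, "' not among sample ids")
  mat <- .char_matrix(seqs)
  bad <- setdiff(unique(as.vector(mat)), names(.iupac_sets()))
  if (length(bad))
    stop("unknown alignment characters: ", paste(bad, collapse = ", "))
  if (any(colSums(mat != "-") == 0L))
    stop("alignment contains a column that is gap in every row")
  reference_length <- sum(mat[reference_id, ] != "-")
  if (!is.null(annotations)) {
    annotations <- .validate_annotations(annotations, reference_length)
  }
  structure(
    list(seqs = seqs, reference_id = reference_id,
         annotations = annotations, reference_length = reference_length),
    class = "plastome_alignment")
}

#' @export
print.plastome_alignment <- function(x, ...) {
  cat("plastome_alignment:", length(x$seqs), "samples, alignment length",
      nchar(x$seqs[[1L]]), "\n")
  cat("reference:", x$reference_id, "(", x$reference_length, "bp ungapped )\n")
  if (!is.null(x$annotations))
    cat("annotations:", nrow(x$annotations), "features\n")
  invisible(x)
}

.char_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

.validate_annotations <- function(annotations, reference_length) {
  need <- c("feature", "start", "end")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  if (is.null(annotations$strand)) annotations$strand <- "*"
  with(annotations, {
    if (any(start > end)) stop("annotation with start > end")
    if (any(start < 1L) || any(end > reference_length))
      stop("annotation outside [1, ", reference_length, "]")
  })
  annotations[c("feature", "start", "end", "strand")]
}

#' Read an aligned FASTA of plastomes
#'
#' @param path aligned FASTA file (one record per plastome).
#' @param reference_id sample id of the reference record.
#' @param annotations optional annotation `data.frame` (see
#'   [plastome_alignment()]) or path to a BED file (read with [read_bed()]).
#' @return a [plastome_alignment()].
#' @export
read_plastome_alignment <- function(path, reference_id, annotations = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- read_bed(annotations)
  plastome_alignment(seqs, reference_id, annotations)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' BED is 0-based half-open; the returned `data.frame` uses the package's
#' 1-based inclusive convention.
#'
#' @param path BED file with at least chrom/start/end; column 4 is used as the
#'   feature name and column 6 as strand when present.
#' @return `data.frame` with columns `feature`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  data.frame(
    feature = if (ncol(bed) >= 4L) as.character(bed[[4L]]) else
      paste0("feature_", seq_len(nrow(bed))),
    start = as.integer(bed[[2L]]) + 1L,
    end = as.integer(bed[[3L]]),
    strand = if (ncol(bed) >= 6L) as.character(bed[[6L]]) else "*",
    stringsAsFactors = FALSE)
}

#' Write 1-based inclusive intervals as BED
#'
#' @param annotations `data.frame` with `feature`, `start`, `end` and
#'   optionally `strand` (1-based inclusive).
#' @param path output path.
#' @param chrom chromosome/sequence name to write (single value).
#' @export
write_bed <- function(annotations, path, chrom = "plastome") {
  strand <- if (is.null(annotations$strand)) "*" else annotations$strand
  bed <- data.frame(chrom = chrom,
                    start = as.integer(annotations$start) - 1L,
                    end = as.integer(annotations$end),
                    name = annotations$feature,
                    score = 0L, strand = strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Excise the redundant inverted repeat from an ungapped plastome
#'
#' Plastomes carry the inverted repeat twice; one copy (IR_A) is removed
#' before window counting so divergence there is not double-counted.
#'
#' @param sequence ungapped sequence (character scalar).
#' @param ir_interval length-2 integer vector `c(start, end)`, 1-based
#'   inclusive, within the sequence; must be non-empty.
#' @return the sequence with the interval excised.
#' @export
strip_inverted_repeat <- function(sequence, ir_interval) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  iv <- as.integer(ir_interval)
  L <- nchar(sequence)
  if (length(iv) != 2L || anyNA(iv) || iv[1L] > iv[2L])
    stop("ir_interval must be c(start, end) with start <= end")
  if (iv[1L] < 1L || iv[2L] > L)
    stop("ir_interval [", iv[1L], ",", iv[2L], "] outside sequence [1,", L, "]")
  paste0(substr(sequence, 1L, iv[1L] - 1L), substr(sequence, iv[2L] + 1L, L))
}

#' Build a sliding-window grid over the reference
#'
#' Only full windows are emitted: the number of windows is
#' `floor((L - w) / s) + 1`, so a partial terminal window is dropped.
#'
#' @param reference_length ungapped reference length in bp (IR_A removed).
#' @param window_size window size in bp (default 1000).
#' @param step step size in bp (default 10).
#' @return an object of class `window_grid` with a `windows` `data.frame`
#'   (`window_id`, `start`, `end`).
#' @export
window_grid <- function(reference_length, window_size = 1000L, step = 10L) {
  reference_length <- as.integer(reference_length)
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (window_size < 1L) stop("window_size must be >= 1")
  if (window_size > reference_length)
    stop("window_size (", window_size, ") exceeds reference length (",
         reference_length, ")")
  starts <- seq.int(1L, reference_length - window_size + 1L, by = step)
  structure(
    list(window_size = window_size, step = step,
         reference_length = reference_length,
         windows = data.frame(window_id = seq_along(starts),
                              start = starts,
                              end = starts + window_size - 1L)),
    class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("window_grid:", nrow(x$windows), "windows of", x$window_size,
      "bp, step", x$step, "bp over", x$reference_length, "bp\n")
  invisible(x)
}

# IUPAC code sets ('-' maps to the empty set). A sample symbol counts as a
# change only when its code set shares no base with the reference symbol's
# set, so N never counts (conservative divergence).
.iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  sets <- strsplit(unname(map), "", fixed = TRUE)
  names(sets) <- names(map)
  sets[["-"]] <- character(0)
  sets[["U"]] <- "T"
  sets[["."]] <- character(0)
  sets
}

.iupac_diff_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sets <- .iupac_sets()
      syms <- names(sets)
      m <- matrix(FALSE, length(syms), length(syms),
                  dimnames = list(syms, syms))
      for (a in syms) for (b in syms) {
        gap_a <- length(sets[[a]]) == 0L
        gap_b <- length(sets[[b]]) == 0L
        m[a, b] <-
          if (gap_a && gap_b) FALSE                # shared gap: not a change
          else if (gap_a || gap_b) TRUE            # indel column
          else length(intersect(sets[[a]], sets[[b]])) == 0L
      }
      cache <<- m
    }
    cache
  }
})

# Per-column anchor on the ungapped reference: base columns get their own
# position; gap-in-reference columns inherit the position of the base 5' of
# the run (0 for insertions before the first reference base, which therefore
# fall outside every window).
.reference_anchor <- function(ref_chars) {
  cumsum(ref_chars != "-")
}

# Vector (length = ungapped reference length) of change-column counts assigned
# to each reference position for one sample.
.position_diffs <- function(alignment, sample_id) {
  mat <- .char_matrix(alignment$seqs)
  ref <- mat[alignment$reference_id, ]
  smp <- mat[sample_id, ]
  dm <- .iupac_diff_matrix()
  diffs <- dm[cbind(ref, smp)]
  anchor <- .reference_anchor(ref)
  keep <- diffs & anchor > 0L
  tabulate(anchor[keep], nbins = alignment$reference_length)
}

#' Count nucleotide changes of a sample versus the reference in a window
#'
#' Changes are counted per alignment column: a substitution column, a
#' deletion column (gap in the sample) and an insertion column (gap in the
#' reference) each count one. Insertion columns are assigned to the reference
#' position immediately 5' of the insertion run. IUPAC ambiguity codes count
#' only when their base set excludes the reference base.
#'
#' @param alignment a [plastome_alignment()].
#' @param sample_id a non-reference sample id.
#' @param window length-2 vector `c(start, end)` in ungapped reference
#'   coordinates (1-based inclusive).
#' @return integer change count.
#' @export
count_changes <- function(alignment, sample_id, window) {
  if (!sample_id %in% names(alignment$seqs))
    stop("unknown sample '", sample_id, "'")
  if (identical(sample_id, alignment$reference_id))
    stop("sample_id must differ from the reference")
  w <- as.integer(window)
  if (length(w) != 2L || w[1L] > w[2L] || w[1L] < 1L ||
      w[2L] > alignment$reference_length)
    stop("window outside [1, ", alignment$reference_length, "]")
  pd <- .position_diffs(alignment, sample_id)
  sum(pd[w[1L]:w[2L]])
}

#' Build the windows x samples divergence matrix
#'
#' @param alignment a [plastome_alignment()].
#' @param grid a [window_grid()] built from the alignment's ungapped
#'   reference length.
#' @return an object of class `divergence_matrix`: integer `counts`
#'   (windows x samples, reference excluded), the `windows` table, and
#'   collapse bookkeeping (`collapsed`, `collapse_map`).
#' @export
build_divergence_matrix <- function(alignment, grid) {
  stopifnot(inherits(alignment, "plastome_alignment"),
            inherits(grid, "window_grid"))
  if (grid$reference_length != alignment$reference_length)
    stop("grid reference length (", grid$reference_length,
         ") does not match alignment (", alignment$reference_length, ")")
  samples <- setdiff(names(alignment$seqs), alignment$reference_id)
  pds <- vapply(samples, function(s) .position_diffs(alignment, s),
                integer(alignment$reference_length))
  # sliding sums via cumulative sums per sample column
  cs <- apply(pds, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = length(samples))
  st <- grid$windows$start
  en <- grid$windows$end
  counts <- cs[en, , drop = FALSE] -
    rbind(0L, cs[, , drop = FALSE])[st, , drop = FALSE]
  counts <- matrix(as.integer(counts), nrow = length(st),
                   dimnames = list(grid$windows$window_id, samples))
  structure(
    list(counts = counts, windows = grid$windows, sample_ids = samples,
         collapsed = FALSE, collapse_map = NULL),
    class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat("divergence_matrix:", nrow(x$counts), "windows x",
      ncol(x$counts), "samples",
      if (x$collapsed) "(collapsed)" else "(uncollapsed)", "\n")
  invisible(x)
}

#' Collapse adjacent windows with identical count vectors
#'
#' Runs of adjacent windows whose count vectors across all samples are
#' identical are merged into one row, shrinking the multiple-testing family
#' for the correlation step. `collapse_map` records the member window ids of
#' each collapsed row.
#'
#' @param matrix an uncollapsed `divergence_matrix`.
#' @return a collapsed `divergence_matrix`; `windows$start`/`end` span the
#'   merged run.
#' @export
collapse_windows <- function(matrix) {
  stopifnot(inherits(matrix, "divergence_matrix"))
  if (isTRUE(matrix$collapsed)) stop("matrix is already collapsed")
  n <- nrow(matrix$counts)
  key <- apply(matrix$counts, 1L, paste, collapse = ",")
  grp <- cumsum(c(TRUE, key[-1L] != key[-n]))
  first <- which(!duplicated(grp))
  idx_by_grp <- split(seq_len(n), grp)
  windows <- data.frame(
    window_id = seq_along(first),
    start = matrix$windows$start[first],
    end = matrix$windows$end[vapply(idx_by_grp, max, integer(1L))])
  counts <- matrix$counts[first, , drop = FALSE]
  rownames(counts) <- windows$window_id
  collapse_map <- lapply(idx_by_grp,
                         function(i) matrix$windows$window_id[i])
  names(collapse_map) <- windows$window_id
  structure(
    list(counts = counts, windows = windows, sample_ids = matrix$sample_ids,
         collapsed = TRUE, collapse_map = collapse_map,
         original_windows = matrix$windows),
    class = "divergence_matrix")
}

#' Expand a collapsed matrix back to the original window grid
#'
#' Inverse of [collapse_windows()], used to check that collapsing is
#' lossless.
#'
#' @param matrix a collapsed `divergence_matrix`.
#' @return the uncollapsed `divergence_matrix`.
#' @export
expand_windows <- function(matrix) {
  stopifnot(inherits(matrix, "divergence_matrix"), isTRUE(matrix$collapsed))
  reps <- lengths(matrix$collapse_map)
  counts <- matrix$counts[rep(seq_len(nrow(matrix$counts)), reps), ,
                          drop = FALSE]
  windows <- matrix$original_windows
  rownames(counts) <- windows$window_id
  structure(
    list(counts = counts, windows = windows, sample_ids = matrix$sample_ids,
         collapsed = FALSE, collapse_map = NULL),
    class = "divergence_matrix")
}

#' Label windows with overlapping annotated features
#'
#' A window is labelled with every feature overlapping it by at least 1 bp;
#' windows without any overlap are labelled `"intergenic"`.
#'
#' @param windows a `window_grid`, `divergence_matrix`, or `data.frame` with
#'   `start`/`end` columns (1-based inclusive reference coordinates).
#' @param annotations annotation `data.frame` (`feature`, `start`, `end`).
#' @return character vector, one comma-separated label per window.
#' @export
intersect_annotations <- function(windows, annotations) {
  if (inherits(windows, "window_grid")) windows <- windows$windows
  if (inherits(windows, "divergence_matrix")) windows <- windows$windows
  stopifnot(is.data.frame(windows),
            all(c("start", "end") %in% names(windows)))
  if (any(annotations$start > annotations$end) ||
      any(annotations$start < 1L))
    stop("malformed annotation interval")
  wr <- IRanges::IRanges(windows$start, windows$end)
  ar <- IRanges::IRanges(annotations$start, annotations$end)
  ov <- IRanges::findOverlaps(wr, ar, minoverlap = 1L)
  labs <- rep("intergenic", length(wr))
  hit <- split(annotations$feature[S4Vectors::subjectHits(ov)],
               S4Vectors::queryHits(ov))
  idx <- as.integer(names(hit))
  labs[idx] <- vapply(hit, function(f) paste(unique(f), collapse = ","), "")
  labs
}

#' Write a divergence matrix (and its collapse map) as TSV
#'
#' @param matrix a `divergence_matrix`.
#' @param path output TSV (`window_id`, `start`, `end`, one column per
#'   sample).
#' @param map_path optional TSV path for the collapse map
#'   (`window_id`, `members`).
#' @export
write_divergence_matrix <- function(matrix, path, map_path = NULL) {
  df <- cbind(matrix$windows, as.data.frame(matrix$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path)) {
    if (!isTRUE(matrix$collapsed)) stop("matrix has no collapse map")
    mm <- data.frame(
      window_id = names(matrix$collapse_map),
      members = vapply(matrix$collapse_map, paste, "", collapse = ","))
    write.table(mm, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a divergence matrix written by [write_divergence_matrix()]
#'
#' @param path TSV path.
#' @return a `divergence_matrix` (uncollapsed flag; collapse map not
#'   restored).
#' @export
read_divergence_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$window_id
  structure(
    list(counts = counts,
         windows = df[c("window_id", "start", "end")],
         sample_ids = colnames(counts),
         collapsed = FALSE, collapse_map = NULL),
    class = "divergence_matrix")
}
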