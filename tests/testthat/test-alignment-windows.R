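test_that("inverted repeat excision removes exactly the interval", {
  expect_identical(strip_inverted_repeat("ACGTACGT", c(3, 4)), "ACACGT")
  expect_identical(strip_inverted_repeat("ACGTACGT", c(1, 8)), "")
  expect_identical(nchar(strip_inverted_repeat(strrep("A", 100), c(10, 30))),
                   79L)
  expect_error(strip_inverted_repeat("ACGT", c(0, 2)), "outside")
  expect_error(strip_inverted_repeat("ACGT", c(3, 5)), "outside")
  expect_error(strip_inverted_repeat("ACGT", c(3, 2)), "start <= end")
  expect_error(strip_inverted_repeat("ACGT", integer(0)), "start")
})

test_that("window grid emits full windows only and obeys the closed form", {
  g <- window_grid(1000, 1000, 10)
  expect_equal(nrow(g$windows), 1L)
  expect_equal(unlist(g$windows[1, c("start", "end")], use.names = FALSE),
               c(1L, 1000L))
  expect_equal(nrow(window_grid(1009, 1000, 10)$windows), 1L)
  g2 <- window_grid(1100, 1000, 10)
  expect_equal(nrow(g2$windows), 11L)
  expect_equal(g2$windows$start, seq(1L, 101L, by = 10L))
  expect_error(window_grid(500, 1000, 10), "exceeds")

  set.seed(11)
  for (i in 1:50) {
    L <- sample(100:5000, 1)
    w <- sample(10:L, 1)
    s <- sample(1:50, 1)
    g <- window_grid(L, w, s)
    expect_equal(nrow(g$windows), floor((L - w) / s) + 1)
    expect_true(all(g$windows$end <= L))
    expect_equal(g$windows$start, seq(1L, by = s,
                                      length.out = nrow(g$windows)))
  }
})

test_that("change counting is per column with 5'-anchored insertions", {
  a <- toy_alignment(c(R = "ACGT", S = "ACGT"))
  expect_equal(count_changes(a, "S", c(1, 4)), 0L)

  # one insertion column, anchored at reference position 2
  a <- toy_alignment(c(R = "AC-GT", S = "ACAGT"))
  expect_equal(count_changes(a, "S", c(1, 4)), 1L)
  expect_equal(count_changes(a, "S", c(3, 4)), 0L)

  # 1 substitution + 2 deletion columns
  a <- toy_alignment(c(R = "ACGTACGT", S = "TCGT--GT"))
  expect_equal(count_changes(a, "S", c(1, 8)), 3L)
  expect_equal(count_changes(a, "S", c(5, 6)), 2L)

  # a 3-bp insertion counts 3 (per column, not per event)
  a <- toy_alignment(c(R = "AC---GT", S = "ACTTTGT"))
  expect_equal(count_changes(a, "S", c(1, 4)), 3L)

  expect_error(count_changes(a, "X", c(1, 2)), "unknown sample")
  expect_error(count_changes(a, "R", c(1, 2)), "differ from the reference")
  expect_error(count_changes(a, "S", c(0, 2)), "outside")
})

test_that("IUPAC ambiguity counts only when it excludes the reference base", {
  a <- toy_alignment(c(R = "ACGT", S = "NCGT"))
  expect_equal(count_changes(a, "S", c(1, 4)), 0L)   # N covers A
  a <- toy_alignment(c(R = "ACGT", S = "RCGT"))
  expect_equal(count_changes(a, "S", c(1, 4)), 0L)   # R = {A,G} covers A
  a <- toy_alignment(c(R = "TCGT", S = "RCGT"))
  expect_equal(count_changes(a, "S", c(1, 4)), 1L)   # R excludes T
})

test_that("divergence matrix matches per-window recounts and handles a SNP", {
  rows <- c(R = "ACGTACGTAC", A = "ACGTACGTAC", B = "ACGTTCGTAC")
  a <- toy_alignment(rows)
  g <- window_grid(10, 4, 2)
  dm <- build_divergence_matrix(a, g)
  expect_equal(dim(dm$counts), c(4L, 2L))
  expect_true(all(dm$counts[, "A"] == 0L))
  # SNP at position 5 hits exactly windows [3,6] and [5,8]
  expect_equal(unname(dm$counts[, "B"]), c(0L, 1L, 1L, 0L))
  # every cell agrees with a direct single-window recount
  for (i in seq_len(nrow(dm$counts))) for (s in dm$sample_ids) {
    expect_equal(dm$counts[i, s],
                 count_changes(a, s, unlist(dm$windows[i, c("start", "end")])))
  }
})

test_that("non-overlapping tiling sums to the total assigned change columns", {
  set.seed(7)
  sim <- simulate_plastome_set(plastome_sim_config(
    ancestor_length = 3000, n_samples = 5, seed = 99))
  a <- sim$alignment
  w <- 300
  g <- window_grid(a$reference_length, w, w)
  dm <- build_divergence_matrix(a, g)
  tiled_end <- max(g$windows$end)
  for (s in dm$sample_ids) {
    expect_equal(sum(dm$counts[, s]),
                 count_changes(a, s, c(1, tiled_end)))
  }
})

test_that("count vectors are invariant to row order and label swaps", {
  rows <- c(R = "ACGTACGT", A = "ACGTTCGT", B = "AC-TACGA")
  g <- window_grid(8, 4, 2)
  dm1 <- build_divergence_matrix(toy_alignment(rows), g)
  dm2 <- build_divergence_matrix(toy_alignment(rows[c(3, 1, 2)],
                                               reference_id = "R"), g)
  expect_equal(dm1$counts[, c("A", "B")], dm2$counts[, c("A", "B")])
  swapped <- rows
  names(swapped)[2:3] <- c("B", "A")
  dm3 <- build_divergence_matrix(toy_alignment(swapped, "R"), g)
  expect_equal(unname(dm1$counts[, "A"]), unname(dm3$counts[, "B"]))
})

test_that("collapsing merges identical adjacent count vectors losslessly", {
  mk <- function(counts_mat) {
    n <- nrow(counts_mat)
    structure(list(
      counts = counts_mat,
      windows = data.frame(window_id = 1:n, start = seq(1, by = 10,
                                                        length.out = n),
                           end = seq(100, by = 10, length.out = n)),
      sample_ids = colnames(counts_mat), collapsed = FALSE,
      collapse_map = NULL), class = "divergence_matrix")
  }
  zero <- mk(matrix(0L, 100, 3, dimnames = list(NULL, c("a", "b", "c"))))
  cz <- collapse_windows(zero)
  expect_equal(nrow(cz$counts), 1L)
  expect_equal(lengths(cz$collapse_map), c(`1` = 100L))
  expect_equal(cz$windows$start, 1L)
  expect_equal(cz$windows$end, 100L + 99L * 10L)

  alt <- mk(matrix(as.integer(rbind(c(0, 1), c(1, 0), c(0, 1), c(1, 0))),
                   4, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(nrow(collapse_windows(alt)$counts), 4L)

  # run-length oracle on the pattern a,a,b,b,a
  ab <- mk(matrix(as.integer(c(0, 0, 1, 1, 0)), 5, 1,
                  dimnames = list(NULL, "s")))
  cab <- collapse_windows(ab)
  expect_equal(nrow(cab$counts), 3L)
  expect_equal(unname(lengths(cab$collapse_map)), c(2L, 2L, 1L))

  expect_error(collapse_windows(cab), "already collapsed")

  set.seed(3)
  for (i in 1:10) {
    m <- mk(matrix(sample(0:2, 60, replace = TRUE), 20, 3,
                   dimnames = list(NULL, c("a", "b", "c"))))
    cm <- collapse_windows(m)
    back <- expand_windows(cm)
    expect_identical(unname(back$counts), unname(m$counts))
    expect_identical(back$windows, m$windows)
  }
})

test_that("annotation intersection labels overlaps and intergenic windows", {
  w <- data.frame(start = 1, end = 1000)
  ann <- data.frame(feature = "geneA", start = 500, end = 600, strand = "+")
  expect_equal(intersect_annotations(w, ann), "geneA")
  ann2 <- data.frame(feature = "geneB", start = 1001, end = 1200,
                     strand = "+")
  expect_equal(intersect_annotations(w, ann2), "intergenic")

  # all-pairs interval oracle on a 3-window x 2-gene toy set
  w3 <- data.frame(start = c(1, 100, 220), end = c(90, 210, 300))
  genes <- data.frame(feature = c("g1", "g2"), start = c(50, 205),
                      end = c(120, 230), strand = c("+", "-"))
  got <- intersect_annotations(w3, genes)
  want <- vapply(seq_len(3), function(i) {
    hits <- genes$feature[pmax(w3$start[i], genes$start) <=
                            pmin(w3$end[i], genes$end)]
    if (length(hits)) paste(hits, collapse = ",") else "intergenic"
  }, "")
  expect_equal(got, want)
  expect_error(intersect_annotations(w, data.frame(feature = "x",
                                                   start = 5, end = 2)),
               "malformed")
})

test_that("BED I/O converts between 0-based half-open and 1-based inclusive", {
  ann <- data.frame(feature = c("g1", "g2"), start = c(1L, 500L),
                    end = c(120L, 600L), strand = c("+", "-"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(ann, path)
  raw <- read.table(path, sep = "\t")
  expect_equal(raw[[2]], c(0L, 499L))  # 0-based starts on disk
  expect_equal(raw[[3]], c(120L, 600L))
  back <- read_bed(path)
  expect_equal(back[c("feature", "start", "end", "strand")], ann)
})

test_that("alignment validation rejects malformed input", {
  expect_error(toy_alignment(c(R = "ACGT", S = "ACG")), "identical length")
  expect_error(toy_alignment(c(R = "ACGT", S = "ACGT"), "Z"),
               "not among sample ids")
  expect_error(toy_alignment(c(R = "AC-T", S = "AC-T")), "gap in every row")
  expect_error(
    plastome_alignment(c(R = "ACGT", S = "ACTT"), "R",
                       annotations = data.frame(feature = "g", start = 2,
                                                end = 9)),
    "outside")
})

test_that("matrix TSV round-trips", {
  rows <- c(R = "ACGTACGTAC", A = "ACCTACGTAC", B = "ACGTTCGTAC")
  dm <- build_divergence_matrix(toy_alignment(rows), window_grid(10, 4, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_divergence_matrix(dm, path)
  back <- read_divergence_matrix(path)
  expect_equal(unname(back$counts), unname(dm$counts))
  expect_equal(back$sample_ids, dm$sample_ids)
})
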