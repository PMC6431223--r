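# Seeded generators for synthetic inputs with the statistical structure the
# pipeline assumes: plastome sets diverged from a common ancestor by SNPs
# plus slippage indels concentrated at oligo(N) stretches and tandem-repeat
# loci (with planted causal loci whose divergence scales the phenotype),
# binomially sampled variegation counts, and a multi-series lipidome with
# planted predictive lipids. Every generator returns a ground-truth manifest
# sufficient to score recovery without re-simulation.

#' Configuration for the synthetic plastome generator
#'
#' @param ancestor_length ancestral genome length in bp (default 20000 for
#'   tests; up to ~140000 for full-plastome-sized runs).
#' @param n_samples number of derived plastomes (tree tips; the ancestor is
#'   additionally emitted as the reference sample `"REF"`).
#' @param snp_rate expected substitutions per bp per unit branch length.
#' @param oligo_stretch_density homopolymer (oligo(N)) runs planted per kb
#'   of ancestor.
#' @param oligo_run_length range of planted run lengths, bp.
#' @param slippage_indel_rate expected 1-bp slippage indels per oligo run
#'   per unit branch length.
#' @param repeat_loci list of tandem-repeat loci, each
#'   `list(start, motif_length, n_units, rate)` (`rate` = expected whole-unit
#'   indel events per unit branch length). `NULL` plants two default loci
#'   (9-bp motif, 20 units) at 30% and 70% of the genome.
#' @param causal_loci list of `list(start, end, beta)` intervals whose
#'   per-sample divergence contributes `beta * change_count` to the
#'   phenotype. `NULL` makes the first repeat locus causal with `beta = 1`.
#' @param noise_sd phenotype noise standard deviation; if `noise_relative`
#'   is `TRUE` it is interpreted as a multiple of the SD of the genetic
#'   signal across samples.
#' @param noise_relative see `noise_sd`.
#' @param seed integer seed (bit-reproducibility contract).
#' @return list of class `plastome_sim_config`.
#' @export
plastome_sim_config <- function(ancestor_length = 20000L,
                                n_samples = 14L,
                                snp_rate = 2e-4,
                                oligo_stretch_density = 1.5,
                                oligo_run_length = c(6L, 12L),
                                slippage_indel_rate = 0.1,
                                repeat_loci = NULL,
                                causal_loci = NULL,
                                noise_sd = 0.5,
                                noise_relative = TRUE,
                                seed = 1L) {
  L <- as.integer(ancestor_length)
  if (is.null(repeat_loci)) {
    mk <- function(frac) list(start = as.integer(frac * L),
                              motif_length = 9L, n_units = 20L, rate = 1.5)
    repeat_loci <- list(mk(0.3), mk(0.7))
  }
  for (rl in repeat_loci) {
    end <- rl$start + rl$motif_length * rl$n_units - 1L
    if (rl$start < 1L || end > L) stop("repeat locus outside ancestor")
  }
  if (is.null(causal_loci)) {
    rl <- repeat_loci[[1L]]
    causal_loci <- list(list(start = rl$start,
                             end = rl$start + rl$motif_length * rl$n_units - 1L,
                             beta = 1))
  }
  for (cl in causal_loci) {
    if (cl$start < 1L || cl$end > L || cl$start > cl$end)
      stop("causal locus outside ancestor")
    if (!is.finite(cl$beta)) stop("beta must be finite")
  }
  stopifnot(snp_rate >= 0, snp_rate <= 1,
            slippage_indel_rate >= 0, noise_sd >= 0, n_samples >= 2L)
  structure(list(ancestor_length = L, n_samples = as.integer(n_samples),
                 snp_rate = snp_rate,
                 oligo_stretch_density = oligo_stretch_density,
                 oligo_run_length = as.integer(oligo_run_length),
                 slippage_indel_rate = slippage_indel_rate,
                 repeat_loci = repeat_loci, causal_loci = causal_loci,
                 noise_sd = noise_sd, noise_relative = isTRUE(noise_relative),
                 seed = as.integer(seed)),
            class = "plastome_sim_config")
}

# Registry-based evolution: every alignment column ever created is tracked
# with a numeric sort key (anchored ancestral position i -> key i; a column
# inserted after reference position p -> key p + j * 1e-6 with a global
# insertion counter j), so column homology is known by construction and no
# realignment is needed.
.evolve_plastomes <- function(config, tree, ancestor, oligo_runs) {
  L <- config$ancestor_length
  reg <- new.env(parent = emptyenv())
  reg$key <- as.numeric(seq_len(L))
  reg$anchor <- seq_len(L)
  reg$anchored <- rep(TRUE, L)
  reg$ins_count <- 0L
  new_columns <- function(anchor, n) {
    ids <- length(reg$key) + seq_len(n)
    keys <- anchor + (reg$ins_count + seq_len(n)) * 1e-6
    reg$ins_count <- reg$ins_count + n
    reg$key <- c(reg$key, keys)
    reg$anchor <- c(reg$anchor, rep(anchor, n))
    reg$anchored <- c(reg$anchored, rep(FALSE, n))
    ids
  }
  pad_state <- function(state) {
    extra <- length(reg$key) - length(state$present)
    if (extra > 0L) {
      state$present <- c(state$present, rep(FALSE, extra))
      state$base <- c(state$base, rep(NA_character_, extra))
    }
    state
  }
  run_interval <- lapply(oligo_runs, function(r) r$start:r$end)
  repeat_ranges <- lapply(config$repeat_loci, function(rl)
    c(rl$start, rl$start + rl$motif_length * rl$n_units - 1L))

  mutate_branch <- function(state, t) {
    state <- pad_state(state)
    present_idx <- which(state$present)
    # substitutions
    n_snp <- rpois(1L, config$snp_rate * L * t)
    if (n_snp > 0L && length(present_idx)) {
      pos <- sample(present_idx, n_snp, replace = TRUE)
      for (p in pos) {
        state$base[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                        state$base[p]), 1L)
      }
    }
    # 1-bp slippage indels at oligo(N) runs
    if (length(oligo_runs)) {
      n_slip <- rpois(1L, config$slippage_indel_rate *
                        length(oligo_runs) * t)
      for (i in seq_len(n_slip)) {
        r <- sample(length(oligo_runs), 1L)
        iv <- run_interval[[r]]
        if (runif(1L) < 0.5) {                      # insertion of one base
          id <- new_columns(oligo_runs[[r]]$end, 1L)
          state <- pad_state(state)
          state$present[id] <- TRUE
          state$base[id] <- oligo_runs[[r]]$base
        } else {                                    # deletion of one base
          cand <- iv[state$present[iv]]
          if (length(cand)) {
            p <- if (length(cand) == 1L) cand else sample(cand, 1L)
            state$present[p] <- FALSE
          }
        }
      }
    }
    # whole-unit indels at tandem-repeat loci
    for (j in seq_along(config$repeat_loci)) {
      rl <- config$repeat_loci[[j]]
      rng <- repeat_ranges[[j]]
      n_ev <- rpois(1L, rl$rate * t)
      for (i in seq_len(n_ev)) {
        if (runif(1L) < 0.5) {                      # insert one motif unit
          motif <- ancestor[rl$start:(rl$start + rl$motif_length - 1L)]
          ids <- new_columns(rng[2L], rl$motif_length)
          state <- pad_state(state)
          state$present[ids] <- TRUE
          state$base[ids] <- motif
        } else {                                    # delete one unit's worth
          in_locus <- which(state$present &
                              reg$anchor[seq_along(state$present)] >= rng[1L] &
                              reg$anchor[seq_along(state$present)] <= rng[2L])
          if (length(in_locus) >= rl$motif_length) {
            start_at <- sample(length(in_locus) - rl$motif_length + 1L, 1L)
            state$present[in_locus[start_at:(start_at + rl$motif_length - 1L)]] <- FALSE
          }
        }
      }
    }
    state
  }

  root_state <- list(present = rep(TRUE, L), base = ancestor)
  n_tip <- length(tree$tip.label)
  states <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  states[[root]] <- root_state
  # cladewise edge order guarantees parents are visited before children
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    states[[child]] <- mutate_branch(states[[parent]],
                                     tree$edge.length[e])
  }
  tips <- lapply(seq_len(n_tip), function(i) pad_state(states[[i]]))
  names(tips) <- tree$tip.label
  list(registry = reg, tips = tips)
}

# Generator-side change count for one sample over a reference interval,
# computed from the column registry (independently of count_changes): an
# anchored column counts when substituted or deleted; an inserted column
# counts when present, at its 5'-anchor position.
.true_locus_count <- function(registry, ancestor, tip, interval) {
  idx <- which(registry$anchor >= interval[1L] &
                 registry$anchor <= interval[2L])
  n <- 0L
  for (i in idx) {
    if (registry$anchored[i]) {
      if (!tip$present[i]) n <- n + 1L
      else if (tip$base[i] != ancestor[registry$anchor[i]]) n <- n + 1L
    } else if (tip$present[i]) n <- n + 1L
  }
  n
}

#' Simulate a set of diverged plastomes with a planted causal locus
#'
#' Builds an ancestral sequence with embedded homopolymer runs and
#' tandem-repeat loci, evolves `n_samples` plastomes along a random
#' coalescent tree (SNPs everywhere; 1-bp slippage indels at the oligo(N)
#' runs; whole-motif-unit indels at the repeat loci), and emits the true
#' gap-explicit alignment (column homology known from the simulation, no
#' realignment), with the unmutated ancestor included as reference sample
#' `"REF"`. Each sample's phenotype is
#' `sum(beta_l * change_count(sample, locus_l)) + N(0, noise_sd)`, so
#' divergence at the causal loci scales inheritance weakness (the phenotype
#' is emitted raw, rescaled to a percent, and discretized into classes
#' 1-5).
#'
#' @param config a [plastome_sim_config()].
#' @param out_dir optional directory; when given, writes `alignment.fasta`,
#'   `annotations.bed`, `tree.nwk`, `phenotype.csv` and `manifest.json`.
#' @return list: `alignment` ([plastome_alignment()]), `tree` (`phylo` over
#'   the non-reference samples), `phenotype` ([phenotype_table()], raw
#'   value), `manifest` (ground truth: per-sample signal/noise, per-locus
#'   planted change counts, causal coordinates), `config`.
#' @export
simulate_plastome_set <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "plastome_sim_config"))
  set.seed(config$seed)
  L <- config$ancestor_length
  ancestor <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # plant tandem repeats (motif repeated n_units times)
  for (rl in config$repeat_loci) {
    motif <- sample(c("A", "C", "G", "T"), rl$motif_length, replace = TRUE)
    iv <- rl$start:(rl$start + rl$motif_length * rl$n_units - 1L)
    ancestor[iv] <- rep(motif, rl$n_units)
  }
  # plant homopolymer runs outside the repeat loci
  n_runs <- max(0L, round(config$oligo_stretch_density * L / 1000))
  repeat_iv <- unlist(lapply(config$repeat_loci, function(rl)
    rl$start:(rl$start + rl$motif_length * rl$n_units - 1L)))
  oligo_runs <- list()
  attempt <- 0L
  while (length(oligo_runs) < n_runs && attempt < 50L * n_runs) {
    attempt <- attempt + 1L
    len <- sample(seq(config$oligo_run_length[1L],
                      config$oligo_run_length[2L]), 1L)
    st <- sample(L - len, 1L)
    iv <- st:(st + len - 1L)
    if (length(intersect(iv, repeat_iv))) next
    clash <- any(vapply(oligo_runs, function(r)
      st <= r$end && (st + len - 1L) >= r$start, logical(1L)))
    if (clash) next
    base <- sample(c("A", "C", "G", "T"), 1L)
    ancestor[iv] <- base
    oligo_runs[[length(oligo_runs) + 1L]] <-
      list(start = st, end = st + len - 1L, base = base)
  }
  tree <- ape::rcoal(config$n_samples)
  tree$tip.label <- sprintf("S%02d", seq_len(config$n_samples))
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  ev <- .evolve_plastomes(config, tree, ancestor, oligo_runs)
  reg <- ev$registry
  tips <- ev$tips
  # alignment columns: ancestral columns always (reference carries them);
  # inserted columns only if present in at least one tip
  present_any <- Reduce(`|`, lapply(tips, function(s) s$present))
  keep <- reg$anchored | present_any
  ord <- order(reg$key[keep])
  cols <- which(keep)[ord]
  row_string <- function(present, base) {
    ch <- ifelse(present[cols], base[cols], "-")
    paste(ch, collapse = "")
  }
  ref_present <- c(rep(TRUE, L), rep(FALSE, length(reg$key) - L))
  ref_base <- c(ancestor, rep(NA_character_, length(reg$key) - L))
  seqs <- c(REF = row_string(ref_present, ref_base),
            vapply(tips, function(s) row_string(s$present, s$base), ""))
  annotations <- rbind(
    do.call(rbind, lapply(seq_along(config$repeat_loci), function(i) {
      rl <- config$repeat_loci[[i]]
      data.frame(feature = paste0("repeat_locus_", i), start = rl$start,
                 end = rl$start + rl$motif_length * rl$n_units - 1L,
                 strand = "+")
    })),
    do.call(rbind, lapply(seq_along(config$causal_loci), function(i) {
      cl <- config$causal_loci[[i]]
      data.frame(feature = paste0("causal_locus_", i), start = cl$start,
                 end = cl$end, strand = "+")
    })))
  alignment <- plastome_alignment(seqs, "REF", annotations)
  # ground-truth planted divergence per sample per causal locus
  locus_counts <- vapply(config$causal_loci, function(cl)
    vapply(tips, function(s)
      .true_locus_count(reg, ancestor, s, c(cl$start, cl$end)),
      integer(1L)),
    integer(length(tips)))
  if (is.null(dim(locus_counts)))
    locus_counts <- matrix(locus_counts, nrow = length(tips))
  dimnames(locus_counts) <- list(names(tips),
                                 paste0("causal_locus_",
                                        seq_along(config$causal_loci)))
  betas <- vapply(config$causal_loci, function(cl) cl$beta, numeric(1L))
  signal <- as.vector(locus_counts %*% betas)
  sd_used <- if (config$noise_relative)
    config$noise_sd * sd(signal) else config$noise_sd
  if (!is.finite(sd_used)) sd_used <- 0
  noise <- rnorm(length(signal), 0, sd_used)
  value <- signal + noise
  rng <- range(value)
  percent <- if (diff(rng) > 0) 100 * (value - rng[1L]) / diff(rng)
  else rep(50, length(value))
  class5 <- as.integer(cut(value, breaks = 5L, labels = FALSE))
  phenotype <- phenotype_table(names(tips), value, series = "synthetic",
                               direction = "low_is_strong")
  phenotype$percent <- percent
  phenotype$class <- class5
  manifest <- list(
    samples = data.frame(sample_id = names(tips), signal = signal,
                         noise = noise, value = value, percent = percent,
                         class = class5),
    locus_counts = locus_counts,
    causal_loci = do.call(rbind, lapply(seq_along(config$causal_loci),
                                        function(i) {
      cl <- config$causal_loci[[i]]
      data.frame(locus = paste0("causal_locus_", i), start = cl$start,
                 end = cl$end, beta = cl$beta)
    })),
    noise_sd_used = sd_used, seed = config$seed)
  out <- list(alignment = alignment, tree = tree, phenotype = phenotype,
              manifest = manifest, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ss <- Biostrings::BStringSet(alignment$seqs)
    Biostrings::writeXStringSet(ss, file.path(out_dir, "alignment.fasta"))
    write_bed(annotations, file.path(out_dir, "annotations.bed"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write.table(phenotype, file.path(out_dir, "phenotype.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      samples = manifest$samples,
      locus_counts = as.data.frame(manifest$locus_counts),
      causal_loci = manifest$causal_loci,
      noise_sd_used = manifest$noise_sd_used, seed = manifest$seed),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate seedling variegation counts for crossing series
#'
#' Per line and season, the number of variegated seedlings is drawn as
#' `Binomial(n_total, rate)`, emulating visual scoring of randomized
#' populations.
#'
#' @param true_biparental_rates named numeric vector of per-line biparental
#'   transmission probabilities in `[0, 1]`.
#' @param n_total seedlings scored per cross per season (scalar, or vector
#'   `c(min, max)` to draw uniformly per cross, mirroring populations of
#'   100-300 plants).
#' @param n_seasons number of seasons (default 3).
#' @param seed integer seed.
#' @return `data.frame` of cross counts (`line_id`, `season`,
#'   `n_variegated`, `n_total`) suitable for [biparental_percent()].
#' @export
simulate_crosses <- function(true_biparental_rates, n_total = 200L,
                             n_seasons = 3L, seed = 1L) {
  rates <- true_biparental_rates
  if (any(rates < 0) || any(rates > 1))
    stop("rates must lie in [0, 1]")
  if (is.null(names(rates)))
    names(rates) <- paste0("line_", seq_along(rates))
  set.seed(seed)
  grid <- expand.grid(line_id = names(rates),
                      season = seq_len(n_seasons),
                      stringsAsFactors = FALSE)
  tot <- if (length(n_total) == 2L)
    sample(seq(n_total[1L], n_total[2L]), nrow(grid), replace = TRUE)
  else rep(as.integer(n_total), nrow(grid))
  grid$n_total <- tot
  grid$n_variegated <- rbinom(nrow(grid), tot,
                              rates[grid$line_id])
  grid[c("line_id", "season", "n_variegated", "n_total")]
}

#' Simulate a multi-series lipidome with planted predictive lipids
#'
#' Levels are `exp(baseline_lipid + series_offset + beta_lipid * class +
#' replicate noise)`; per-series lipid dropout leaves `n_shared` lipids
#' measured in every series (the merge intersection), and `n_planted` shared
#' lipids carry a class effect of magnitude `effect_size` (random sign).
#'
#' @param n_genotypes number of genotypes (default 16), assigned inheritance
#'   classes cycling over 1..5 so every series contains class-1 genotypes.
#' @param n_replicates replicates per genotype per series (default 5).
#' @param n_series experimental series (default 3).
#' @param n_lipids total annotated lipids (default 184).
#' @param n_shared lipids measured in all series (default 102).
#' @param n_planted planted predictive lipids among the shared set
#'   (default 8).
#' @param effect_size |beta| of planted lipids on the log scale (default 1).
#' @param noise_sd replicate noise SD on the log scale (default 0.5).
#' @param series_offset_sd SD of per-lipid series offsets (default 0.5).
#' @param baseline_sd SD of per-lipid baselines (default 1).
#' @param seed integer seed.
#' @return list: `series` (named list of raw single-series
#'   [lipid_matrix()]), `manifest` (planted lipid ids/betas, genotype
#'   classes, lipid classes).
#' @export
simulate_lipidome <- function(n_genotypes = 16L, n_replicates = 5L,
                              n_series = 3L, n_lipids = 184L,
                              n_shared = 102L, n_planted = 8L,
                              effect_size = 1, noise_sd = 0.5,
                              series_offset_sd = 0.5, baseline_sd = 1,
                              seed = 1L) {
  if (n_genotypes < 4L) stop("need at least 4 genotypes")
  if (n_shared > n_lipids) stop("n_shared cannot exceed n_lipids")
  if (n_planted > n_shared) stop("n_planted cannot exceed n_shared")
  set.seed(seed)
  genotypes <- sprintf("G%02d", seq_len(n_genotypes))
  classes <- rep(1:5, length.out = n_genotypes)
  lipid_ids <- sprintf("lipid_%03d", seq_len(n_lipids))
  class_pool <- c(MGDG = 0.12, DGDG = 0.12, SQDG = 0.05, PG = 0.07,
                  PC = 0.13, PI = 0.04, PE = 0.07, FA = 0.10, TAG = 0.20,
                  CoQ = 0.03, chlorophyll = 0.04, pheophytin = 0.03)
  lipid_class <- sample(names(class_pool), n_lipids, replace = TRUE,
                        prob = class_pool)
  planted <- sample(lipid_ids[seq_len(n_shared)], n_planted)
  beta <- setNames(rep(0, n_lipids), lipid_ids)
  beta[planted] <- effect_size * sample(c(-1, 1), n_planted, replace = TRUE)
  baseline <- setNames(rnorm(n_lipids, 5, baseline_sd), lipid_ids)
  # lipids beyond the shared set are each missing from >= 1 series
  measured_in <- lapply(seq_len(n_lipids), function(i) {
    if (i <= n_shared) seq_len(n_series)
    else {
      drop_n <- sample(seq_len(n_series - 1L), 1L)
      setdiff(seq_len(n_series), sample(n_series, drop_n))
    }
  })
  series <- list()
  for (s in seq_len(n_series)) {
    lip_idx <- which(vapply(measured_in, function(m) s %in% m, logical(1L)))
    offs <- rnorm(length(lip_idx), 0, series_offset_sd)
    smp <- expand.grid(replicate = seq_len(n_replicates),
                       genotype = genotypes, stringsAsFactors = FALSE)
    smp$series <- s
    smp$inheritance_class <- classes[match(smp$genotype, genotypes)]
    smp$sample_id <- sprintf("%s_s%d_r%d", smp$genotype, s, smp$replicate)
    vals <- matrix(NA_real_, nrow(smp), length(lip_idx),
                   dimnames = list(smp$sample_id, lipid_ids[lip_idx]))
    for (j in seq_along(lip_idx)) {
      l <- lip_idx[j]
      mu <- baseline[l] + offs[j] + beta[l] * smp$inheritance_class
      vals[, j] <- exp(mu + rnorm(nrow(smp), 0, noise_sd))
    }
    series[[paste0("series_", s)]] <- lipid_matrix(
      vals,
      smp[c("sample_id", "genotype", "series", "replicate",
            "inheritance_class")],
      data.frame(lipid_id = lipid_ids[lip_idx],
                 lipid_class = lipid_class[lip_idx]))
  }
  manifest <- list(
    planted = data.frame(lipid_id = planted,
                         beta = unname(beta[planted])),
    genotype_classes = data.frame(genotype = genotypes, class = classes),
    lipid_classes = data.frame(lipid_id = lipid_ids,
                               lipid_class = lipid_class),
    n_shared = n_shared, seed = seed)
  list(series = series, manifest = manifest)
}
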