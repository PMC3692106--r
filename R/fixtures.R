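# Deterministic synthetic-data generators with planted ground truth. Every
# generator is a pure function of (parameters, seed): identical calls yield
# byte-identical written tables, so every downstream stage can be tested
# without any external download.

make_locus_ids <- function(n) {
  chr <- ((seq_len(n) - 1L) %% 5L) + 1L
  sprintf("AT%dG%05d", chr, seq_len(n) * 10L)
}

#' Generate a tissue-panel expression fixture with planted effects
#'
#' Emulates a triplicate log2 RMA-style developmental panel: each gene gets a
#' constant background level across conditions, selected genes get an
#' additive log2 effect in one tissue, and replicates get additive Gaussian
#' noise. With `noise_sd = 0` a planted gene exceeds its own other conditions
#' by exactly the stated effect.
#'
#' @param n_genes number of genes (>= 1).
#' @param tissue_groups condition labels; names, if set, give each condition's
#'   tissue-category group.
#' @param planted data.frame with columns `gene` (1-based gene index),
#'   `tissue` (condition label), `effect` (log2 units); may be empty.
#' @param noise_sd replicate noise standard deviation, log2 units.
#' @param seed integer seed.
#' @param n_reps replicates per cell (default 3).
#' @param background_range background levels drawn uniformly from this range
#'   (log2 units); default 6..10, a typical RMA intensity band.
#' @return an [expression_matrix()] on the log2 scale.
#' @export
generate_expression_fixture <- function(n_genes, tissue_groups,
                                        planted = NULL, noise_sd = 0.1,
                                        seed = 1L, n_reps = 3L,
                                        background_range = c(6, 10)) {
  stopifnot(n_genes >= 1L)
  conditions <- as.character(tissue_groups)
  groups <- if (!is.null(names(tissue_groups))) names(tissue_groups) else conditions
  withr::with_seed(seed, {
    gene_ids <- make_locus_ids(n_genes)
    background <- stats::runif(n_genes, background_range[1], background_range[2])
    mu <- matrix(background, nrow = n_genes, ncol = length(conditions))
    if (!is.null(planted) && nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        j <- match(planted$tissue[i], conditions)
        if (is.na(j))
          validation_error(sprintf("planted effect on unknown tissue '%s'",
                                   planted$tissue[i]))
        g <- planted$gene[i]
        if (g < 1 || g > n_genes)
          validation_error(sprintf("planted gene index %d out of range", g))
        mu[g, j] <- mu[g, j] + planted$effect[i]
      }
    }
    arr <- array(rep(mu, n_reps), dim = c(n_genes, length(conditions), n_reps))
    if (noise_sd > 0)
      arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
    expression_matrix(gene_ids, conditions, arr, scale = "log2", groups = groups)
  })
}

#' Circadian ground truth for one gene
#'
#' The planted model is `value(t) = m + A * cos(2*pi*(t - phase)/24)`: mean
#' level `m`, amplitude `A` (half the peak-to-trough swing) and peak clock
#' time `phase` in hours. `m > A >= 0` keeps expression positive.
#'
#' @param gene_id locus identifier.
#' @param m mean linear expression level.
#' @param A amplitude, same units.
#' @param phase peak clock time, hours in `[0, 24)`.
#' @param noise_sd additive noise scale (linear units).
#' @return one-row data.frame; rbind rows to build a truth table.
#' @export
circadian_truth <- function(gene_id, m, A, phase, noise_sd = 0) {
  if (A < 0) validation_error("amplitude A must be >= 0")
  if (m <= A) validation_error("need m > A to keep expression positive")
  if (phase < 0 || phase >= 24) validation_error("phase must lie in [0, 24)")
  data.frame(gene_id = as.character(gene_id), m = m, A = A, phase = phase,
             noise_sd = noise_sd, stringsAsFactors = FALSE)
}

#' Generate diurnal time-series fixtures from planted sine parameters
#'
#' Evaluates each gene's planted harmonic on the sampling schedule (default
#' 0..44 h at 4-h steps, 12 points) and adds Gaussian noise on the linear
#' scale. Returns the series together with the truth table so recovery tests
#' can compare fitted against planted parameters.
#'
#' @param truths data.frame of [circadian_truth()] rows.
#' @param schedule sampling times in hours.
#' @param seed integer seed.
#' @param condition_label growth-condition tag for the series.
#' @return `list(series = <list of circadian_series>, truth = truths)`.
#' @export
generate_circadian_fixture <- function(truths,
                                       schedule = default_circadian_schedule(),
                                       seed = 1L, condition_label = "LL") {
  stopifnot(is.data.frame(truths), nrow(truths) >= 1L)
  if (any(truths$m <= truths$A))
    validation_error("need m > A for every gene to keep expression positive")
  withr::with_seed(seed, {
    series <- lapply(seq_len(nrow(truths)), function(i) {
      tt <- truths[i, ]
      v <- tt$m + tt$A * cos(2 * pi * (schedule - tt$phase) / 24)
      if (tt$noise_sd > 0)
        v <- v + stats::rnorm(length(v), sd = tt$noise_sd)
      circadian_series(tt$gene_id, schedule, pmax(v, .Machine$double.eps),
                       condition_label = condition_label)
    })
    list(series = series, truth = truths)
  })
}

#' Generate a motif annotation fixture
#'
#' Random motif sequences of the profile's length, centered uniformly over
#' the legal positions within the profile's upstream region (half-integer
#' centers exactly when the length is even). Designated genes can be left
#' motif-less to exercise the no-motif fallback rule downstream.
#'
#' @param profile a [motif_profile()].
#' @param gene_ids genes to annotate.
#' @param motifs_per_gene annotations per gene (>= 0).
#' @param seed integer seed.
#' @param empty_genes gene IDs deliberately given zero annotations.
#' @return a [motif_table()].
#' @export
generate_motif_fixture <- function(profile, gene_ids, motifs_per_gene = 3L,
                                   seed = 1L, empty_genes = character(0)) {
  stopifnot(motifs_per_gene >= 0L)
  k <- profile$motif_length
  starts_legal <- seq(-profile$region_width, -k)   # most-upstream base
  keep <- setdiff(gene_ids, empty_genes)
  withr::with_seed(seed, {
    n <- length(keep) * motifs_per_gene
    df <- data.frame(
      gene_id = rep(keep, each = motifs_per_gene),
      motif_seq = vapply(seq_len(n), function(i)
        paste(sample(DNA_ALPHABET, k, replace = TRUE), collapse = ""), ""),
      center = sample(starts_legal, n, replace = TRUE) + (k - 1) / 2,
      stringsAsFactors = FALSE
    )
    motif_table(df, profile)
  })
}

#' Generate promoter baseline sequences
#'
#' I.i.d. bases with the stated GC fraction; used as fill-in baselines.
#'
#' @param gene_ids record IDs.
#' @param length sequence length in bp.
#' @param gc_fraction fraction of G+C in `[0, 1]`.
#' @param seed integer seed.
#' @return named list of [promoter_record()].
#' @export
generate_promoter_fixture <- function(gene_ids, length = 500L,
                                      gc_fraction = 0.36, seed = 1L) {
  stopifnot(length >= 1L)
  if (gc_fraction < 0 || gc_fraction > 1)
    validation_error("gc_fraction must lie in [0, 1]")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  withr::with_seed(seed, {
    recs <- lapply(gene_ids, function(g)
      promoter_record(g, paste(sample(DNA_ALPHABET, length, replace = TRUE,
                                      prob = p), collapse = "")))
    stats::setNames(recs, gene_ids)
  })
}

#' Materialize a complete demo dataset directory
#'
#' Writes an expression table, a diurnal table, motif tables under both
#' built-in profiles, and a promoter FASTA, all derived deterministically
#' from one seed. Used by the `make-fixtures` CLI verb and by examples.
#'
#' @param dir output directory (created if absent).
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return invisibly, a named list of the written file paths.
#' @export
write_demo_dataset <- function(dir, n_genes = 60L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tissues <- c(Flower = "Flower", Leaf = "Leaf", Root = "Root",
               Seed = "Seed", Stem = "Stem")
  planted <- data.frame(gene = c(1L, 2L), tissue = c("Leaf", "Root"),
                        effect = c(4, 3))
  expr <- generate_expression_fixture(n_genes, tissues, planted,
                                      noise_sd = 0.1, seed = seed)
  truths <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    withr::with_seed(seed + i, {
      m <- stats::runif(1, 50, 500)
      circadian_truth(expr$gene_ids[i], m, stats::runif(1, 0.05, 0.8) * m,
                      stats::runif(1, 0, 24), noise_sd = 0.05 * m)
    })
  }))
  circ <- generate_circadian_fixture(truths, seed = seed)
  mot7 <- generate_motif_fixture(profile_coexpression(), expr$gene_ids,
                                 motifs_per_gene = 2L, seed = seed,
                                 empty_genes = expr$gene_ids[3])
  mot8 <- generate_motif_fixture(profile_wordfreq(), expr$gene_ids,
                                 motifs_per_gene = 2L, seed = seed + 1L,
                                 empty_genes = expr$gene_ids[3])
  proms <- generate_promoter_fixture(expr$gene_ids, length = 500L, seed = seed)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    circadian = file.path(dir, "circadian.tsv"),
    motifs_coexpression = file.path(dir, "motifs_coexpression.tsv"),
    motifs_wordfreq = file.path(dir, "motifs_wordfreq.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    truth = file.path(dir, "circadian_truth.tsv")
  )
  write_expression_table(expr, paths$expression)
  write_circadian_table(circ$series, paths$circadian)
  write_motif_table(mot7, paths$motifs_coexpression)
  write_motif_table(mot8, paths$motifs_wordfreq)
  write_promoter_fasta(proms, paths$promoters)
  utils::write.table(circ$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
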