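# Expression mining: rank-list construction over tissue panels, closed-form
# harmonic regression of diurnal series, phase-binned circadian ranking, and
# the motif-retrieval walkers with the no-motif fallback rule.

#' Describe one gene-expression property
#'
#' A property is a condition (tissue label, or a phase bin for circadian
#' ranking), a direction (maximum or minimum value desired), whether the
#' values are normalized to each gene's own mean, and the replicate
#' summarizer used. Circadian properties use direction `max` only (largest
#' amplitude).
#'
#' @param condition condition label or `"phase_<h>"` bin tag.
#' @param direction `"max"` or `"min"`.
#' @param normalized logical; relative to the gene's mean expression.
#' @param summarizer `"mean"` or `"median"` replicate summary.
#' @return an object of class `property_descriptor`.
#' @export
property_descriptor <- function(condition, direction = c("max", "min"),
                                normalized = FALSE,
                                summarizer = c("mean", "median")) {
  structure(
    list(condition = condition, direction = match.arg(direction),
         normalized = isTRUE(normalized), summarizer = match.arg(summarizer)),
    class = "property_descriptor"
  )
}

#' Collapse replicates to one value per (gene, condition)
#'
#' @param expr an [expression_matrix()].
#' @param method `"mean"` or `"median"`.
#' @return numeric matrix genes x conditions, with the input scale attached
#'   as attribute `"scale"`.
#' @export
summarize_replicates <- function(expr, method = c("mean", "median")) {
  method <- match.arg(method)
  f <- if (method == "mean") mean else stats::median
  out <- apply(expr$values, c(1, 2), f)
  dimnames(out) <- list(expr$gene_ids, expr$conditions)
  attr(out, "scale") <- expr$scale
  out
}

#' Normalize each gene to its own mean expression
#'
#' On the log2 scale the gene's mean across conditions is subtracted (so the
#' per-gene mean of normalized values is 0); on the linear scale each value
#' is divided by the gene's mean (per-gene mean 1). Used to rank genes by
#' how specific their expression is to one condition rather than by absolute
#' level.
#'
#' @param summary genes x conditions matrix from [summarize_replicates()].
#' @param scale `"log2"` or `"linear"`; defaults to the matrix's own
#'   `"scale"` attribute.
#' @return matrix of the same shape, `"scale"` attribute preserved.
#' @export
normalize_by_gene <- function(summary, scale = attr(summary, "scale")) {
  if (is.null(scale)) validation_error("scale must be given or attached")
  scale <- match.arg(scale, c("log2", "linear"))
  if (scale == "linear" && any(summary <= 0))
    validation_error("linear-scale values must be strictly positive to normalize")
  m <- rowMeans(summary)
  out <- if (scale == "log2") sweep(summary, 1, m, "-") else sweep(summary, 1, m, "/")
  attr(out, "scale") <- scale
  out
}

#' Rank all genes by one expression property
#'
#' Produces a complete ordering: values monotone non-increasing for
#' direction `max`, non-decreasing for `min`; ties broken by lexicographic
#' gene ID so the ordering is deterministic.
#'
#' @param values genes x conditions matrix (summarized, optionally
#'   normalized) with gene IDs as rownames.
#' @param descriptor a [property_descriptor()]; its `condition` must be a
#'   column of `values`.
#' @return an object of class `rank_list`: `list(descriptor, entries)` where
#'   `entries` is a data.frame `(gene_id, value)` in rank order.
#' @export
build_rank_list <- function(values, descriptor) {
  j <- match(descriptor$condition, colnames(values))
  if (is.na(j))
    validation_error(sprintf("unknown condition '%s'", descriptor$condition))
  v <- values[, j]
  ids <- rownames(values)
  ord <- if (descriptor$direction == "max") order(-v, ids) else order(v, ids)
  structure(
    list(descriptor = descriptor,
         entries = data.frame(gene_id = ids[ord], value = unname(v[ord]),
                              stringsAsFactors = FALSE)),
    class = "rank_list"
  )
}

new_mining_result <- function(gene_id, rank, descriptor, motifs, skipped) {
  structure(
    list(gene_id = gene_id, rank = rank, property = descriptor,
         motifs = motifs, skipped = skipped),
    class = "mining_result"
  )
}

#' Retrieve motifs from the most extreme genes of a rank list
#'
#' Walks the rank list in order and returns the first `k` genes that carry
#' at least one motif annotation; genes without motifs are passed over and
#' recorded in each result's `skipped` field. This is the fallback rule:
#' when no motifs are found for a gene, the next most extreme gene is used.
#'
#' @param rank a [rank_list()][build_rank_list].
#' @param joined mapping from [join_by_gene()] (or any named list whose
#'   elements have a `motifs` data.frame).
#' @param k number of motif-bearing genes to return (default 1).
#' @return list of `k` `mining_result` objects, in rank order.
#' @export
motif_express <- function(rank, joined, k = 1L) {
  stopifnot(k >= 1L)
  results <- vector("list", k)
  found <- 0L
  skipped <- character(0)
  for (i in seq_len(nrow(rank$entries))) {
    g <- rank$entries$gene_id[i]
    rec <- joined[[g]]
    motifs <- if (is.null(rec)) NULL else rec$motifs
    if (is.null(motifs) || nrow(motifs) == 0L) {
      skipped <- c(skipped, g)
      next
    }
    found <- found + 1L
    results[[found]] <- new_mining_result(g, i, rank$descriptor, motifs, skipped)
    skipped <- character(0)
    if (found == k) return(results)
  }
  validation_error(sprintf(
    "only %d gene(s) with motif annotations available, %d requested", found, k))
}

#' Top-10 variant genes with motifs
#'
#' Identical to [motif_express()] with `k = 10`: the ten most extreme
#' motif-bearing genes, for selection among variant expression patterns.
#'
#' @inheritParams motif_express
#' @export
motif_ranking <- function(rank, joined) motif_express(rank, joined, k = 10L)

#' Closed-form 24-h harmonic fit of a diurnal series
#'
#' Least-squares fit of `value(t) = m + a*cos(2*pi*t/24) + b*sin(2*pi*t/24)`
#' with the period fixed at 24 h. Amplitude is `A = sqrt(a^2 + b^2)` and the
#' phase is the clock time in `[0, 24)` at which the fitted curve peaks. The
#' model is linear in (m, a, b), so the optimum is exact and needs no
#' iteration. A constant series fits with `A = 0` and phase reported as 0 by
#' convention.
#'
#' @param series a [circadian_series()] with at least 3 time points whose
#'   harmonic design is non-degenerate.
#' @return an object of class `sine_fit`: gene_id, m, A, phase, period,
#'   rmse, normalized_amplitude (`A/m`, the fold-change-style measure).
#' @export
fit_sine <- function(series) {
  t <- series$times
  y <- series$values
  if (length(t) < 3L)
    validation_error("need at least 3 time points to fit the harmonic")
  w <- 2 * pi / 24
  X <- cbind(1, cos(w * t), sin(w * t))
  qrx <- qr(X)
  if (qrx$rank < 3L)
    validation_error("degenerate sampling design: times collapse modulo 24 h")
  beta <- qr.coef(qrx, y)
  m <- beta[1]; a <- beta[2]; b <- beta[3]
  A <- sqrt(a^2 + b^2)
  phase <- if (A < 1e-12) 0 else (atan2(b, a) / w) %% 24
  if (A < 1e-12) A <- 0
  resid <- y - X %*% beta
  structure(
    list(gene_id = series$gene_id, m = unname(m), A = unname(A),
         phase = unname(phase), period = 24,
         rmse = sqrt(mean(resid^2)),
         normalized_amplitude = if (m > 0) unname(A / m) else NA_real_),
    class = "sine_fit"
  )
}

#' Fit every series and tabulate the results
#'
#' @param series list of [circadian_series()].
#' @return data.frame: gene_id, m, A, phase, rmse, normalized_amplitude.
#' @export
fit_sine_all <- function(series) {
  rows <- lapply(series, function(s) {
    f <- fit_sine(s)
    data.frame(gene_id = f$gene_id, m = f$m, A = f$A, phase = f$phase,
               rmse = f$rmse, normalized_amplitude = f$normalized_amplitude,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank genes within a circadian phase bin by amplitude
#'
#' Genes whose fitted peak time falls in `[bin, bin + 4)` hours are ranked by
#' amplitude `A` (or by `A/m` when `normalized`), descending; genes outside
#' the bin are excluded. Bins are the 4-h buckets 0, 4, 8, 12, 16, 20,
#' aligned to the sampling grid. An empty bin yields an empty rank list.
#'
#' @param fits data.frame from [fit_sine_all()].
#' @param phase_bin one of 0, 4, 8, 12, 16, 20.
#' @param normalized rank by fold-change-style `A/m` instead of raw `A`.
#' @return a `rank_list`.
#' @export
circadian_rank <- function(fits, phase_bin, normalized = FALSE) {
  if (!phase_bin %in% seq(0, 20, by = 4))
    validation_error("phase_bin must be one of 0, 4, 8, 12, 16, 20")
  sel <- fits$phase >= phase_bin & fits$phase < phase_bin + 4
  sub <- fits[sel, , drop = FALSE]
  v <- if (normalized) sub$normalized_amplitude else sub$A
  ord <- order(-v, sub$gene_id)
  structure(
    list(descriptor = property_descriptor(paste0("phase_", phase_bin), "max",
                                          normalized = normalized),
         entries = data.frame(gene_id = sub$gene_id[ord], value = v[ord],
                              stringsAsFactors = FALSE)),
    class = "rank_list"
  )
}

#' Motifs of the strongest circadian gene in a phase bin
#'
#' [motif_express()] with `k = 1` applied to a circadian rank list: returns
#' the motif annotations of the largest-amplitude gene peaking in the chosen
#' bin, falling back to the runner-up when the winner carries no motifs.
#'
#' @param rank a `rank_list` from [circadian_rank()].
#' @param joined mapping from [join_by_gene()].
#' @return a single `mining_result`.
#' @export
motif_circadian <- function(rank, joined) {
  if (nrow(rank$entries) == 0L)
    validation_error("no candidate genes: the requested phase bin is empty")
  motif_express(rank, joined, k = 1L)[[1]]
}

#' Export a rank list or sine-fit table as TSV
#'
#' @param x a `rank_list` or a [fit_sine_all()] data.frame.
#' @param path output file.
#' @export
write_rank_list <- function(x, path) {
  df <- if (inherits(x, "rank_list")) x$entries else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
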