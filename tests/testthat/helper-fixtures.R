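# Small in-code fixtures shared across test files.

tiny_expression <- function() {
  # 2 genes x 2 conditions x 3 replicates, log2 scale
  arr <- array(NA_real_, dim = c(2, 2, 3))
  arr[1, 1, ] <- c(2, 4, 9)   # G1 Leaf replicates
  arr[2, 1, ] <- c(4, 6, 8)   # G2 Leaf
  arr[1, 2, ] <- c(1, 1, 1)   # G1 Root
  arr[2, 2, ] <- c(2, 2, 2)   # G2 Root
  expression_matrix(c("G1", "G2"), c("Leaf", "Root"), arr, scale = "log2")
}

tiny_motifs <- function(profile = profile_wordfreq()) {
  motif_table(data.frame(
    gene_id = c("G1", "G1", "G3"),
    motif_seq = c("ATTGCCAC", "GGGGCCCC", "ACGTACGT"),
    center = c(-204.5, -30.5, -100.5),
    stringsAsFactors = FALSE
  ), profile)
}

# independent selection oracle: among motif-bearing genes, the k most extreme
# values (ties to the lexicographically smaller gene ID)
oracle_select <- function(values, has_motif, direction, k = 1L) {
  ids <- names(values)
  keep <- ids[has_motif[ids]]
  v <- values[keep]
  ord <- if (direction == "max") order(-v, keep) else order(v, keep)
  keep[ord][seq_len(k)]
}

# independent grid-search oracle for the fixed-period harmonic fit
oracle_sine_grid <- function(times, values, phase_step = 0.1) {
  w <- 2 * pi / 24
  best <- list(sse = Inf)
  for (phi in seq(0, 24 - phase_step, by = phase_step)) {
    x <- cos(w * (times - phi))
    fit <- stats::lm(values ~ x)
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best$sse)
      best <- list(sse = sse, m = unname(stats::coef(fit)[1]),
                   A = unname(stats::coef(fit)[2]), phase = phi)
  }
  if (best$A < 0) {   # fold a negative amplitude onto the opposite phase
    best$A <- -best$A
    best$phase <- (best$phase + 12) %% 24
  }
  best
}

circular_diff_h <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

canvas_string <- function(design) paste(design$canvas, collapse = "")
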