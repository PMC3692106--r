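# The promoter design canvas: a strictly upstream sequence of length L over
# positions -L..-1, edited by motif placement operations with overlap
# arbitration, baseline fill-in, change tracking, and a replayable edit log.
# Empty positions are dashes, matching the convention that a design is a
# sequence of motifs separated by empty base pairs.

#' Create a blank promoter design canvas
#'
#' The canvas spans TSS-relative positions `-length .. -1` (position 0 does
#' not exist: designs are strictly upstream) and starts as all dashes. An
#' optional baseline promoter of the same length supplies fill-in bases at
#' the final design step.
#'
#' @param length canvas length in bp (>= 1).
#' @param baseline optional [promoter_record()] of matching length.
#' @param name design name (FASTA/GFF3 sequence ID on export).
#' @return an object of class `promoter_design`.
#' @export
new_design <- function(length, baseline = NULL, name = "design") {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "promoter_record"))
    if (baseline$length != length)
      validation_error(sprintf("baseline length %d != canvas length %d",
                               baseline$length, length))
  }
  d <- structure(
    list(name = name, length = length,
         canvas = rep("-", length),
         baseline = baseline,
         placed = data.frame(motif_seq = character(0), center = numeric(0),
                             source_gene = character(0),
                             source_dataset = character(0),
                             op_id = integer(0), stringsAsFactors = FALSE),
         log = list()),
    class = "promoter_design"
  )
  append_log(d, "new_design",
             params = list(length = length, name = name,
                           baseline_id = if (is.null(baseline)) NULL else baseline$gene_id,
                           baseline_seq = if (is.null(baseline)) NULL else baseline$sequence))
}

#' @export
print.promoter_design <- function(x, ...) {
  cat(sprintf("promoter_design '%s': %d bp, %d placed motif(s), %d empty position(s)\n",
              x$name, x$length, nrow(x$placed), sum(x$canvas == "-")))
  invisible(x)
}

#' @export
format.promoter_design <- function(x, ...) paste(x$canvas, collapse = "")

append_log <- function(design, op, params = list(), altered = integer(0),
                       conflicts = integer(0)) {
  design$log[[length(design$log) + 1L]] <- list(
    op = op, params = params,
    altered = as.numeric(altered), conflicts = as.numeric(conflicts))
  design
}

current_op_id <- function(design) length(design$log)

# Write one motif onto a canvas character vector. Returns the new canvas
# plus the altered positions (bases that actually changed) and the conflict
# positions (footprint bases already occupied). Raises under policy "fail"
# before any mutation.
apply_motif_to_canvas <- function(canvas, L, motif_seq, center, policy) {
  motif_seq <- toupper(motif_seq)
  k <- nchar(motif_seq)
  if (!is_dna(motif_seq))
    validation_error(sprintf("motif '%s' contains non-ACGT characters", motif_seq))
  if (!center_has_legal_parity(center, k))
    validation_error(sprintf(
      "center %s has wrong parity for a %d-bp motif (must be %s)",
      format(center), k, if (k %% 2 == 1) "an integer" else "a half-integer"))
  s <- motif_start(center, k)
  e <- motif_end(center, k)
  if (s < -L || e > -1)
    validation_error(sprintf(
      "footprint %g..%g falls outside the canvas [-%d, -1]", s, e, L))
  pos <- seq(s, e)
  idx <- pos_to_index(pos, L)
  bases <- strsplit(motif_seq, "")[[1]]
  occupied <- canvas[idx] != "-"
  if (policy == "fail" && any(occupied))
    conflict_error(sprintf(
      "motif %s at center %s overlaps occupied positions %s (existing bases %s)",
      motif_seq, format(center), paste(pos[occupied], collapse = ", "),
      paste(canvas[idx[occupied]], collapse = "")),
      positions = pos[occupied])
  write <- if (policy == "keep_existing") !occupied else rep(TRUE, k)
  altered <- pos[write & canvas[idx] != bases]
  canvas[idx[write]] <- bases[write]
  list(canvas = canvas, altered = altered, conflicts = pos[occupied])
}

record_placement <- function(design, motif_seq, center, source_gene,
                             source_dataset) {
  design$placed <- rbind(design$placed, data.frame(
    motif_seq = motif_seq, center = center,
    source_gene = source_gene, source_dataset = source_dataset,
    op_id = current_op_id(design), stringsAsFactors = FALSE))
  design
}

#' Place a motif at an explicit center position
#'
#' Writes the motif bases over its footprint. When the footprint overlaps
#' previously written bases the conflict is resolved per `policy`:
#' `keep_existing` leaves the old bases in the overlap, `use_new` overwrites
#' them, and `fail` raises a conflict error before any mutation. Altered
#' positions are recorded in the edit log.
#'
#' @param design a [new_design()].
#' @param motif_seq DNA text over A/C/G/T.
#' @param center TSS offset of the motif's middle base pair; a half-integer
#'   for even-length motifs.
#' @param policy `"fail"`, `"keep_existing"` or `"use_new"`.
#' @param source_gene,source_dataset provenance recorded with the placement;
#'   defaults describe a manually input motif.
#' @return the updated design.
#' @export
place_motif <- function(design, motif_seq, center,
                        policy = c("fail", "keep_existing", "use_new"),
                        source_gene = NA_character_,
                        source_dataset = "user-input") {
  policy <- match.arg(policy)
  res <- apply_motif_to_canvas(design$canvas, design$length, motif_seq,
                               center, policy)
  design$canvas <- res$canvas
  design <- append_log(design, "place_motif",
                       params = list(motif_seq = toupper(motif_seq),
                                     center = center, policy = policy,
                                     source_gene = source_gene,
                                     source_dataset = source_dataset),
                       altered = res$altered, conflicts = res$conflicts)
  record_placement(design, toupper(motif_seq), center, source_gene,
                   source_dataset)
}

#' Place a motif at its natural promoter location
#'
#' The default placement strategy: the same TSS-relative position the motif
#' occupies in the natural promoter it was annotated on.
#'
#' @param design a [new_design()].
#' @param annotation one row of a [motif_table()] (fields `gene_id`,
#'   `motif_seq`, `center`, `dataset`).
#' @inheritParams place_motif
#' @return the updated design.
#' @export
place_at_natural <- function(design, annotation,
                             policy = c("fail", "keep_existing", "use_new")) {
  policy <- match.arg(policy)
  place_motif(design, annotation$motif_seq[1], annotation$center[1],
              policy = policy,
              source_gene = annotation$gene_id[1],
              source_dataset = annotation$dataset[1] %||% "unknown")
}

#' Collect all annotated motifs of one gene onto the canvas
#'
#' Places every annotation at its natural position in table order, resolving
#' per-annotation overlaps per `policy`. Under `policy = "fail"` the
#' operation is atomic: the first conflict aborts and the design is
#' unchanged. One log entry summarizes all placements and conflicts.
#'
#' @param design a [new_design()].
#' @param annotations a [motif_table()] (typically all rows of one gene).
#' @inheritParams place_motif
#' @return the updated design.
#' @export
collect_all_motifs <- function(design, annotations,
                               policy = c("fail", "keep_existing", "use_new")) {
  policy <- match.arg(policy)
  canvas <- design$canvas
  altered <- numeric(0)
  conflicts <- numeric(0)
  for (i in seq_len(nrow(annotations))) {
    res <- apply_motif_to_canvas(canvas, design$length,
                                 annotations$motif_seq[i],
                                 annotations$center[i], policy)
    canvas <- res$canvas
    altered <- union(altered, res$altered)
    conflicts <- union(conflicts, res$conflicts)
  }
  design$canvas <- canvas
  design <- append_log(design, "collect_all_motifs",
                       params = list(gene_id = unique(annotations$gene_id),
                                     motif_seq = annotations$motif_seq,
                                     center = annotations$center,
                                     dataset = annotations$dataset,
                                     policy = policy),
                       altered = sort(altered), conflicts = sort(conflicts))
  for (i in seq_len(nrow(annotations)))
    design <- record_placement(design, annotations$motif_seq[i],
                               annotations$center[i],
                               annotations$gene_id[i],
                               annotations$dataset[i] %||% "unknown")
  design
}

#' Stack multiple copies of a motif upstream of an anchor site
#'
#' Places the anchor copy at `anchor_center` and `n_extra` further copies
#' strictly upstream, copy *i* centered at `anchor_center - i * (k +
#' spacing)`, leaving exactly `spacing` positions between adjacent
#' footprints. All `n_extra + 1` footprints are validated against the canvas
#' bounds before any base is written (atomic).
#'
#' @param design a [new_design()].
#' @param motif_seq DNA text.
#' @param anchor_center center of the most-downstream (anchor) copy.
#' @param n_extra number of additional upstream copies (>= 0; 0 degenerates
#'   to [place_motif()]).
#' @param spacing empty base pairs between adjacent copies (>= 0).
#' @inheritParams place_motif
#' @return the updated design.
#' @export
stack_motif <- function(design, motif_seq, anchor_center, n_extra, spacing,
                        policy = c("fail", "keep_existing", "use_new"),
                        source_gene = NA_character_,
                        source_dataset = "user-input") {
  policy <- match.arg(policy)
  stopifnot(n_extra >= 0L, spacing >= 0L)
  k <- nchar(motif_seq)
  centers <- anchor_center - (0:n_extra) * (k + spacing)
  for (ct in centers) {
    if (!center_has_legal_parity(ct, k))
      validation_error("anchor center has wrong parity for the motif length")
    if (motif_start(ct, k) < -design$length || motif_end(ct, k) > -1)
      validation_error(sprintf(
        "stacked copy at center %s has footprint %g..%g outside the canvas [-%d, -1]",
        format(ct), motif_start(ct, k), motif_end(ct, k), design$length))
  }
  canvas <- design$canvas
  altered <- numeric(0)
  conflicts <- numeric(0)
  for (ct in centers) {
    res <- apply_motif_to_canvas(canvas, design$length, motif_seq, ct, policy)
    canvas <- res$canvas
    altered <- union(altered, res$altered)
    conflicts <- union(conflicts, res$conflicts)
  }
  design$canvas <- canvas
  design <- append_log(design, "stack_motif",
                       params = list(motif_seq = toupper(motif_seq),
                                     anchor_center = anchor_center,
                                     n_extra = n_extra, spacing = spacing,
                                     policy = policy,
                                     source_gene = source_gene,
                                     source_dataset = source_dataset),
                       altered = sort(altered), conflicts = sort(conflicts))
  for (ct in centers)
    design <- record_placement(design, toupper(motif_seq), ct, source_gene,
                               source_dataset)
  design
}

#' Fill empty positions from the baseline sequence
#'
#' Every dash is replaced by the baseline base at the same position; bases
#' written by motif placements are untouched. Idempotent; the usual final
#' design step.
#'
#' @param design a design with a baseline.
#' @return the updated design.
#' @export
fill_baseline <- function(design) {
  if (is.null(design$baseline))
    validation_error("design has no baseline sequence to fill from")
  empty <- which(design$canvas == "-")
  bases <- strsplit(design$baseline$sequence, "")[[1]]
  design$canvas[empty] <- bases[empty]
  append_log(design, "fill_baseline",
             altered = index_to_pos(empty, design$length))
}

#' Positions where the design differs from its baseline
#'
#' Returns the TSS-relative positions whose canvas base is written (not a
#' dash) and differs from the baseline base -- the positions a front-end
#' would highlight as altered. Invariant under [fill_baseline()], which only
#' copies baseline bases.
#'
#' @param design a design with a baseline.
#' @return sorted numeric vector of TSS-relative positions.
#' @export
diff_from_baseline <- function(design) {
  if (is.null(design$baseline))
    validation_error("design has no baseline sequence to compare against")
  bases <- strsplit(design$baseline$sequence, "")[[1]]
  idx <- which(design$canvas != "-" & design$canvas != bases)
  index_to_pos(idx, design$length)
}

#' Suggest a placement position for a motif from its annotation record
#'
#' A frequency heuristic over the genome-wide annotation table: the most
#' frequent center among occurrences of the identical motif sequence; ties
#' go to the center closest to the TSS. For a motif never seen in the table
#' the closest-to-TSS center that fits the motif is suggested (footprint
#' ending at position -1).
#'
#' @param motif_seq DNA text.
#' @param annotations a [motif_table()] (may be empty).
#' @return a TSS-relative center offset.
#' @export
suggest_position <- function(motif_seq, annotations) {
  motif_seq <- toupper(motif_seq)
  k <- nchar(motif_seq)
  centers <- annotations$center[annotations$motif_seq == motif_seq]
  if (length(centers) == 0L)
    return(-1 - (k - 1) / 2)
  tab <- table(centers)
  best <- as.numeric(names(tab)[tab == max(tab)])
  max(best)   # centers are negative: the largest is closest to the TSS
}

#' Export a design as FASTA, GFF3 and a replayable log
#'
#' Writes `<base_name>.fasta` (final sequence; remaining dashes become `N`
#' with a warning), `<base_name>.gff3` (placed motifs as `TF_binding_site`
#' features, 1-based inclusive coordinates via `pos + L + 1` on a contig of
#' length L, always the sense strand) and `<base_name>.log.jsonl` (the edit
#' log; [replay_design()] reproduces the design from it exactly).
#'
#' @param design a design.
#' @param base_name output file stem.
#' @param dir output directory.
#' @return invisibly, named list of written paths.
#' @export
export_design <- function(design, base_name, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(fasta = file.path(dir, paste0(base_name, ".fasta")),
                gff3 = file.path(dir, paste0(base_name, ".gff3")),
                log = file.path(dir, paste0(base_name, ".log.jsonl")))
  seq_chars <- design$canvas
  if (any(seq_chars == "-")) {
    warning(sprintf("%d unfilled position(s) written as N", sum(seq_chars == "-")))
    seq_chars[seq_chars == "-"] <- "N"
  }
  dna <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(dna) <- design$name
  Biostrings::writeXStringSet(dna, paths$fasta, width = 70L)
  L <- design$length
  if (nrow(design$placed) > 0L) {
    k <- nchar(design$placed$motif_seq)
    gr <- GenomicRanges::GRanges(
      seqnames = design$name,
      ranges = IRanges::IRanges(
        start = pos_to_index(motif_start(design$placed$center, k), L),
        end = pos_to_index(motif_end(design$placed$center, k), L)),
      strand = "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = design$placed$source_dataset,
      type = "TF_binding_site",
      motif_seq = design$placed$motif_seq,
      center = design$placed$center,
      op_id = design$placed$op_id)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  GenomeInfoDb::seqlengths(gr) <-
    stats::setNames(rep(L, length(GenomeInfoDb::seqlevels(gr))),
                    GenomeInfoDb::seqlevels(gr))
  rtracklayer::export.gff3(gr, paths$gff3)
  write_design_log(design, paths$log)
  invisible(paths)
}

#' Write / read / replay the edit log
#'
#' The log is line-delimited JSON, one design operation per line, append-only
#' in spirit: replaying it against a fresh canvas reproduces the design --
#' canvas, placed-motif list and baseline diff -- exactly. The log is the
#' persistent design state used by the command-line front-end.
#'
#' @param design a design.
#' @param path log file path.
#' @export
write_design_log <- function(design, path) {
  lines <- vapply(design$log, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null")),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_design_log
#' @return [read_design_log()]: the list of log entries.
#' @export
read_design_log <- function(path) {
  if (!file.exists(path)) io_error(sprintf("log file not found: %s", path))
  lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
}

#' @rdname write_design_log
#' @param entries log entries from [read_design_log()] (or a path to a log).
#' @return [replay_design()]: the reconstructed design.
#' @export
replay_design <- function(entries) {
  if (is.character(entries)) entries <- read_design_log(entries)
  if (length(entries) == 0L || entries[[1]]$op != "new_design")
    validation_error("log must start with a new_design entry")
  p <- entries[[1]]$params
  baseline <- if (!is.null(p$baseline_seq))
    promoter_record(p$baseline_id, p$baseline_seq) else NULL
  d <- new_design(p$length, baseline = baseline, name = p$name)
  for (e in entries[-1]) {
    p <- e$params
    d <- switch(e$op,
      place_motif = place_motif(d, p$motif_seq, p$center, policy = p$policy,
                                source_gene = p$source_gene %||% NA_character_,
                                source_dataset = p$source_dataset),
      collect_all_motifs = collect_all_motifs(
        d, data.frame(gene_id = rep(p$gene_id, length.out = length(p$motif_seq)),
                      motif_seq = p$motif_seq, center = p$center,
                      dataset = p$dataset, stringsAsFactors = FALSE),
        policy = p$policy),
      stack_motif = stack_motif(d, p$motif_seq, p$anchor_center, p$n_extra,
                                p$spacing, policy = p$policy,
                                source_gene = p$source_gene %||% NA_character_,
                                source_dataset = p$source_dataset),
      fill_baseline = fill_baseline(d),
      validation_error(sprintf("unknown log op '%s'", e$op))
    )
  }
  d
}
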