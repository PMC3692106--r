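# In-memory model of the four input tables (expression panel, diurnal series,
# motif annotations, promoter baselines), their tabular readers/writers, and
# the gene-ID join aligning expression values with motif locations.

#' Motif dataset profile
#'
#' Describes the conventions of a motif annotation source: the fixed motif
#' length and the width of the upstream promoter region within which motifs
#' are annotated. Two built-in profiles mirror the common public sources:
#' co-expression-derived 7-bp motifs annotated within 200 bp of the TSS, and
#' word-frequency-derived 8-bp motifs within 500 bp.
#'
#' @param name dataset tag (character scalar).
#' @param motif_length motif length in base pairs (>= 1).
#' @param region_width width in bp of the upstream region holding annotations
#'   (>= motif_length).
#' @return An object of class `motif_profile`.
#' @export
motif_profile <- function(name, motif_length, region_width) {
  motif_length <- as.integer(motif_length)
  region_width <- as.integer(region_width)
  if (motif_length < 1L)
    validation_error("motif_length must be >= 1")
  if (region_width < motif_length)
    validation_error("region_width must be >= motif_length")
  structure(
    list(name = name, motif_length = motif_length, region_width = region_width),
    class = "motif_profile"
  )
}

#' @rdname motif_profile
#' @export
profile_coexpression <- function() motif_profile("coexpression", 7L, 200L)

#' @rdname motif_profile
#' @export
profile_wordfreq <- function() motif_profile("wordfreq", 8L, 500L)

#' Expression matrix with replicates
#'
#' Genes x conditions with a uniform number of replicate measurements per
#' cell, plus explicit scale metadata. `values` is a 3-d array indexed
#' (gene, condition, replicate). Scale is never inferred from the values:
#' tissue-panel microarray summaries are log2 (RMA) while diurnal series are
#' linear, and the two behave differently under normalization.
#'
#' @param gene_ids unique locus identifiers.
#' @param conditions unique condition labels.
#' @param values numeric array of dim (genes, conditions, replicates).
#' @param scale `"log2"` or `"linear"`.
#' @param groups optional tissue-category group per condition; defaults to the
#'   condition labels themselves.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(gene_ids, conditions, values,
                              scale = c("log2", "linear"), groups = NULL) {
  scale <- match.arg(scale)
  gene_ids <- as.character(gene_ids)
  conditions <- as.character(conditions)
  if (anyDuplicated(gene_ids))
    validation_error(sprintf("duplicate gene ID: %s",
                             gene_ids[duplicated(gene_ids)][1]))
  if (anyDuplicated(conditions))
    validation_error("duplicate condition labels")
  if (length(dim(values)) != 3L)
    validation_error("values must be a 3-d array (gene x condition x replicate)")
  if (dim(values)[1] != length(gene_ids) || dim(values)[2] != length(conditions))
    validation_error("values dimensions do not match gene_ids / conditions")
  if (dim(values)[3] < 1L)
    validation_error("each cell needs at least one replicate")
  if (any(!is.finite(values)))
    validation_error("expression values must be finite numbers")
  if (scale == "linear" && any(values <= 0))
    validation_error("linear-scale expression values must be strictly positive")
  if (is.null(groups)) groups <- conditions
  groups <- as.character(groups)
  if (length(groups) != length(conditions))
    validation_error("groups must have one entry per condition")
  dimnames(values) <- list(gene_ids, conditions, NULL)
  structure(
    list(gene_ids = gene_ids, conditions = conditions, groups = groups,
         values = values, scale = scale),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d conditions x %d replicates (%s scale)\n",
              length(x$gene_ids), length(x$conditions), dim(x$values)[3], x$scale))
  invisible(x)
}

n_replicates <- function(x) dim(x$values)[3]

#' Diurnal expression series for one gene
#'
#' Linear-scale expression sampled on a fixed schedule, by default 12 points
#' at 4-h intervals over 44 h (two diurnal cycles).
#'
#' @param gene_id locus identifier.
#' @param times sampling times in hours, strictly increasing.
#' @param values positive linear-scale expression, one per time.
#' @param condition_label growth-condition tag.
#' @return An object of class `circadian_series`.
#' @export
circadian_series <- function(gene_id, times, values, condition_label = "LL") {
  if (length(times) != length(values))
    validation_error("times and values must have equal length")
  if (any(diff(times) <= 0))
    validation_error("times must be strictly increasing")
  if (any(values <= 0))
    validation_error("circadian series values must be strictly positive (linear scale)")
  structure(
    list(gene_id = as.character(gene_id), times = as.numeric(times),
         values = as.numeric(values), condition_label = condition_label),
    class = "circadian_series"
  )
}

#' Default diurnal sampling schedule: 0, 4, ..., 44 h (12 points)
#' @export
default_circadian_schedule <- function() seq(0, 44, by = 4)

#' Promoter baseline record
#'
#' Upstream DNA written 5'->3', ending at the base immediately before the
#' TSS; used as the baseline that fills unoccupied canvas positions.
#'
#' @param gene_id locus identifier.
#' @param sequence DNA text over A/C/G/T.
#' @return An object of class `promoter_record`.
#' @export
promoter_record <- function(gene_id, sequence) {
  sequence <- toupper(sequence)
  if (!is_dna(sequence))
    validation_error(sprintf("promoter sequence for %s contains non-ACGT characters",
                             gene_id))
  structure(
    list(gene_id = as.character(gene_id), sequence = sequence,
         length = nchar(sequence)),
    class = "promoter_record"
  )
}

#' Validate a table of motif annotations against a dataset profile
#'
#' Each row is one motif occurrence: the annotated gene, the motif sequence,
#' and the offset of the motif's center base pair from the TSS (negative
#' upstream; a half-integer for even-length motifs). The motif footprint must
#' lie entirely within `[-region_width, -1]`.
#'
#' @param df data.frame with columns `gene_id`, `motif_seq`, `center`.
#' @param profile a [motif_profile()].
#' @return the validated data.frame with a `dataset` column and the profile
#'   attached as attribute `"profile"`; class `motif_table`.
#' @export
motif_table <- function(df, profile) {
  stopifnot(inherits(profile, "motif_profile"))
  need <- c("gene_id", "motif_seq", "center")
  if (!all(need %in% names(df)))
    validation_error(paste("motif table needs columns:", paste(need, collapse = ", ")))
  df$gene_id <- as.character(df$gene_id)
  df$motif_seq <- toupper(as.character(df$motif_seq))
  df$center <- as.numeric(df$center)
  k <- profile$motif_length
  for (i in seq_len(nrow(df))) {
    seq_i <- df$motif_seq[i]
    c_i <- df$center[i]
    if (nchar(seq_i) != k)
      validation_error(sprintf(
        "row %d: motif %s has length %d, profile '%s' requires %d",
        i, seq_i, nchar(seq_i), profile$name, k))
    if (!is_dna(seq_i))
      validation_error(sprintf("row %d: motif %s contains non-ACGT characters", i, seq_i))
    if (!center_has_legal_parity(c_i, k))
      validation_error(sprintf(
        "row %d: center %s has wrong parity for a %d-bp motif (must be %s)",
        i, format(c_i), k, if (k %% 2 == 1) "an integer" else "a half-integer"))
    if (motif_start(c_i, k) < -profile$region_width || motif_end(c_i, k) > -1)
      validation_error(sprintf(
        "row %d: footprint %g..%g outside annotated region [-%d, -1]",
        i, motif_start(c_i, k), motif_end(c_i, k), profile$region_width))
  }
  df$dataset <- rep(profile$name, nrow(df))
  rownames(df) <- NULL
  attr(df, "profile") <- profile
  class(df) <- c("motif_table", "data.frame")
  df
}

# ---- tabular I/O -----------------------------------------------------------
# Dialect: delimiter auto-detected (tab or comma); replicate columns named
# condition.1, condition.2, ...; half-integer centers serialized as decimals;
# '#'-prefixed metadata lines before the header.

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

read_table_lines <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 1L) parse_error(sprintf("%s: no header row", path))
  list(meta = meta, body = body)
}

split_fields <- function(lines, sep, path, offset = 0L) {
  parts <- strsplit(lines, sep, fixed = TRUE)
  n <- lengths(parts)
  if (length(unique(n)) > 1L) {
    bad <- which(n != n[1])[1]
    parse_error(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                        path, bad + offset, n[bad], n[1]))
  }
  parts
}

as_numeric_checked <- function(x, path, what) {
  suppressWarnings(v <- as.numeric(x))
  if (anyNA(v)) {
    bad <- x[is.na(v)][1]
    parse_error(sprintf("%s: non-numeric %s value '%s'", path, what, bad))
  }
  v
}

#' Read / write an expression table
#'
#' Delimited text (tab or comma, auto-detected): first column `gene_id`,
#' remaining columns `condition.replicate` (e.g. `Leaf.1`, `Leaf.2`).
#' An optional `#groups` metadata line carries the tissue-category group of
#' each condition. Scale is stated explicitly, never inferred.
#'
#' @param path file path.
#' @param scale `"log2"` or `"linear"`.
#' @return [read_expression_table()] returns an [expression_matrix()].
#' @export
read_expression_table <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  x <- read_table_lines(path)
  sep <- detect_sep(x$body[1])
  parts <- split_fields(x$body, sep, path, offset = length(x$meta))
  header <- parts[[1]]
  if (length(header) < 2L) parse_error(sprintf("%s: no data columns", path))
  labels <- header[-1]
  cond <- sub("\\.[0-9]+$", "", labels)
  rep_idx <- suppressWarnings(as.integer(sub("^.*\\.", "", labels)))
  if (anyNA(rep_idx))
    parse_error(sprintf("%s: column labels must look like condition.replicate", path))
  conditions <- unique(cond)
  n_rep <- length(labels) / length(conditions)
  if (n_rep != floor(n_rep) ||
      !identical(labels, paste(rep(conditions, each = n_rep),
                               rep(seq_len(n_rep), length(conditions)), sep = ".")))
    parse_error(sprintf("%s: replicate columns must be grouped per condition", path))
  rows <- parts[-1]
  gene_ids <- vapply(rows, `[`, "", 1L)
  if (anyDuplicated(gene_ids))
    validation_error(sprintf("%s: duplicate gene ID %s", path,
                             gene_ids[duplicated(gene_ids)][1]))
  vals <- t(vapply(rows, function(r) as_numeric_checked(r[-1], path, "expression"),
                   numeric(length(labels))))
  arr <- array(NA_real_, dim = c(length(gene_ids), length(conditions), n_rep))
  for (j in seq_along(conditions)) {
    cols <- (j - 1L) * n_rep + seq_len(n_rep)
    arr[, j, ] <- vals[, cols, drop = FALSE]
  }
  groups <- NULL
  gline <- grep("^#groups", x$meta, value = TRUE)
  if (length(gline)) {
    kv <- strsplit(strsplit(sub("^#groups[ \t]*", "", gline[1]), ";")[[1]], "=")
    gmap <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    groups <- unname(gmap[conditions])
  }
  expression_matrix(gene_ids, conditions, arr, scale = scale, groups = groups)
}

#' @rdname read_expression_table
#' @param x an [expression_matrix()].
#' @param sep field delimiter, tab or comma.
#' @export
write_expression_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "expression_matrix"))
  n_rep <- n_replicates(x)
  header <- c("gene_id", paste(rep(x$conditions, each = n_rep),
                               rep(seq_len(n_rep), length(x$conditions)), sep = "."))
  flat <- matrix(NA_real_, nrow = length(x$gene_ids), ncol = length(header) - 1L)
  for (j in seq_along(x$conditions)) {
    cols <- (j - 1L) * n_rep + seq_len(n_rep)
    flat[, cols] <- x$values[, j, ]
  }
  lines <- c(
    paste0("#groups\t", paste(x$conditions, x$groups, sep = "=", collapse = ";")),
    paste(header, collapse = sep),
    vapply(seq_along(x$gene_ids), function(i)
      paste(c(x$gene_ids[i], format(flat[i, ], trim = TRUE, digits = 15)),
            collapse = sep), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a motif annotation table
#'
#' Delimited text with columns `gene_id`, `motif_seq`, `center`; every row is
#' validated against the dataset profile (motif length, center parity,
#' footprint within the annotated region). Rows keep file order.
#'
#' @param path file path.
#' @param profile a [motif_profile()].
#' @return [read_motif_table()] returns a [motif_table()].
#' @export
read_motif_table <- function(path, profile) {
  x <- read_table_lines(path)
  sep <- detect_sep(x$body[1])
  parts <- split_fields(x$body, sep, path, offset = length(x$meta))
  header <- parts[[1]]
  need <- c("gene_id", "motif_seq", "center")
  if (!all(need %in% header))
    parse_error(sprintf("%s: header must contain %s", path, paste(need, collapse = ", ")))
  rows <- parts[-1]
  get <- function(col) vapply(rows, `[`, "", match(col, header))
  df <- data.frame(
    gene_id = get("gene_id"),
    motif_seq = get("motif_seq"),
    center = if (length(rows)) as_numeric_checked(get("center"), path, "center") else numeric(0),
    stringsAsFactors = FALSE
  )
  motif_table(df, profile)
}

#' @rdname read_motif_table
#' @param motifs a [motif_table()].
#' @param sep field delimiter.
#' @export
write_motif_table <- function(motifs, path, sep = "\t") {
  lines <- c(
    paste(c("gene_id", "motif_seq", "center"), collapse = sep),
    vapply(seq_len(nrow(motifs)), function(i)
      paste(c(motifs$gene_id[i], motifs$motif_seq[i],
              format(motifs$center[i], trim = TRUE, digits = 15)), collapse = sep), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a diurnal series table
#'
#' One row per gene; columns `gene_id`, then `t<h>` for each sampling time in
#' hours. A `#condition` metadata line carries the growth-condition tag.
#'
#' @param path file path.
#' @return [read_circadian_table()] returns a list of [circadian_series()].
#' @export
read_circadian_table <- function(path) {
  x <- read_table_lines(path)
  sep <- detect_sep(x$body[1])
  parts <- split_fields(x$body, sep, path, offset = length(x$meta))
  header <- parts[[1]]
  if (header[1] != "gene_id" || length(header) < 4L)
    parse_error(sprintf("%s: header must be gene_id, t0, t4, ...", path))
  times <- as_numeric_checked(sub("^t", "", header[-1]), path, "time")
  cond <- "LL"
  cline <- grep("^#condition", x$meta, value = TRUE)
  if (length(cline)) cond <- sub("^#condition[ \t]*", "", cline[1])
  lapply(parts[-1], function(r)
    circadian_series(r[1], times, as_numeric_checked(r[-1], path, "expression"),
                     condition_label = cond))
}

#' @rdname read_circadian_table
#' @param series list of [circadian_series()] sharing one schedule.
#' @param sep field delimiter.
#' @export
write_circadian_table <- function(series, path, sep = "\t") {
  times <- series[[1]]$times
  lines <- c(
    paste0("#condition\t", series[[1]]$condition_label),
    paste(c("gene_id", paste0("t", format(times, trim = TRUE))), collapse = sep),
    vapply(series, function(s)
      paste(c(s$gene_id, format(s$values, trim = TRUE, digits = 15)), collapse = sep), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write promoter baseline sequences as FASTA
#'
#' Record IDs are gene locus IDs; sequences are upstream DNA ending at the
#' base immediately before the TSS.
#'
#' @param path FASTA file path.
#' @return [read_promoter_fasta()] returns a named list of [promoter_record()].
#' @export
read_promoter_fasta <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  recs <- lapply(seq_along(set), function(i)
    promoter_record(names(set)[i], as.character(set[[i]])))
  stats::setNames(recs, names(set))
}

#' @rdname read_promoter_fasta
#' @param records list of [promoter_record()].
#' @export
write_promoter_fasta <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, function(r) r$sequence, ""))
  names(seqs) <- vapply(records, function(r) r$gene_id, "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Join expression rows with motif annotations by gene locus ID
#'
#' The expression matrix drives the key set: the result holds exactly the
#' genes of `expr`, each mapped to its expression values and its (possibly
#' empty) annotation rows. Genes without motifs are a legal state -- the
#' mining fallback rule depends on them.
#'
#' @param expr an [expression_matrix()], or a character vector of gene IDs.
#' @param motifs a [motif_table()] (or plain data.frame with the same columns).
#' @return named list: per gene, `list(expression = , motifs = )`.
#' @export
join_by_gene <- function(expr, motifs) {
  gene_ids <- if (inherits(expr, "expression_matrix")) expr$gene_ids else as.character(expr)
  by_gene <- split(seq_len(nrow(motifs)), motifs$gene_id)
  out <- lapply(seq_along(gene_ids), function(i) {
    g <- gene_ids[i]
    idx <- by_gene[[g]]
    list(
      expression = if (inherits(expr, "expression_matrix")) expr$values[i, , ] else NULL,
      motifs = if (is.null(idx)) motifs[0, , drop = FALSE]
               else motifs[idx, , drop = FALSE]
    )
  })
  stats::setNames(out, gene_ids)
}
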