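# The design canvas: placement geometry, conflict arbitration, baseline
# fill, change tracking, suggestion heuristic, export and replay.

test_that("a new design is an empty canvas with a creation log entry", {
  d <- new_design(500)
  expect_equal(canvas_string(d), strrep("-", 500))
  expect_equal(nrow(d$placed), 0L)
  expect_equal(d$log[[1]]$op, "new_design")
  expect_equal(d$log[[1]]$params$length, 500L)
  bl <- promoter_record("AT5G23240", strrep("ACGT", 125))
  db <- new_design(500, baseline = bl)
  expect_equal(db$log[[1]]$params$baseline_id, "AT5G23240")
  short <- promoter_record("G1", strrep("A", 499))
  expect_error(new_design(500, baseline = short), class = "validation_error")
})

test_that("placement writes the exact footprint of the center", {
  d <- place_motif(new_design(500), "ATTGCCAC", -204.5)
  filled <- which(d$canvas != "-")
  expect_equal(filled, 293:300)                       # positions -208..-201
  expect_equal(paste(d$canvas[293:300], collapse = ""), "ATTGCCAC")
  # parity and range violations
  expect_error(place_motif(new_design(500), "ATTGCCAC", -204),
               "parity", class = "validation_error")
  expect_error(place_motif(new_design(500), "ATTGCCA", -204.5),
               "parity", class = "validation_error")
  expect_error(place_motif(new_design(200), "ATTGCCAC", -204.5),
               "outside", class = "validation_error")
  # footprint reaching position 0 is off-canvas
  expect_error(place_motif(new_design(500), "ATTGCCAC", -3.5),
               "outside", class = "validation_error")
})

test_that("overlap conflicts are resolved per policy", {
  d <- place_motif(new_design(100), "AAAAAAAA", -50.5)
  # keep_existing: second placement cannot change occupied bases
  kept <- place_motif(d, "CCCCCCCC", -50.5, policy = "keep_existing")
  expect_equal(canvas_string(kept), canvas_string(d))
  # idempotence of re-placing the same motif
  again <- place_motif(d, "AAAAAAAA", -50.5, policy = "keep_existing")
  expect_equal(canvas_string(again), canvas_string(d))
  # use_new overwrites the overlap
  new <- place_motif(d, "CCCCCCCC", -46.5, policy = "use_new")
  expect_equal(paste(new$canvas[which(new$canvas != "-")], collapse = ""),
               "AAAACCCCCCCC")
  # fail raises before any mutation, naming the overlapping interval
  err <- expect_error(place_motif(d, "CCCCCCCC", -46.5, policy = "fail"),
                      class = "conflict_error")
  expect_match(conditionMessage(err), "-50")
  # on an empty canvas all three policies agree
  for (p in c("fail", "keep_existing", "use_new"))
    expect_equal(canvas_string(place_motif(new_design(60), "ACGTACGT",
                                           -30.5, policy = p)),
                 canvas_string(place_motif(new_design(60), "ACGTACGT", -30.5)))
})

test_that("natural placement carries annotation provenance", {
  ann <- tiny_motifs()[1, , drop = FALSE]   # ATTGCCAC at -204.5 from G1
  d <- place_at_natural(new_design(500), ann)
  expect_equal(which(d$canvas != "-"), 293:300)
  expect_equal(d$placed$source_gene, "G1")
  expect_equal(d$placed$source_dataset, "wordfreq")
  expect_equal(d$log[[2]]$params$source_dataset, "wordfreq")
  # a 7-mer at center -100 occupies -103..-97
  ann7 <- motif_table(data.frame(gene_id = "G9", motif_seq = "ACGTACG",
                                 center = -100), profile_coexpression())
  d7 <- place_at_natural(new_design(500), ann7[1, , drop = FALSE])
  expect_equal(which(d7$canvas != "-"),
               (-103:-97) + 501)
})

test_that("collect_all_motifs places in table order and aborts atomically", {
  anns <- motif_table(data.frame(
    gene_id = "G1",
    motif_seq = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
    center = c(-100.5, -50.5, -20.5)), profile_wordfreq())
  d <- collect_all_motifs(new_design(200), anns)
  expect_equal(nrow(d$placed), 3L)
  expect_equal(sum(d$canvas != "-"), 24L)
  expect_length(d$log, 2L)   # creation + one summarizing entry
  # overlapping pair: later row wins under use_new
  ov <- motif_table(data.frame(
    gene_id = "G1", motif_seq = c("AAAAAAAA", "CCCCCCCC"),
    center = c(-50.5, -46.5)), profile_wordfreq())
  dov <- collect_all_motifs(new_design(200), ov, policy = "use_new")
  expect_equal(paste(dov$canvas[dov$canvas != "-"], collapse = ""),
               "AAAACCCCCCCC")
  # atomic abort under fail: canvas identical to input
  base <- place_motif(new_design(200), "TTTTTTTT", -47.5)
  expect_error(collect_all_motifs(base, ov, policy = "fail"),
               class = "conflict_error")
  expect_equal(sum(base$canvas != "-"), 8L)
})

test_that("stacking lays copies upstream at pitch k + spacing", {
  d <- stack_motif(new_design(200), "ACGTACGT", -100.5, n_extra = 2, spacing = 5)
  expect_equal(d$placed$center, c(-100.5, -113.5, -126.5))   # pitch 8+5 = 13
  # exactly `spacing` empty positions between adjacent footprints
  occ <- which(d$canvas != "-")
  runs <- rle(seq_len(200) %in% occ)
  expect_equal(runs$lengths[runs$values == FALSE & seq_along(runs$values) > 1 &
                              seq_along(runs$values) < length(runs$values)],
               c(5, 5))
  # n_extra = 0 degenerates to place_motif
  expect_equal(canvas_string(stack_motif(new_design(60), "ACGTACGT", -30.5, 0, 5)),
               canvas_string(place_motif(new_design(60), "ACGTACGT", -30.5)))
  # boundary: the error appears exactly when the most-upstream footprint
  # start would cross -L (anchor -40.5, 8-mer, spacing 5 on a 200-bp canvas:
  # copy i starts at -44 - 13 i; i = 12 still fits at -200, i = 13 violates)
  expect_silent(stack_motif(new_design(200), "ACGTACGT", -40.5, 12, 5))
  expect_error(stack_motif(new_design(200), "ACGTACGT", -40.5, 13, 5),
               "outside", class = "validation_error")
})

test_that("random stacks agree with a brute-force layout oracle", {
  withr::with_seed(31, {
    for (trial in 1:25) {
      k <- sample(4:10, 1)
      n <- sample(0:6, 1)
      s <- sample(0:8, 1)
      L <- 400L
      motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
      start0 <- -sample(60:90, 1)
      center <- start0 + (k - 1) / 2
      d <- stack_motif(new_design(L), motif, center, n, s)
      # oracle: write copies by hand at starts start0 - i*(k+s)
      oracle <- rep("-", L)
      for (i in 0:n) {
        st <- start0 - i * (k + s)
        oracle[(st:(st + k - 1)) + L + 1] <- strsplit(motif, "")[[1]]
      }
      expect_equal(canvas_string(d), paste(oracle, collapse = ""))
      expect_equal(nchar(canvas_string(d)), L)   # canvas length invariant
    }
  })
})

test_that("baseline fill is exact, idempotent, and leaves motifs untouched", {
  bl <- generate_promoter_fixture("G1", length = 200, seed = 5)$G1
  # empty canvas + fill -> equals baseline
  d0 <- fill_baseline(new_design(200, baseline = bl))
  expect_equal(canvas_string(d0), bl$sequence)
  # one 8-mer placed, then fill: exactly L - 8 positions from baseline
  d <- place_motif(new_design(200, baseline = bl), "ATTGCCAC", -100.5)
  filled <- fill_baseline(d)
  bases <- strsplit(bl$sequence, "")[[1]]
  from_baseline <- sum(filled$canvas == bases & d$canvas == "-")
  expect_equal(from_baseline, 200 - 8)
  expect_equal(paste(filled$canvas[97:104], collapse = ""), "ATTGCCAC")
  # idempotent
  expect_equal(canvas_string(fill_baseline(filled)), canvas_string(filled))
  expect_error(fill_baseline(new_design(10)), class = "validation_error")
})

test_that("diff_from_baseline reports written positions that differ", {
  bl <- promoter_record("G1", strrep("A", 100))
  # motif identical to the baseline substring: empty diff
  d_same <- place_motif(new_design(100, baseline = bl), "AAAAAAAA", -50.5)
  expect_length(diff_from_baseline(d_same), 0L)
  # motif differing at 3 of 8 bases
  d3 <- place_motif(new_design(100, baseline = bl), "AACAACTA", -50.5)
  expect_length(diff_from_baseline(d3), 3L)
  # fill cannot alter the diff
  expect_equal(diff_from_baseline(fill_baseline(d3)), diff_from_baseline(d3))
  expect_error(diff_from_baseline(new_design(10)), class = "validation_error")
})

test_that("suggest_position uses the mode, ties to the TSS, else closest fit", {
  anns <- motif_table(data.frame(
    gene_id = sprintf("g%d", 1:4),
    motif_seq = rep("ACGTACG", 4),
    center = c(-100, -100, -100, -150)), profile_coexpression())
  expect_equal(suggest_position("ACGTACG", anns), -100)
  tie <- motif_table(data.frame(
    gene_id = sprintf("g%d", 1:4), motif_seq = rep("ACGTACG", 4),
    center = c(-100, -100, -50, -50)), profile_coexpression())
  expect_equal(suggest_position("ACGTACG", tie), -50)
  # unseen 7-mer: closest in-range center is -4 (footprint -7..-1)
  expect_equal(suggest_position("TTTTTTT", anns), -4)
  expect_equal(suggest_position("TTTTTTTT", anns), -4.5)
})

test_that("export writes FASTA/GFF3/log and the log replays byte-identically", {
  dir <- withr::local_tempdir()
  bl <- generate_promoter_fixture("AT5G23240", length = 500, seed = 6)$AT5G23240
  d <- new_design(500, baseline = bl, name = "synth1")
  d <- stack_motif(d, "ATTGCCAC", -204.5, n_extra = 10, spacing = 5,
                   source_gene = "AT5G23240", source_dataset = "wordfreq")
  d <- fill_baseline(d)
  paths <- export_design(d, "synth1", dir)
  # GFF3 coordinates: footprint -208..-201 maps to 293..300 on a 500-bp contig
  gff <- readLines(paths$gff3)
  feat <- gff[!startsWith(gff, "#")]
  expect_length(feat, 11L)
  f1 <- strsplit(feat[1], "\t")[[1]]
  expect_equal(as.integer(f1[4:5]), c(293L, 300L))
  expect_equal(f1[3], "TF_binding_site")
  expect_equal(f1[7], "+")
  expect_match(f1[9], "motif_seq=ATTGCCAC")
  expect_match(f1[9], "center=-204.5")
  # replay -> re-export -> byte-identical FASTA; placed list and diff match
  d2 <- replay_design(paths$log)
  paths2 <- export_design(d2, "synth1_replay", dir)
  expect_identical(readLines(paths2$fasta)[-1], readLines(paths$fasta)[-1])
  expect_equal(d2$placed, d$placed)
  expect_equal(diff_from_baseline(d2), diff_from_baseline(d))
  # unfilled positions export as N with a warning
  du <- place_motif(new_design(20), "ACGTACGT", -10.5)
  expect_warning(pu <- export_design(du, "unfilled", dir), "N")
  expect_match(paste(readLines(pu$fasta)[-1], collapse = ""), "N")
})

test_that("canvas length is invariant under every operation", {
  bl <- generate_promoter_fixture("G1", length = 120, seed = 2)$G1
  d <- new_design(120, baseline = bl)
  for (step in list(
    function(x) place_motif(x, "ACGTACGT", -60.5),
    function(x) collect_all_motifs(x, motif_table(data.frame(
      gene_id = "G1", motif_seq = "AAAATTTT", center = -20.5),
      profile_wordfreq())),
    function(x) stack_motif(x, "GGGGCCCC", -80.5, 2, 3, policy = "use_new"),
    fill_baseline)) {
    d <- step(d)
    expect_length(d$canvas, 120L)
  }
})
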