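test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_transcripts = 1, length_mean = 100,
                          length_sd = 0, n_withheld = 0, novel_rate = 0,
                          de_spec = list(), seed = 7)
  s1 <- generate_transcriptome(cfg)
  s2 <- generate_transcriptome(cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$truth$expression, s2$truth$expression)

  cfg2 <- small_config(seed = 12)
  a <- simulate_dge_library(generate_transcriptome(cfg2), "X1")
  b <- simulate_dge_library(generate_transcriptome(cfg2), "X1")
  expect_identical(a$counts, b$counts)
})

test_that("impossible length constraints are rejected, AT-only flagged tagless", {
  expect_error(synthetic_config(length_mean = 15), "21")
  cfg <- synthetic_config(n_transcripts = 5, gc_fraction = 0,
                          n_withheld = 0, novel_rate = 0,
                          de_spec = list(), seed = 1)
  st <- generate_transcriptome(cfg)
  expect_true(all(strsplit(paste(as.character(st$sequences),
                                 collapse = ""), "")[[1]] %in% c("A", "T")))
  expect_setequal(st$truth$tagless_ids, names(st$sequences))
})

test_that("most generated transcripts carry a valid 3'-most tag site", {
  cfg <- synthetic_config(n_transcripts = 50, length_mean = 500,
                          n_withheld = 0, novel_rate = 0,
                          de_spec = list(), seed = 2)
  st <- generate_transcriptome(cfg)
  n_with_site <- sum(vapply(as.character(st$sequences), function(s)
    length(oracle_forward_tags(s)) > 0, logical(1)))
  expect_gte(n_with_site, 48)
  expect_setequal(names(st$sequences)[vapply(as.character(st$sequences),
    function(s) length(oracle_forward_tags(s)) == 0, logical(1))],
    st$truth$tagless_ids)
})

test_that("expression columns are cpm-normalized and DE folds are planted", {
  cfg <- synthetic_config(n_transcripts = 200, de_spec = list(),
                          n_withheld = 0, novel_rate = 0, seed = 3)
  E <- simulate_expression(cfg)
  expect_equal(unname(colSums(E)), rep(1e6, 3), tolerance = 1e-9)
  ## no DE spec: all columns identical after renormalization
  expect_equal(E[, "X1"], E[, "X2"])
  expect_equal(E[, "X1"], E[, "Xin"])

  cfg8 <- synthetic_config(n_transcripts = 200,
                           de_spec = list(list(sample = "X1", n = 1,
                                               fold = 8)),
                           n_withheld = 0, novel_rate = 0, seed = 3)
  E8 <- simulate_expression(cfg8)
  de <- attr(E8, "de_labels")
  expect_equal(nrow(de), 1)
  ratio <- E8[de$transcript_id, "X1"] / E8[de$transcript_id, "Xin"]
  expect_lt(abs(ratio - 8) / 8, 0.05)
  ## overlapping planting rejected
  expect_error(simulate_expression(
    synthetic_config(n_transcripts = 3, n_withheld = 0, novel_rate = 0,
                     de_spec = list(list(sample = "X1", n = 3, fold = 2),
                                    list(sample = "X2", n = 3, fold = 2)))),
    "de_spec")
})

test_that("a clean single-transcript library collapses to one tag", {
  cfg <- synthetic_config(n_transcripts = 1, length_mean = 300,
                          library_depths = c(X1 = 1000L),
                          antisense_rate = 0, error_rate = 0,
                          novel_rate = 0, n_withheld = 0,
                          de_spec = list(), x2_mixture = NULL, seed = 5)
  st <- generate_transcriptome(cfg)
  expect_length(st$truth$tagless_ids, 0)
  lib <- simulate_dge_library(st, "X1")
  expect_length(lib$counts, 1)
  expect_equal(unname(lib$counts), 1000L)
  expect_equal(names(lib$counts),
               unname(st$truth$canonical_tags[1]))
})

test_that("error_rate = 1 puts every emitted tag at Hamming distance 1", {
  cfg <- synthetic_config(n_transcripts = 1, length_mean = 300,
                          library_depths = c(X1 = 500L),
                          antisense_rate = 0, error_rate = 1,
                          novel_rate = 0, n_withheld = 0,
                          de_spec = list(), x2_mixture = NULL, seed = 5)
  st <- generate_transcriptome(cfg)
  canon <- unname(st$truth$canonical_tags[1])
  lib <- simulate_dge_library(st, "X1")
  hd <- vapply(names(lib$counts), function(tg)
    sum(charToRaw(tg) != charToRaw(canon)), integer(1))
  expect_true(all(hd == 1))
  expect_equal(sum(lib$counts), 500L)
})

test_that("library counts follow the multinomial expectation", {
  cfg <- synthetic_config(n_transcripts = 200,
                          library_depths = c(X1 = 1000000L),
                          antisense_rate = 0, error_rate = 0,
                          novel_rate = 0, n_withheld = 0,
                          de_spec = list(), x2_mixture = NULL, seed = 42)
  st <- generate_transcriptome(cfg)
  lib <- simulate_dge_library(st, "X1", seed = 42)
  counts <- attr(lib, "transcript_counts")
  eligible <- setdiff(names(st$sequences), st$truth$tagless_ids)
  p <- st$truth$expression[eligible, "X1"]
  p <- p / sum(p)
  mu <- 1e6 * p
  sd3 <- 3 * sqrt(1e6 * p * (1 - p))
  within <- abs(counts[eligible] - mu) <= sd3
  expect_gte(mean(within), 0.95)
  expect_equal(sum(lib$counts), 1000000L)
})

test_that("the genome embeds transcripts verbatim with correct placements", {
  ## single transcript, no spacers: the contig is the transcript (either
  ## orientation) and the placement covers it entirely
  cfg <- synthetic_config(n_transcripts = 1, length_mean = 200,
                          n_withheld = 0, novel_rate = 0,
                          de_spec = list(), seed = 6)
  st <- generate_transcriptome(cfg)
  gen <- generate_genome(st, spacer_mean = 0, seed = 6)
  g <- as.character(gen$genome)[[1]]
  tx <- as.character(st$sequences)[[1]]
  expect_true(g == tx || g == rc(tx))
  expect_equal(gen$placements$start, 1L)
  expect_equal(gen$placements$end, nchar(tx))

  ## every placement is verbatim on its recorded strand
  st2 <- small_study()
  gen2 <- generate_genome(st2, seed = 9)
  seqs <- as.character(st2$sequences)
  gs <- as.character(gen2$genome)
  for (i in seq_len(nrow(gen2$placements))) {
    pl <- gen2$placements[i, ]
    embedded <- substr(gs[[pl$contig]], pl$start, pl$end)
    truthseq <- seqs[[pl$transcript_id]]
    if (pl$strand == "+") expect_equal(embedded, truthseq)
    else expect_equal(embedded, rc(truthseq))
  }
  ## reverse-strand placements are not found verbatim on the forward strand
  minus <- gen2$placements[gen2$placements$strand == "-", ][1, ]
  expect_false(grepl(seqs[[minus$transcript_id]], gs[[minus$contig]],
                     fixed = TRUE))
  expect_true(grepl(rc(seqs[[minus$transcript_id]]), gs[[minus$contig]],
                    fixed = TRUE))
})

test_that("column sums, withheld exclusion and depth conservation hold", {
  st <- small_study()
  tr <- st$truth
  expect_equal(unname(colSums(tr$expression)), rep(1e6, 3),
               tolerance = 1e-9)
  expect_length(intersect(tr$withheld_ids,
                          names(reference_sequences(st))), 0)
  for (s in c("X1", "X2", "Xin")) {
    lib <- simulate_dge_library(st, s)
    expect_equal(sum(lib$counts),
                 unname(tr$config$library_depths[[s]]))
  }
})
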