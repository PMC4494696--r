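test_that("exact mapping classifies canonical tags and the 3'-most rule demotes", {
  ## one transcript with two tag sites, at positions 11 and 52
  tx <- paste0(strrep("A", 10), "CATG", strrep("G", 37),
               "CATG", strrep("T", 17), "AAAA")
  ix <- build_tag_index(c(tx1 = tx), "txp", strand_mode = "forward")
  lo <- paste0("CATG", substr(strrep("G", 37), 1, 17))
  hi <- paste0("CATG", strrep("T", 17))
  lib <- tag_library(setNames(c(5L, 7L), c(lo, hi)))
  mp <- map_tags_exact(lib, ix)
  rec <- as.data.frame(mp$records)
  expect_equal(rec$status[rec$tag == hi], "one_match")
  expect_equal(rec$sense[rec$tag == hi], "sense")
  ## the tag at the lower position loses its only hit -> orphan
  expect_equal(rec$status[rec$tag == lo], "orphan")
  ## without resolution both map
  mp2 <- map_tags_exact(lib, ix, resolve_3prime = FALSE)
  expect_true(all(mp2$records$status == "one_match"))
})

test_that("a zero-noise synthetic library maps fully, all sense", {
  cfg <- small_config(seed = 8, antisense_rate = 0, error_rate = 0,
                      novel_rate = 0, n_withheld = 0)
  st <- generate_transcriptome(cfg)
  lib <- simulate_dge_library(st, "X1")
  ix <- build_tag_index(reference_sequences(st), "txp",
                        strand_mode = "forward", polyA_pad = TRUE)
  mp <- map_tags_exact(lib, ix)
  expect_equal(sum(mp$records$status == "orphan"), 0)
  expect_true(all(mp$records$sense == "sense"))
  ## truth linkage: every emitted tag is the canonical tag of >= 1 transcript
  expect_true(all(names(lib$counts) %in% st$truth$canonical_tags))
})

test_that("mapping summary arithmetic and recount oracle agree", {
  ## three tags hitting 1, 2 and 0 references
  t1 <- paste0("CATG", strrep("A", 17))
  t2 <- paste0("CATG", strrep("C", 17))
  t3 <- paste0("CATG", strrep("G", 17))
  refs <- c(r1 = paste0("TT", t1, "TT"),
            r2 = paste0("TT", t2, "TT"),
            r3 = paste0("GG", t2, "GG"))
  ix <- build_tag_index(refs, "toy", strand_mode = "forward")
  lib <- tag_library(setNames(c(5L, 5L, 5L), c(t1, t2, t3)))
  s <- summarize_mapping(map_tags_exact(lib, ix))
  expect_equal(s$mapped, 2)
  expect_equal(s$one_match, 1)
  expect_equal(s$multi_match, 1)
  expect_equal(s$orphan, 1)
  expect_equal(s$contigs_per_tag, 1.5)
  expect_false(s$degenerate)

  ## all-orphan library: degenerate contigs-per-tag reported as 0
  lib0 <- tag_library(setNames(5L, paste0("CATG", strrep("T", 17))))
  s0 <- summarize_mapping(map_tags_exact(lib0, ix))
  expect_equal(s0$contigs_per_tag, 0)
  expect_true(s0$degenerate)

  ## synthetic run: summary equals an independent tally over raw records
  st <- small_study()
  slib <- filter_by_cutoff(simulate_dge_library(st, "X1"), 5)
  six <- build_tag_index(reference_sequences(st), "txp")
  mp <- map_tags_exact(slib, six)
  ss <- summarize_mapping(mp)
  rec <- as.data.frame(mp$records)
  expect_equal(ss$mapped, sum(rec$n_hits > 0))
  expect_equal(ss$one_match, sum(rec$n_hits == 1))
  expect_equal(ss$multi_match, sum(rec$n_hits > 1))
  expect_equal(ss$orphan, sum(rec$n_hits == 0))
  expect_equal(ss$mapped + ss$orphan, nrow(rec))
  expect_equal(ss$contigs_per_tag, mean(rec$n_refs[rec$n_hits > 0]))
})

test_that("reference overlap counts subsets by set algebra", {
  t1 <- paste0("CATG", strrep("A", 17))
  t2 <- paste0("CATG", strrep("C", 17))
  t3 <- paste0("CATG", strrep("G", 17))
  ixA <- build_tag_index(c(a1 = paste0("T", t1, "T", t3, "T")), "A",
                         strand_mode = "forward")
  ixB <- build_tag_index(c(b1 = paste0("T", t2, "T", t3, "T")), "B",
                         strand_mode = "forward")
  lib <- tag_library(setNames(c(5L, 5L, 5L), c(t1, t2, t3)))
  ov <- reference_overlap(list(A = map_tags_exact(lib, ixA,
                                                  resolve_3prime = FALSE),
                               B = map_tags_exact(lib, ixB,
                                                  resolve_3prime = FALSE)))
  expect_setequal(ov$subset, c("A", "B", "A+B"))
  expect_true(all(abs(ov$percent - 100 / 3) < 1e-9))
  ## the tag in both sets contributes only to the intersection subset
  expect_equal(ov$count[ov$subset == "A+B"], 1)

  ## three-reference synthetic scenario vs plain set algebra
  st <- small_study()
  seqs <- as.character(reference_sequences(st))
  sets <- list(full = seqs,
               most = seqs[seq_len(round(0.8 * length(seqs)))],
               half = seqs[seq_len(round(0.5 * length(seqs)))])
  lib2 <- filter_by_cutoff(simulate_dge_library(st, "X1"), 5)
  mps <- lapply(names(sets), function(nm)
    map_tags_exact(lib2, build_tag_index(sets[[nm]], nm)))
  names(mps) <- names(sets)
  ov2 <- reference_overlap(mps)
  mapped_sets <- lapply(mps, function(m)
    m$records$tag[m$records$status != "orphan"])
  oracle <- table(vapply(unique(unlist(mapped_sets)), function(tg)
    paste(names(sets)[vapply(mapped_sets, function(x) tg %in% x,
                             logical(1))], collapse = "+"), ""))
  expect_equal(sort(setNames(ov2$count, ov2$subset)),
               sort(setNames(as.integer(oracle), names(oracle))))
  ## top-k truncation
  expect_equal(nrow(reference_overlap(mps, top_k = 2)), 2)
})

test_that("mismatch mapping finds planted variants at the right distance", {
  set.seed(42)
  genome <- c(g1 = paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                         collapse = ""))
  tag0 <- substr(genome[[1]], 101, 121)
  tag1 <- tag0
  substr(tag1, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                substr(tag0, 5, 5))[1]
  h1 <- map_tags_mismatch(tag1, genome, max_mismatches = 2)
  hit <- h1[h1$fwd_start == 101 & h1$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches, 1L)
  ## three substitutions exceed the limit everywhere
  tag3 <- tag0
  for (p in c(2, 9, 16))
    substr(tag3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(tag0, p, p))[1]
  h3 <- map_tags_mismatch(tag3, genome, max_mismatches = 2)
  expect_false(any(h3$fwd_start == 101 & h3$strand == "+"))
  ## reverse-strand hits are reported with forward coordinates
  tagr <- rc(substr(genome[[1]], 501, 521))
  hr <- map_tags_mismatch(tagr, genome, max_mismatches = 0)
  expect_true(any(hr$fwd_start == 501 & hr$strand == "-"))
  ## empty genome: everything orphan
  expect_equal(nrow(map_tags_mismatch(tag0, character(0))), 0)
})

test_that("mismatch mapping with 0 mismatches equals exact genome mapping", {
  st <- small_study()
  gen <- generate_genome(st, seed = 5)
  lib <- filter_by_cutoff(simulate_dge_library(st, "X1"), 5)
  tags <- head(names(lib$counts), 40)
  ix <- build_tag_index(gen$genome, "genome")
  mp <- map_tags_exact(tag_library(setNames(rep(5L, length(tags)), tags)),
                       ix, resolve_3prime = FALSE)
  exact_keys <- with(as.data.frame(mp$hits),
                     paste(tag, reference_id, fwd_start, strand))
  mm <- map_tags_mismatch(tags, gen$genome, max_mismatches = 0)
  mm_keys <- with(mm, paste(tag, reference_id, fwd_start, strand))
  expect_setequal(mm_keys, exact_keys)
})

test_that("orphan fraction never increases when reference sets are unioned", {
  st <- small_study()
  lib <- filter_by_cutoff(simulate_dge_library(st, "X1"), 5)
  seqs <- as.character(st$sequences)      # includes withheld transcripts
  half <- build_tag_index(seqs[1:30], "half")
  full <- build_tag_index(seqs, "full")
  orphan_frac <- function(ix)
    summarize_mapping(map_tags_exact(lib, ix))$orphan / length(lib$counts)
  expect_gte(orphan_frac(half), orphan_frac(full))
})
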