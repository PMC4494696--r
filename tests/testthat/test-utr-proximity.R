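test_that("the longest ORF is found on either strand", {
  o <- longest_orf("ATGAAATAA")
  expect_equal(o$strand, "+")
  expect_equal(o$length, 9)
  expect_equal(o$start, 1)
  o2 <- longest_orf(rc("ATGAAATAA"))
  expect_equal(o2$strand, "-")
  expect_equal(o2$length, 9)
  expect_null(longest_orf("CCCCCCCCC"))     # no ATG, no stop
  expect_null(longest_orf("ATGAA"))         # too short
})

test_that("longest ORF equals an exhaustive six-frame scan", {
  brute <- function(seq) {
    L <- nchar(seq)
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else rc(seq)
      for (start in 1:(L - 5)) {
        if (substr(s, start, start + 2) != "ATG") next
        p <- start + 3
        while (p + 2 <= L) {
          if (substr(s, p, p + 2) %in% c("TAA", "TAG", "TGA")) {
            len <- p + 2 - start + 1
            cand <- list(strand = strand,
                         frame = ((start - 1) %% 3) + 1,
                         start = start, length = len)
            better <- is.null(best) || len > best$length ||
              (len == best$length && best$strand == "-" &&
                 strand == "+") ||
              (len == best$length && best$strand == strand &&
                 start < best$start)
            if (better) best <- cand
            break
          }
          p <- p + 3
        }
      }
    }
    best
  }
  set.seed(17)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
    got <- longest_orf(s)
    want <- brute(s)
    expect_equal(got, want)
  }
})

test_that("transcripts are placed on the genome and oriented by ORF", {
  st <- small_study()
  gen <- generate_genome(st, seed = 21)
  pl <- place_transcripts(st$sequences, gen$genome)
  truth <- gen$placements
  got <- pl$placements[match(truth$transcript_id,
                             pl$placements$transcript_id), ]
  expect_equal(got$contig, truth$contig)
  expect_equal(got$start, truth$start)
  expect_equal(got$end, truth$end)
  expect_equal(got$match_strand, truth$strand)
  expect_length(pl$unplaced, 0)
  ## 3'-end coordinate follows the effective strand
  plus <- pl$placements[pl$placements$strand == "+", ]
  minus <- pl$placements[pl$placements$strand == "-", ]
  expect_true(all(plus$three_prime_pos == plus$end))
  expect_true(all(minus$three_prime_pos == minus$start))
  ## a transcript absent from the genome is reported unplaced
  alien <- c(st$sequences,
             Biostrings::DNAStringSet(c(alien = strrep("ACGT", 50))))
  pl2 <- place_transcripts(alien, gen$genome)
  expect_equal(pl2$unplaced, "alien")
})

test_that("external placements round-trip through GFF3 and orient tags", {
  st <- small_study()
  gen <- generate_genome(st, seed = 22)
  path <- tempfile(fileext = ".gff3")
  write_placements_gff3(gen$placements, path)
  back <- read_placements_gff3(path)
  o1 <- gen$placements[order(gen$placements$transcript_id), ]
  o2 <- back[order(back$transcript_id),
             c("transcript_id", "contig", "start", "end", "strand")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
  pl <- place_transcripts(st$sequences, gen$genome,
                          external_placements = back)
  expect_equal(nrow(pl$placements), nrow(gen$placements))
})

test_that("proximity profile bins tags by signed distance to 3' ends", {
  ## hand-built contig: transcript ends at 500, a genome-only tag sits
  ## exactly at the 3' end, another 301 nt downstream, one past the window
  placements <- data.frame(transcript_id = "t1", contig = "c1",
                           start = 1L, end = 500L, strand = "+",
                           three_prime_pos = 500L)
  hits <- data.frame(reference_id = "c1", strand = "+",
                     fwd_start = c(500L, 801L, 1500L, 1501L),
                     fwd_end = c(520L, 821L, 1520L, 1521L))
  prof <- proximity_profile(placements, hits, window = 1000,
                            binwidth = 50)
  expect_equal(prof$n_tags_assigned, 3)   # 1501 - 500 = 1001 > window
  h <- prof$histogram
  expect_equal(h$count[h$bin_start == 0], 1)      # distance 0
  expect_equal(h$count[h$bin_start == 300], 1)    # distance 301
  expect_equal(h$count[h$bin_start == 1000], 1)   # distance 1000, last bin
  expect_equal(sum(h$count), 3)
  ## a mismatched strand is never assigned
  hits_minus <- transform(hits, strand = "-")
  expect_equal(proximity_profile(placements, hits_minus,
                                 window = 1000)$n_tags_assigned, 0)
})

test_that("novel transcripts downstream of annotated ends peak at their offset", {
  set.seed(33)
  spacer <- function(n) paste(sample(c("A", "C", "G"), n, replace = TRUE,
                                     prob = c(.4, .2, .4)), collapse = "")
  annotated <- paste0(spacer(400), "ATG", spacer(60), "TAA",
                      "CATG", spacer(17), spacer(16))
  novel_tag <- paste0("CATG", spacer(17))
  contig <- paste0(annotated, spacer(300), novel_tag, spacer(200))
  placements <- place_transcripts(
    Biostrings::DNAStringSet(c(tx = annotated)),
    c(c1 = contig))$placements
  hits <- map_tags_mismatch(novel_tag, c(c1 = contig),
                            max_mismatches = 0)
  prof <- proximity_profile(placements, hits, window = 1000,
                            binwidth = 50)
  expect_equal(prof$n_tags_assigned, 1)
  mode_bin <- prof$histogram$bin_start[which.max(prof$histogram$count)]
  expect_true(abs(mode_bin - 300) <= 50)
})

test_that("the signed-distance histogram is invariant under genome flip", {
  st <- small_study()
  gen <- generate_genome(st, seed = 25)
  lib <- filter_by_cutoff(simulate_dge_library(st, "X1"), 5)
  tags <- names(lib$counts)
  run_profile <- function(genome) {
    pl <- place_transcripts(reference_sequences(st), genome)
    ix <- build_tag_index(genome, "genome")
    mp <- map_tags_exact(tag_library(
      setNames(rep(5L, length(tags)), tags)), ix,
      resolve_3prime = FALSE)
    proximity_profile(pl$placements, as.data.frame(mp$hits),
                      window = 500, genome = genome)
  }
  fwd <- run_profile(gen$genome)
  flipped <- Biostrings::reverseComplement(gen$genome)
  names(flipped) <- names(gen$genome)
  rev <- run_profile(flipped)
  expect_equal(fwd$histogram$count, rev$histogram$count)
  expect_equal(fwd$fraction_covered, rev$fraction_covered)
  expect_lte(fwd$n_tags_assigned, length(tags))
})
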