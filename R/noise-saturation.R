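## Randomization null models for the occurrence cutoff, and saturation
## curves of distinct mapped tags versus subsampled depth.
##
## Randomized libraries keep the exact count vector (the rank-abundance
## structure) but replace every tag with a fresh random 21-mer drawn
## i.i.d. from the library's empirical base composition; mapping such a
## library measures how many hits arise by sequence chance alone at each
## occurrence cutoff.

#' Randomize a tag library
#'
#' Produces a library that resembles the original in size and nucleotide
#' abundance.  With `preserve_counts = TRUE` (the default) the multiset
#' of counts is preserved exactly -- the sorted count vector is identical
#' -- and each count is reassigned to a new random 21-mer whose bases are
#' drawn i.i.d. from the empirical base frequencies of the original tag
#' sequences; this isolates sequence specificity from the abundance
#' structure.  With `preserve_counts = FALSE` the library is randomized
#' at read level: the same total number of reads is drawn as i.i.d.
#' random 21-mers and re-aggregated, which additionally randomizes tag
#' recurrence and is the null model used by the occurrence-cutoff
#' calibration (random reads essentially never recur, so their counts
#' collapse to singletons).
#'
#' @param library a [tag_library()].
#' @param seed integer seed.
#' @param preserve_counts keep the exact count vector (default) or
#'   randomize at read level.
#' @return a randomized `tag_library`.
#' @export
randomize_library <- function(library, seed = 1L, preserve_counts = TRUE) {
  stopifnot(inherits(library, "tag_library"))
  comp <- base_composition(names(library$counts))
  withr::with_seed(seed, {
    out <- library
    if (preserve_counts) {
      n <- length(library$counts)
      new_tags <- random_kmers(n, 21L, comp)
      ## keep the number of distinct tags: redraw clashes (impossible for
      ## degenerate compositions, where we give up after a few rounds)
      for (iter in seq_len(100)) {
        dup <- duplicated(new_tags)
        if (!any(dup)) break
        if (sum(comp > 0) <= 1) break
        new_tags[dup] <- random_kmers(sum(dup), 21L, comp)
      }
      out$counts <- setNames(unname(library$counts), new_tags)
    } else {
      D <- sum(library$counts)
      reads <- random_kmers(D, 21L, comp)
      agg <- data.table::data.table(tag = reads)[, .N, by = tag]
      out$counts <- setNames(agg$N, agg$tag)
      out$total_reads <- as.numeric(D)
    }
    out$sample_id <- paste0(library$sample_id, "_rand")
    out
  })
}

random_kmers <- function(n, k, comp) {
  cols <- lapply(seq_len(k), function(i)
    sample(DNA_BASES, n, replace = TRUE, prob = comp))
  do.call(paste0, cols)
}

#' Randomize a reference sequence set
#'
#' Same number of sequences and same lengths as the original; bases drawn
#' i.i.d. from the set's pooled empirical composition.
#'
#' @param reference named character vector or [Biostrings::DNAStringSet].
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] of randomized sequences.
#' @export
randomize_reference <- function(reference, seed = 1L) {
  seqs <- as_named_seqs(reference)
  if (length(seqs) == 0) stop("empty reference")
  comp <- base_composition(seqs)
  withr::with_seed(seed, {
    rnd <- vapply(nchar(seqs), function(L)
      paste(sample(DNA_BASES, L, replace = TRUE, prob = comp),
            collapse = ""), character(1))
    names(rnd) <- names(seqs)
    DNAStringSet(rnd)
  })
}

#' Specificity scan over occurrence cutoffs
#'
#' For each cutoff, counts the distinct observed tags with count >= cutoff
#' that map exactly to the index, and the same quantity for read-level
#' randomized replicates of the library.  The randomized replicates
#' measure how much of the library a given cutoff would accept if reads
#' were sequence noise: random reads essentially never recur, so their
#' pass-counts (`random_candidates_mean`) and hit counts collapse between
#' cutoffs 1 and 5 and stay flat beyond, which is what the cutoff
#' recommendation exploits (see [recommend_cutoff()]).
#'
#' @param library a [tag_library()] (unfiltered).
#' @param index a [build_tag_index()] result.
#' @param cutoffs occurrence cutoffs to scan (default 1, 5, 10, 15, 20).
#' @param n_rand number of randomized replicates (>= 2; the full-scale
#'   calibration uses 500 library randomizations, smaller values trade
#'   precision for speed and the reported SD scales accordingly).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @return a data.frame of class `specificity_scan` with one row per
#'   cutoff: `cutoff`, `candidates` (observed tags at or above the
#'   cutoff), `observed_hits`, `random_candidates_mean`,
#'   `random_hits_mean`, `random_hits_sd`, `n_replicates`, `seed`.
#' @export
specificity_scan <- function(library, index, cutoffs = c(1, 5, 10, 15, 20),
                             n_rand = 20, seed = 1L) {
  stopifnot(inherits(library, "tag_library"), inherits(index, "tag_index"),
            n_rand >= 2)
  cutoffs <- sort(unique(as.integer(cutoffs)))
  tagset <- index_tag_set(index)
  hits_at <- function(counts, cuts) {
    mapped <- names(counts) %in% tagset
    vapply(cuts, function(cf) sum(mapped & counts >= cf), numeric(1))
  }
  cand_at <- function(counts, cuts)
    vapply(cuts, function(cf) sum(counts >= cf), numeric(1))
  observed <- hits_at(library$counts, cutoffs)
  candidates <- cand_at(library$counts, cutoffs)
  rnd_hits <- matrix(0, nrow = length(cutoffs), ncol = n_rand)
  rnd_cand <- matrix(0, nrow = length(cutoffs), ncol = n_rand)
  for (r in seq_len(n_rand)) {
    rl <- randomize_library(library, seed = seed + r,
                            preserve_counts = FALSE)
    rnd_hits[, r] <- hits_at(rl$counts, cutoffs)
    rnd_cand[, r] <- cand_at(rl$counts, cutoffs)
  }
  out <- data.frame(cutoff = cutoffs,
                    candidates = as.integer(candidates),
                    observed_hits = as.integer(observed),
                    random_candidates_mean = rowMeans(rnd_cand),
                    random_hits_mean = rowMeans(rnd_hits),
                    random_hits_sd = apply(rnd_hits, 1, sd),
                    n_replicates = n_rand,
                    seed = as.integer(seed))
  class(out) <- c("specificity_scan", "data.frame")
  out
}

#' Recommend an occurrence cutoff from a specificity scan
#'
#' The recommended cutoff is the smallest scanned cutoff after which the
#' random pass-through drops by less than one order of magnitude --
#' beyond that point a stricter cutoff buys no substantial gain in
#' specificity.  The drop is estimated from the random-hit means when the
#' randomized libraries actually produce hits (mean at the loosest cutoff
#' at least `min_signal`); otherwise -- the usual case for compact
#' references, where a random 21-mer virtually never matches the index --
#' from the mean number of randomized tags passing each cutoff
#' (`random_candidates_mean`), of which the expected random-hit count is
#' a constant multiple.
#'
#' @param scan a [specificity_scan()] result.
#' @param fold the "order of magnitude" drop threshold (default 10).
#' @param min_signal minimal random-hit mean for direct ratio estimation.
#' @return the recommended cutoff (a scalar from the scanned cutoffs).
#' @export
recommend_cutoff <- function(scan, fold = 10, min_signal = 5) {
  stopifnot(inherits(scan, "specificity_scan"), nrow(scan) >= 2)
  use_hits <- scan$random_hits_mean[1] >= min_signal
  v <- if (use_hits) scan$random_hits_mean else scan$random_candidates_mean
  k <- nrow(scan)
  ratio <- ifelse(v[-1] == 0 & v[-k] == 0, 1,
                  v[-k] / pmax(v[-1], .Machine$double.eps))
  below <- which(ratio < fold)
  if (length(below)) scan$cutoff[min(below)] else scan$cutoff[k]
}

#' Saturation curve of distinct mapped tags
#'
#' Reads are subsampled without replacement at read level (a tag with
#' count c contributes c draws) and the number of distinct tags mapping
#' to each index is recorded at every cumulative step, ending exactly at
#' the full library depth.
#'
#' @param library a [tag_library()].
#' @param indexes a `tag_index` or a named list of them.
#' @param step subsample increment in reads (default 200000).
#' @param seed integer seed for the read permutation.
#' @return a data.frame of class `saturation_curve` in long form:
#'   `reference_set`, `subsample_size`, `distinct_mapped`, plus a
#'   `distinct_total` series counting all distinct tags irrespective of
#'   mapping.
#' @export
saturation_curve <- function(library, indexes, step = 200000, seed = 1L) {
  stopifnot(inherits(library, "tag_library"), step > 0)
  if (inherits(indexes, "tag_index")) {
    indexes <- setNames(list(indexes), indexes$name)
  }
  depth <- sum(library$counts)
  sizes <- if (step >= depth) depth else
    unique(c(seq(step, depth, by = step), depth))
  tags <- names(library$counts)
  reads <- rep.int(seq_along(tags), library$counts)
  first_seen <- withr::with_seed(seed, {
    perm <- sample(reads)
    fs <- integer(length(tags))
    new <- !duplicated(perm)
    fs[perm[new]] <- which(new)
    fs
  })
  series <- lapply(names(indexes), function(nm) {
    mapped <- tags %in% index_tag_set(indexes[[nm]])
    data.frame(reference_set = nm,
               subsample_size = sizes,
               distinct_mapped = vapply(sizes, function(s)
                 sum(first_seen[mapped] <= s), numeric(1)))
  })
  series$total <- data.frame(reference_set = "distinct_total",
                             subsample_size = sizes,
                             distinct_mapped = vapply(sizes, function(s)
                               sum(first_seen <= s), numeric(1)))
  out <- do.call(rbind, series)
  rownames(out) <- NULL
  attr(out, "step") <- step
  attr(out, "seed") <- seed
  class(out) <- c("saturation_curve", "data.frame")
  out
}
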