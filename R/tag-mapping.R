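## Tag mapping against theoretical tag indexes.
##
## Exact mapping identifies all perfect matches of observed tags in a
## reference index; when several distinct observed tags hit the same
## (reference, strand), only the tag(s) at the maximal position -- the
## ones closest to the 3' end -- retain that hit.  The rule demotes hits,
## never deletes records: a tag losing all its hits becomes orphan for
## that reference set.  Mismatch-tolerant mapping (up to 2 substitutions,
## for genome rescue of unmappable tags) uses pigeonhole seeding: a
## 21-mer within Hamming distance 2 must match one of its three 7-mer
## thirds exactly.

#' Map observed tags exactly against a tag index
#'
#' @param library a [tag_library()] (its distinct tags are mapped).
#' @param index a [build_tag_index()] result.
#' @param resolve_3prime apply the 3'-most resolution rule (default TRUE).
#' @return an object of class `tag_mapping`: a list with `reference_set`,
#'   `records` (one row per well-formed library tag: `tag`, `count`,
#'   `status` in one_match/multi_match/orphan, `sense` in
#'   sense/antisense/both/none, `n_hits`, `n_refs`) and `hits` (retained
#'   hits with reference_id, position, strand, mismatches = 0).
#'   Malformed tags (not 21 nt over ACGT) are counted and skipped with a
#'   warning.
#' @export
map_tags_exact <- function(library, index, resolve_3prime = TRUE) {
  stopifnot(inherits(library, "tag_library"), inherits(index, "tag_index"))
  tags <- names(library$counts)
  ok <- grepl("^[ACGT]{21}$", tags)
  if (any(!ok))
    warning(sum(!ok), " malformed tag(s) skipped (must be 21 nt over ACGT)")
  tags <- tags[ok]
  occ <- index$occurrences
  hits <- if (nrow(occ))
    occ[data.table::data.table(tag = tags), on = "tag", nomatch = NULL]
  else data.table::as.data.table(empty_tags())
  if (nrow(hits) && resolve_3prime) {
    ## keep only the observed tag(s) whose position is maximal per
    ## (reference, strand); ties are all kept
    hits <- hits[, keep := position == max(position),
                 by = .(reference_id, strand)][keep == TRUE][, keep := NULL]
  }
  hits[, mismatches := 0L]
  per_tag <- hits[, .(n_hits = .N,
                      n_refs = data.table::uniqueN(reference_id),
                      sense = sense_label(strand)),
                  by = tag]
  records <- data.table::data.table(tag = tags,
                                    count = as.integer(library$counts[tags]))
  records <- merge(records, per_tag, by = "tag", all.x = TRUE, sort = FALSE)
  records[is.na(n_hits), `:=`(n_hits = 0L, n_refs = 0L, sense = "none")]
  records[, status := ifelse(n_hits == 0L, "orphan",
                             ifelse(n_hits == 1L, "one_match", "multi_match"))]
  out <- list(reference_set = index$name, records = records,
              hits = hits[, c("tag", "reference_id", "position", "strand",
                              "fwd_start", "fwd_end", "is_3prime_most",
                              "mismatches"), with = FALSE])
  class(out) <- "tag_mapping"
  out
}

sense_label <- function(strands) {
  s <- unique(strands)
  if (all(s == "+")) "sense" else if (all(s == "-")) "antisense" else "both"
}

#' Summarize a mapping in reference-table form
#'
#' Produces the per-reference accounting used in mapping summary tables:
#' mapped (= one_match + multi_match), one match, more than one match,
#' orphan, and the mean number of distinct reference sequences hit per
#' mapped tag ("contigs per tag").  When every tag is orphan the mean is
#' undefined and reported as 0 with the `degenerate` flag set.
#'
#' @param mapping a `tag_mapping`.
#' @return a one-row data.frame.
#' @export
summarize_mapping <- function(mapping) {
  stopifnot(inherits(mapping, "tag_mapping"))
  r <- mapping$records
  mapped <- sum(r$status != "orphan")
  cpt <- if (mapped > 0) mean(r$n_refs[r$status != "orphan"]) else 0
  data.frame(reference_set = mapping$reference_set,
             total = nrow(r),
             mapped = mapped,
             one_match = sum(r$status == "one_match"),
             multi_match = sum(r$status == "multi_match"),
             orphan = sum(r$status == "orphan"),
             contigs_per_tag = cpt,
             degenerate = mapped == 0)
}

#' Reference-set overlap of mapped tags ("Venn stave" counts)
#'
#' For a library mapped against several reference sets, computes for each
#' tag the subset of sets in which it has at least one hit, and counts
#' tags per subset, in descending order with percentages of the total
#' number of mapped tags.  A tag hitting all sets contributes only to the
#' full-intersection subset.
#'
#' @param mappings a named list of `tag_mapping` objects for the same
#'   library (names default to each mapping's `reference_set`).
#' @param top_k optionally truncate to the `top_k` largest subsets.
#' @return a data.frame with `subset` (set names joined by `+`),
#'   `n_sets`, `count` and `percent`.
#' @export
reference_overlap <- function(mappings, top_k = NULL) {
  if (inherits(mappings, "tag_mapping")) mappings <- list(mappings)
  nm <- names(mappings)
  if (is.null(nm)) nm <- vapply(mappings, `[[`, "", "reference_set")
  names(mappings) <- nm
  per_set <- lapply(mappings, function(m)
    m$records$tag[m$records$status != "orphan"])
  all_tags <- unique(unlist(per_set))
  if (length(all_tags) == 0)
    return(data.frame(subset = character(0), n_sets = integer(0),
                      count = integer(0), percent = numeric(0)))
  member <- vapply(per_set, function(tt) all_tags %in% tt,
                   logical(length(all_tags)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  labels <- apply(member, 1, function(row) paste(nm[row], collapse = "+"))
  tab <- sort(table(labels), decreasing = TRUE)
  out <- data.frame(subset = names(tab),
                    n_sets = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(all_tags))
  if (!is.null(top_k)) out <- head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Mismatch-tolerant tag mapping against genome sequences
#'
#' Reports every 21-mer window of the genome (both strands) within the
#' given Hamming distance of each query tag.  Intended for tags orphaned
#' by exact mapping; substitutions are allowed at any of the 21 positions
#' (including the CATG anchor).  Candidates are generated by pigeonhole
#' seeding on the three 7-mer thirds of the tag and verified by direct
#' comparison.
#'
#' @param tags character vector of 21-mers.
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @param max_mismatches 0, 1 or 2.
#' @param both_strands also scan the reverse strand (default TRUE).
#' @return a data.frame of hits: `tag`, `reference_id`, `strand`,
#'   `fwd_start`/`fwd_end` (window interval on the forward strand),
#'   `position` (window start on the hit strand, matching the tag-index
#'   convention) and `mismatches`.  Tags without any hit are absent; an
#'   empty genome yields no hits.
#' @export
map_tags_mismatch <- function(tags, genome, max_mismatches = 2,
                              both_strands = TRUE) {
  stopifnot(max_mismatches %in% 0:2)
  seqs <- as_named_seqs(genome, "g")
  if (length(seqs) == 0 || sum(nchar(seqs)) == 0)
    return(mismatch_empty())
  bad <- !grepl("^[ACGT]{21}$", tags)
  if (any(bad)) {
    warning(sum(bad), " malformed query tag(s) skipped")
    tags <- tags[!bad]
  }
  tags <- unique(tags)
  strands <- if (both_strands) c("+", "-") else "+"
  res <- list()
  for (sid in names(seqs)) {
    L <- nchar(seqs[[sid]])
    if (L < 21) next
    for (st in strands) {
      subj <- if (st == "+") seqs[[sid]] else revcomp(seqs[[sid]])
      subj_raw <- charToRaw(subj)
      for (tg in tags) {
        cand <- seed_candidates(tg, subj, L)
        if (length(cand) == 0) next
        mm <- hamming_at(charToRaw(tg), subj_raw, cand)
        hit <- cand[mm <= max_mismatches]
        if (length(hit) == 0) next
        mmh <- mm[mm <= max_mismatches]
        fwd_start <- if (st == "+") hit else L - (hit + 20L) + 1L
        res[[length(res) + 1L]] <- data.frame(
          tag = tg, reference_id = sid, strand = st,
          fwd_start = fwd_start, fwd_end = fwd_start + 20L,
          position = hit, mismatches = mmh)
      }
    }
  }
  if (length(res) == 0) return(mismatch_empty())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$tag, out$reference_id, out$fwd_start, out$strand), ]
}

mismatch_empty <- function() {
  data.frame(tag = character(0), reference_id = character(0),
             strand = character(0), fwd_start = integer(0),
             fwd_end = integer(0), position = integer(0),
             mismatches = integer(0))
}

seed_candidates <- function(tag, subject, L) {
  ## pigeonhole: with <= 2 mismatches over 3 disjoint thirds, at least
  ## one third matches exactly
  offsets <- c(1L, 8L, 15L)
  cand <- integer(0)
  for (o in offsets) {
    part <- substr(tag, o, o + 6L)
    ## lookahead so that overlapping seed occurrences are all found
    m <- gregexpr(paste0("(?=", part, ")"), subject, perl = TRUE)[[1]]
    if (m[1] == -1) next
    cand <- c(cand, as.integer(m) - o + 1L)
  }
  cand <- unique(cand)
  cand[cand >= 1L & cand + 20L <= L]
}

hamming_at <- function(tag_raw, subj_raw, starts) {
  vapply(starts, function(s)
    sum(subj_raw[s:(s + 20L)] != tag_raw), integer(1))
}

#' @export
print.tag_mapping <- function(x, ...) {
  s <- summarize_mapping(x)
  cat("Tag mapping vs '", x$reference_set, "': ", s$mapped, "/", s$total,
      " mapped (", s$one_match, " one-match, ", s$multi_match,
      " multi-match, ", s$orphan, " orphan)\n", sep = "")
  invisible(x)
}
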