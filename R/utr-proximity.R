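## 3'-UTR tag proximity: orient transcripts by their longest ORF, place
## them on the genome, and histogram genome-mapped tag positions relative
## to the transcript 3' ends.
##
## Tags mapping to the genome but to no transcript may come from
## unannotated 3'-UTR sequence downstream of the annotated transcript
## ends; the proximity profile quantifies that signal.

#' Longest open reading frame across six frames
#'
#' Finds the longest ATG-to-stop ORF over both strands and all three
#' frames.  Ties are broken in favour of the forward strand, then the
#' smallest start coordinate.
#'
#' @param sequence a character string (length >= 6).
#' @return a list with `strand`, `frame` (1-3), `start` (1-based on the
#'   reported strand) and `length` (nt, stop codon included), or `NULL`
#'   when no ORF exists.
#' @export
longest_orf <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L < 6) return(NULL)
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (f in 1:3) {
      starts <- seq(f, L - 2, by = 3)
      codons <- substring(s, starts, starts + 2)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% stops)
      if (!length(atg) || !length(stp)) next
      nxt <- stp[findInterval(atg, stp) + 1L]
      ok <- !is.na(nxt)
      if (!any(ok)) next
      for (i in which(ok)) {
        found[[length(found) + 1L]] <- list(
          strand = strand, frame = f, start = starts[atg[i]],
          length = (nxt[i] - atg[i] + 1L) * 3L)
      }
    }
  }
  if (!length(found)) return(NULL)
  lens <- vapply(found, `[[`, numeric(1), "length")
  best <- found[lens == max(lens)]
  if (length(best) > 1) {
    fwd <- vapply(best, function(o) o$strand == "+", logical(1))
    if (any(fwd)) best <- best[fwd]
    st <- vapply(best, `[[`, numeric(1), "start")
    best <- best[order(st)]
  }
  best[[1]]
}

#' Place transcripts on a genome
#'
#' Uses externally supplied placements when given; otherwise searches for
#' each transcript verbatim on both genome strands (exact substring
#' placement, the synthetic-data path).  Each placement is oriented: when
#' the transcript's longest ORF lies on the reverse strand, the effective
#' transcript orientation is flipped relative to the match strand.  The
#' 3' end coordinate is the placement end on the + strand and the start
#' on the - strand.
#'
#' @param transcripts named character vector or
#'   [Biostrings::DNAStringSet].
#' @param genome named character vector or DNAStringSet.
#' @param external_placements optional data.frame with columns
#'   `transcript_id`, `contig`, `start`, `end`, `strand` (e.g. from
#'   [read_placements_gff3()]).
#' @return a list with `placements` (data.frame: `transcript_id`,
#'   `contig`, `start`, `end`, `match_strand`, `orf_strand`, `strand`
#'   (effective orientation), `three_prime_pos`, `ambiguous`) and
#'   `unplaced` (transcript ids not found).
#' @export
place_transcripts <- function(transcripts, genome,
                              external_placements = NULL) {
  tseq <- as_named_seqs(transcripts, "t")
  orf_strand <- vapply(tseq, function(s) {
    o <- longest_orf(s)
    if (is.null(o)) NA_character_ else o$strand
  }, character(1))
  if (is.null(external_placements)) {
    gseq <- as_named_seqs(genome, "g")
    rows <- list()
    unplaced <- character(0)
    for (id in names(tseq)) {
      hits <- list()
      for (cid in names(gseq)) {
        for (st in c("+", "-")) {
          pat <- if (st == "+") tseq[[id]] else revcomp(tseq[[id]])
          m <- gregexpr(pat, gseq[[cid]], fixed = TRUE)[[1]]
          if (m[1] == -1) next
          for (p in as.integer(m))
            hits[[length(hits) + 1L]] <- data.frame(
              transcript_id = id, contig = cid, start = p,
              end = p + nchar(pat) - 1L, match_strand = st)
        }
      }
      if (!length(hits)) { unplaced <- c(unplaced, id); next }
      h <- do.call(rbind, hits)
      h$ambiguous <- nrow(h) > 1
      rows[[length(rows) + 1L]] <- h
    }
    pl <- if (length(rows)) do.call(rbind, rows) else
      data.frame(transcript_id = character(0), contig = character(0),
                 start = integer(0), end = integer(0),
                 match_strand = character(0), ambiguous = logical(0))
  } else {
    pl <- as.data.frame(external_placements)
    names(pl)[names(pl) == "strand"] <- "match_strand"
    pl$ambiguous <- pl$transcript_id %in%
      pl$transcript_id[duplicated(pl$transcript_id)]
    unplaced <- setdiff(names(tseq), pl$transcript_id)
  }
  if (nrow(pl)) {
    pl$orf_strand <- orf_strand[pl$transcript_id]
    flip <- !is.na(pl$orf_strand) & pl$orf_strand == "-"
    pl$strand <- ifelse(xor(pl$match_strand == "-", flip), "-", "+")
    pl$three_prime_pos <- ifelse(pl$strand == "+", pl$end, pl$start)
  } else {
    pl$orf_strand <- character(0)
    pl$strand <- character(0)
    pl$three_prime_pos <- integer(0)
  }
  rownames(pl) <- NULL
  list(placements = pl[, c("transcript_id", "contig", "start", "end",
                           "match_strand", "orf_strand", "strand",
                           "three_prime_pos", "ambiguous")],
       unplaced = unplaced)
}

## strand-aware CATG anchor coordinate of a tag hit on forward axis:
## first base of CATG in read orientation
hit_anchor <- function(fwd_start, fwd_end, strand) {
  ifelse(strand == "+", fwd_start, fwd_end)
}

#' Tag proximity profile around transcript 3' ends
#'
#' Bins genome-mapped tags by their signed distance to the nearest
#' annotated transcript 3' end (strand-consistent; positive = downstream
#' in transcript orientation), and reports the fraction of CATG targets
#' in the downstream windows that carry a sequenced tag.
#'
#' @param placements placements data.frame from [place_transcripts()].
#' @param hits genome tag hits with columns `reference_id` (contig),
#'   `strand` and `fwd_start`/`fwd_end` (as produced by
#'   [map_tags_mismatch()], or by [map_tags_exact()] hits joined with
#'   the index coordinates).
#' @param window half-width of the region around each 3' end (nt).
#' @param binwidth histogram bin width (nt).
#' @param genome optional genome sequences; required for the
#'   `fraction_covered` denominator (all CATG sites in the downstream
#'   windows), reported as `NA` otherwise.
#' @return a list of class `proximity_profile`: `histogram` (data.frame
#'   `bin_start`, `bin_mid`, `count`), `n_tags_assigned`,
#'   `fraction_covered`, `window`, `binwidth`.
#' @export
proximity_profile <- function(placements, hits, window = 1000,
                              binwidth = 50, genome = NULL) {
  if (is.list(placements) && !is.data.frame(placements))
    placements <- placements$placements
  stopifnot(all(c("contig", "strand", "three_prime_pos") %in%
                  names(placements)))
  anchors <- hit_anchor(hits$fwd_start, hits$fwd_end, hits$strand)
  dist_best <- rep(NA_real_, length(anchors))
  for (i in seq_along(anchors)) {
    pm <- placements[placements$contig == hits$reference_id[i] &
                     placements$strand == hits$strand[i], ]
    if (!nrow(pm)) next
    d <- ifelse(pm$strand == "+",
                anchors[i] - pm$three_prime_pos,
                pm$three_prime_pos - anchors[i])
    j <- which.min(abs(d))     # nearest 3' end only, no double counting
    if (abs(d[j]) <= window) dist_best[i] <- d[j]
  }
  assigned <- dist_best[!is.na(dist_best)]
  breaks <- seq(-window, window + binwidth, by = binwidth)
  ## right-open bins starting at -window; distance 0 falls in [0, binwidth)
  cnt <- table(cut(assigned, breaks = breaks, right = FALSE))
  hist <- data.frame(bin_start = breaks[-length(breaks)],
                     bin_mid = breaks[-length(breaks)] + binwidth / 2,
                     count = as.integer(cnt))
  frac <- NA_real_
  if (!is.null(genome)) {
    gseq <- as_named_seqs(genome, "g")
    sites <- catg_sites_downstream(placements, gseq, window)
    if (nrow(sites)) {
      key_hit <- paste(hits$reference_id, hits$strand, anchors)
      covered <- paste(sites$contig, sites$strand, sites$anchor) %in% key_hit
      frac <- mean(covered)
    }
  }
  out <- list(histogram = hist, n_tags_assigned = length(assigned),
              fraction_covered = frac, window = window, binwidth = binwidth)
  class(out) <- "proximity_profile"
  out
}

catg_sites_downstream <- function(placements, gseq, window) {
  rows <- list()
  for (i in seq_len(nrow(placements))) {
    cid <- placements$contig[i]
    if (!cid %in% names(gseq)) next
    L <- nchar(gseq[[cid]])
    tpp <- placements$three_prime_pos[i]
    st <- placements$strand[i]
    if (st == "+") {
      from <- min(tpp + 1L, L); to <- min(tpp + window, L)
      if (from > to) next
      region <- substr(gseq[[cid]], from, to)
      m <- gregexpr("CATG", region, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      anchor <- from + as.integer(m) - 1L
    } else {
      from <- max(tpp - window, 1L); to <- max(tpp - 1L, 1L)
      if (from > to) next
      region <- revcomp(substr(gseq[[cid]], from, to))
      m <- gregexpr("CATG", region, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      anchor <- to - as.integer(m) + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(contig = cid, strand = st,
                                            anchor = anchor)
  }
  if (!length(rows))
    return(data.frame(contig = character(0), strand = character(0),
                      anchor = integer(0)))
  unique(do.call(rbind, rows))
}

#' @export
print.proximity_profile <- function(x, ...) {
  cat("3'-proximity profile: ", x$n_tags_assigned,
      " tags within +/-", x$window, " nt of a 3' end; ",
      "downstream CATG coverage ",
      if (is.na(x$fraction_covered)) "NA" else
        sprintf("%.2f%%", 100 * x$fraction_covered), "\n", sep = "")
  invisible(x)
}
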