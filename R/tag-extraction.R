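## Virtual NlaIII/MmeI digestion: theoretical 21-bp tag extraction.
##
## A theoretical tag is "CATG" plus the 17 following bases on the scanned
## strand.  Coordinates are 1-based and inclusive; `position` is the first
## base of CATG on the indexed strand, and reverse-strand occurrences also
## record the equivalent forward-strand interval (fwd_start/fwd_end), the
## GFF3 convention used for placements.

empty_tags <- function() {
  data.frame(tag = character(0), reference_id = character(0),
             position = integer(0), strand = character(0),
             is_3prime_most = logical(0), padded = logical(0),
             fwd_start = integer(0), fwd_end = integer(0),
             stringsAsFactors = FALSE)
}

scan_strand <- function(seq, polyA_pad) {
  L <- nchar(seq)
  m <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  if (L == 0 || m[1] == -1) return(NULL)
  pos <- as.integer(m)
  full <- pos + 20L <= L
  tags <- character(length(pos))
  padded <- logical(length(pos))
  keep <- logical(length(pos))
  for (i in seq_along(pos)) {
    if (full[i]) {
      w <- substr(seq, pos[i], pos[i] + 20L)
      if (grepl("^[ACGT]{21}$", w)) { tags[i] <- w; keep[i] <- TRUE }
    } else if (polyA_pad) {
      w <- substr(seq, pos[i], L)
      if (grepl("^[ACGT]+$", w)) {
        tags[i] <- paste0(w, strrep("A", 21L - nchar(w)))
        padded[i] <- TRUE
        keep[i] <- TRUE
      }
    }
  }
  if (!any(keep)) return(NULL)
  data.frame(tag = tags[keep], position = pos[keep], padded = padded[keep],
             stringsAsFactors = FALSE)
}

#' Extract all theoretical DGE tags from a sequence
#'
#' Scans a sequence for every CATG occurrence followed by at least 17
#' usable bases and returns the corresponding CATG+17 theoretical tags.
#' Windows containing non-ACGT characters are disqualified rather than
#' expanded.  With `strand_mode = "both"` the reverse complement is
#' scanned as well (antisense tag space); minus-strand occurrences carry
#' their own coordinate on the reverse strand plus the equivalent
#' forward-strand interval.
#'
#' @param sequence a single character string (or anything coercible).
#' @param strand_mode `"forward"` or `"both"`.
#' @param polyA_pad complete a terminal CATG with fewer than 17 following
#'   bases using A's (the poly(A) tail); default off, which is the right
#'   setting for reference indexing since reference sequences carry no
#'   poly(A) tail.
#' @param reference_id optional id stored alongside each occurrence.
#' @return a data.frame with columns `tag`, `reference_id`, `position`
#'   (1-based first base of CATG on the indexed strand), `strand`,
#'   `is_3prime_most` (maximal position per strand), `padded`,
#'   `fwd_start`, `fwd_end`.  Empty for sequences without a qualifying
#'   site.
#' @export
extract_theoretical_tags <- function(sequence,
                                     strand_mode = c("both", "forward"),
                                     polyA_pad = FALSE,
                                     reference_id = NA_character_) {
  strand_mode <- match.arg(strand_mode)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1) stop("sequence must be a single string")
  L <- nchar(sequence)
  out <- list()
  fw <- scan_strand(sequence, polyA_pad)
  if (!is.null(fw)) {
    fw$strand <- "+"
    fw$fwd_start <- fw$position
    fw$fwd_end <- pmin(fw$position + 20L, L)
    out$fw <- fw
  }
  if (strand_mode == "both" && L > 0) {
    rv <- scan_strand(revcomp(sequence), polyA_pad)
    if (!is.null(rv)) {
      rv$strand <- "-"
      rv$fwd_start <- pmax(L - (rv$position + 20L) + 1L, 1L)
      rv$fwd_end <- L - rv$position + 1L
      out$rv <- rv
    }
  }
  if (length(out) == 0) return(empty_tags())
  res <- do.call(rbind, out)
  res$reference_id <- reference_id
  res$is_3prime_most <- FALSE
  for (s in unique(res$strand)) {
    i <- which(res$strand == s)
    res$is_3prime_most[i] <- res$position[i] == max(res$position[i])
  }
  rownames(res) <- NULL
  res[, c("tag", "reference_id", "position", "strand", "is_3prime_most",
          "padded", "fwd_start", "fwd_end")]
}

#' Canonical 3'-most tag of a transcript
#'
#' The tag actually produced by the NlaIII/MmeI protocol: the CATG site
#' closest to the poly(A) tail on the annotated (forward) strand.  With
#' `polyA_pad = TRUE` a terminal CATG with fewer than 17 following bases
#' is completed with A's, emulating the poly(A) tail that the sequenced
#' cDNA fragment would provide; without padding, the 3'-most CATG with a
#' full 17-nt suffix is used instead.
#'
#' @inheritParams extract_theoretical_tags
#' @return a one-row data.frame (same columns as
#'   [extract_theoretical_tags()]), or `NULL` when no site qualifies.
#' @export
canonical_3prime_tag <- function(sequence, polyA_pad = FALSE,
                                 reference_id = NA_character_) {
  tags <- extract_theoretical_tags(sequence, strand_mode = "forward",
                                   polyA_pad = polyA_pad,
                                   reference_id = reference_id)
  if (nrow(tags) == 0) return(NULL)
  tags[which.max(tags$position), , drop = FALSE]
}

#' Build a theoretical tag index for a reference set
#'
#' Constructs the database of all possible CATG+17 theoretical tags for a
#' reference sequence set.  All tags per sequence are kept; the 3'-most
#' preference is applied later, at mapping time.  Identical tag sequences
#' arising from different references accumulate occurrences.
#'
#' @param reference a named character vector, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param name label for the reference set (reported in summaries).
#' @param strand_mode `"both"` (default; supports antisense detection) or
#'   `"forward"`.
#' @param polyA_pad see [extract_theoretical_tags()]; default off.
#' @return an object of class `tag_index`: a list with the occurrence
#'   table (`occurrences`, keyed by tag), the set `name`, scan settings
#'   and per-sequence lengths.
#' @export
build_tag_index <- function(reference, name = "reference",
                            strand_mode = c("both", "forward"),
                            polyA_pad = FALSE) {
  strand_mode <- match.arg(strand_mode)
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference)) && file.exists(reference))
    reference <- readDNAStringSet(reference)
  seqs <- as_named_seqs(reference)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("reference sequences must be named")
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # FASTA id up to first space
  if (anyDuplicated(names(seqs)))
    stop("duplicate reference ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  occ <- lapply(names(seqs), function(id)
    extract_theoretical_tags(seqs[[id]], strand_mode = strand_mode,
                             polyA_pad = polyA_pad, reference_id = id))
  occ <- data.table::rbindlist(occ)
  if (nrow(occ)) data.table::setkeyv(occ, "tag")
  idx <- list(name = name, occurrences = occ, strand_mode = strand_mode,
              polyA_pad = polyA_pad, n_sequences = length(seqs),
              seq_lengths = setNames(nchar(seqs), names(seqs)))
  class(idx) <- "tag_index"
  idx
}

#' @export
print.tag_index <- function(x, ...) {
  cat("Theoretical tag index '", x$name, "': ",
      nrow(x$occurrences), " occurrences of ",
      length(unique(x$occurrences$tag)), " distinct tags over ",
      x$n_sequences, " sequences (strand_mode=", x$strand_mode,
      ", polyA_pad=", x$polyA_pad, ")\n", sep = "")
  invisible(x)
}

#' Serialize a tag index to TSV
#'
#' Writes the occurrence table (tag, reference_id, position, strand,
#' is_3prime_most) for inspection.
#'
#' @param index a `tag_index`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tag_index <- function(index, path) {
  stopifnot(inherits(index, "tag_index"))
  write_tsv_schema(as.data.frame(index$occurrences)[
    , c("tag", "reference_id", "position", "strand", "is_3prime_most")],
    path)
  invisible(path)
}

index_tag_set <- function(index) {
  unique(index$occurrences$tag)
}
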