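## Readers and writers for the pipeline's plain-text interchange
## formats: TSV tag libraries (GEO-style processed tag files), annotation
## and ontology-edge TSVs, GFF3 placements and YAML truth files.
## Every TSV written by the package starts with a '# columns:' schema
## comment; readers skip '#' lines.

write_tsv_schema <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tag-count library from TSV
#'
#' Expects two columns (tag, count); a header line and '#' comments are
#' optional.  Tags must be 21-nt uppercase ACGT strings; offending rows
#' are reported with their line numbers.  Counts on duplicate tag lines
#' are aggregated.
#'
#' @param path input TSV.
#' @param sample_id library label (defaults to the file name).
#' @return a [tag_library()].
#' @export
read_tag_library <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty tag library file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("malformed rows (need 2 tab-separated columns) at line(s): ",
         paste(head(lineno[lengths(parts) < 2], 5), collapse = ", "))
  tagv <- vapply(parts, `[[`, "", 1)
  cntv <- vapply(parts, `[[`, "", 2)
  if (tolower(tagv[1]) == "tag") {   # header
    tagv <- tagv[-1]; cntv <- cntv[-1]; lineno <- lineno[-1]
  }
  if (length(tagv) == 0) stop("no data rows in ", path)
  bad_tag <- !grepl("^[ACGT]{21}$", tagv)
  cnt <- suppressWarnings(as.numeric(cntv))
  bad_cnt <- is.na(cnt) | cnt < 0 | cnt != round(cnt)
  if (any(bad_tag | bad_cnt))
    stop("invalid tag/count rows in ", path, " at line(s): ",
         paste(head(lineno[bad_tag | bad_cnt], 10), collapse = ", "),
         " (tags must be 21 nt over ACGT, counts non-negative integers)")
  counts <- tapply(cnt, tagv, sum)
  tag_library(setNames(as.integer(counts), names(counts)),
              sample_id = sample_id)
}

#' Write a tag library to TSV
#'
#' @param library a [tag_library()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tag_library <- function(library, path) {
  stopifnot(inherits(library, "tag_library"))
  df <- data.frame(tag = names(library$counts),
                   count = as.integer(library$counts))
  df <- df[order(-df$count, df$tag), ]
  write_tsv_schema(df, path)
}

#' Write transcript placements as GFF3
#'
#' One `match` feature per placement, 1-based inclusive coordinates,
#' transcript id in the `ID` attribute.
#'
#' @param placements data.frame with `transcript_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_placements_gff3 <- function(placements, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = placements$contig,
    ranges = IRanges::IRanges(placements$start, placements$end),
    strand = placements$strand,
    ID = placements$transcript_id,
    type = "match")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript placements from GFF3
#'
#' @param path GFF3 file with `ID` attributes naming transcripts.
#' @return a data.frame with `transcript_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_placements_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(transcript_id = as.character(gr$ID),
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a sequence-to-term annotation TSV
#'
#' Two columns: sequence id, term id; '#' comments and an optional
#' header are skipped.
#'
#' @param path input TSV.
#' @return named list: sequence id -> character vector of term ids.
#' @export
read_annotations <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("sequence_id", "term_id"),
                   colClasses = "character")
  if (nrow(df) && tolower(df$sequence_id[1]) %in% c("sequence_id", "id"))
    df <- df[-1, ]
  split(df$term_id, df$sequence_id)
}

#' Read ontology parent edges from TSV
#'
#' Two columns: child term, parent term (is_a relationships).
#'
#' @param path input TSV.
#' @return a data.frame with columns `child` and `parent`.
#' @export
read_ontology_edges <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("child", "parent"),
                   colClasses = "character")
  if (nrow(df) && tolower(df$child[1]) == "child") df <- df[-1, ]
  df
}

#' Write the synthetic ground truth as YAML
#'
#' @param truth the `truth` element of a `synthetic_study`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  expr <- truth$expression
  y <- list(
    transcripts = rownames(expr),
    samples = colnames(expr),
    expression_cpm = setNames(
      lapply(colnames(expr), function(s) unname(expr[, s])),
      colnames(expr)),
    de_labels = if (nrow(truth$de_labels))
      lapply(seq_len(nrow(truth$de_labels)), function(i)
        as.list(truth$de_labels[i, ])) else list(),
    antisense_flags = as.list(truth$antisense_flags),
    withheld_ids = as.list(truth$withheld_ids),
    tagless_ids = as.list(truth$tagless_ids),
    seed = truth$config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a synthetic ground-truth YAML file
#'
#' @param path file written by [write_truth_yaml()].
#' @return a list mirroring the truth structure (expression as a matrix).
#' @export
read_truth_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  expr <- do.call(cbind, lapply(y$expression_cpm, unlist))
  rownames(expr) <- y$transcripts
  de <- if (length(y$de_labels))
    do.call(rbind, lapply(y$de_labels, as.data.frame)) else
    data.frame(transcript_id = character(0), sample = character(0),
               fold = numeric(0))
  list(expression = expr, de_labels = de,
       antisense_flags = unlist(y$antisense_flags),
       withheld_ids = unlist(y$withheld_ids),
       tagless_ids = unlist(y$tagless_ids),
       seed = y$seed)
}
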