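# Shared fixtures: a small synthetic study (fast) and the full-scale
# default configuration used by the end-to-end checks.

small_config <- function(seed = 4, ...) {
  args <- list(
    n_transcripts = 60,
    n_withheld = 5,
    library_depths = c(X1 = 60000L, X2 = 57000L, Xin = 19000L),
    de_spec = list(list(sample = "X1", n = 6, fold = 8),
                   list(sample = "Xin", n = 3, fold = 8)),
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_transcriptome(small_config())
    cache
  }
})

# a tiny deterministic tag library built by hand
toy_library <- function() {
  tag_library(c(CATGAAAAAAAAAAAAAAAAA = 10L,
                CATGCCCCCCCCCCCCCCCCC = 5L,
                CATGGGGGGGGGGGGGGGGGG = 4L,
                CATGTTTTTTTTTTTTTTTTT = 1L),
              sample_id = "toy")
}

# independent brute-force scan: all CATG+17 windows of a sequence
oracle_forward_tags <- function(seq) {
  L <- nchar(seq)
  out <- character(0)
  if (L < 21) return(out)
  for (p in seq_len(L - 20)) {
    w <- substr(seq, p, p + 20)
    if (substr(w, 1, 4) == "CATG" && grepl("^[ACGT]{21}$", w))
      out <- c(out, w)
  }
  out
}

rc <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

random_tag <- function(n = 1) {
  vapply(seq_len(n), function(i)
    paste(c("CATG", sample(c("A", "C", "G", "T"), 17, replace = TRUE)),
          collapse = ""), character(1))
}
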