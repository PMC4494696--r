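## Synthetic DGE study generator.
##
## Emulates a three-fraction (X1 / X2 / Xin) DGE tag-profiling experiment:
## a reference transcriptome, a genome harbouring the transcripts, a
## heavy-tailed expression profile with planted fraction-specific
## overexpression, and tag libraries produced by virtual NlaIII/MmeI
## digestion with configurable sequencing error, antisense transcription
## and novel (reference-absent) transcripts.

DNA_BASES <- c("A", "C", "G", "T")

#' Configuration for the synthetic DGE study
#'
#' Bundles and validates every parameter of the simulated experiment.
#' Defaults describe a scaled-down three-fraction study: library depths
#' keep the relative proportions of a typical sorted-fraction experiment
#' (the deepest library at one million reads), baseline expression is
#' log-normal with a heavy tail as observed in rank-abundance curves of
#' real DGE libraries, a small set of transcripts is overexpressed
#' eight-fold in a single fraction, antisense tags arise at a lower rate
#' than sense tags, and a small fraction of reads originates from
#' transcripts withheld from the emitted reference (novel transcripts).
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param length_mean,length_sd transcript length distribution (nt);
#'   `length_mean` must be at least 21 so that a tag can fit.
#' @param gc_fraction GC content of the random sequences, in `[0, 1]`.
#' @param library_depths named integer vector of read depths per sample.
#' @param de_spec list of `list(sample =, n =, fold =)` entries planting
#'   `n` transcripts overexpressed `fold`-fold in `sample`; folds must be
#'   >= 1 and no transcript is planted twice.
#' @param antisense_rate probability that a read reports the tag of the
#'   reverse-complement strand rather than the sense strand.
#' @param error_rate per-read probability of a single-base substitution
#'   at a uniformly chosen position of the 21-mer.
#' @param novel_rate proportion of reads drawn from withheld transcripts.
#' @param n_withheld number of transcripts withheld from the reference.
#' @param meanlog,sdlog parameters of the log-normal baseline expression.
#' @param x2_mixture named weights (over other samples) used to build the
#'   X2 expression column as a mixture, mirroring the observation that
#'   the intermediate fraction shares most of its transcripts with X1;
#'   set to `NULL` to disable.
#' @param polyA_pad should the simulator complete a terminal CATG site
#'   having fewer than 17 following bases with the poly(A) tail?
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_transcripts = 150,
                             length_mean = 500,
                             length_sd = 150,
                             gc_fraction = 0.32,
                             library_depths = c(X1 = 1000000L,
                                                X2 = 958000L,
                                                Xin = 321000L),
                             de_spec = list(
                               list(sample = "X1", n = 15, fold = 8),
                               list(sample = "X2", n = 3,  fold = 8),
                               list(sample = "Xin", n = 6, fold = 8)),
                             antisense_rate = 0.05,
                             error_rate = 0.005,
                             novel_rate = 0.01,
                             n_withheld = 10,
                             meanlog = 1.0,
                             sdlog = 1.5,
                             x2_mixture = c(X1 = 0.6, Xin = 0.4),
                             polyA_pad = TRUE,
                             seed = 1L) {
  stopifnot(length(n_transcripts) == 1, n_transcripts >= 1)
  if (length_mean < 21)
    stop("length_mean must be >= 21: a 21-bp tag cannot fit in shorter transcripts")
  for (p in c(gc_fraction, antisense_rate, error_rate, novel_rate))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("proportions (gc_fraction, antisense_rate, error_rate, novel_rate) must lie in [0, 1]")
  if (is.null(names(library_depths)) || any(names(library_depths) == ""))
    stop("library_depths must be a named vector")
  if (any(library_depths <= 0)) stop("library depths must be > 0")
  if (n_withheld >= n_transcripts)
    stop("n_withheld must be smaller than n_transcripts")
  if (novel_rate > 0 && n_withheld < 1)
    stop("novel_rate > 0 requires at least one withheld transcript")
  n_de <- 0L
  for (d in de_spec) {
    stopifnot(all(c("sample", "n", "fold") %in% names(d)))
    if (!d$sample %in% names(library_depths))
      stop("de_spec sample '", d$sample, "' is not a configured library")
    if (d$fold < 1) stop("fold changes must be >= 1")
    n_de <- n_de + d$n
  }
  if (n_de > n_transcripts - n_withheld)
    stop("de_spec plants more transcripts than available in the reference")
  if (!is.null(x2_mixture)) {
    if (!all(names(x2_mixture) %in% names(library_depths)))
      stop("x2_mixture weights must be named after configured samples")
    x2_mixture <- x2_mixture / sum(x2_mixture)
  }
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              length_mean = length_mean, length_sd = length_sd,
              gc_fraction = gc_fraction,
              library_depths = library_depths,
              de_spec = de_spec,
              antisense_rate = antisense_rate, error_rate = error_rate,
              novel_rate = novel_rate, n_withheld = as.integer(n_withheld),
              meanlog = meanlog, sdlog = sdlog,
              x2_mixture = x2_mixture,
              polyA_pad = isTRUE(polyA_pad),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

random_dna <- function(n_seq, lengths, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n_seq), function(i) {
    paste(sample(DNA_BASES, lengths[i], replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

has_tag_site <- function(seqs) {
  ## a usable site is any CATG followed by >= 17 nt
  vapply(seqs, function(s) {
    m <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    any(m > 0 & m + 20 <= nchar(s))
  }, logical(1), USE.NAMES = FALSE)
}

#' Generate a synthetic reference transcriptome with ground truth
#'
#' Draws `n_transcripts` random sequences at the configured GC content and
#' length distribution, regenerating sequences without a usable tag site
#' (a CATG followed by at least 17 nt) until at least 95% carry one --
#' unless the base composition makes CATG impossible, in which case the
#' affected transcripts are simply flagged tagless.  A subset of
#' transcripts is withheld from the emitted reference to act as novel
#' transcripts, and the expected expression matrix with planted
#' differential expression is attached as ground truth.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_study` with elements
#'   `sequences` (a [Biostrings::DNAStringSet] of *all* transcripts,
#'   including withheld ones) and `truth`, a list carrying the expected
#'   cpm `expression` matrix, `de_labels`, `antisense_flags`,
#'   `withheld_ids`, `tagless_ids`, the canonical (poly(A)-padded)
#'   `canonical_tags` and `antisense_tags`, and the `config` itself.
#' @seealso [reference_sequences()] to obtain the emitted reference only.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- sprintf("t%04d", seq_len(config$n_transcripts))
  gc <- config$gc_fraction
  ## CATG requires every one of A, C, G, T; skip regeneration when impossible
  catg_possible <- gc > 0 && gc < 1
  sim <- withr::with_seed(config$seed, {
    lens <- pmax(30L, as.integer(round(rnorm(config$n_transcripts,
                                             config$length_mean,
                                             config$length_sd))))
    seqs <- random_dna(config$n_transcripts, lens, gc)
    if (catg_possible) {
      for (iter in seq_len(50)) {
        ok <- has_tag_site(seqs)
        if (mean(ok) >= 0.95) break
        seqs[!ok] <- random_dna(sum(!ok), lens[!ok], gc)
      }
    }
    withheld <- if (config$n_withheld > 0)
      sort(sample(ids, config$n_withheld)) else character(0)
    list(seqs = seqs, withheld = withheld)
  })
  names(sim$seqs) <- ids
  canon <- vapply(sim$seqs, function(s) {
    tg <- canonical_3prime_tag(s, polyA_pad = config$polyA_pad)
    if (is.null(tg)) NA_character_ else tg$tag
  }, character(1))
  anti <- vapply(sim$seqs, function(s) {
    tg <- canonical_3prime_tag(revcomp(s), polyA_pad = config$polyA_pad)
    if (is.null(tg)) NA_character_ else tg$tag
  }, character(1))
  ## plant fraction markers only on transcripts the assay can observe:
  ## withheld transcripts cannot be recovered and tagless transcripts
  ## emit no reads at all
  expr <- simulate_expression(config, transcript_ids = ids,
                              de_exclude = union(sim$withheld,
                                                 ids[is.na(canon)]),
                              seed = config$seed + 1L)
  truth <- list(expression = expr,
                de_labels = attr(expr, "de_labels"),
                antisense_flags = !is.na(anti),
                withheld_ids = sim$withheld,
                tagless_ids = ids[is.na(canon)],
                canonical_tags = canon,
                antisense_tags = anti,
                config = config)
  out <- list(sequences = DNAStringSet(sim$seqs), truth = truth)
  class(out) <- "synthetic_study"
  out
}

#' Emitted reference sequences of a synthetic study
#'
#' The reference excludes withheld (novel) transcripts; reads simulated
#' from those transcripts can therefore never map and become orphan tags.
#'
#' @param study a `synthetic_study` from [generate_transcriptome()].
#' @return a [Biostrings::DNAStringSet].
#' @export
reference_sequences <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  keep <- setdiff(names(study$sequences), study$truth$withheld_ids)
  study$sequences[keep]
}

#' Simulate the expected expression matrix
#'
#' Baseline abundances are drawn once from a log-normal distribution and
#' shared across samples; transcripts listed in the `de_spec` are then
#' multiplied by their fold change in the target sample only.  When an
#' `x2_mixture` is configured and all referenced samples exist, the X2
#' column is rebuilt as the stated mixture of the other columns before
#' X2-specific folds are applied, so that the intermediate fraction
#' resembles a blend of stem-cell-like and differentiated expression.
#' Finally every column is renormalised to counts per million.
#'
#' @param config a [synthetic_config()].
#' @param transcript_ids optional row names (defaults to `t0001`, ...).
#' @param de_exclude transcript ids never chosen for planting (used for
#'   withheld transcripts, which could not be recovered downstream).
#' @param seed seed for this step (defaults to `config$seed + 1`).
#' @return a transcripts x samples matrix of expected cpm; each column
#'   sums to 1e6.  The planted assignments are attached as the
#'   `de_labels` attribute (a data.frame with columns `transcript_id`,
#'   `sample`, `fold`).
#' @export
simulate_expression <- function(config, transcript_ids = NULL,
                                de_exclude = character(0),
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_transcripts
  if (is.null(transcript_ids)) transcript_ids <- sprintf("t%04d", seq_len(n))
  stopifnot(length(transcript_ids) == n)
  samples <- names(config$library_depths)
  withr::with_seed(seed, {
    base <- rlnorm(n, config$meanlog, config$sdlog)
    E <- matrix(base, nrow = n, ncol = length(samples),
                dimnames = list(transcript_ids, samples))
    pool <- setdiff(transcript_ids, de_exclude)
    labels <- list()
    for (d in config$de_spec) {
      if (d$n == 0) next
      if (d$n > length(pool))
        stop("overlapping or oversized de_spec: not enough unplanted transcripts")
      chosen <- sample(pool, d$n)
      pool <- setdiff(pool, chosen)
      labels[[length(labels) + 1L]] <-
        data.frame(transcript_id = chosen, sample = d$sample, fold = d$fold)
    }
    de <- if (length(labels)) do.call(rbind, labels) else
      data.frame(transcript_id = character(0), sample = character(0),
                 fold = numeric(0))
    mix <- config$x2_mixture
    apply_folds <- function(E, which_samples) {
      for (i in seq_len(nrow(de))) {
        if (!de$sample[i] %in% which_samples) next
        E[de$transcript_id[i], de$sample[i]] <-
          E[de$transcript_id[i], de$sample[i]] * de$fold[i]
      }
      E
    }
    if (!is.null(mix) && "X2" %in% samples && all(names(mix) %in% samples)) {
      E <- apply_folds(E, setdiff(samples, "X2"))
      E[, "X2"] <- as.numeric(E[, names(mix), drop = FALSE] %*% mix)
      E <- apply_folds(E, "X2")
    } else {
      E <- apply_folds(E, samples)
    }
    E <- sweep(E, 2, colSums(E), "/") * 1e6
    attr(E, "de_labels") <- de
    E
  })
}

substitute_base <- function(tags, positions) {
  ## one random substitution per tag at the given 1-based positions
  old <- substr(tags, positions, positions)
  pick <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1),
                 character(1), USE.NAMES = FALSE)
  paste0(substr(tags, 1, positions - 1L), pick,
         substr(tags, positions + 1L, 21L))
}

#' Simulate one DGE tag library
#'
#' Draws the configured number of reads multinomially in proportion to the
#' expected expression, with the withheld (novel) transcripts contributing
#' the configured share of reads.  Each read reports its transcript's
#' canonical 3'-most tag; with probability `antisense_rate` it reports the
#' reverse-complement strand's own 3'-most tag instead, and with
#' probability `error_rate` a single uniformly chosen base of the emitted
#' 21-mer is substituted.  Transcripts without any usable tag site are
#' excluded from the draw (and reported), so the emitted counts always sum
#' exactly to the configured depth.
#'
#' @param study a `synthetic_study` from [generate_transcriptome()].
#' @param sample_id one of the configured sample names.
#' @param config the study configuration (defaults to the one recorded in
#'   the truth).
#' @param seed seed for this library (defaults to a sample-specific
#'   offset of the study seed so the three libraries are independent yet
#'   reproducible).
#' @return a [tag_library()] whose attributes record the per-transcript
#'   read counts (`transcript_counts`), the number of antisense and
#'   erroneous reads, and any tagless transcripts that were skipped.
#' @export
simulate_dge_library <- function(study, sample_id,
                                 config = study$truth$config,
                                 seed = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  samples <- names(config$library_depths)
  if (!sample_id %in% samples) stop("unknown sample: ", sample_id)
  if (is.null(seed))
    seed <- config$seed + 7919L * match(sample_id, samples)
  depth <- as.integer(config$library_depths[[sample_id]])
  truth <- study$truth
  ids <- names(study$sequences)
  sense_tag <- truth$canonical_tags
  anti_tag <- truth$antisense_tags
  eligible <- !is.na(sense_tag)
  if (!any(eligible)) stop("no transcript carries a tag site")
  expr <- truth$expression[, sample_id]
  w <- expr * eligible
  novel <- ids %in% truth$withheld_ids
  p <- numeric(length(ids))
  if (config$novel_rate > 0 && any(novel & eligible)) {
    p[!novel] <- (1 - config$novel_rate) * w[!novel] / sum(w[!novel])
    p[novel] <- config$novel_rate * w[novel] / sum(w[novel])
  } else {
    p[!novel] <- w[!novel] / sum(w[!novel])
  }
  withr::with_seed(seed, {
    reads <- as.integer(rmultinom(1, depth, p))
    names(reads) <- ids
    can_anti <- !is.na(anti_tag)
    n_anti <- integer(length(ids))
    n_anti[can_anti] <- rbinom(sum(can_anti), reads[can_anti],
                               config$antisense_rate)
    n_sense <- reads - n_anti
    emit_tag <- c(rep(sense_tag, n_sense), rep(anti_tag, n_anti))
    n_err <- rbinom(1, length(emit_tag), config$error_rate)
    err_idx <- if (n_err > 0) sample(length(emit_tag), n_err) else integer(0)
    if (n_err > 0) {
      pos <- sample(21L, n_err, replace = TRUE)
      emit_tag[err_idx] <- substitute_base(emit_tag[err_idx], pos)
    }
    counts <- sort(table(emit_tag), decreasing = TRUE)
    lib <- tag_library(setNames(as.integer(counts), names(counts)),
                       sample_id = sample_id)
    attr(lib, "transcript_counts") <- reads
    attr(lib, "n_antisense_reads") <- sum(n_anti)
    attr(lib, "n_error_reads") <- n_err
    attr(lib, "tagless_skipped") <- ids[!eligible]
    lib
  })
}

#' Embed transcripts in a synthetic genome
#'
#' Each transcript is embedded verbatim -- on a random strand, as either
#' the sequence itself or its reverse complement -- in genome contigs,
#' separated by random spacer sequence of the same base composition.
#' Withheld transcripts are embedded too: genuinely novel transcripts are
#' absent from the transcriptome reference but present in the genome.
#'
#' @param study a `synthetic_study`, or a named [Biostrings::DNAStringSet].
#' @param spacer_mean mean spacer length (nt, Poisson); 0 gives abutting
#'   transcripts and no flanking sequence.
#' @param per_contig number of transcripts per genome contig.
#' @param seed integer seed.
#' @return a list with `genome` (DNAStringSet) and `placements`, a
#'   data.frame with 1-based inclusive `start`/`end` and `strand` per
#'   transcript.
#' @export
generate_genome <- function(study, spacer_mean = 300, per_contig = 10,
                            seed = 1L) {
  seqs <- if (inherits(study, "synthetic_study"))
    as_named_seqs(study$sequences, "t") else as_named_seqs(study, "t")
  if (length(seqs) == 0) stop("transcriptome is empty")
  comp <- base_composition(seqs)
  withr::with_seed(seed, {
    grp <- ceiling(seq_along(seqs) / per_contig)
    placements <- vector("list", length(seqs))
    contigs <- character(max(grp))
    k <- 0L
    for (g in seq_len(max(grp))) {
      idx <- which(grp == g)
      contig_id <- sprintf("contig%02d", g)
      parts <- character(0)
      cursor <- 0L
      for (i in idx) {
        sp <- if (spacer_mean > 0) rpois(1, spacer_mean) else 0L
        if (sp > 0) {
          parts <- c(parts, paste(sample(DNA_BASES, sp, replace = TRUE,
                                         prob = comp), collapse = ""))
          cursor <- cursor + sp
        }
        strand <- sample(c("+", "-"), 1)
        s <- seqs[[i]]
        emb <- if (strand == "+") s else revcomp(s)
        parts <- c(parts, emb)
        k <- k + 1L
        placements[[k]] <- data.frame(
          transcript_id = names(seqs)[i], contig = contig_id,
          start = cursor + 1L, end = cursor + nchar(s), strand = strand)
        cursor <- cursor + nchar(s)
      }
      sp <- if (spacer_mean > 0) rpois(1, spacer_mean) else 0L
      if (sp > 0)
        parts <- c(parts, paste(sample(DNA_BASES, sp, replace = TRUE,
                                       prob = comp), collapse = ""))
      contigs[g] <- paste(parts, collapse = "")
    }
    names(contigs) <- sprintf("contig%02d", seq_len(max(grp)))
    list(genome = DNAStringSet(contigs),
         placements = do.call(rbind, placements))
  })
}

#' Simulate GO-style annotations with a planted enriched term
#'
#' Builds a small random term DAG and annotates transcripts so that one
#' marker term decorates transcripts planted as overexpressed in a chosen
#' fraction at a higher rate than the background, emulating a functional
#' category genuinely enriched in that fraction.
#'
#' @param study a `synthetic_study`.
#' @param target_sample fraction whose planted transcripts carry the
#'   marker term preferentially.
#' @param n_terms number of ontology terms.
#' @param background_rate,target_rate marker-term annotation probability
#'   for unplanted and planted transcripts.
#' @param seed integer seed.
#' @return list with `direct` (named list id -> terms), `edges`
#'   (data.frame child/parent) and `marker_term`.
#' @export
simulate_go_annotations <- function(study, target_sample = "X1",
                                    n_terms = 30,
                                    background_rate = 0.15,
                                    target_rate = 0.6,
                                    seed = 1L) {
  stopifnot(inherits(study, "synthetic_study"))
  ids <- setdiff(names(study$sequences), study$truth$withheld_ids)
  de <- study$truth$de_labels
  planted <- de$transcript_id[de$sample == target_sample]
  withr::with_seed(seed, {
    terms <- sprintf("T%03d", seq_len(n_terms))
    ## random tree: every non-root term has one parent among earlier terms
    parent <- c(NA, vapply(2:n_terms,
                           function(i) sample(i - 1L, 1), integer(1)))
    edges <- data.frame(child = terms[-1], parent = terms[parent[-1]])
    marker <- terms[n_terms]  # a leaf-ish term
    direct <- lapply(ids, function(id) {
      tt <- sample(terms[-n_terms], sample(1:3, 1))
      rate <- if (id %in% planted) target_rate else background_rate
      if (runif(1) < rate) tt <- c(tt, marker)
      unique(tt)
    })
    names(direct) <- ids
    list(direct = direct, edges = edges, marker_term = marker)
  })
}

## coerce a DNAStringSet / character vector to a named character vector
## (base::as.character drops names from character input)
as_named_seqs <- function(x, prefix = "seq") {
  seqs <- if (is.character(x)) x else as.character(x)
  if (!is.character(x) && !is.null(names(x))) names(seqs) <- names(x)
  if (length(seqs) && is.null(names(seqs)))
    names(seqs) <- sprintf("%s%03d", prefix, seq_along(seqs))
  seqs
}

base_composition <- function(seqs) {
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                      levels = DNA_BASES))
  p <- as.numeric(tab)
  if (sum(p) == 0) stop("cannot derive base composition of empty sequences")
  setNames(p / sum(p), DNA_BASES)
}

revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic DGE study:", cfg$n_transcripts, "transcripts (",
      length(x$truth$withheld_ids), "withheld ),",
      length(cfg$library_depths), "libraries\n")
  cat("  depths:", paste(names(cfg$library_depths),
                         cfg$library_depths, sep = "=", collapse = " "), "\n")
  cat("  planted DE:", nrow(x$truth$de_labels), "transcripts; seed",
      cfg$seed, "\n")
  invisible(x)
}
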