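## Tag-library containers, cpm normalisation and the binomial
## between-library comparison test.
##
## The test treats the rounded cpm values of a tag in two libraries as
## pseudo-counts x >= y and asks how surprising the split is when each of
## the x + y observations had an equal chance of falling in either
## library: p = P(X >= x) with X ~ Binomial(x + y, 1/2), evaluated by
## exact tail summation in log space.  For y = 0 this reduces to
## p = 0.5^x exactly.

#' Construct a tag library
#'
#' A tag library is an immutable per-sample multiset of 21-bp tags with
#' raw counts; `total_reads` records the sequencing depth (the sum of all
#' counts at load time) and is kept as the cpm denominator even after
#' filtering.
#'
#' @param counts named non-negative integer vector (names are tags).
#' @param sample_id library label.
#' @param total_reads depth; defaults to `sum(counts)`.
#' @return an object of class `tag_library`.
#' @export
tag_library <- function(counts, sample_id = "library",
                        total_reads = sum(counts)) {
  if (length(counts) == 0) stop("empty tag library")
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("counts must be named by tag sequence")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(names(counts))) {
    counts <- tapply(counts, names(counts), sum)
    counts <- setNames(as.integer(counts), names(counts))
  }
  lib <- list(sample_id = sample_id,
              counts = setNames(as.integer(counts), names(counts)),
              total_reads = as.numeric(total_reads),
              cutoff = 1L)
  class(lib) <- "tag_library"
  lib
}

#' @export
print.tag_library <- function(x, ...) {
  cat("Tag library '", x$sample_id, "': ", length(x$counts),
      " distinct tags, ", format(x$total_reads, big.mark = ","),
      " total reads", sep = "")
  if (x$cutoff > 1) cat(" (filtered at count >=", x$cutoff, ")")
  cat("\n")
  invisible(x)
}

#' Filter a library by the reliability cutoff
#'
#' Tags sequenced fewer than `min_count` times are discarded as
#' potentially artefactual; the parent library's total read count is
#' retained as the normalisation denominator.
#'
#' @param library a [tag_library()].
#' @param min_count occurrence cutoff (default 5: tags seen five times or
#'   more are treated as reliable).
#' @return a new, filtered `tag_library`.
#' @export
filter_by_cutoff <- function(library, min_count = 5) {
  stopifnot(inherits(library, "tag_library"), min_count >= 1)
  keep <- library$counts >= min_count
  if (!any(keep)) stop("cutoff ", min_count, " removes every tag")
  out <- library
  out$counts <- library$counts[keep]
  out$cutoff <- as.integer(min_count)
  out
}

#' Counts-per-million normalisation
#'
#' cpm = count / total_reads x 1e6, where `total_reads` is the pre-filter
#' depth of the library, so that filtering does not silently rescale the
#' surviving tags.
#'
#' @param library a [tag_library()].
#' @return a named numeric vector of cpm values.
#' @export
normalize_cpm <- function(library) {
  stopifnot(inherits(library, "tag_library"))
  if (library$total_reads <= 0) stop("library has no reads")
  library$counts / library$total_reads * 1e6
}

#' Round half-up to the nearest integer
#'
#' The pseudo-count convention of the comparison test: 5.73 rounds to 6
#' and 5.22 to 5 (unlike R's banker's rounding).
#'
#' @param x numeric.
#' @return integer-valued numeric.
#' @export
round_half_up <- function(x) floor(x + 0.5)

## exact upper binomial tail P(X >= x), X ~ Bin(n, 1/2), in log space
binom_tail_log <- function(x, n) {
  if (n == 0 || x <= 0) return(0)         # log(1)
  k <- x:n
  lt <- lchoose(n, k) - n * log(2)
  mx <- max(lt)
  min(0, mx + log(sum(exp(lt - mx))))
}

#' Binomial comparison of two cpm profiles
#'
#' For every tag, the two cpm values are rounded half-up to pseudo-counts
#' and the one-sided equal-chance binomial tail is computed: with
#' x = max and y = min of the rounded values, p = P(X >= x) for
#' X ~ Binomial(x + y, 1/2).  The p-value is symmetric in its arguments;
#' a tag absent from both libraries (x = y = 0) carries no evidence and
#' gets p = 1.
#'
#' @param cpm_a,cpm_b named numeric cpm vectors (the union of tags is
#'   compared, absent tags count as 0), or unnamed vectors of equal
#'   length.
#' @param tags optional tag names when the inputs are unnamed.
#' @return a data.frame with `tag`, `cpm_a`, `cpm_b`, `pseudo_a`,
#'   `pseudo_b`, `p_value`, `log10_p` (exact even when `p_value`
#'   underflows) and `direction` (`a>b`, `b>a` or `equal`, from the
#'   pseudo-counts).
#' @export
compare_libraries <- function(cpm_a, cpm_b, tags = NULL) {
  if (any(cpm_a < 0, cpm_b < 0)) stop("cpm values must be non-negative")
  if (!is.null(names(cpm_a)) && !is.null(names(cpm_b))) {
    tags <- union(names(cpm_a), names(cpm_b))
    a <- ifelse(tags %in% names(cpm_a), cpm_a[tags], 0)
    b <- ifelse(tags %in% names(cpm_b), cpm_b[tags], 0)
  } else {
    if (length(cpm_a) != length(cpm_b))
      stop("unnamed cpm vectors must have equal length")
    a <- as.numeric(cpm_a); b <- as.numeric(cpm_b)
    if (is.null(tags)) tags <- sprintf("tag%05d", seq_along(a))
  }
  pa <- round_half_up(a)
  pb <- round_half_up(b)
  x <- pmax(pa, pb)
  y <- pmin(pa, pb)
  lp <- mapply(binom_tail_log, x, x + y)
  data.frame(tag = tags, cpm_a = unname(a), cpm_b = unname(b),
             pseudo_a = unname(pa), pseudo_b = unname(pb),
             p_value = pmax(exp(lp), .Machine$double.xmin),
             log10_p = lp / log(10),
             direction = ifelse(pa > pb, "a>b",
                                ifelse(pb > pa, "b>a", "equal")),
             stringsAsFactors = FALSE)
}

#' Splashplot coordinates of three-fraction expression
#'
#' Projects each tag onto signed log2 differences: the x coordinate is
#' sign(X1 - Xin) * log2(|X1 - Xin|) whenever the absolute cpm difference
#' exceeds 1 (and 0 otherwise, since log2 of sub-unit differences would
#' invert the sign semantics), and likewise for y with X2.  Quadrants
#' classify fraction specificity; points with either coordinate 0 are
#' labelled `axis`.
#'
#' @param cpm_x1,cpm_x2,cpm_xin cpm vectors (named or positional, as in
#'   [compare_libraries()]).
#' @param tags optional names.
#' @return a data.frame with `tag`, `x`, `y`, `quadrant`
#'   (`++`, `+-`, `-+`, `--` or `axis`).
#' @export
splash_coordinates <- function(cpm_x1, cpm_x2, cpm_xin, tags = NULL) {
  named <- !is.null(names(cpm_x1)) && !is.null(names(cpm_x2)) &&
    !is.null(names(cpm_xin))
  if (named) {
    tags <- Reduce(union, list(names(cpm_x1), names(cpm_x2),
                               names(cpm_xin)))
    get <- function(v) ifelse(tags %in% names(v), v[tags], 0)
    x1 <- get(cpm_x1); x2 <- get(cpm_x2); xin <- get(cpm_xin)
  } else {
    x1 <- cpm_x1; x2 <- cpm_x2; xin <- cpm_xin
    if (is.null(tags)) tags <- sprintf("tag%05d", seq_along(x1))
  }
  coord <- function(a, b) {
    d <- a - b
    ifelse(abs(d) > 1, sign(d) * log2(abs(d)), 0)
  }
  x <- coord(x1, xin)
  y <- coord(x2, xin)
  quadrant <- ifelse(x == 0 | y == 0, "axis",
                     paste0(ifelse(x > 0, "+", "-"),
                            ifelse(y > 0, "+", "-")))
  data.frame(tag = tags, x = unname(x), y = unname(y), quadrant = quadrant,
             stringsAsFactors = FALSE)
}

#' Pairwise correlation of cell-fraction expression
#'
#' Pearson and Spearman correlation matrices over the tags shared by all
#' columns of a cpm matrix.
#'
#' @param cpm_matrix tags x samples numeric matrix (>= 3 rows).
#' @return a list with symmetric `pearson` and `spearman` matrices
#'   (diagonal 1; `NA` where a column is constant and Pearson is
#'   undefined) and `n_tags`.
#' @export
correlate_fractions <- function(cpm_matrix) {
  cpm_matrix <- as.matrix(cpm_matrix)
  if (nrow(cpm_matrix) < 3) stop("need at least 3 shared tags")
  constant <- apply(cpm_matrix, 2, function(v) sd(v) == 0)
  if (any(constant))
    warning("constant column(s): ",
            paste(colnames(cpm_matrix)[constant], collapse = ", "),
            "; correlations reported as NA")
  pear <- suppressWarnings(cor(cpm_matrix, method = "pearson"))
  spear <- suppressWarnings(cor(cpm_matrix, method = "spearman"))
  list(pearson = pear, spearman = spear, n_tags = nrow(cpm_matrix))
}

#' Assign tags to the fraction where they are mostly expressed
#'
#' A tag's fraction is the argmax of its cpm across samples, accepted
#' only when the tag's expression differs significantly (binomial test,
#' `p < alpha`) from at least one other fraction.
#'
#' @param cpm_matrix tags x samples cpm matrix.
#' @param alpha significance threshold (default 0.001, the candidate
#'   selection level).
#' @return a data.frame with `tag`, `fraction`, `max_cpm`, `best_p` (the
#'   smallest pairwise p-value against another fraction) and
#'   `significant`.
#' @export
fraction_assignments <- function(cpm_matrix, alpha = 0.001) {
  cpm_matrix <- as.matrix(cpm_matrix)
  samples <- colnames(cpm_matrix)
  if (is.null(samples)) stop("cpm_matrix must have sample column names")
  best <- samples[max.col(cpm_matrix, ties.method = "first")]
  best_p <- rep(1, nrow(cpm_matrix))
  for (s in samples) {
    i <- which(best == s)
    if (!length(i)) next
    others <- setdiff(samples, s)
    pm <- sapply(others, function(o)
      compare_libraries(cpm_matrix[i, s], cpm_matrix[i, o],
                        tags = rownames(cpm_matrix)[i])$p_value)
    if (is.null(dim(pm))) pm <- matrix(pm, nrow = length(i))
    best_p[i] <- apply(pm, 1, min)
  }
  data.frame(tag = rownames(cpm_matrix), fraction = best,
             max_cpm = cpm_matrix[cbind(seq_len(nrow(cpm_matrix)),
                                        match(best, samples))],
             best_p = best_p,
             significant = best_p < alpha,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment of comparison p-values
#'
#' The comparison workflow applies no multiple-testing correction by
#' default (candidate selection uses raw p < 0.001); this helper adds an
#' FDR-adjusted column for users who want one.
#'
#' @param comparison a [compare_libraries()] result.
#' @return the same data.frame with a `p_adjusted` column.
#' @export
adjust_comparison <- function(comparison) {
  comparison$p_adjusted <- stats::p.adjust(comparison$p_value,
                                           method = "BH")
  comparison
}
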