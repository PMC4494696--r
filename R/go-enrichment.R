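## Two-tailed hypergeometric GO term enrichment with ancestor
## propagation.
##
## Annotations are propagated upwards through the ontology (a term
## implies all its ancestors) before testing.  The two-tailed p-value is
## the minimum-likelihood construction: the sum of all hypergeometric
## point probabilities no larger than that of the observed table, which
## covers both over- and under-representation.

#' Propagate annotations to ancestor terms
#'
#' Each sequence annotated with a term is also annotated with every
#' ancestor of that term along the parent edges (is_a relationships).
#'
#' @param direct named list: sequence id -> character vector of term ids,
#'   or a two-column data.frame (sequence_id, term_id).
#' @param ontology_edges data.frame with columns `child` and `parent`.
#' @return named list: sequence id -> term ids closed over ancestors.
#'   A cycle in the edges is rejected with the offending path.
#' @export
propagate_annotations <- function(direct, ontology_edges) {
  if (is.data.frame(direct))
    direct <- split(as.character(direct[[2]]), as.character(direct[[1]]))
  stopifnot(all(c("child", "parent") %in% names(ontology_edges)))
  parents <- split(as.character(ontology_edges$parent),
                   as.character(ontology_edges$child))
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term, path = character(0)) {
    if (term %in% path)
      stop("cycle in ontology edges: ",
           paste(c(path[which(path == term):length(path)], term),
                 collapse = " -> "))
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    out <- term
    for (p in parents[[term]])
      out <- union(out, ancestors(p, c(path, term)))
    anc_cache[[term]] <- out
    out
  }
  lapply(direct, function(terms)
    sort(unique(unlist(lapply(unique(terms), ancestors)))))
}

#' Two-tailed hypergeometric test (minimum-likelihood definition)
#'
#' For a 2x2 term-by-set table with `k` annotated sequences in a study
#' set of size `n`, against `K` annotated in a background of size `N`,
#' the two-tailed p-value sums the point probabilities of every outcome
#' j with P(X = j) <= P(X = k), clamped to 1.  This accounts for both
#' significant over-representation (positive tail) and
#' under-representation (negative tail).
#'
#' @param k,n,K,N table margins (`k <= n <= N`, `k <= K <= N`).
#' @return the two-tailed p-value in (0, 1].
#' @export
hypergeom_two_tailed <- function(k, n, K, N) {
  if (length(k) > 1)
    return(mapply(hypergeom_two_tailed, k, n, K, N))
  if (n > N || K > N || k > n || k > K || k < max(0, n - (N - K)))
    stop("inconsistent hypergeometric margins (k=", k, ", n=", n,
         ", K=", K, ", N=", N, ")")
  support <- max(0, n - (N - K)):min(n, K)
  d <- dhyper(support, K, N - K, n)
  dk <- dhyper(k, K, N - K, n)
  ## small relative slack so equal-probability outcomes are included
  ## despite floating point noise
  min(1, sum(d[d <= dk * (1 + 1e-7)]))
}

#' Term enrichment of fraction-specific sequence sets
#'
#' Tests every ontology term for over- or under-representation in each
#' fraction's study set against the background, using the two-tailed
#' hypergeometric test on propagated annotations.  Effect size is
#' reported as the Haldane-corrected log2 odds ratio of the 2x2 table.
#'
#' @param study_sets named list: fraction -> character vector of sequence
#'   ids (must be subsets of the background).
#' @param propagated propagated annotations ([propagate_annotations()]).
#' @param background character vector of background sequence ids; by
#'   default all annotated sequences (unannotated sequences carry no
#'   information in a term test).
#' @param alpha significance threshold (default 1e-5).
#' @return a data.frame with one row per (fraction, term):
#'   `fraction`, `term`, `k`, `n`, `K`, `N`, `p`, `log_odds`,
#'   `direction` (over/under) and `significant`, ordered by `p`.
#' @export
enrich_fraction_sets <- function(study_sets, propagated,
                                 background = names(propagated),
                                 alpha = 1e-5) {
  background <- unique(background)
  N <- length(background)
  ann <- propagated[intersect(background, names(propagated))]
  term_members <- split(rep(names(ann), lengths(ann)), unlist(ann))
  res <- list()
  for (fr in names(study_sets)) {
    set <- unique(study_sets[[fr]])
    if (length(set) == 0) {
      warning("empty study set for fraction ", fr)
      next
    }
    if (!all(set %in% background))
      stop("study set '", fr, "' is not a subset of the background")
    n <- length(set)
    for (term in names(term_members)) {
      members <- term_members[[term]]
      K <- length(members)
      k <- sum(set %in% members)
      p <- hypergeom_two_tailed(k, n, K, N)
      lo <- log2(((k + 0.5) / (n - k + 0.5)) /
                 ((K - k + 0.5) / ((N - n) - (K - k) + 0.5)))
      res[[length(res) + 1L]] <- data.frame(
        fraction = fr, term = term, k = k, n = n, K = K, N = N,
        p = p, log_odds = lo,
        direction = if (k / n >= K / N) "over" else "under",
        significant = p < alpha)
    }
  }
  if (!length(res))
    return(data.frame(fraction = character(0), term = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), log_odds = numeric(0),
                      direction = character(0), significant = logical(0)))
  out <- do.call(rbind, res)
  out[order(out$p), ]
}
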