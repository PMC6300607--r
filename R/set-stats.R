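#' Hypergeometric overlap test
#'
#' Exact upper-tail hypergeometric test of the overlap between two gene
#' sets drawn from a common universe: with `N = |universe|`,
#' `k = |A intersect B|`, the p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, |A|, |B|)`, computed by exact tail summation
#' (no normal approximation) and including the observed `k`. Fold
#' enrichment is `k / (|A||B|/N)`.
#'
#' @param A,B Character vectors of ids; must be subsets of `universe`.
#' @param universe Character vector: the background id set.
#' @return One-row tibble: `n_a`, `n_b`, `n_universe`, `overlap`, `p`,
#'   `fold_enrichment`.
#' @export
hypergeom_overlap <- function(A, B, universe) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  universe <- unique(as.character(universe))
  extra <- c(setdiff(A, universe), setdiff(B, universe))
  if (length(extra) > 0L) {
    abort(paste0("ids outside the universe: ",
                 paste(head(unique(extra), 10), collapse = ", ")))
  }
  N <- length(universe); ka <- length(A); kb <- length(B)
  k <- length(intersect(A, B))
  kmax <- min(ka, kb)
  p <- if (k == 0) 1 else sum(dhyper(k:kmax, ka, N - ka, kb))
  p <- min(1, p)
  expected <- ka * kb / N
  tibble(n_a = ka, n_b = kb, n_universe = N, overlap = k, p = p,
         fold_enrichment = if (expected > 0) k / expected else NA_real_)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass convention: the sum
#' of probabilities, over all tables with the observed margins, of
#' tables no more probable than the observed one (the convention of
#' [stats::fisher.test()], which this wraps after validation).
#'
#' @param t A 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts with at least one positive margin.
#' @return The two-sided p-value (single numeric).
#' @export
fisher_exact <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2L, 2L))) abort("a 2x2 table is required")
  if (any(is.na(t)) || any(t < 0) || any(t != round(t))) {
    abort("table cells must be non-negative integers")
  }
  if (sum(t) == 0) abort("at least one positive margin is required")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    # a zero margin admits a single compatible table
    return(1)
  }
  stats::fisher.test(t)$p.value
}

#' Hypergeometric enrichment profile over a gene-set collection
#'
#' Tests the overlap of a query set with every set of a collection
#' (e.g. read from GMT via [read_gmt()]), with BH adjustment across the
#' collection. Collection/query members outside the universe are dropped
#' with a warning.
#'
#' @param query Character vector of ids.
#' @param collections Named list of character vectors.
#' @param universe Background id set.
#' @return Tibble with `set`, `n_set`, `overlap`, `p`, `q`
#'   (BH-adjusted), in collection order.
#' @export
enrichment_profile <- function(query, collections, universe) {
  universe <- unique(as.character(universe))
  if (length(collections) == 0L) {
    return(tibble(set = character(), n_set = integer(), overlap = integer(),
                  p = numeric(), q = numeric()))
  }
  query <- unique(as.character(query))
  dropped <- length(setdiff(query, universe)) +
    sum(vapply(collections, function(s) length(setdiff(s, universe)), integer(1)))
  if (dropped > 0L) {
    warn(paste0(dropped, " id(s) outside the universe dropped"))
  }
  query <- intersect(query, universe)
  rows <- imap(collections, function(s, nm) {
    s <- intersect(unique(as.character(s)), universe)
    res <- hypergeom_overlap(query, s, universe)
    tibble(set = nm, n_set = length(s), overlap = res$overlap, p = res$p)
  }) |> list_rbind()
  rows$q <- bh_adjust(rows$p)
  rows
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (tab-separated: set name, description,
#'   member ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  fgsea::gmtPathways(path)
}

#' Read a one-id-per-line text file
#'
#' @param path Path to a plain-text id list.
#' @return Character vector of unique, non-empty ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) abort(paste0("id list not found: ", path))
  ids <- trimws(readr::read_lines(path))
  unique(ids[nzchar(ids)])
}
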