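## Over-representation analysis: GMT gene-set collections, exact
## hypergeometric upper-tail overlap tests, BH within collection, and the
## significance rule (q < 0.05 and at least 3 overlapping genes).

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then gene symbols. Symbols
#' are uppercased and de-duplicated; malformed lines (fewer than three
#' fields or no genes) raise an error with the line number.
#'
#' @param path GMT file
#' @return named list of character vectors
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    genes <- unique(toupper(trimws(parts[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (length(parts) < 3 || !length(genes))
      stop("malformed GMT line ", i, ": need name, description and >=1 gene")
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Exact hypergeometric overlap test
#'
#' Upper-tail probability that a random draw of `n = |query|` genes from a
#' universe of size `N` contains at least the observed `k` genes of the
#' reference set (size `K` within the universe). Genes outside the universe
#' are dropped (with their count reported); matching ignores case and order.
#'
#' @param query character vector of query genes
#' @param reference character vector of reference-set genes
#' @param universe character vector defining the background
#' @param set_name label used in the `set` column of the result
#' @return one-row data.frame: `set`, `k`, `K`, `n`, `N`, `p`,
#'   `dropped_from_universe`, and the overlapping genes as a comma string
#' @export
hypergeomOverlap <- function(query, reference, universe, set_name = "reference") {
  u <- unique(toupper(universe))
  if (!length(u)) stop("empty universe")
  q <- unique(toupper(query))
  r <- unique(toupper(reference))
  dropped <- sum(!q %in% u) + sum(!r %in% u)
  q <- intersect(q, u); r <- intersect(r, u)
  if (!length(q)) stop("empty query after intersection with the universe")
  k <- length(intersect(q, r)); K <- length(r); n <- length(q); N <- length(u)
  # P(X >= k), exact tail of Hypergeometric(N, K, n)
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(set = set_name, k = k, K = K, n = n, N = N, p = p,
             dropped_from_universe = dropped,
             overlap = paste(sort(intersect(q, r)), collapse = ","))
}

#' Over-representation analysis across a collection
#'
#' One [hypergeomOverlap()] per gene set, BH adjustment across the
#' collection, and a significance flag requiring both q < 0.05 and an
#' overlap of at least 3 genes. Results are sorted by p.
#'
#' @param query character vector of query genes (e.g. clock predictors)
#' @param collection named list of gene sets (from [readGmt()])
#' @param universe background gene vector (all measured, annotated genes)
#' @param q_cutoff FDR threshold for the flag
#' @param min_genes minimum overlap size for the flag
#' @return data.frame of per-set results with `q` and `significant`
#' @export
oraCollection <- function(query, collection, universe, q_cutoff = 0.05,
                          min_genes = 3) {
  if (!length(collection)) stop("empty gene-set collection")
  res <- do.call(rbind, lapply(names(collection), function(nm)
    hypergeomOverlap(query, collection[[nm]], universe, set_name = nm)))
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < q_cutoff & res$k >= min_genes
  res[order(res$p), , drop = FALSE]
}
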