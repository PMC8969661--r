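## Hypergeometric over-representation of a query gene list against a
## gene-set collection, with Benjamini-Hochberg FDR.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; order-preserving (permuting the input permutes the output
#' identically).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, with universe size N, set size K (after intersection with
#' the universe), query size n and overlap k, the enrichment p-value is
#' the hypergeometric upper tail P(X >= k). Query members outside the
#' universe are dropped with a warning. Results are sorted by p (ties
#' broken by set name for determinism) and carry BH q-values computed
#' across all sets in the collection.
#'
#' @param query Character vector of gene symbols.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of gene symbols defining the universe
#'   (e.g. all annotated genes on the platform).
#' @return data.frame with columns `set_name`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, `overlap` (comma-separated overlap members).
#' @examples
#' hypergeometric_enrich(c("A", "B"), list(S = c("A", "B")), c("A", "B", "C", "D"))
#' @export
hypergeometric_enrich <- function(query, sets, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("universe must be nonempty")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ..." else "")
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(toupper(sets[[nm]])), universe)
    K <- length(set)
    overlap <- intersect(query, set)
    k <- length(overlap)
    # upper tail P(X >= k); k = 0 gives p = 1
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               overlap = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), c("set_name", "k", "K", "n", "N",
                                           "p", "q", "overlap")]
  rownames(out) <- NULL
  out
}
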