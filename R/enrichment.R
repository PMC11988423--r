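#' Over-representation analysis of a gene list against gene sets
#'
#' One-sided hypergeometric (Fisher) test per gene set with Benjamini-Hochberg
#' correction across the tested sets. With `N` background genes, `n` list
#' genes, `K` set members in the background, and `k` set members in the list:
#' fold enrichment = `(k/n) / (K/N)` and `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Sets with no background member are skipped.
#'
#' @param gene_list Character vector of genes of interest (must be a subset of
#'   `background`; duplicates are collapsed).
#' @param gene_sets Named list of character vectors, or a data frame with
#'   columns `set_id`, `gene_id` (long format; an optional `name` column is
#'   carried through).
#' @param background Character vector: the reference gene universe.
#' @return Data frame sorted by FDR: `set_id`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p_value`, `fdr`.
#' @examples
#' ora(c("g1", "g2"), list(s = c("g1", "g2", "g3")), paste0("g", 1:20))
#' @export
ora <- function(gene_list, gene_sets, background) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background must be nonempty")
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, background)
  if (length(outside) > 0) {
    stop("gene list contains genes outside the background: ",
         paste(head(outside, 5), collapse = ", "))
  }
  if (is.data.frame(gene_sets)) {
    gene_sets <- split(as.character(gene_sets$gene_id), gene_sets$set_id)
  }
  if (is.null(names(gene_sets))) stop("gene sets must be named")
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(sid) {
    members <- intersect(unique(gene_sets[[sid]]), background)
    K <- length(members)
    if (K == 0) return(NULL)  # set absent from the background: skipped
    k <- length(intersect(members, gene_list))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = sid, k = k, K = K, n = n, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = min(max(p, 0), 1), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(set_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$fdr, out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
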