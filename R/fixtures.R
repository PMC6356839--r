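# Packaged reference tables from the published glioblastoma analysis:
# the top-100 gene occurrence-frequency table over the 27 last-hidden-layer
# network nodes, and the 39-gene signature obtained from it at an occurrence
# threshold of 10.

#' Published gene occurrence-frequency table
#'
#' The 100 most frequently flagged genes across the 27 last-hidden-layer
#' nodes of the published glioblastoma network, with their occurrence counts
#' (range 8-17).
#'
#' @return a `gene_frequency_table` (data.frame with `gene_id`, `frequency`;
#'   attribute `n_nodes = 27`).
#' @export
gbm_gene_frequency <- function() {
  path <- system.file("extdata", "gbm_node_gene_frequency.tsv",
                      package = "deepcoxsig", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frequency, tab$gene_id), ]
  rownames(tab) <- NULL
  attr(tab, "n_nodes") <- 27L
  class(tab) <- c("gene_frequency_table", "data.frame")
  tab
}

#' Published 39-gene prognostic signature
#'
#' @return character vector of the 39 signature genes (occurrence >= 10 of
#'   27 nodes), in published order.
#' @export
gbm_signature_genes <- function() {
  path <- system.file("extdata", "gbm_signature39.txt",
                      package = "deepcoxsig", mustWork = TRUE)
  readLines(path)
}
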