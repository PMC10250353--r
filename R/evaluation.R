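# Consensus sets and sensitivity/precision of predicted gene sets.

#' Consensus gene set across screens
#'
#' Genes called in at least `min_screens` of the supplied sets. With
#' `min_screens = 1` this is the union; with `min_screens` equal to the
#' number of sets, the intersection.
#'
#' @param gene_sets list of character vectors of gene ids.
#' @param min_screens minimum number of sets a gene must appear in
#'   (default 2).
#' @return character vector of consensus gene ids.
#' @export
consensus_set <- function(gene_sets, min_screens = 2) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 2)
  if (min_screens > length(gene_sets))
    stop("min_screens exceeds the number of gene sets")
  sets <- lapply(gene_sets, function(s) unique(trimws(as.character(s))))
  tab <- table(unlist(sets))
  sort(names(tab)[tab >= min_screens])
}

#' Sensitivity and precision against a consensus set
#'
#' Sensitivity is the percentage of the consensus set recovered by the
#' predictions; precision is the percentage of predictions that lie in the
#' consensus set:
#' \deqn{Sensitivity = 100 |P \cap C| / |C|, \quad
#'       Precision = 100 |P \cap C| / |P|.}
#' Gene ids are compared as exact strings after whitespace trimming.
#'
#' @param predicted character vector of predicted gene ids.
#' @param consensus character vector of reference/consensus gene ids.
#' @return list with `sensitivity_pct`, `precision_pct`, `n_overlap`,
#'   `n_predicted`, `n_consensus`.
#' @export
sensitivity_precision <- function(predicted, consensus) {
  predicted <- unique(trimws(as.character(predicted)))
  consensus <- unique(trimws(as.character(consensus)))
  if (!length(predicted)) stop("predicted gene set is empty")
  if (!length(consensus)) stop("consensus gene set is empty")
  overlap <- length(intersect(predicted, consensus))
  list(sensitivity_pct = 100 * overlap / length(consensus),
       precision_pct = 100 * overlap / length(predicted),
       n_overlap = overlap,
       n_predicted = length(predicted),
       n_consensus = length(consensus))
}
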