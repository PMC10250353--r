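# Per-guide cutting/fitness scores and per-gene fitness aggregation.

#' Compute per-guide cutting and fitness scores
#'
#' The cutting score of guide i is
#' \deqn{CS_i = -\log_2(\bar{x}_{T_1,i} / \bar{x}_{C_1,i})}
#' the negative log2 fold change of its replicate-averaged normalised
#' abundance in the repair-deficient treatment arm versus its control:
#' active guides are depleted there, so depletion gives positive CS. The
#' fitness score is
#' \deqn{FS_i = \log_2(\bar{x}_{T_2,i} / \bar{x}_{C_2,i})}
#' so guides whose cut impairs growth carry negative FS. Replicates are
#' averaged on the normalised scale first; ratios are taken of the means,
#' never averaged per replicate.
#'
#' Whichever score arms are present in the data are computed; a tolerance
#' screen supplies only the fs arm (the stress condition as treatment) and
#' its score lands in the `fs` column.
#'
#' @param norm a `normalized_counts` object from [normalize_counts()].
#' @param library a [guide_library()]; used to attach gene ids.
#' @return A `guide_scores` data frame: `guide_id`, `gene_id`,
#'   `nontargeting`, `cs`, `fs` (NA for an absent arm), `score_source`.
#' @export
guide_scores <- function(norm, library) {
  stopifnot(inherits(norm, "normalized_counts"))
  rm <- norm$role_means
  ids <- norm$guide_ids
  cs <- if (!is.null(rm$cs_control) && !is.null(rm$cs_treatment))
    -log2(rm$cs_treatment / rm$cs_control) else rep(NA_real_, length(ids))
  fs <- if (!is.null(rm$fs_control) && !is.null(rm$fs_treatment))
    log2(rm$fs_treatment / rm$fs_control) else rep(NA_real_, length(ids))
  idx <- match(ids, library$guide_id)
  if (anyNA(idx)) stop("normalized counts contain guides absent from library")
  scores <- data.frame(guide_id = ids,
                       gene_id = library$gene_id[idx],
                       nontargeting = library$nontargeting[idx],
                       cs = as.numeric(cs), fs = as.numeric(fs),
                       score_source = "computed",
                       stringsAsFactors = FALSE)
  class(scores) <- c("guide_scores", "data.frame")
  scores
}

#' Attach externally computed scores
#'
#' Precomputed CS/FS values — or predicted guide activities standing in for
#' CS — can replace the log2-fold-change computation. Downstream behaviour
#' is identical; rows are marked `score_source = "external"`.
#'
#' @param library a [guide_library()].
#' @param table data frame with `guide_id` and `cs` and/or `fs` columns.
#' @param allow_partial keep going when some library guides have no row in
#'   `table` (they get NA scores); default FALSE rejects mismatches.
#' @return A `guide_scores` data frame covering the guides of `table`
#'   (ordered as the library).
#' @export
attach_external_scores <- function(library, table, allow_partial = FALSE) {
  if (is.null(table) || !nrow(table)) stop("external score table is empty")
  if (!"guide_id" %in% names(table)) stop("score table needs a guide_id column")
  if (!any(c("cs", "fs") %in% names(table)))
    stop("score table needs a cs and/or fs column")
  table$guide_id <- trimws(as.character(table$guide_id))
  unknown <- setdiff(table$guide_id, library$guide_id)
  if (length(unknown))
    stop("score table contains guide_ids absent from library: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) " ..." else "")
  idx <- match(library$guide_id, table$guide_id)
  if (anyNA(idx) && !allow_partial)
    stop(sum(is.na(idx)), " library guide(s) missing from score table ",
         "(use allow_partial = TRUE to keep them with NA scores)")
  scores <- data.frame(guide_id = library$guide_id,
                       gene_id = library$gene_id,
                       nontargeting = library$nontargeting,
                       cs = if ("cs" %in% names(table))
                         as.numeric(table$cs[idx]) else NA_real_,
                       fs = if ("fs" %in% names(table))
                         as.numeric(table$fs[idx]) else NA_real_,
                       score_source = "external",
                       stringsAsFactors = FALSE)
  scores <- scores[!is.na(idx) | allow_partial, , drop = FALSE]
  rownames(scores) <- NULL
  class(scores) <- c("guide_scores", "data.frame")
  scores
}

#' Gene-level fitness scores over a corrected library
#'
#' The fitness score of gene g is the arithmetic mean of the fitness
#' scores of its retained guides,
#' \deqn{FS_g = \sum_{i \in g} FS_i / m_g,}
#' where m_g counts the guides targeting g in the (CS-corrected) library.
#' Non-targeting guides never contribute.
#'
#' @param scores a `guide_scores` table with an `fs` column.
#' @param corrected a `corrected_library` from [correct_library()]; pass the
#'   uncorrected result of `correct_library(..., threshold = -Inf)` for an
#'   all-guides analysis.
#' @return A `gene_scores` data frame: `gene_id`, `fs_g`, `m_g`,
#'   `guide_ids_used` (list column).
#' @export
gene_fitness <- function(scores, corrected) {
  stopifnot(inherits(corrected, "corrected_library"))
  keep <- corrected$retained
  idx <- match(keep$guide_id, scores$guide_id)
  if (anyNA(idx)) stop("corrected library guide missing from score table")
  fs <- scores$fs[idx]
  if (anyNA(fs)) stop("fitness scores missing for retained guides")
  by_gene <- split(seq_len(nrow(keep)), keep$gene_id)
  fs_g <- vapply(by_gene, function(i) mean(fs[i]), 0)
  m_g <- lengths(by_gene)
  stopifnot(all(m_g >= 1))
  genes <- data.frame(gene_id = names(by_gene), fs_g = unname(fs_g),
                      m_g = unname(m_g), stringsAsFactors = FALSE)
  genes$guide_ids_used <- unname(lapply(by_gene,
                                        function(i) keep$guide_id[i]))
  class(genes) <- c("gene_scores", "data.frame")
  genes
}

#' Fraction of guides with both negative CS and negative FS
#'
#' Guides depleting in the fitness arm despite an apparently inactive CS
#' are the signature of alternative DNA repair (e.g. microhomology-mediated
#' end joining) masking cutting; this diagnostic reports how common the
#' pattern is.
#'
#' @param scores a `guide_scores` table with both `cs` and `fs`.
#' @return percentage (0-100) of guides with CS < 0 and FS < 0.
#' @export
negative_score_fraction <- function(scores) {
  if (anyNA(scores$cs) || anyNA(scores$fs))
    stop("both cs and fs must be present for all guides")
  100 * mean(scores$cs < 0 & scores$fs < 0)
}

#' Write a guide score table to TSV
#' @param scores a `guide_scores` data frame.
#' @param path output path.
#' @export
write_guide_scores <- function(scores, path) {
  utils::write.table(scores[c("guide_id", "gene_id", "cs", "fs")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a gene score table to TSV
#' @param genes a `gene_scores` data frame.
#' @param path output path.
#' @export
write_gene_scores <- function(genes, path) {
  utils::write.table(genes[c("gene_id", "fs_g", "m_g")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
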