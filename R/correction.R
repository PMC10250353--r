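# CS-corrected libraries, threshold sweeps and the ac-coefficient.

#' Build a CS-corrected library
#'
#' Removes every guide whose cutting score is below the threshold `T`.
#' A guide with CS exactly equal to `T` is retained. If all of a gene's
#' guides fall below `T`, the gene keeps its single highest-CS guide (ties
#' broken lexicographically by guide id), so every gene of the input
#' library survives correction. Non-targeting guides are excluded.
#'
#' @param library a [guide_library()].
#' @param scores a `guide_scores` table with a `cs` value for every
#'   targeting guide of `library`.
#' @param threshold minimum CS for a guide to be retained; `-Inf` yields
#'   the uncorrected (all targeting guides) library.
#' @return A `corrected_library`: list with `threshold`, `retained`
#'   (data frame `guide_id`, `gene_id`, `cs`), `fallback_genes` (genes kept
#'   only through their best guide), `n_genes`.
#' @export
correct_library <- function(library, scores, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  targeting <- library[!library$nontargeting, , drop = FALSE]
  idx <- match(targeting$guide_id, scores$guide_id)
  if (anyNA(idx)) stop("library guides missing from score table: ",
                       paste(utils::head(targeting$guide_id[is.na(idx)], 5),
                             collapse = ", "))
  cs <- scores$cs[idx]
  if (anyNA(cs)) stop("cutting scores missing for some guides")
  df <- data.frame(guide_id = targeting$guide_id,
                   gene_id = targeting$gene_id, cs = cs,
                   stringsAsFactors = FALSE)
  # deterministic fallback: order by gene, then CS descending, then guide_id
  df <- df[order(df$gene_id, -df$cs, df$guide_id), ]
  pass <- df$cs >= threshold
  gene_has_pass <- tapply(pass, df$gene_id, any)
  first_of_gene <- !duplicated(df$gene_id)  # the gene's max-CS guide
  keep <- pass | (first_of_gene & !gene_has_pass[df$gene_id])
  retained <- df[keep, , drop = FALSE]
  rownames(retained) <- NULL
  fallback <- names(gene_has_pass)[!gene_has_pass]
  structure(list(threshold = threshold, retained = retained,
                 fallback_genes = fallback,
                 n_genes = length(gene_has_pass)),
            class = "corrected_library")
}

#' Average library coverage (guides per gene)
#'
#' Total retained guides divided by the number of genes; fallback guides
#' count. With every gene present by construction, coverage is >= 1.
#'
#' @param corrected a `corrected_library`.
#' @return average guides per gene.
#' @export
average_coverage <- function(corrected) {
  stopifnot(inherits(corrected, "corrected_library"))
  nrow(corrected$retained) / corrected$n_genes
}

#' The ac-coefficient
#'
#' The product of a CS threshold and the average coverage of the library
#' corrected at that threshold. Raising the threshold enriches for active
#' guides but erodes coverage (and statistical power); the coefficient's
#' constrained maximum marks the working threshold.
#'
#' @param threshold CS threshold.
#' @param coverage average guides per gene of the corrected library.
#' @return `threshold * coverage`.
#' @export
ac_coefficient <- function(threshold, coverage) threshold * coverage

#' Sweep CS thresholds and profile the ac-coefficient
#'
#' Corrects the library at each grid value and records coverage and
#' ac-coefficient; optionally runs the full significance stage per
#' threshold (null re-estimated each time) to count essential genes.
#'
#' @param library a [guide_library()].
#' @param scores a `guide_scores` table (cs required; fs required when
#'   `with_calls`).
#' @param grid increasing threshold values; default 0.5 to
#'   `ceiling(max(cs))` in steps of 0.5.
#' @param with_calls also compute the number of significant genes at each
#'   threshold.
#' @param mode,alpha,null_params,seed significance settings used when
#'   `with_calls` (see [estimate_null()] and [call_genes()]).
#' @return An `ac_curve` data frame: `threshold`, `avg_coverage`,
#'   `ac_coefficient`, `n_essential` (NA unless `with_calls`).
#' @export
sweep_thresholds <- function(library, scores, grid = NULL,
                             with_calls = FALSE, mode = "one_tailed",
                             alpha = 0.05, null_params = list(),
                             seed = NULL) {
  if (is.null(grid)) {
    cs_max <- max(scores$cs[!scores$nontargeting], na.rm = TRUE)
    grid <- seq(0.5, max(0.5, ceiling(cs_max)), by = 0.5)
  }
  stopifnot(length(grid) >= 1, !is.unsorted(grid))
  rows <- lapply(seq_along(grid), function(k) {
    t_k <- grid[k]
    corrected <- correct_library(library, scores, t_k)
    cov <- average_coverage(corrected)
    n_ess <- NA_integer_
    if (with_calls) {
      genes <- gene_fitness(scores, corrected)
      pool <- nonessential_pool(genes, mode = mode)
      null <- do.call(estimate_null,
                      c(list(genes = genes, scores = scores,
                             corrected = corrected, pool = pool,
                             library = library,
                             seed = if (is.null(seed)) NULL else seed + k),
                        null_params))
      calls <- call_genes(genes, null, alpha = alpha)
      n_ess <- sum(calls$significant)
    }
    data.frame(threshold = t_k, avg_coverage = cov,
               ac_coefficient = ac_coefficient(t_k, cov),
               n_essential = n_ess)
  })
  curve <- do.call(rbind, rows)
  class(curve) <- c("ac_curve", "data.frame")
  curve
}

#' Optimal CS threshold from an ac-coefficient curve
#'
#' The threshold with the maximal ac-coefficient among rows whose average
#' coverage exceeds `min_coverage` (default 2: below two guides per gene
#' there is too little power to call essentiality reliably). Ties resolve
#' to the smallest threshold, which retains more guides.
#'
#' @param curve an `ac_curve` from [sweep_thresholds()].
#' @param min_coverage coverage floor (exclusive).
#' @return the selected threshold.
#' @export
optimal_threshold <- function(curve, min_coverage = 2) {
  eligible <- curve[curve$avg_coverage > min_coverage, , drop = FALSE]
  if (!nrow(eligible))
    stop("no threshold keeps average coverage above ", min_coverage,
         "; try a finer or lower grid")
  best <- eligible$ac_coefficient == max(eligible$ac_coefficient)
  min(eligible$threshold[best])
}

#' @export
print.corrected_library <- function(x, ...) {
  cat("corrected_library: T =", x$threshold, "|", nrow(x$retained),
      "guides /", x$n_genes, "genes (coverage",
      round(average_coverage(x), 3), ") |", length(x$fallback_genes),
      "fallback gene(s)\n")
  invisible(x)
}
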