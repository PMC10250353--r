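# End-to-end orchestration: essentiality and tolerance analyses.

#' Run the full essentiality analysis
#'
#' Pipeline: abundance QC filter -> normalisation -> per-guide CS/FS ->
#' threshold sweep -> optimal threshold -> CS-corrected gene scores ->
#' resampling null -> significance calls. Also runs the uncorrected
#' (all-guides) analysis for comparison. Alternatively accepts precomputed
#' per-guide scores (`scores`), skipping counts entirely.
#'
#' @param counts a [screen_counts()] with all four roles (ignored when
#'   `scores` given).
#' @param library a [guide_library()].
#' @param scores optional precomputed `guide_scores` table (e.g. from
#'   [attach_external_scores()]); CS may be a predicted activity.
#' @param threshold fixed CS threshold; when NULL (default) the sweep
#'   picks the ac-coefficient optimum.
#' @param pseudocount,scale normalisation settings.
#' @param qc_fraction low-abundance filter fraction applied to the raw
#'   library/control samples (default 0.05); NULL disables.
#' @param qc_reference roles or sample ids defining the QC reference
#'   abundance; defaults to the control roles present.
#' @param grid threshold grid for [sweep_thresholds()].
#' @param min_coverage coverage floor for [optimal_threshold()].
#' @param mode `"one_tailed"` (essentiality) or `"two_tailed"`.
#' @param alpha FDR threshold.
#' @param null_params list overriding [estimate_null()] sampling sizes.
#' @param seed master seed for the resampling null.
#' @return An `essentiality_run` list: `scores`, `curve`, `threshold`,
#'   `corrected`, `genes`, `null`, `calls`, and `uncorrected`
#'   (genes/null/calls without CS filtering), plus `qc_report` and
#'   `metadata`.
#' @export
run_essentiality <- function(counts = NULL, library, scores = NULL,
                             threshold = NULL, pseudocount = 1,
                             scale = 1e6, qc_fraction = 0.05,
                             qc_reference = NULL, grid = NULL,
                             min_coverage = 2, mode = "one_tailed",
                             alpha = 0.05, null_params = list(),
                             seed = 1L) {
  qc_report <- NULL
  if (is.null(scores)) {
    if (is.null(counts))
      stop("either counts or a precomputed score table is required")
    need <- c("cs_control", "cs_treatment", "fs_control", "fs_treatment")
    missing_roles <- setdiff(need, counts$samples$role)
    if (length(missing_roles))
      stop("counts lack required roles: ",
           paste(missing_roles, collapse = ", "))
    if (!is.null(qc_fraction)) {
      flt <- filter_low_abundance(counts, library,
                                  reference = qc_reference,
                                  fraction = qc_fraction,
                                  pseudocount = pseudocount, scale = scale)
      counts <- flt$counts
      library <- flt$library
      qc_report <- flt$report
    }
    norm <- normalize_counts(counts, pseudocount, scale)
    scores <- guide_scores(norm, library)
  } else {
    keep <- library$guide_id %in% scores$guide_id
    library <- library[keep | library$nontargeting, , drop = FALSE]
    class(library) <- c("guide_library", "data.frame")
  }
  if (anyNA(scores$cs[!scores$nontargeting]))
    stop("cutting scores required for activity correction")

  curve <- sweep_thresholds(library, scores, grid = grid)
  t_star <- threshold %||% optimal_threshold(curve, min_coverage)

  analyse <- function(t_val, seed_offset) {
    corrected <- correct_library(library, scores, t_val)
    genes <- gene_fitness(scores, corrected)
    if (diff(range(genes$fs_g)) == 0) {
      # constant score profile (e.g. treatment identical to control):
      # nothing can be significant and no null can be estimated
      warning("all gene scores identical; no significant genes")
      p0 <- if (mode == "two_tailed") 1 else 0.5
      calls <- data.frame(gene_id = genes$gene_id, fs_g = genes$fs_g,
                          m_g = genes$m_g, z = 0, p = p0,
                          q = fdr_adjust(rep(p0, nrow(genes))),
                          significant = FALSE, direction = "depleted",
                          stringsAsFactors = FALSE)
      class(calls) <- c("gene_calls", "data.frame")
      null <- structure(list(mu = genes$fs_g[1], sigma = 0, N = NA_integer_,
                             mode = mode, pool_size = NA_integer_,
                             seed = seed + seed_offset),
                        class = "null_model")
      return(list(corrected = corrected, genes = genes, null = null,
                  calls = calls))
    }
    pool <- nonessential_pool(genes, mode = mode)
    null <- do.call(estimate_null,
                    c(list(genes = genes, scores = scores,
                           corrected = corrected, pool = pool,
                           library = library, mode = mode,
                           seed = seed + seed_offset),
                      null_params))
    list(corrected = corrected, genes = genes, null = null,
         calls = call_genes(genes, null, alpha = alpha))
  }
  main <- analyse(t_star, 0L)
  unc <- analyse(-Inf, 1L)

  structure(list(scores = scores, curve = curve, threshold = t_star,
                 corrected = main$corrected, genes = main$genes,
                 null = main$null, calls = main$calls,
                 uncorrected = unc[c("genes", "null", "calls")],
                 qc_report = qc_report,
                 metadata = list(mode = mode, alpha = alpha,
                                 pseudocount = pseudocount, scale = scale,
                                 qc_fraction = qc_fraction,
                                 min_coverage = min_coverage,
                                 threshold = t_star, seed = seed,
                                 null_params = null_params)),
            class = "essentiality_run")
}

#' Run a tolerance (stress-condition) analysis
#'
#' Computes tolerance scores (log2 fold change of the stress condition
#' versus standard growth, exactly as a fitness score) from counts whose
#' `fs_control`/`fs_treatment` roles hold the standard and stress samples,
#' combines them with cutting scores from a prior essentiality run,
#' filters guides with very low control abundance, corrects the library
#' and calls significant genes (one-tailed lower by default).
#'
#' @param counts [screen_counts()] with `fs_control` (standard growth) and
#'   `fs_treatment` (stress) roles.
#' @param library a [guide_library()].
#' @param cs_scores `guide_scores` table (or data frame with `guide_id`,
#'   `cs`) from the essentiality analysis.
#' @param threshold CS threshold; when NULL, re-optimised by sweeping the
#'   ac-coefficient on the tolerance data.
#' @param control_filter_fraction abundance filter on the control sample
#'   (default 0.025); NULL disables.
#' @param pseudocount,scale,min_coverage,mode,alpha,null_params,seed as in
#'   [run_essentiality()].
#' @return An `essentiality_run` (tolerance scores in the fs slots).
#' @export
run_tolerance <- function(counts, library, cs_scores, threshold = NULL,
                          control_filter_fraction = 0.025,
                          pseudocount = 1, scale = 1e6, min_coverage = 2,
                          mode = "one_tailed", alpha = 0.05,
                          null_params = list(), seed = 1L) {
  if (is.null(cs_scores) || !"cs" %in% names(cs_scores))
    stop("a cutting-score table from a prior essentiality run is required")
  qc_report <- NULL
  if (!is.null(control_filter_fraction)) {
    flt <- filter_low_abundance(counts, library,
                                reference = "fs_control",
                                fraction = control_filter_fraction,
                                pseudocount = pseudocount, scale = scale)
    counts <- flt$counts
    library <- flt$library
    qc_report <- flt$report
  }
  norm <- normalize_counts(counts, pseudocount, scale)
  ts <- guide_scores(norm, library)
  idx <- match(ts$guide_id, cs_scores$guide_id)
  ts$cs <- cs_scores$cs[idx]
  missing_cs <- is.na(ts$cs) & !ts$nontargeting
  if (any(missing_cs)) {
    warning(sum(missing_cs), " guide(s) lack a CS value; dropped")
    drop_ids <- ts$guide_id[missing_cs]
    ts <- ts[!missing_cs, , drop = FALSE]
    library <- library[!library$guide_id %in% drop_ids, , drop = FALSE]
    class(library) <- c("guide_library", "data.frame")
  }
  run <- run_essentiality(library = library, scores = ts,
                          threshold = threshold, min_coverage = min_coverage,
                          mode = mode, alpha = alpha,
                          null_params = null_params, seed = seed)
  run$qc_report <- qc_report
  run
}

#' Write run outputs and metadata to a directory
#'
#' Emits the guide score table, ac-coefficient curve, gene calls
#' (corrected and uncorrected) as TSV plus a JSON metadata file capturing
#' the parameters and seeds needed to reproduce the run.
#'
#' @param run an `essentiality_run`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_guide_scores(run$scores, file.path(dir, "guide_scores.tsv"))
  utils::write.table(as.data.frame(run$curve), file.path(dir, "ac_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_calls(run$calls, file.path(dir, "gene_calls.tsv"))
  write_gene_calls(run$uncorrected$calls,
                   file.path(dir, "gene_calls_uncorrected.tsv"))
  meta <- run$metadata
  meta$null <- unclass(run$null)[c("mu", "sigma", "N", "pool_size", "seed")]
  meta$qc <- if (is.null(run$qc_report)) NULL else
    run$qc_report[c("n_removed", "dropped_genes", "cutoff", "fraction")]
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.essentiality_run <- function(x, ...) {
  cat("Activity-corrected screen analysis\n")
  cat(sprintf("  optimal threshold T = %.3g (coverage %.3g, ac-coefficient %.4g)\n",
              x$threshold, average_coverage(x$corrected),
              ac_coefficient(x$threshold, average_coverage(x$corrected))))
  cat(sprintf("  null: mu = %.4g, sigma = %.4g, N = %d\n",
              x$null$mu, x$null$sigma, x$null$N))
  cat(sprintf("  significant genes: %d corrected vs %d uncorrected (of %d)\n",
              sum(x$calls$significant),
              sum(x$uncorrected$calls$significant), nrow(x$calls)))
  invisible(x)
}
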