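# Resampling null distribution and gene significance calls.

#' Putatively non-significant gene pool
#'
#' For essentiality (one-tailed) analyses, roughly a fifth of a yeast
#' genome is essential, so genes with fitness scores above the 20th
#' percentile are treated as putatively non-essential. For bidirectional
#' (two-tailed) analyses, the middle 95% of gene scores (between the 2.5th
#' and 97.5th percentiles, exclusive) is treated as putatively
#' non-significant. Percentiles use R's default linear interpolation.
#'
#' @param genes a `gene_scores` table.
#' @param mode `"one_tailed"` or `"two_tailed"`.
#' @param percentile_low,percentile_high pool bounds; defaults 0.20 for
#'   one-tailed, 0.025/0.975 for two-tailed.
#' @return character vector of pool gene ids.
#' @export
nonessential_pool <- function(genes, mode = c("one_tailed", "two_tailed"),
                              percentile_low = NULL,
                              percentile_high = NULL) {
  mode <- match.arg(mode)
  if (nrow(genes) < 10) stop("need at least 10 genes to form a null pool")
  fs <- genes$fs_g
  if (mode == "one_tailed") {
    lo <- stats::quantile(fs, percentile_low %||% 0.20, names = FALSE)
    pool <- genes$gene_id[fs > lo]
  } else {
    lo <- stats::quantile(fs, percentile_low %||% 0.025, names = FALSE)
    hi <- stats::quantile(fs, percentile_high %||% 0.975, names = FALSE)
    pool <- genes$gene_id[fs > lo & fs < hi]
  }
  if (!length(pool))
    stop("non-significant gene pool is empty (degenerate score distribution)")
  pool
}

# Step-down rule for the pseudogene size N: start from the library's
# average coverage rounded to the nearest integer and decrement while the
# total draw (n_pseudogenes * N) is at least twice the guide-pool size.
reduce_pseudogene_size <- function(n_init, pool_size, n_pseudogenes = 1000) {
  n <- n_init
  while (n > 0 && (n_pseudogenes * n) / pool_size >= 2) n <- n - 1
  if (n < 1) stop("pseudogene size reduced to zero; guide pool too small")
  n
}

#' Estimate the non-essential null distribution
#'
#' The null for gene fitness scores is assumed Gaussian. Its mean is the
#' median of all gene fitness scores. Its standard deviation is estimated
#' by pseudogene resampling: (i) sample `n_genes_sampled` pool genes and
#' pool the fitness scores of their retained guides; (ii) form
#' `n_pseudogenes` pseudogenes, each the mean of `N` guides drawn from the
#' pool without replacement; (iii) take the standard deviation of the
#' pseudogene scores; (iv) repeat `n_repeats` times and average the
#' standard deviations. `N` starts at the original library's average
#' coverage rounded to the nearest integer and is decremented while the
#' total number of guides drawn would reach twice the pool size.
#'
#' Pool genes are drawn without replacement when the pool is large enough,
#' with replacement otherwise. `N` is fixed from the first repeat's pool
#' and recorded. A constant guide pool yields `sigma = 0` with a warning.
#'
#' @param genes a `gene_scores` table (all genes; supplies mu).
#' @param scores the `guide_scores` table backing `genes`.
#' @param corrected the `corrected_library` the scores were aggregated
#'   over; pseudogenes draw from guides retained in it.
#' @param pool gene ids from [nonessential_pool()].
#' @param library the original (uncorrected) [guide_library()], used for
#'   the initial value of `N`.
#' @param n_genes_sampled genes sampled per repeat (default 1000).
#' @param n_pseudogenes pseudogenes per repeat (default 1000).
#' @param n_repeats resampling repeats averaged into sigma (default 50).
#' @param mode tail mode label carried into the model.
#' @param seed integer seed; drawn and recorded when NULL.
#' @return A `null_model`: list with `mu`, `sigma`, `N`, `mode`,
#'   `pool_size`, sampling parameters and `seed`.
#' @export
estimate_null <- function(genes, scores, corrected, pool, library,
                          n_genes_sampled = 1000, n_pseudogenes = 1000,
                          n_repeats = 50, mode = "one_tailed",
                          seed = NULL) {
  stopifnot(length(pool) >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  mu <- stats::median(genes$fs_g)

  ret <- corrected$retained
  idx <- match(ret$guide_id, scores$guide_id)
  fs_by_gene <- split(scores$fs[idx], ret$gene_id)
  fs_by_gene <- fs_by_gene[intersect(names(fs_by_gene), pool)]
  if (!length(fs_by_gene))
    stop("no pool genes have retained guides")

  targeting <- !library$nontargeting
  coverage0 <- sum(targeting) / length(unique(library$gene_id[targeting]))
  n_init <- round(coverage0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  replace_genes <- length(fs_by_gene) < n_genes_sampled
  N <- NULL
  pool_size_recorded <- NULL
  sds <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    sampled <- sample(names(fs_by_gene), n_genes_sampled,
                      replace = replace_genes)
    pool_fs <- unlist(fs_by_gene[sampled], use.names = FALSE)
    if (is.null(N)) {
      N <- reduce_pseudogene_size(n_init, length(pool_fs), n_pseudogenes)
      pool_size_recorded <- length(pool_fs)
    }
    n_avail <- length(pool_fs)
    pseudo <- vapply(seq_len(n_pseudogenes), function(j)
      mean(pool_fs[sample.int(n_avail, min(N, n_avail))]), 0)
    sds[r] <- stats::sd(pseudo)
  }
  sigma <- mean(sds)
  if (sigma == 0)
    warning("degenerate null: all pooled guide scores identical (sigma = 0)")
  structure(list(mu = mu, sigma = sigma, N = N, mode = mode,
                 pool_size = pool_size_recorded,
                 n_pool_genes = length(fs_by_gene),
                 n_genes_sampled = n_genes_sampled,
                 n_pseudogenes = n_pseudogenes, n_repeats = n_repeats,
                 seed = seed),
            class = "null_model")
}

# set.seed inside a function should not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Call significant genes against the null
#'
#' Each gene's fitness score is standardised against the null,
#' `z = (FS_g - mu) / sigma`. One-tailed mode tests for scores
#' significantly below the null mean (`p = Phi(z)`); two-tailed mode tests
#' both directions (`p = 2 Phi(-|z|)`). P-values are Benjamini-Hochberg
#' adjusted and genes with `q < alpha` are called significant.
#'
#' @param genes a `gene_scores` table.
#' @param null a `null_model` from [estimate_null()].
#' @param alpha FDR threshold (default 0.05).
#' @return A `gene_calls` data frame: `gene_id`, `fs_g`, `m_g`, `z`, `p`,
#'   `q`, `significant`, `direction` (`"depleted"`/`"enriched"`).
#' @export
call_genes <- function(genes, null, alpha = 0.05) {
  stopifnot(inherits(null, "null_model"))
  if (!is.finite(null$sigma) || null$sigma <= 0)
    stop("null sigma must be positive; got ", null$sigma)
  z <- (genes$fs_g - null$mu) / null$sigma
  p <- if (null$mode == "two_tailed") 2 * stats::pnorm(-abs(z))
       else stats::pnorm(z)
  q <- fdr_adjust(p)
  calls <- data.frame(gene_id = genes$gene_id, fs_g = genes$fs_g,
                      m_g = genes$m_g, z = z, p = p, q = q,
                      significant = q < alpha,
                      direction = ifelse(z <= 0, "depleted", "enriched"),
                      stringsAsFactors = FALSE)
  class(calls) <- c("gene_calls", "data.frame")
  calls
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
fdr_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Write gene calls to TSV
#' @param calls a `gene_calls` data frame.
#' @param path output path.
#' @export
write_gene_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "null_model (%s): mu = %.4g, sigma = %.4g, N = %d (pool %d guides from %d genes), %d repeats, seed %d\n",
    x$mode, x$mu, x$sigma, x$N, x$pool_size, x$n_pool_genes, x$n_repeats,
    x$seed))
  invisible(x)
}
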