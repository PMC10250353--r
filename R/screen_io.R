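# I/O, normalisation and abundance QC for pooled screen count data.

NONTARGETING <- "__nontargeting__"

#' Construct a guide library
#'
#' A guide library maps guide identifiers to target genes. Non-targeting
#' control guides carry no gene and are flagged instead.
#'
#' @param guide_id character vector of unique guide identifiers.
#' @param gene_id character vector of target genes; `NA` (or empty string)
#'   for non-targeting guides.
#' @param sequence optional nucleotide sequences.
#' @param nontargeting logical vector; guides flagged `TRUE` are treated as
#'   non-targeting controls regardless of `gene_id`.
#' @return A `guide_library` object: a data frame with columns `guide_id`,
#'   `gene_id` (`NA` for non-targeting), `sequence`, `nontargeting`.
#' @export
guide_library <- function(guide_id, gene_id, sequence = NULL,
                          nontargeting = NULL) {
  guide_id <- trimws(as.character(guide_id))
  gene_id <- trimws(as.character(gene_id))
  gene_id[gene_id == ""] <- NA_character_
  if (is.null(nontargeting)) nontargeting <- is.na(gene_id)
  nontargeting <- as.logical(nontargeting) | is.na(gene_id)
  gene_id[nontargeting] <- NA_character_
  if (anyDuplicated(guide_id))
    stop("duplicate guide_id in library: ",
         paste(unique(guide_id[duplicated(guide_id)]), collapse = ", "))
  if (any(!nontargeting & is.na(gene_id)))
    stop("targeting guides must have a gene_id")
  lib <- data.frame(guide_id = guide_id, gene_id = gene_id,
                    stringsAsFactors = FALSE)
  lib$sequence <- if (is.null(sequence)) NA_character_ else as.character(sequence)
  lib$nontargeting <- nontargeting
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Read a guide library from a delimited file
#'
#' Expects a header with guide and gene columns; an optional `nontargeting`
#' 0/1 column marks control guides (an empty gene field with the flag set
#' also works). TSV by default, CSV via `sep = ","` or a `.csv` extension.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @param guide_col,gene_col column names holding guide and gene ids.
#' @return A [guide_library()].
#' @export
read_guide_library <- function(path, sep = NULL, guide_col = "guide_id",
                               gene_col = "gene_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c(guide_col, gene_col))
    if (!col %in% names(df))
      stop("guide library is missing required column '", col, "'")
  nt <- if ("nontargeting" %in% names(df))
    as.integer(df$nontargeting) == 1L else NULL
  guide_library(df[[guide_col]], df[[gene_col]],
                sequence = df[["sequence"]], nontargeting = nt)
}

#' Write a guide library to TSV
#' @param library a [guide_library()].
#' @param path output path.
#' @export
write_guide_library <- function(library, path) {
  out <- as.data.frame(library)
  out$nontargeting <- as.integer(out$nontargeting)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

SAMPLE_ROLES <- c("cs_control", "cs_treatment", "fs_control", "fs_treatment")

#' Read a sample sheet
#'
#' Assigns count columns to screening roles. Accepts a TSV/CSV with columns
#' `sample_id`, `role`, `replicate`, or a YAML file mapping each role to a
#' list of sample ids.
#'
#' Roles are `cs_control`/`cs_treatment` (the repair-deficient arm that
#' yields cutting scores) and `fs_control`/`fs_treatment` (the fitness or
#' tolerance arm).
#'
#' @param path file path (`.yaml`/`.yml` parsed as YAML, else delimited).
#' @return data frame with columns `sample_id`, `role`, `replicate`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    spec <- yaml::read_yaml(path)
    rows <- lapply(names(spec), function(role) {
      ids <- unlist(spec[[role]])
      data.frame(sample_id = as.character(ids), role = role,
                 replicate = seq_along(ids), stringsAsFactors = FALSE)
    })
    sheet <- do.call(rbind, rows)
  } else {
    sheet <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                               stringsAsFactors = FALSE)
  }
  sample_sheet(sheet)
}

#' Validate a sample sheet data frame
#' @param sheet data frame with `sample_id`, `role` and optional `replicate`.
#' @return the validated sheet.
#' @export
sample_sheet <- function(sheet) {
  need <- c("sample_id", "role")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(sheet$role), SAMPLE_ROLES)
  if (length(bad))
    stop("unknown sample role(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(SAMPLE_ROLES, collapse = ", "), ")")
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (is.null(sheet$replicate))
    sheet$replicate <- stats::ave(seq_len(nrow(sheet)), sheet$role,
                                  FUN = seq_along)
  sheet[c("sample_id", "role", "replicate")]
}

#' Construct a screen counts object
#'
#' @param counts non-negative integer matrix, guides in rows, samples in
#'   columns; column names must match the sample sheet.
#' @param sheet a sample sheet (see [sample_sheet()]).
#' @param library optional [guide_library()]; counts for guides absent from
#'   the library are dropped with a warning.
#' @return A `screen_counts` object: list with `counts` matrix (rownames =
#'   guide ids), `samples` sheet, and `dropped` (guides not in the library).
#' @export
screen_counts <- function(counts, sheet, library = NULL) {
  sheet <- sample_sheet(sheet)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have guide_id rownames")
  missing_cols <- setdiff(sheet$sample_id, colnames(counts))
  if (length(missing_cols))
    stop("sample sheet names count columns that do not exist: ",
         paste(missing_cols, collapse = ", "))
  counts <- counts[, sheet$sample_id, drop = FALSE]
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "double"
  dropped <- character(0)
  if (!is.null(library)) {
    keep <- rownames(counts) %in% library$guide_id
    dropped <- rownames(counts)[!keep]
    if (length(dropped))
      warning(length(dropped), " guide(s) in counts absent from library; ",
              "dropped")
    counts <- counts[keep, , drop = FALSE]
  }
  structure(list(counts = counts, samples = sheet, dropped = dropped),
            class = "screen_counts")
}

#' Read raw guide counts with role assignments
#'
#' @param path delimited file: first column `guide_id`, one integer column
#'   per sample.
#' @param sheet sample sheet data frame or path (see [read_sample_sheet()]).
#' @param library optional [guide_library()] used to validate guide ids.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return A [screen_counts()] object.
#' @export
read_counts <- function(path, sheet, library = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  df <- utils::read.table(path, header = TRUE, sep = sep %||% guess_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  id_col <- names(df)[1]
  ids <- as.character(df[[id_col]])
  num <- df[setdiff(names(df), id_col)]
  for (col in names(num)) {
    v <- suppressWarnings(as.numeric(num[[col]]))
    if (any(is.na(v) & !is.na(num[[col]])) || anyNA(v))
      stop("non-numeric count in column '", col, "'")
    if (any(v < 0)) stop("negative count in column '", col, "'")
    num[[col]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  screen_counts(m, sheet, library = library)
}

#' Write screen counts to TSV
#' @param counts a [screen_counts()] object.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  out <- data.frame(guide_id = rownames(counts$counts),
                    counts$counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalise counts to a common scale
#'
#' Adds a pseudocount to every raw count, scales each sample to a fixed
#' total (counts-per-million by default), and averages replicates within
#' each role. Only ratios of per-role means enter downstream scores, so any
#' common scale is equivalent.
#'
#' @param counts a [screen_counts()] object.
#' @param pseudocount added to each raw count before normalisation
#'   (default 1), so zero counts stay representable.
#' @param scale per-sample total after normalisation (default 1e6).
#' @return A `normalized_counts` object: list with `norm` matrix,
#'   `role_means` (one averaged abundance vector per role present),
#'   `samples`, `pseudocount`, `scale`.
#' @export
normalize_counts <- function(counts, pseudocount = 1, scale = 1e6) {
  stopifnot(inherits(counts, "screen_counts"))
  m <- counts$counts + pseudocount
  totals <- colSums(m)
  if (any(totals <= 0)) stop("sample with non-positive total after pseudocount")
  norm <- sweep(m, 2, totals, "/") * scale
  role_means <- lapply(split(counts$samples$sample_id, counts$samples$role),
                       function(ids) rowMeans(norm[, ids, drop = FALSE]))
  structure(list(norm = norm, role_means = role_means,
                 samples = counts$samples, guide_ids = rownames(norm),
                 pseudocount = pseudocount, scale = scale),
            class = "normalized_counts")
}

#' Remove guides with very low control abundance
#'
#' Drops guides whose mean normalised abundance across the reference
#' samples falls below `fraction` of the library-wide mean in those
#' samples. Used with `fraction = 0.05` against the raw-library/control
#' samples before scoring, and with `fraction = 0.025` against the
#' tolerance-screen control. Genes losing all guides are dropped from the
#' library and reported.
#'
#' @param counts a [screen_counts()] object.
#' @param library a [guide_library()].
#' @param reference roles (or explicit sample ids) defining the reference
#'   abundance; defaults to the control roles present.
#' @param fraction abundance cut as a fraction of the library mean, in (0,1).
#' @param pseudocount,scale passed to [normalize_counts()].
#' @return list with filtered `library`, `counts`, and a `report` holding
#'   removed guides, dropped genes and the abundance cutoff used.
#' @export
filter_low_abundance <- function(counts, library,
                                 reference = NULL, fraction = 0.05,
                                 pseudocount = 1, scale = 1e6) {
  stopifnot(inherits(counts, "screen_counts"), fraction > 0, fraction < 1)
  if (is.null(reference))
    reference <- intersect(c("cs_control", "fs_control"),
                           counts$samples$role)
  ids <- counts$samples$sample_id[counts$samples$role %in% reference]
  if (!length(ids)) ids <- intersect(reference, counts$samples$sample_id)
  if (!length(ids)) stop("reference samples not found: ",
                         paste(reference, collapse = ", "))
  norm <- normalize_counts(counts, pseudocount, scale)
  abund <- rowMeans(norm$norm[, ids, drop = FALSE])
  cutoff <- fraction * mean(abund)
  removed <- names(abund)[abund < cutoff]
  if (length(removed) == length(abund))
    stop("abundance filter would remove every guide")
  keep_lib <- library[!library$guide_id %in% removed, , drop = FALSE]
  genes_before <- unique(library$gene_id[!library$nontargeting])
  genes_after <- unique(keep_lib$gene_id[!keep_lib$nontargeting])
  dropped_genes <- setdiff(genes_before, genes_after)
  keep_counts <- counts$counts[!rownames(counts$counts) %in% removed, ,
                               drop = FALSE]
  class(keep_lib) <- c("guide_library", "data.frame")
  list(library = keep_lib,
       counts = structure(list(counts = keep_counts,
                               samples = counts$samples,
                               dropped = counts$dropped),
                          class = "screen_counts"),
       report = list(n_removed = length(removed), removed = removed,
                     dropped_genes = dropped_genes, cutoff = cutoff,
                     fraction = fraction, reference_samples = ids))
}

#' Pairwise replicate correlations for one role
#'
#' Diagnostic: Pearson correlation between replicates on log-normalised
#' abundances. Well-behaved screens show high replicate agreement.
#'
#' @param counts a [screen_counts()] object.
#' @param role one of the screening roles.
#' @param pseudocount,scale passed to [normalize_counts()].
#' @return data frame with `sample_a`, `sample_b`, `pearson_r`; empty (with
#'   a warning) when the role has a single replicate.
#' @export
replicate_correlation <- function(counts, role, pseudocount = 1,
                                  scale = 1e6) {
  stopifnot(inherits(counts, "screen_counts"))
  ids <- counts$samples$sample_id[counts$samples$role == role]
  empty <- data.frame(sample_a = character(0), sample_b = character(0),
                      pearson_r = numeric(0))
  if (length(ids) < 2) {
    warning("role '", role, "' has fewer than 2 replicates")
    return(empty)
  }
  lg <- log2(normalize_counts(counts, pseudocount, scale)$norm[, ids,
                                                               drop = FALSE])
  pairs <- utils::combn(ids, 2)
  data.frame(sample_a = pairs[1, ], sample_b = pairs[2, ],
             pearson_r = apply(pairs, 2, function(p)
               stats::cor(lg[, p[1]], lg[, p[2]])))
}

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts:", nrow(x$counts), "guides x", ncol(x$counts),
      "samples\n")
  tab <- table(x$samples$role)
  cat("  roles:", paste(sprintf("%s (%d)", names(tab), tab),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.guide_library <- function(x, ...) {
  cat("guide_library:", nrow(x), "guides,",
      length(unique(x$gene_id[!x$nontargeting])), "genes,",
      sum(x$nontargeting), "non-targeting\n")
  invisible(x)
}
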