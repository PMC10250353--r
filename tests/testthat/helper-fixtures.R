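# Small in-code fixtures shared across tests.

# library of n_genes genes x guides_per_gene guides (+ optional NT controls)
tiny_library <- function(n_genes = 2, guides_per_gene = 3,
                         n_nontargeting = 0) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  gid <- rep(genes, each = guides_per_gene)
  guides <- sprintf("%s_s%d", gid, rep(seq_len(guides_per_gene), n_genes))
  nt <- if (n_nontargeting > 0) sprintf("nt%02d", seq_len(n_nontargeting))
        else character(0)
  guide_library(c(guides, nt), c(gid, rep(NA, length(nt))))
}

default_sheet <- function(replicates = 2) {
  roles <- c("cs_control", "cs_treatment", "fs_control", "fs_treatment")
  do.call(rbind, lapply(roles, function(r)
    data.frame(sample_id = sprintf("%s_%d", r, seq_len(replicates)),
               role = r, replicate = seq_len(replicates))))
}

# counts object with a deterministic matrix unless one is supplied
tiny_counts <- function(library, replicates = 2, mat = NULL) {
  sheet <- default_sheet(replicates)
  n <- nrow(library)
  if (is.null(mat)) {
    set.seed(99)
    mat <- matrix(rpois(n * nrow(sheet), 100), nrow = n,
                  dimnames = list(library$guide_id, sheet$sample_id))
  }
  screen_counts(mat, sheet, library = library)
}

# guide score table built directly (skipping counts)
score_table <- function(library, cs, fs = NULL) {
  df <- data.frame(guide_id = library$guide_id, cs = cs)
  if (!is.null(fs)) df$fs <- fs
  attach_external_scores(library, df)
}

# independent brute-force BH step-up (kept separate from fdr_adjust)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

write_tsv_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = if (ext == ".csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}
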