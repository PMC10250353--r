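test_that("cutting and fitness scores follow the log2 fold-change definitions", {
  lib <- tiny_library(1, 3)
  sheet <- default_sheet(1)
  # equal totals per sample so normalisation preserves ratios
  mat <- cbind(cs_control_1 = c(15, 15, 15),
               cs_treatment_1 = c(15, 1, 29),  # x/8 after pseudocount for g2
               fs_control_1 = c(15, 16, 14),
               fs_treatment_1 = c(15, 16, 14))
  # craft exact ratios on the pseudocounted scale instead: totals equal
  mat[, "cs_treatment_1"] <- c(15, 1, 29)
  rownames(mat) <- lib$guide_id
  norm <- normalize_counts(screen_counts(mat, sheet))
  sc <- guide_scores(norm, lib)
  # identical treatment/control -> score 0
  expect_equal(sc$cs[1], 0)
  expect_equal(sc$fs, rep(0, 3))
  # treatment at 1/8 of control abundance -> CS = 3 (depletion positive)
  expect_equal(sc$cs[2], -log2((1 + 1) / (15 + 1)), tolerance = 1e-12)
  expect_equal(sc$cs[2], 3)

  # FS hand example: control 16, treatment 4 (equal totals) -> -2
  mat2 <- cbind(cs_control_1 = c(10, 10), cs_treatment_1 = c(10, 10),
                fs_control_1 = c(15, 3), fs_treatment_1 = c(3, 15))
  lib2 <- tiny_library(1, 2)
  rownames(mat2) <- lib2$guide_id
  sc2 <- guide_scores(normalize_counts(screen_counts(mat2, sheet)), lib2)
  expect_equal(sc2$fs[1], log2(4 / 16))
  expect_equal(sc2$fs[1], -2)
})

test_that("role swap negates every score exactly", {
  lib <- tiny_library(4, 4, n_nontargeting = 3)
  counts <- tiny_counts(lib, replicates = 3)
  swap <- counts$samples
  swap$role <- c(cs_control = "cs_treatment", cs_treatment = "cs_control",
                 fs_control = "fs_treatment",
                 fs_treatment = "fs_control")[swap$role]
  counts_sw <- screen_counts(counts$counts, swap)
  sc <- guide_scores(normalize_counts(counts), lib)
  sc_sw <- guide_scores(normalize_counts(counts_sw), lib)
  expect_equal(sc_sw$cs, -sc$cs, tolerance = 1e-12)
  expect_equal(sc_sw$fs, -sc$fs, tolerance = 1e-12)
})

test_that("gene fitness equals the brute-force per-gene mean (random tables)", {
  for (rep in 1:10) {
    set.seed(rep)
    n_genes <- sample(3:8, 1)
    gpg <- sample(2:6, 1)
    lib <- tiny_library(n_genes, gpg, n_nontargeting = 2)
    cs <- runif(nrow(lib), 0, 8)
    fs <- rnorm(nrow(lib), -1, 2)
    sc <- score_table(lib, cs, fs)
    t_val <- runif(1, 0, 8)
    corrected <- correct_library(lib, sc, t_val)
    genes <- gene_fitness(sc, corrected)
    # independent oracle: loop over genes, mean of retained guide fs
    for (g in unique(lib$gene_id[!lib$nontargeting])) {
      ids <- corrected$retained$guide_id[corrected$retained$gene_id == g]
      expected <- sum(sc$fs[match(ids, sc$guide_id)]) / length(ids)
      expect_equal(genes$fs_g[genes$gene_id == g], expected,
                   tolerance = 1e-12)
      expect_equal(genes$m_g[genes$gene_id == g], length(ids))
    }
    # non-targeting guides never reach the gene table
    expect_false(any(is.na(genes$gene_id)))
    expect_equal(sort(genes$gene_id),
                 sort(unique(lib$gene_id[!lib$nontargeting])))
  }
})

test_that("correction excludes low-CS guides from gene means", {
  lib <- guide_library(c("a", "b"), c("g1", "g1"))
  sc <- score_table(lib, cs = c(5, 1), fs = c(-4, 0))
  genes <- gene_fitness(sc, correct_library(lib, sc, 4.5))
  expect_equal(genes$fs_g, -4)
  expect_equal(genes$m_g, 1)
  # single retained guide keeps its own score
  lib1 <- guide_library("a", "g1")
  sc1 <- score_table(lib1, cs = 2, fs = -1.7)
  g1 <- gene_fitness(sc1, correct_library(lib1, sc1, 0))
  expect_equal(g1$fs_g, -1.7)
  expect_equal(g1$m_g, 1)
})

test_that("external score tables replace computed scores", {
  lib <- tiny_library(2, 2)
  tab <- data.frame(guide_id = lib$guide_id, cs = 1:4, fs = c(-1, 0, 1, 2))
  sc <- attach_external_scores(lib, tab)
  expect_equal(sc$score_source, rep("external", 4))
  expect_equal(sc$cs, 1:4)

  expect_error(attach_external_scores(lib, tab[0, ]), "empty")
  expect_error(attach_external_scores(lib,
                                      data.frame(guide_id = "zzz", cs = 1)),
               "absent from library")
  expect_error(attach_external_scores(lib, tab[1:2, ]), "missing from")
  part <- attach_external_scores(lib, tab[1:2, ], allow_partial = TRUE)
  expect_equal(nrow(part), 4)
  expect_true(anyNA(part$cs))
})

test_that("negative-score diagnostic counts the CS<0 & FS<0 pattern", {
  lib <- tiny_library(1, 4)
  sc <- score_table(lib, cs = c(1, -1, -2, 3), fs = c(-1, 1, -2, -3))
  expect_equal(negative_score_fraction(sc), 25)
  sc0 <- score_table(lib, cs = rep(1, 4), fs = rep(-1, 4))
  expect_equal(negative_score_fraction(sc0), 0)
  scA <- score_table(lib, cs = rep(-1, 4), fs = rep(-1, 4))
  expect_equal(negative_score_fraction(scA), 100)
})
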