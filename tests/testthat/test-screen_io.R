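test_that("guide libraries parse, validate and round-trip", {
  path <- write_tsv_tmp(data.frame(
    guide_id = c("a", "b", "c"), gene_id = c("g1", "g1", "g2"),
    nontargeting = c(0, 0, 0)))
  lib <- read_guide_library(path)
  expect_s3_class(lib, "guide_library")
  expect_equal(nrow(lib), 3)
  expect_equal(length(unique(lib$gene_id)), 2)

  # duplicate guide ids rejected
  bad <- write_tsv_tmp(data.frame(guide_id = c("a", "a"),
                                  gene_id = c("g1", "g2")))
  expect_error(read_guide_library(bad), "duplicate")

  # missing column is a format error
  nog <- write_tsv_tmp(data.frame(guide = "a", gene_id = "g1"))
  expect_error(read_guide_library(nog), "missing required column")

  # empty gene + nontargeting flag -> sentinel entry
  ntp <- write_tsv_tmp(data.frame(guide_id = c("a", "n1"),
                                  gene_id = c("g1", ""),
                                  nontargeting = c(0, 1)))
  lib2 <- read_guide_library(ntp)
  expect_true(lib2$nontargeting[lib2$guide_id == "n1"])
  expect_true(is.na(lib2$gene_id[lib2$guide_id == "n1"]))

  # round-trip is lossless
  out <- tempfile(fileext = ".tsv")
  write_guide_library(lib2, out)
  back <- read_guide_library(out)
  expect_equal(back$guide_id, lib2$guide_id)
  expect_equal(back$gene_id, lib2$gene_id)
  expect_equal(back$nontargeting, lib2$nontargeting)
})

test_that("counts parse with roles attached and bad input is rejected", {
  lib <- tiny_library(2, 2)
  sheet <- default_sheet(1)
  df <- data.frame(guide_id = lib$guide_id,
                   cs_control_1 = c(10, 20, 30, 40),
                   cs_treatment_1 = c(1, 2, 3, 4),
                   fs_control_1 = c(5, 5, 5, 5),
                   fs_treatment_1 = c(9, 9, 9, 9))
  counts <- read_counts(write_tsv_tmp(df), sheet, library = lib)
  expect_equal(ncol(counts$counts), 4)
  expect_equal(sort(unique(counts$samples$role)),
               sort(c("cs_control", "cs_treatment", "fs_control",
                      "fs_treatment")))

  df_bad <- df
  df_bad$cs_control_1[1] <- -3
  expect_error(read_counts(write_tsv_tmp(df_bad), sheet, library = lib),
               "negative")

  # sample sheet naming a missing column is a config error
  sheet_bad <- rbind(sheet, data.frame(sample_id = "ghost",
                                       role = "cs_control", replicate = 2))
  expect_error(read_counts(write_tsv_tmp(df), sheet_bad, library = lib),
               "do not exist")

  # unknown guide dropped with a warning, exclusion counted
  df_extra <- rbind(df, data.frame(guide_id = "rogue", cs_control_1 = 1,
                                   cs_treatment_1 = 1, fs_control_1 = 1,
                                   fs_treatment_1 = 1))
  expect_warning(
    counts2 <- read_counts(write_tsv_tmp(df_extra), sheet, library = lib),
    "absent from library")
  expect_equal(counts2$dropped, "rogue")
  expect_equal(nrow(counts2$counts), 4)
})

test_that("normalisation applies pseudocount and a common scale", {
  lib <- tiny_library(1, 2)
  mat <- matrix(c(1, 3, 0, 50, 10, 10, 10, 10),
                nrow = 2,
                dimnames = list(lib$guide_id,
                                default_sheet(1)$sample_id))
  counts <- screen_counts(mat, default_sheet(1))
  norm <- normalize_counts(counts)
  # raws [1,3], +1 pseudocount -> (2/6, 4/6) * 1e6
  expect_equal(norm$norm[, "cs_control_1"], c(2, 4) / 6 * 1e6,
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero raw count survives via pseudocount
  expect_true(all(norm$norm > 0))
  # equal raw counts -> scale / n each
  expect_equal(unname(norm$norm[, "fs_control_1"]), rep(5e5, 2))
  # every sample sums to the scale
  expect_equal(unname(colSums(norm$norm)), rep(1e6, 4), tolerance = 1e-6)
})

test_that("low-abundance filtering applies the fractional cut and is idempotent", {
  lib <- tiny_library(2, 3)
  sheet <- default_sheet(1)
  # one guide far below 5% of the mean reference abundance
  base <- c(1000, 1000, 1000, 1000, 1000, 4)
  mat <- matrix(rep(base, 4), ncol = 4,
                dimnames = list(lib$guide_id, sheet$sample_id))
  counts <- screen_counts(mat, sheet)
  flt <- filter_low_abundance(counts, lib, fraction = 0.05)
  expect_equal(flt$report$n_removed, 1)
  expect_equal(flt$report$removed, "g02_s3")
  expect_equal(nrow(flt$library), 5)

  # idempotent: re-filtering removes nothing
  flt2 <- filter_low_abundance(flt$counts, flt$library, fraction = 0.05)
  expect_equal(flt2$report$n_removed, 0)

  # all-equal abundances -> nothing removed
  eq <- screen_counts(matrix(100, nrow = 6, ncol = 4,
                             dimnames = list(lib$guide_id,
                                             sheet$sample_id)), sheet)
  expect_equal(filter_low_abundance(eq, lib,
                                    fraction = 0.05)$report$n_removed, 0)

  # the 2.5% tolerance-screen setting removes guides below 2.5% of mean
  mild <- base
  mild[6] <- 33  # ~4% of the library mean: passes 2.5%, fails 5%
  mc <- screen_counts(matrix(rep(mild, 4), ncol = 4,
                             dimnames = list(lib$guide_id,
                                             sheet$sample_id)), sheet)
  expect_equal(filter_low_abundance(mc, lib, reference = "fs_control",
                                    fraction = 0.025)$report$n_removed, 0)
  expect_equal(filter_low_abundance(mc, lib, reference = "fs_control",
                                    fraction = 0.05)$report$n_removed, 1)
})

test_that("replicate correlations cover all pairs with expected signs", {
  lib <- tiny_library(3, 4)
  sheet <- data.frame(sample_id = c("r1", "r2", "r3"),
                      role = "cs_control", replicate = 1:3)
  set.seed(5)
  v <- rpois(12, 200)
  mat <- cbind(r1 = v, r2 = v, r3 = rev(v) + max(v) - v)
  rownames(mat) <- lib$guide_id
  counts <- screen_counts(mat, sheet)
  tab <- replicate_correlation(counts, "cs_control")
  expect_equal(nrow(tab), 3)  # choose(3, 2)
  r12 <- tab$pearson_r[tab$sample_a == "r1" & tab$sample_b == "r2"]
  expect_equal(r12, 1.0)
  # anti-ranked replicate correlates negatively with the originals
  expect_true(tab$pearson_r[tab$sample_a == "r1" & tab$sample_b == "r3"] < 0)

  single <- screen_counts(mat[, 1, drop = FALSE],
                          sheet[1, , drop = FALSE])
  expect_warning(empty <- replicate_correlation(single, "cs_control"),
                 "fewer than 2")
  expect_equal(nrow(empty), 0)
})

test_that("counts round-trip through write/read", {
  lib <- tiny_library(2, 2)
  counts <- tiny_counts(lib)
  path <- tempfile(fileext = ".tsv")
  write_counts(counts, path)
  back <- read_counts(path, counts$samples, library = lib)
  expect_equal(back$counts, counts$counts)
})
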