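# Synthetic pooled-screen generator with ground truth.

#' Simulation configuration
#'
#' Describes a synthetic genome-wide negative-selection screen with two
#' arms: a repair-deficient arm where any productive cut is lethal (so
#' depletion tracks guide activity and yields cutting scores) and a
#' repair-proficient arm where cutting an essential gene is deleterious
#' (yielding fitness scores). Defaults emulate a yeast knockout screen:
#' thousands of genes at ~6 guides/gene, a fifth of genes essential, and a
#' sizeable fraction of inactive guides.
#'
#' Guide activity is a two-component Beta mixture on \[0, 1\]: inactive
#' guides near 0 (`Beta(1.5, 30)`), active guides high (`Beta(6, 2.5)`).
#' A fully active guide depletes by `cs_depletion` log2 units in the
#' repair-deficient arm. Essential genes carry a log2 fitness cost drawn
#' from `Gamma(shape = 1.8, scale = 2.2)` (mean ~4 log2 over the screen,
#' spanning mild to severe); non-essential genes are fitness-neutral up to
#' tiny `Normal(0, 0.02)` jitter. Per-guide effects scale with activity.
#' Initial abundances are lognormal (`sdlog = 0.5`); each replicate is a
#' Dirichlet-multinomial read sample at `depth_per_guide` expected reads
#' per guide; the default `overdispersion = 50` reproduces the
#' replicate-level log2 fold-change noise (~0.4) typical of pooled
#' screens, and 0 gives a clean multinomial.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene guides designed per gene.
#' @param n_nontargeting non-targeting control guides (activity 0).
#' @param essential_fraction fraction of genes that are essential.
#' @param inactive_guide_fraction fraction of targeting guides drawn from
#'   the inactive activity component.
#' @param cs_depletion log2 depletion of a fully active guide in the
#'   repair-deficient arm.
#' @param essential_effect_shape,essential_effect_scale Gamma parameters
#'   of the (negated) essential-gene log2 fitness cost.
#' @param nonessential_effect_sd sd of non-essential gene effects (log2).
#' @param depth_per_guide expected reads per guide per sample.
#' @param replicates replicates per sample role.
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   gives a plain multinomial, larger values add replicate noise
#'   (concentration = n_guides * depth_per_guide / overdispersion).
#' @param initial_sdlog lognormal sdlog of initial guide abundances.
#' @param seed integer seed used by [simulate_screen()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000, guides_per_gene = 6,
                       n_nontargeting = 100, essential_fraction = 0.20,
                       inactive_guide_fraction = 0.40, cs_depletion = 6,
                       essential_effect_shape = 1.8,
                       essential_effect_scale = 2.2,
                       nonessential_effect_sd = 0.02,
                       depth_per_guide = 500, replicates = 3,
                       overdispersion = 50, initial_sdlog = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$guides_per_gene >= 1,
            cfg$essential_fraction >= 0, cfg$essential_fraction <= 1,
            cfg$inactive_guide_fraction >= 0,
            cfg$inactive_guide_fraction <= 1,
            cfg$depth_per_guide > 0, cfg$replicates >= 1,
            cfg$overdispersion >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a pooled CRISPR screen with ground truth
#'
#' Generates a guide library, raw counts for all four sample roles and the
#' underlying truth (per-gene essentiality and effect, per-guide
#' activity). Selection follows exponential growth: relative abundance in
#' the repair-deficient treatment is
#' `initial * 2^(-cs_depletion * activity)`, and in the fitness treatment
#' `initial * 2^(effect_gene * activity)`. Controls sample the initial
#' abundances. Reads are multinomial per replicate, so each sample's
#' counts sum exactly to the configured depth.
#'
#' @param config a [sim_config()].
#' @return list with `library` ([guide_library()]), `counts`
#'   ([screen_counts()] with `replicates` per role), and `truth` (list of
#'   `genes` and `guides` data frames).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  n_t <- config$n_genes * config$guides_per_gene
  guide_gene <- rep(gene_ids, each = config$guides_per_gene)
  guide_ids <- sprintf("%s_g%d", guide_gene,
                       rep(seq_len(config$guides_per_gene), config$n_genes))
  nt_ids <- if (config$n_nontargeting > 0)
    sprintf("nt_%04d", seq_len(config$n_nontargeting)) else character(0)

  essential <- stats::runif(config$n_genes) < config$essential_fraction
  effect <- ifelse(essential,
                   -stats::rgamma(config$n_genes,
                                  shape = config$essential_effect_shape,
                                  scale = config$essential_effect_scale),
                   stats::rnorm(config$n_genes, 0,
                                config$nonessential_effect_sd))

  inactive <- stats::runif(n_t) < config$inactive_guide_fraction
  activity <- ifelse(inactive, stats::rbeta(n_t, 1.5, 30),
                     stats::rbeta(n_t, 6, 2.5))
  all_ids <- c(guide_ids, nt_ids)
  all_activity <- c(activity, rep(0, length(nt_ids)))
  n_all <- length(all_ids)

  guide_effect <- c(effect[match(guide_gene, gene_ids)],
                    rep(0, length(nt_ids)))

  initial <- stats::rlnorm(n_all, 0, config$initial_sdlog)
  rel_cs <- initial * 2^(-config$cs_depletion * all_activity)
  rel_fs <- initial * 2^(guide_effect * all_activity)

  depth <- round(config$depth_per_guide * n_all)
  draw <- function(rel) {
    p <- rel / sum(rel)
    if (config$overdispersion > 0) {
      conc <- depth / config$overdispersion
      g <- stats::rgamma(length(p), shape = p * conc)
      p <- g / sum(g)
    }
    stats::rmultinom(1, depth, p)[, 1]
  }
  roles <- c("cs_control", "cs_treatment", "fs_control", "fs_treatment")
  rels <- list(cs_control = initial, cs_treatment = rel_cs,
               fs_control = initial, fs_treatment = rel_fs)
  sheet <- do.call(rbind, lapply(roles, function(role)
    data.frame(sample_id = sprintf("%s_%d", role,
                                   seq_len(config$replicates)),
               role = role, replicate = seq_len(config$replicates),
               stringsAsFactors = FALSE)))
  mat <- sapply(seq_len(nrow(sheet)), function(i) draw(rels[[sheet$role[i]]]))
  colnames(mat) <- sheet$sample_id
  rownames(mat) <- all_ids

  lib <- guide_library(all_ids,
                       c(guide_gene, rep(NA_character_, length(nt_ids))))
  truth <- list(genes = data.frame(gene_id = gene_ids,
                                   essential = essential, effect = effect,
                                   stringsAsFactors = FALSE),
                guides = data.frame(guide_id = all_ids,
                                    gene_id = c(guide_gene,
                                                rep(NA_character_,
                                                    length(nt_ids))),
                                    activity = all_activity,
                                    stringsAsFactors = FALSE))
  list(library = lib, counts = screen_counts(mat, sheet), truth = truth,
       config = config)
}

#' Write a simulated screen to a directory
#'
#' Emits `library.tsv`, `counts.tsv`, `sample_sheet.tsv`,
#' `truth_genes.tsv`, `truth_guides.tsv`.
#'
#' @param sim result of [simulate_screen()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulated_screen <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_guide_library(sim$library, file.path(dir, "library.tsv"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$counts$samples, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$guides, file.path(dir, "truth_guides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
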