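#' Default CROP-seq sgRNA panel
#'
#' Two sgRNAs per targeted region plus non-targeting controls, mirroring a
#' 40 + 6 design.
#'
#' @param n_targets targeted regions (default 20).
#' @param sgrnas_per_target sgRNAs per region (default 2).
#' @param n_nontargeting non-targeting controls (default 6).
#' @param target_genes optional gene ids recycled over targets; defaults to
#'   synthetic `TGT` labels.
#' @param seed RNG seed.
#' @return data.table (sgrna_id, sequence, target_gene; NA for
#'   non-targeting).
#' @export
make_sgrna_panel <- function(n_targets = 20L, sgrnas_per_target = 2L,
                             n_nontargeting = 6L, target_genes = NULL,
                             seed = 1L) {
  set.seed(seed)
  if (is.null(target_genes)) target_genes <- sprintf("TGT%02d", seq_len(n_targets))
  stopifnot(length(target_genes) == n_targets)
  n <- n_targets * sgrnas_per_target + n_nontargeting
  data.table(
    sgrna_id = c(sprintf("sg%02d", seq_len(n_targets * sgrnas_per_target)),
                 sprintf("NT%02d", seq_len(n_nontargeting))),
    sequence = random_distinct_dna(n, 20L),
    target_gene = c(rep(target_genes, each = sgrnas_per_target),
                    rep(NA_character_, n_nontargeting)))
}

#' Simulate a CROP-seq screen
#'
#' Most cells carry one dominant sgRNA (single infection); a stated fraction
#' are ambiguous doublet-like cells constructed to fail the downstream
#' dominance rule. Target genes of perturbed cells are down-scaled by the
#' planted effect.
#'
#' @param n_cells number of cells (default 2000).
#' @param sgrnas an sgRNA panel from [make_sgrna_panel()].
#' @param n_genes genes in the expression matrix; targeted genes are the
#'   first columns (default 50).
#' @param frac_ambiguous fraction of ambiguous cells (default 0.05).
#' @param effect knockdown multiplier applied to a targeting sgRNA's gene
#'   (default 0.5).
#' @param umi_mean mean UMI count of the dominant sgRNA (default 30).
#' @param seed RNG seed.
#' @return list: `sgrna_counts` (cells x sgRNAs), `expr` (cells x genes),
#'   `truth` (cell_id, sgrna_id, ambiguous), `sgrnas`, `effect_table`.
#' @export
simulate_cropseq <- function(n_cells = 2000L, sgrnas = make_sgrna_panel(),
                             n_genes = 50L, frac_ambiguous = 0.05,
                             effect = 0.5, umi_mean = 30, seed = 1L) {
  set.seed(seed)
  stopifnot(!anyDuplicated(sgrnas$sequence), frac_ambiguous >= 0,
            frac_ambiguous < 1)
  ns <- nrow(sgrnas)
  targets <- unique(sgrnas$target_gene[!is.na(sgrnas$target_gene)])
  genes <- c(targets, sprintf("BG%03d", seq_len(max(0L, n_genes - length(targets)))))
  n_genes <- length(genes)

  n_amb <- round(frac_ambiguous * n_cells)
  amb <- seq_len(n_amb)               # first cells ambiguous, rest single
  truth <- data.table(cell_id = sprintf("cell%05d", seq_len(n_cells)),
                      sgrna_id = sample(sgrnas$sgrna_id, n_cells, replace = TRUE),
                      ambiguous = FALSE)
  truth[amb, `:=`(sgrna_id = NA_character_, ambiguous = TRUE)]

  counts <- matrix(rpois(n_cells * ns, 0.05), n_cells, ns,
                   dimnames = list(truth$cell_id, sgrnas$sgrna_id))
  single <- which(!truth$ambiguous)
  j <- match(truth$sgrna_id[single], sgrnas$sgrna_id)
  counts[cbind(single, j)] <- counts[cbind(single, j)] + rpois(length(single), umi_mean) + 1L
  for (i in amb) {                    # two comparable sgRNAs; redraw until
    repeat {                          # neither dominates at factor 3
      jj <- sample(ns, 2)
      cnt <- rpois(2, umi_mean / 2) + 1L
      counts[i, jj] <- cnt
      tot <- sum(counts[i, ])
      if (all(counts[i, ] < 3 * (tot - counts[i, ]))) break
    }
  }

  base_mu <- rlnorm(n_genes, log(5), 0.5)
  depth <- rlnorm(n_cells, 0, 0.3)
  mu <- outer(depth, base_mu)
  effect_table <- sgrnas[!is.na(target_gene),
                         .(sgrna_id, gene_id = target_gene, effect = effect)]
  for (k in seq_len(nrow(effect_table))) {
    cells <- which(truth$sgrna_id == effect_table$sgrna_id[k])
    g <- match(effect_table$gene_id[k], genes)
    mu[cells, g] <- mu[cells, g] * effect_table$effect[k]
  }
  expr <- matrix(rnbinom(length(mu), mu = mu, size = 2), n_cells, n_genes,
                 dimnames = list(truth$cell_id, genes))
  list(sgrna_counts = counts, expr = expr, truth = truth,
       sgrnas = sgrnas, effect_table = effect_table)
}

#' Simulate a genotyped cohort with a polygenic liability
#'
#' Dosages are binomial(2, MAF) per SNP; the binary phenotype is Bernoulli
#' with logit `alpha + beta_per_sd * z` where `z` is the standardized
#' weighted score and `alpha = logit(prevalence)`.
#'
#' @param n individuals (default 20000).
#' @param n_snps scored SNPs (default 114).
#' @param weights per-SNP effect weights; default N(0, 0.15) draws.
#' @param beta_per_sd log-odds per score SD (default 0.3).
#' @param prevalence baseline case fraction (default 0.2).
#' @param maf_range uniform MAF range (default 0.05-0.5).
#' @param seed RNG seed.
#' @return list: `dosages` (n x n_snps), `weights` (data.table), `phenotype`
#'   (0/1), `score_z` (true standardized score), `params`.
#' @export
simulate_cohort <- function(n = 20000L, n_snps = 114L, weights = NULL,
                            beta_per_sd = 0.3, prevalence = 0.2,
                            maf_range = c(0.05, 0.5), seed = 1L) {
  set.seed(seed)
  stopifnot(n >= 10, n_snps >= 1, prevalence > 0, prevalence < 1)
  if (is.null(weights)) weights <- rnorm(n_snps, 0, 0.15)
  stopifnot(length(weights) == n_snps)
  ids <- sprintf("snp%04d", seq_len(n_snps))
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  dos <- sapply(maf, function(f) rbinom(n, 2L, f))
  dimnames(dos) <- list(sprintf("ind%05d", seq_len(n)), ids)
  raw <- drop(dos %*% weights)
  z <- (raw - mean(raw)) / sd(raw)
  alpha <- qlogis(prevalence)
  y <- rbinom(n, 1L, plogis(alpha + beta_per_sd * z))
  list(dosages = dos,
       weights = data.table(variant_id = ids, weight = weights,
                            effect_allele = "alt", maf = maf),
       phenotype = y, score_z = z,
       params = list(beta_per_sd = beta_per_sd, prevalence = prevalence,
                     seed = seed))
}
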