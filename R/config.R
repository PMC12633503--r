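# Fixed assay sequences. The pairing library read 1 carries the vector/adapter
# sequence immediately 5' of the synthesized oligo; read 2 and the DNA/cDNA
# count libraries carry their own fixed prefixes ahead of the 20-base barcode.
ADAPTER_PAIRING_R1 <- "GGCCTAACTGGCCGGTACCCTGAGTACTGTATGGGCGGGTACC"
ADAPTER_PAIRING_R2 <- "TCACCATGGTGGCTTTACCAACAG"
ADAPTER_COUNT      <- "CTTGGCAATCCGGTACTTAGCGCATCTAAC"
OLIGO_ADAPTER_5    <- "GAGTACTGTATGGGCGGGTACC"
OLIGO_ADAPTER_3    <- "GCTAGCGACAAAAGTGTCAACT"
SGRNA_SEARCH_SEQ   <- "CTTGTGGAAAGGACGAAACACCG"

# ChromHMM core-15 states treated as active chromatin.
ACTIVE_CHROM_STATES <- c(
  "1_TssA", "2_TssAFlank", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG",
  "7_Enh", "8_ZNF/Rpts", "10_TssBiv", "11_BivFlnk", "12_EnhBiv"
)

#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline with its published
#' default. All downstream functions accept a config built here, so a single
#' object documents the analysis settings of a run.
#'
#' @param enhancer_padj BH-adjusted p cutoff for calling an element an
#'   enhancer (default 0.05).
#' @param enhancer_log2fc_min exclusive lower bound on cDNA/DNA log2 fold
#'   change for enhancers (default 0).
#' @param dav_fdr BH FDR cutoff for differential activity variants
#'   (default 0.01).
#' @param specificity_padj adjusted-p cutoff for stimulus-responsive /
#'   cell-type-specific enhancer calls (default 0.05).
#' @param pseudocount added to counts (allele-sum level) before ratios and
#'   logs (default 1).
#' @param map_score_min minimum oligo mapping score, matched bases / total
#'   bases; a score of exactly this value is kept (default 0.95).
#' @param min_trimmed_len minimum retained read-1 length after adapter
#'   removal (default 80).
#' @param adapter_mismatch maximum substitutions tolerated when locating a
#'   fixed adapter (default 2; no indels).
#' @param barcode_len barcode length in bases (default 20).
#' @param oligo_map_len length of the oligo prefix used as mapping reference
#'   (default 107).
#' @param pfm_value_min minimum PFM probability for the motif-disruption
#'   rule (default 0.3, exclusive).
#' @param pfm_ratio_min minimum ref/alt (or alt/ref) PFM probability ratio
#'   for disruption (default 2, exclusive).
#' @param pfm_eps floor applied to PFM probabilities in ratios (default 1e-3).
#' @param motif_halfwidth half-width of the scanned window around a variant
#'   (default 20, i.e. 41-base windows).
#' @param motif_score_frac fraction of the maximum achievable log-odds score
#'   required for a motif match (default 0.8).
#' @param motif_enrich_padj adjusted-p cutoff for motif enrichment
#'   (default 0.01).
#' @param loop_anchor_pad pad added to each loop anchor side for variant
#'   annotation (default 2500).
#' @param loop_anchor_width anchor width after resizing about the midpoint
#'   for loop-based target nomination (default 5000).
#' @param anchor_mode "resize" (to `loop_anchor_width` about the midpoint,
#'   default) or "pad" (add `loop_anchor_width` each side).
#' @param promoter_upstream,promoter_downstream promoter window relative to
#'   the TSS for peak classification (defaults 2000 and 500).
#' @param tss_pad promoter half-width (TSS +/- this) for loop target genes
#'   (default 500).
#' @param proximal_tss_window maximum variant-TSS distance for proximal
#'   target genes, inclusive (default 20000).
#' @param coaccess_min minimum co-accessibility score, exclusive
#'   (default 0.3).
#' @param coaccess_halfwidth co-accessible anchor half-width about its
#'   midpoint (default 2000).
#' @param n_permutations random-region iterations for peak enrichment
#'   (default 1000).
#' @param sgrna_dominance dominance factor k: a cell is assigned to an sgRNA
#'   when its counts are >= k times the sum of all other sgRNA counts
#'   (default 3).
#' @param min_cells_per_sgrna minimum assigned cells for a knockdown test
#'   (default 3).
#' @param de_q q-value cutoff for significant knockdown (default 0.1).
#' @param de_p_suggestive unadjusted-p cutoff for suggestive knockdown
#'   (default 0.05).
#' @param scale_factor library-size scale factor for single-cell
#'   normalization (default 1e4).
#'
#' @return A list of class `mpra_config`.
#' @export
mpra_config <- function(enhancer_padj = 0.05,
                        enhancer_log2fc_min = 0,
                        dav_fdr = 0.01,
                        specificity_padj = 0.05,
                        pseudocount = 1,
                        map_score_min = 0.95,
                        min_trimmed_len = 80,
                        adapter_mismatch = 2,
                        barcode_len = 20,
                        oligo_map_len = 107,
                        pfm_value_min = 0.3,
                        pfm_ratio_min = 2,
                        pfm_eps = 1e-3,
                        motif_halfwidth = 20,
                        motif_score_frac = 0.8,
                        motif_enrich_padj = 0.01,
                        loop_anchor_pad = 2500,
                        loop_anchor_width = 5000,
                        anchor_mode = c("resize", "pad"),
                        promoter_upstream = 2000,
                        promoter_downstream = 500,
                        tss_pad = 500,
                        proximal_tss_window = 20000,
                        coaccess_min = 0.3,
                        coaccess_halfwidth = 2000,
                        n_permutations = 1000,
                        sgrna_dominance = 3,
                        min_cells_per_sgrna = 3,
                        de_q = 0.1,
                        de_p_suggestive = 0.05,
                        scale_factor = 1e4) {
  anchor_mode <- match.arg(anchor_mode)
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  stopifnot(all(vapply(cfg[num], function(x) length(x) == 1 && is.finite(x), logical(1))))
  if (any(unlist(cfg[num]) < 0)) stop("thresholds must be non-negative")
  stopifnot(cfg$pseudocount > 0, cfg$n_permutations >= 1,
            cfg$promoter_upstream >= 0, cfg$promoter_downstream >= 0)
  structure(cfg, class = "mpra_config")
}

#' @export
print.mpra_config <- function(x, ...) {
  cat("mpra_config with", length(x), "settings\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
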