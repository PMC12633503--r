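#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted value of the i-th smallest p is `min over j >= i of
#' min(1, m/j * p_(j))`, which is monotone in rank and capped at 1. NAs are
#' left NA and excluded from the family size.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  stopifnot(all(p[ok] >= 0 & p[ok] <= 1))
  o <- order(p[ok])
  adj <- pmin(1, m / seq_len(m) * p[ok][o])
  adj <- rev(cummin(rev(adj)))
  out[ok][o] <- adj
  out
}

#' Reference/alternative allele count ratios
#'
#' Per variant and sample, the ratio of allele-summed counts with a
#' pseudocount: `R = (ref + pc) / (alt + pc)`. Missing allele rows count as
#' zero, so a variant with neither allele observed has ratio 1.
#'
#' @param counts allele-aggregated count table.
#' @param cfg an [mpra_config()].
#' @return data.table (variant_id, sample_id, molecule, condition, ratio).
#' @export
allelic_ratios <- function(counts, cfg = mpra_config()) {
  counts <- as.data.table(counts)
  pc <- cfg$pseudocount
  w <- dcast(counts, variant_id + sample_id + molecule + condition ~ allele,
             value.var = "count", fill = 0, fun.aggregate = sum)
  if (!"ref" %in% names(w)) w[, ref := 0]
  if (!"alt" %in% names(w)) w[, alt := 0]
  w[, ratio := (ref + pc) / (alt + pc)]
  out <- w[, .(variant_id, sample_id, molecule, condition, ratio)]
  setorder(out, variant_id, sample_id)
  out[]
}

#' Call differential activity variants (DAVs)
#'
#' For each variant with at least one active allele: take the median of the
#' DNA-replicate ratios as the control (computed on the log scale, so an
#' even replicate count uses the geometric mean of the middle pair and
#' allele-label swaps negate the effect exactly), normalize every
#' RNA-replicate ratio by it, and test the log2 normalized RNA ratios
#' against 0 with a
#' one-sample Student's t-test (default). `effect` is the mean log2
#' normalized RNA ratio (positive = reference allele stronger). BH across
#' tested variants; DAVs satisfy `padj < cfg$dav_fdr`. Variants with zero
#' variance across RNA replicates get p = 1 and a degenerate flag.
#'
#' `method = "two_sample"` instead runs a Welch t-test of log2 RNA ratios
#' versus log2 DNA ratios, which also propagates DNA-ratio noise.
#'
#' @param ratios an [allelic_ratios()] table.
#' @param active_variants variant ids with at least one active allele (the
#'   tested family).
#' @param cfg an [mpra_config()].
#' @param method "one_sample" (default) or "two_sample".
#' @return data.table (variant_id, condition, effect, p, padj, is_dav,
#'   degenerate).
#' @export
call_davs <- function(ratios, active_variants, cfg = mpra_config(),
                      method = c("one_sample", "two_sample")) {
  method <- match.arg(method)
  ratios <- as.data.table(ratios)
  cond <- if ("condition" %in% names(ratios)) ratios$condition[1] else "ctrl"
  r <- ratios[variant_id %in% active_variants]
  if (nrow(r) == 0) stop("no active variant present in the ratio table")
  rna <- dcast(r[molecule == "RNA"], variant_id ~ sample_id,
               value.var = "ratio")
  dna <- dcast(r[molecule == "DNA"], variant_id ~ sample_id,
               value.var = "ratio")
  stopifnot(identical(rna$variant_id, dna$variant_id))
  rna_m <- as.matrix(rna, rownames = "variant_id")
  dna_m <- as.matrix(dna, rownames = "variant_id")
  if (ncol(rna_m) < 2) stop("need at least 2 RNA replicates")
  # median of the DNA-replicate ratios, taken on the log scale (for an even
  # replicate count this is the geometric mean of the middle pair), so that
  # swapping the allele labels negates the effect exactly
  m_dna <- 2^apply(log2(dna_m), 1, median)
  lr <- log2(rna_m / m_dna)
  if (method == "one_sample") {
    tt <- row_t1(lr)
    out <- data.table(variant_id = rownames(rna_m), condition = cond,
                      effect = tt$mean, p = tt$p, degenerate = tt$degenerate)
  } else {
    w <- row_welch(lr, log2(dna_m / m_dna))
    out <- data.table(variant_id = rownames(rna_m), condition = cond,
                      effect = rowMeans(lr), p = w$p, degenerate = w$degenerate)
  }
  out[, padj := bh_adjust(p)]
  out[, is_dav := padj < cfg$dav_fdr]
  out[]
}

#' Cross-condition DAV classification
#'
#' Set algebra on DAV flags across two conditions or cell lines. Labels are
#' assigned only to variants tested in both; a variant tested in one
#' condition but untestable in the other (inactive there) is labelled
#' `neither` with `untested = TRUE`, never "specific".
#'
#' @param davs_a,davs_b [call_davs()] tables for conditions A and B.
#' @return data.table (variant_id, in_a, in_b, dav_a, dav_b, label,
#'   untested).
#' @export
classify_context <- function(davs_a, davs_b) {
  a <- as.data.table(davs_a)[, .(variant_id, dav_a = is_dav,
                                 effect_a = effect)]
  b <- as.data.table(davs_b)[, .(variant_id, dav_b = is_dav,
                                 effect_b = effect)]
  out <- merge(a, b, by = "variant_id", all = TRUE)
  out[, `:=`(in_a = !is.na(dav_a), in_b = !is.na(dav_b))]
  out[, untested := !(in_a & in_b)]
  out[, label := fcase(
    in_a & in_b & dav_a & dav_b, "shared",
    in_a & in_b & dav_a & !dav_b, "a_specific",
    in_a & in_b & !dav_a & dav_b, "b_specific",
    default = "neither")]
  out[, .(variant_id, in_a, in_b, dav_a, dav_b, effect_a, effect_b,
          label, untested)]
}
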