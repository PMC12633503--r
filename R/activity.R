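# Vectorized Welch two-sample t-test on the rows of two matrices.
# Returns mean difference (x - y), t, df and two-sided p. Rows where both
# groups have zero variance get p = 1 and a degenerate flag.
row_welch <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(tt), df)
  degen <- se2 == 0
  p[degen] <- 1
  tt[degen] <- 0
  list(diff = mx - my, t = tt, df = df, p = p, degenerate = degen)
}

# One-sample t of each row against 0.
row_t1 <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (n - 1)
  tt <- m / sqrt(v / n)
  p <- 2 * pt(-abs(tt), n - 1)
  degen <- v == 0
  p[degen] <- 1
  tt[degen] <- 0
  list(mean = m, t = tt, p = p, degenerate = degen)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors relative to the geometric-mean
#' pseudo-reference, computed over elements with all-positive counts.
#'
#' @param counts numeric matrix, elements x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no element with all-positive counts; cannot compute size factors")
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(median(col - ref)))
  stopifnot(all(sf > 0))
  sf
}

# Cast an allele-aggregated count table to an element x sample matrix.
counts_matrix <- function(counts, by_allele = TRUE) {
  counts <- as.data.table(counts)
  id <- if (by_allele) counts[, paste0(variant_id, ":", allele)]
        else counts$variant_id
  dt <- data.table(element_id = id, sample_id = counts$sample_id,
                   count = counts$count)
  dt <- dt[, .(count = sum(count)), by = .(element_id, sample_id)]
  w <- dcast(dt, element_id ~ sample_id, value.var = "count", fill = 0)
  m <- as.matrix(w, rownames = "element_id")
  storage.mode(m) <- "double"
  m
}

#' Call transcriptionally active elements
#'
#' Normalizes DNA and RNA samples jointly by median-of-ratios size factors,
#' then per element runs a Welch two-sample t-test of
#' `log2(normalized count + pseudocount)`, RNA replicates versus DNA
#' replicates. `log2fc` is the difference of group means (cDNA/DNA).
#' P-values are BH-adjusted across all tested elements; enhancers satisfy
#' `padj < cfg$enhancer_padj` and `log2fc > cfg$enhancer_log2fc_min`.
#'
#' @param counts allele-aggregated count table (from [tally_counts()] or
#'   [aggregate_allele_counts()]) containing DNA and RNA samples of one
#'   condition.
#' @param cfg an [mpra_config()].
#' @param by_allele test each (variant, allele) element separately (TRUE,
#'   enhancer calling) or merge alleles first (FALSE).
#' @return data.table (element_id, condition, log2fc, p, padj, is_enhancer,
#'   degenerate).
#' @export
call_active_elements <- function(counts, cfg = mpra_config(),
                                 by_allele = TRUE) {
  counts <- as.data.table(counts)
  cond <- if ("condition" %in% names(counts)) counts$condition[1] else "ctrl"
  m <- counts_matrix(counts, by_allele = by_allele)
  mol <- ifelse(grepl("^DNA", colnames(m)), "DNA", "RNA")
  if (sum(mol == "DNA") < 2 || sum(mol == "RNA") < 2)
    stop("need at least 2 replicates per molecule type")
  norm <- sweep(m, 2, size_factors(m), "/")
  lg <- log2(norm + cfg$pseudocount)
  w <- row_welch(lg[, mol == "RNA", drop = FALSE],
                 lg[, mol == "DNA", drop = FALSE])
  out <- data.table(element_id = rownames(m), condition = cond,
                    log2fc = w$diff, p = w$p, degenerate = w$degenerate)
  out[, padj := bh_adjust(p)]
  out[, is_enhancer := padj < cfg$enhancer_padj &
        log2fc > cfg$enhancer_log2fc_min]
  out[]
}

#' Merge allele counts per variant
#'
#' Sums reference and alternative counts for each variant and sample;
#' missing allele rows count as zero.
#'
#' @param counts allele-aggregated count table.
#' @return data.table (variant_id, sample_id, molecule, condition, count).
#' @export
merge_alleles <- function(counts) {
  out <- as.data.table(counts)[, .(count = sum(count)),
                               by = .(variant_id, sample_id, molecule,
                                      condition)]
  setorder(out, variant_id, sample_id)
  out[]
}

#' Stimulus-responsive (or cell-type-specific) elements
#'
#' For every element called an enhancer in at least one of the two
#' conditions, computes the per-replicate activity ratio
#' `(normalized RNA + pseudocount) / (normalized DNA + pseudocount)` with
#' alleles merged, divides all ratios by the median control-replicate ratio,
#' and runs a Welch t-test of the log2 normalized ratios, comparison versus
#' control. BH adjustment across tested elements; responsive elements have
#' `padj < cfg$specificity_padj`. Running it on two cell lines instead of
#' two stimulation states yields cell-type-specific elements.
#'
#' @param counts_ctrl,counts_cmp allele-aggregated count tables for the
#'   control and comparison condition.
#' @param enhancers character vector of variant ids that are enhancers in
#'   either condition (the tested family).
#' @param cfg an [mpra_config()].
#' @return data.table (variant_id, log2fc, p, padj, responsive).
#' @export
condition_response <- function(counts_ctrl, counts_cmp, enhancers,
                               cfg = mpra_config()) {
  if (length(enhancers) == 0) stop("empty enhancer set")
  ratio_mat <- function(counts) {
    m <- counts_matrix(merge_alleles(as.data.table(counts)),
                       by_allele = FALSE)
    norm <- sweep(m, 2, size_factors(m), "/")
    mol <- ifelse(grepl("^DNA", colnames(m)), "DNA", "RNA")
    dna <- norm[, mol == "DNA", drop = FALSE]
    rna <- norm[, mol == "RNA", drop = FALSE]
    if (ncol(dna) != ncol(rna))
      stop("paired replicate ratios need equal DNA and RNA replicate counts")
    (rna + cfg$pseudocount) / (dna + cfg$pseudocount)
  }
  rc <- ratio_mat(counts_ctrl)
  rs <- ratio_mat(counts_cmp)
  common <- intersect(intersect(rownames(rc), rownames(rs)), enhancers)
  if (length(common) == 0) stop("no tested enhancer present in both conditions")
  rc <- rc[common, , drop = FALSE]
  rs <- rs[common, , drop = FALSE]
  ctrl_med <- apply(rc, 1, median)
  lc <- log2(rc / ctrl_med)
  ls <- log2(rs / ctrl_med)
  w <- row_welch(ls, lc)
  out <- data.table(variant_id = common, log2fc = w$diff, p = w$p)
  out[, padj := bh_adjust(p)]
  out[, responsive := padj < cfg$specificity_padj]
  out[]
}
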