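# Internal coordinates are 1-based closed (Bioconductor convention); BED and
# BEDPE files are converted at the I/O boundary.

dt2gr <- function(dt, start_col = "start", end_col = "end") {
  GRanges(dt$chrom, IRanges(dt[[start_col]], dt[[end_col]]))
}

points_gr <- function(dt) GRanges(dt$chrom, IRanges(dt$pos, dt$pos))

# which points fall in any interval
point_in <- function(points_dt, iv_dt) {
  if (nrow(iv_dt) == 0) return(rep(FALSE, nrow(points_dt)))
  countOverlaps(points_gr(points_dt), dt2gr(iv_dt)) > 0
}

#' Read/write BED and BEDPE
#'
#' BED is 0-based half-open on disk; internal tables are 1-based closed.
#'
#' @param path file path.
#' @param extra_cols names for columns beyond chrom/start/end (BED) or the
#'   six anchor columns (BEDPE).
#' @return data.table.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  dt <- fread(path, header = FALSE)
  setnames(dt, 1:3, c("chrom", "start", "end"))
  dt[, start := start + 1L]
  if (!is.null(extra_cols) && ncol(dt) >= 3 + length(extra_cols))
    setnames(dt, 4:(3 + length(extra_cols)), extra_cols)
  dt[]
}

#' @rdname read_bed
#' @param dt interval table (1-based closed).
#' @export
write_bed <- function(dt, path) {
  out <- copy(as.data.table(dt))
  out[, start := start - 1L]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @export
read_bedpe <- function(path, extra_cols = NULL) {
  dt <- fread(path, header = FALSE)
  setnames(dt, 1:6, c("chrom1", "start1", "end1", "chrom2", "start2", "end2"))
  dt[, `:=`(start1 = start1 + 1L, start2 = start2 + 1L)]
  if (!is.null(extra_cols) && ncol(dt) >= 6 + length(extra_cols))
    setnames(dt, 7:(6 + length(extra_cols)), extra_cols)
  dt[]
}

#' @rdname read_bed
#' @export
write_bedpe <- function(dt, path) {
  out <- copy(as.data.table(dt))
  out[, `:=`(start1 = start1 - 1L, start2 = start2 - 1L)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF-like variant table
#'
#' Accepts a plain VCF (CHROM, POS, ID, REF, ALT in the first five columns,
#' `#` headers) or a TSV with columns variant_id, chrom, pos, ref, alt.
#'
#' @param path file path.
#' @return data.table (variant_id, chrom, pos, ref, alt).
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 200)
  if (any(startsWith(first, "#CHROM")) || any(startsWith(first, "##"))) {
    dt <- fread(path, skip = "#CHROM")
    setnames(dt, 1:5, c("chrom", "pos", "variant_id", "ref", "alt"))
    return(dt[, .(variant_id, chrom, pos, ref, alt)])
  }
  dt <- fread(path)
  stopifnot(all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(dt)))
  dt[, .(variant_id, chrom, pos, ref, alt)]
}

# resize/pad loop anchors per config
anchor_intervals <- function(chrom, start, end, cfg) {
  if (cfg$anchor_mode == "resize") {
    mid <- floor((start + end) / 2)
    half <- floor(cfg$loop_anchor_width / 2)
    data.table(chrom = chrom, start = pmax(1L, as.integer(mid - half)),
               end = as.integer(mid + half))
  } else {
    data.table(chrom = chrom,
               start = pmax(1L, as.integer(start - cfg$loop_anchor_width)),
               end = as.integer(end + cfg$loop_anchor_width))
  }
}

#' Annotate variants with functional overlaps
#'
#' Point-in-interval tests on the variant position: accessible-chromatin
#' peak per cell type, active chromatin state, chromatin loop anchor (each
#' anchor padded by `cfg$loop_anchor_pad` on either side) and eQTL
#' membership (identifier join).
#'
#' @param variants data.table (variant_id, chrom, pos).
#' @param bundle an [make_annotations()] bundle (or any list with `peaks`,
#'   `loops`, `chromhmm`, `eqtls`).
#' @param cfg an [mpra_config()].
#' @return data.table of per-variant logical flags.
#' @export
annotate_variants <- function(variants, bundle, cfg = mpra_config()) {
  variants <- as.data.table(variants)
  out <- variants[, .(variant_id, chrom, pos)]
  for (ct in unique(bundle$peaks$celltype)) {
    out[, (paste0("peak_", ct)) :=
          point_in(variants, bundle$peaks[celltype == ct])]
  }
  active <- bundle$chromhmm[state %in% ACTIVE_CHROM_STATES]
  out[, active_state := point_in(variants, active)]
  anchors <- rbind(
    bundle$loops[, .(chrom = chrom1, start = start1, end = end1)],
    bundle$loops[, .(chrom = chrom2, start = start2, end = end2)])
  anchors[, `:=`(start = pmax(1L, start - cfg$loop_anchor_pad),
                 end = end + cfg$loop_anchor_pad)]
  out[, loop_anchor := point_in(variants, anchors)]
  out[, eqtl := variant_id %in%
        bundle$eqtls[significant == TRUE, variant_id]]
  out[]
}

#' Classify peaks as promoters or enhancers
#'
#' A peak overlapping any strand-aware promoter window
#' (`-cfg$promoter_upstream` to `+cfg$promoter_downstream` around a TSS;
#' reversed for minus-strand genes) is a promoter, all others are enhancers.
#'
#' @param peaks interval table (chrom, start, end).
#' @param genes gene table (gene_id, chrom, tss, strand).
#' @param cfg an [mpra_config()].
#' @return the peak table with a `class` column.
#' @export
classify_peaks <- function(peaks, genes, cfg = mpra_config()) {
  peaks <- as.data.table(peaks)
  genes <- as.data.table(genes)
  prom <- genes[, .(chrom,
                    start = pmax(1L, ifelse(strand == "+",
                                            tss - cfg$promoter_upstream,
                                            tss - cfg$promoter_downstream)),
                    end = ifelse(strand == "+",
                                 tss + cfg$promoter_downstream,
                                 tss + cfg$promoter_upstream))]
  ov <- countOverlaps(dt2gr(peaks), dt2gr(prom)) > 0
  out <- copy(peaks)
  out[, class := ifelse(ov, "promoter", "enhancer")]
  out[]
}

#' Peak enrichment of DAVs: permutation and Fisher tests
#'
#' (a) Permutation: `cfg$n_permutations` draws of chromosome-matched random
#' positions (one per DAV, length-matched single-base positions) over the
#' toy genome; empirical p = (1 + #\{permutation overlap >= observed\}) /
#' (N + 1). (b) Fisher's exact test on the 2x2 table of in-peak versus
#' out-of-peak for DAVs versus the non-DAV tested variants.
#'
#' @param davs data.table (variant_id, chrom, pos) of DAVs.
#' @param tested_variants the same columns for all tested variants
#'   (including the DAVs).
#' @param peaks interval table.
#' @param chrom_sizes data.table (chrom, length).
#' @param cfg an [mpra_config()].
#' @param seed RNG seed for the permutations.
#' @return one-row data.table (n_dav, observed, expected_perm, perm_p,
#'   fisher_or, fisher_p).
#' @export
peak_enrichment <- function(davs, tested_variants, peaks, chrom_sizes,
                            cfg = mpra_config(), seed = 1L) {
  set.seed(seed)
  davs <- as.data.table(davs)
  tested_variants <- as.data.table(tested_variants)
  observed <- sum(point_in(davs, peaks))
  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  n <- nrow(davs)
  N <- cfg$n_permutations
  # chromosome-matched random positions, membership tested against the
  # merged per-chromosome peak set with findInterval (fast, GRanges-free)
  peaks <- as.data.table(peaks)
  merged <- lapply(split(peaks, peaks$chrom), function(pk) {
    r <- IRanges::reduce(IRanges(pk$start, pk$end))
    list(start = BiocGenerics::start(r), end = BiocGenerics::end(r))
  })
  perm_ov <- integer(N)
  for (cc in unique(davs$chrom)) {
    idx <- which(davs$chrom == cc)
    pos <- matrix(1L + floor(runif(length(idx) * N) * sizes[[cc]]),
                  nrow = length(idx))
    mg <- merged[[cc]]
    if (is.null(mg)) next
    hit <- {
      j <- findInterval(pos, mg$start)
      j > 0 & pos <= mg$end[pmax(j, 1L)]
    }
    perm_ov <- perm_ov + .colSums(hit, length(idx), N)
  }
  perm_p <- (1 + sum(perm_ov >= observed)) / (N + 1)
  bg <- tested_variants[!variant_id %in% davs$variant_id]
  bg_in <- sum(point_in(bg, peaks))
  tab <- matrix(c(observed, n - observed, bg_in, nrow(bg) - bg_in),
                2, byrow = TRUE)
  ft <- fisher.test(tab)
  data.table(n_dav = n, observed = observed,
             expected_perm = mean(perm_ov), perm_p = perm_p,
             fisher_or = unname(ft$estimate), fisher_p = ft$p.value)
}

#' Nominate target genes by four methods
#'
#' * `proximal`: gene TSS within `cfg$proximal_tss_window` of the variant
#'   (inclusive).
#' * `loop`: loop anchors brought to `cfg$loop_anchor_width` (resized about
#'   the midpoint by default), gene promoter (TSS +/- `cfg$tss_pad`,
#'   inclusive) in one anchor and the variant in the other, either
#'   orientation.
#' * `coaccess`: co-accessible pairs with score strictly greater than
#'   `cfg$coaccess_min`; anchors become midpoint +/-
#'   `cfg$coaccess_halfwidth`; TSS in one anchor and the variant in the
#'   other.
#' * `eqtl`: significant variant-gene pairs joined by identifier.
#'
#' @param davs data.table (variant_id, chrom, pos).
#' @param bundle annotation bundle with `genes`, `loops`, `coaccess`,
#'   `eqtls`.
#' @param cfg an [mpra_config()].
#' @return data.table (variant_id, gene_id, method), unique rows.
#' @export
nominate_targets <- function(davs, bundle, cfg = mpra_config()) {
  davs <- as.data.table(davs)
  genes <- as.data.table(bundle$genes)
  res <- list()

  # proximal: TSS within the window, inclusive
  pj <- genes[davs, on = "chrom", allow.cartesian = TRUE, nomatch = NULL]
  prox <- pj[abs(pos - tss) <= cfg$proximal_tss_window,
             .(variant_id, gene_id, method = "proximal")]
  res$proximal <- prox

  # loop: promoter in one anchor, DAV in the other
  if (nrow(bundle$loops)) {
    a1 <- anchor_intervals(bundle$loops$chrom1, bundle$loops$start1,
                           bundle$loops$end1, cfg)
    a2 <- anchor_intervals(bundle$loops$chrom2, bundle$loops$start2,
                           bundle$loops$end2, cfg)
    gp <- GRanges(genes$chrom, IRanges(pmax(1L, genes$tss - cfg$tss_pad),
                                       genes$tss + cfg$tss_pad))
    vp <- points_gr(davs)
    hit_pairs <- function(anch_v, anch_g) {
      hv <- findOverlaps(vp, dt2gr(anch_v))
      hg <- findOverlaps(gp, dt2gr(anch_g))
      dv <- data.table(variant_id = davs$variant_id[queryHits(hv)],
                       loop = subjectHits(hv))
      dg <- data.table(gene_id = genes$gene_id[queryHits(hg)],
                       loop = subjectHits(hg))
      merge(dv, dg, by = "loop", allow.cartesian = TRUE)[
        , .(variant_id, gene_id)]
    }
    lp <- rbind(hit_pairs(a1, a2), hit_pairs(a2, a1))
    if (nrow(lp)) res$loop <- unique(lp)[, method := "loop"]
  }

  # co-accessibility: strict score threshold, midpoint +/- halfwidth
  ca <- as.data.table(bundle$coaccess)[score > cfg$coaccess_min]
  if (nrow(ca)) {
    mid1 <- floor((ca$start1 + ca$end1) / 2)
    mid2 <- floor((ca$start2 + ca$end2) / 2)
    c1 <- data.table(chrom = ca$chrom1,
                     start = pmax(1L, as.integer(mid1 - cfg$coaccess_halfwidth)),
                     end = as.integer(mid1 + cfg$coaccess_halfwidth))
    c2 <- data.table(chrom = ca$chrom2,
                     start = pmax(1L, as.integer(mid2 - cfg$coaccess_halfwidth)),
                     end = as.integer(mid2 + cfg$coaccess_halfwidth))
    gt <- GRanges(genes$chrom, IRanges(genes$tss, genes$tss))
    vp <- points_gr(davs)
    hit_pairs2 <- function(anch_v, anch_g) {
      hv <- findOverlaps(vp, dt2gr(anch_v))
      hg <- findOverlaps(gt, dt2gr(anch_g))
      dv <- data.table(variant_id = davs$variant_id[queryHits(hv)],
                       pair = subjectHits(hv))
      dg <- data.table(gene_id = genes$gene_id[queryHits(hg)],
                       pair = subjectHits(hg))
      merge(dv, dg, by = "pair", allow.cartesian = TRUE)[
        , .(variant_id, gene_id)]
    }
    cp <- rbind(hit_pairs2(c1, c2), hit_pairs2(c2, c1))
    if (nrow(cp)) res$coaccess <- unique(cp)[, method := "coaccess"]
  }

  # eQTL: identifier join on significant pairs
  eq <- as.data.table(bundle$eqtls)[significant == TRUE &
                                      variant_id %in% davs$variant_id]
  if (nrow(eq)) res$eqtl <- eq[, .(variant_id, gene_id = gene,
                                   method = "eqtl")]

  out <- unique(rbindlist(res, use.names = TRUE))
  setorder(out, variant_id, gene_id, method)
  out[]
}

#' Concordance between MPRA allelic effects and eQTL slopes
#'
#' MPRA effect is mean log2(ref/alt) activity; eQTL slope is per
#' alternative allele. Alt-favoring activity (effect < 0) is concordant
#' with an alt-increasing eQTL (slope > 0): concordant iff
#' `sign(-effect) == sign(slope)`. Zero-effect variants are excluded from
#' the denominator.
#'
#' @param davs [call_davs()] table (variant_id, effect).
#' @param eqtls eQTL table (variant_id, gene, slope, significant).
#' @return list: `fraction_concordant`, `labels` (per variant-gene pair).
#' @export
eqtl_concordance <- function(davs, eqtls) {
  davs <- as.data.table(davs)
  eqtls <- as.data.table(eqtls)[significant == TRUE]
  j <- eqtls[davs, on = "variant_id", nomatch = NULL]
  j <- j[effect != 0 & slope != 0]
  j[, concordant := sign(-effect) == sign(slope)]
  list(fraction_concordant = if (nrow(j)) mean(j$concordant) else NA_real_,
       labels = j[, .(variant_id, gene, effect, slope, concordant)])
}
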