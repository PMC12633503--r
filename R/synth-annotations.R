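#' Generate a synthetic annotation bundle
#'
#' Builds every interval resource the annotation stages consume against the
#' library's toy genome: accessible-chromatin peaks for several cell types,
#' chromatin loops, a gene/TSS table, an eQTL table, co-accessibility pairs
#' and ChromHMM-style state segments, together with planted truth (which
#' variants sit in peaks, which variant-gene pairs are linked by loops and
#' co-accessibility, and which eQTL slopes were signed to agree with the
#' planted allelic effects).
#'
#' All intervals are 1-based closed; BED/BEDPE writers convert on output.
#'
#' @param library an `mpra_library`.
#' @param seed RNG seed.
#' @param truth optional [make_truth()] table used to sign concordant eQTL
#'   slopes.
#' @param celltypes cell-type labels (default hepatocyte, stellate,
#'   cholangiocyte).
#' @param genes_per_chrom genes per chromosome (default 60).
#' @param frac_in_peak fraction of variants planted inside a peak per cell
#'   type (default 0.3).
#' @param frac_looped,frac_coaccess,frac_eqtl fractions of variants with a
#'   planted loop / co-accessibility / eQTL link (defaults 0.3, 0.3, 0.5).
#' @return list of class `mpra_annotations`.
#' @export
make_annotations <- function(library, seed = library$params$seed + 4L,
                             truth = NULL,
                             celltypes = c("hepatocyte", "stellate",
                                           "cholangiocyte"),
                             genes_per_chrom = 60L,
                             frac_in_peak = 0.3,
                             frac_looped = 0.3,
                             frac_coaccess = 0.3,
                             frac_eqtl = 0.5) {
  stopifnot(inherits(library, "mpra_library"))
  set.seed(seed)
  v <- library$variants
  chroms <- names(library$genome)
  clen <- library$params$chrom_len
  chrom_sizes <- data.table(chrom = chroms, length = clen)

  genes <- rbindlist(lapply(chroms, function(cc) data.table(
    chrom = cc,
    tss = sort(sample(2000:(clen - 2000), genes_per_chrom)),
    strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE))))
  genes[, gene_id := sprintf("GENE%04d", seq_len(.N))]
  setcolorder(genes, c("gene_id", "chrom", "tss", "strand"))

  clamp <- function(x, lo = 1L, hi = clen) pmin(pmax(x, lo), hi)

  # peaks: planted around a variant subset per cell type + random decoys
  peaks <- list(); in_peak <- list()
  for (ct in celltypes) {
    pv <- v[sample(.N, round(frac_in_peak * .N))]
    planted <- pv[, .(chrom, start = clamp(pos - 250L), end = clamp(pos + 249L),
                      celltype = ct)]
    rnd_chrom <- sample(chroms, 200, replace = TRUE)
    rnd_start <- sample(clen - 600L, 200)
    decoys <- data.table(chrom = rnd_chrom, start = rnd_start,
                         end = rnd_start + 499L, celltype = ct)
    peaks[[ct]] <- rbind(planted, decoys)
    in_peak[[ct]] <- data.table(variant_id = pv$variant_id, celltype = ct)
  }
  peaks <- rbindlist(peaks)
  in_peak <- rbindlist(in_peak)

  # loops: variant-anchor <-> gene-promoter-anchor, plus random decoys
  lv <- v[sample(.N, round(frac_looped * .N))]
  lg <- genes[lv, on = "chrom", allow.cartesian = TRUE][
    , .SD[sample(.N, 1)], by = "variant_id"]
  loops <- lg[, .(chrom1 = chrom, start1 = clamp(pos - 500L),
                  end1 = clamp(pos + 499L),
                  chrom2 = chrom, start2 = clamp(tss - 400L),
                  end2 = clamp(tss + 399L), source = "synthetic_hic")]
  rnd <- data.table(chrom1 = sample(chroms, 100, replace = TRUE))
  rnd[, `:=`(start1 = sample(clen - 2000L, .N))]
  rnd[, `:=`(end1 = start1 + 999L, chrom2 = chrom1,
             start2 = clamp(start1 + sample(5000:50000, .N)))]
  rnd[, `:=`(end2 = clamp(start2 + 999L), source = "synthetic_decoy")]
  loops <- rbind(loops, rnd)
  loop_pairs <- lg[, .(variant_id, gene_id)]

  # eQTLs: signed to agree with planted allelic effects for a labeled subset
  ev <- v[sample(.N, round(frac_eqtl * .N))]
  eg <- genes[ev, on = "chrom", allow.cartesian = TRUE][
    , .SD[sample(.N, 1)], by = "variant_id"]
  eqtls <- eg[, .(variant_id, gene = gene_id,
                  slope = rnorm(.N, 0, 0.4), significant = TRUE)]
  concordant_set <- character(0)
  if (!is.null(truth)) {
    td <- truth[is_dav == TRUE & variant_id %in% eqtls$variant_id]
    if (nrow(td)) {
      half1 <- td[seq_len(ceiling(.N / 2))]
      # MPRA effect is log2(ref/alt); an alt-favoring variant (effect < 0)
      # is concordant with an alt-increasing eQTL (slope > 0)
      eqtls[half1, on = "variant_id",
            slope := -sign(i.allelic_log2fc) * abs(slope)]
      concordant_set <- half1$variant_id
    }
  }

  # co-accessibility pairs: variant-center <-> TSS-center with score > 0.3
  cv2 <- v[sample(.N, round(frac_coaccess * .N))]
  cg <- genes[cv2, on = "chrom", allow.cartesian = TRUE][
    , .SD[sample(.N, 1)], by = "variant_id"]
  coaccess <- cg[, .(chrom1 = chrom, start1 = clamp(pos - 100L),
                     end1 = clamp(pos + 99L),
                     chrom2 = chrom, start2 = clamp(tss - 100L),
                     end2 = clamp(tss + 99L),
                     score = runif(.N, 0.35, 1))]
  dec <- data.table(chrom1 = sample(chroms, 150, replace = TRUE))
  dec[, start1 := sample(clen - 40000L, .N)]
  dec[, `:=`(end1 = start1 + 199L, chrom2 = chrom1,
             start2 = start1 + sample(2000:30000, .N))]
  dec[, `:=`(end2 = start2 + 199L, score = runif(.N, 0, 0.3))]
  coaccess <- rbind(coaccess, dec)
  coaccess_pairs <- cg[, .(variant_id, gene_id)]

  # ChromHMM-style segmentation: non-overlapping tiles with random states
  states <- c(ACTIVE_CHROM_STATES, "9_Het", "13_ReprPC", "14_ReprPCWk",
              "15_Quies")
  chromhmm <- rbindlist(lapply(chroms, function(cc) {
    bounds <- seq(1L, clen, by = 5000L)
    data.table(chrom = cc, start = bounds,
               end = clamp(bounds + 4999L),
               state = sample(states, length(bounds), replace = TRUE))
  }))

  structure(list(
    chrom_sizes = chrom_sizes, genes = genes, peaks = peaks,
    loops = loops, eqtls = eqtls, coaccess = coaccess,
    chromhmm = chromhmm,
    truth = list(in_peak = in_peak, loop_pairs = loop_pairs,
                 coaccess_pairs = coaccess_pairs,
                 eqtl_concordant = concordant_set)),
    class = "mpra_annotations")
}

#' @export
print.mpra_annotations <- function(x, ...) {
  cat("mpra_annotations:", nrow(x$peaks), "peaks,", nrow(x$loops), "loops,",
      nrow(x$eqtls), "eQTLs,", nrow(x$genes), "genes\n")
  invisible(x)
}
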