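# Independent brute-force oracles; deliberately simple and loop-based so
# they stay independent of the implementation paths they check.

# exhaustive Hamming scan over every reference (the mapping-score oracle)
oracle_map_oligo <- function(query, ref_seqs, min_score = 0.95) {
  len <- min(nchar(query), nchar(ref_seqs[1]))
  q <- strsplit(substr(query, 1, len), "")[[1]]
  matched <- vapply(ref_seqs, function(r) {
    sum(q == strsplit(substr(r, 1, len), "")[[1]])
  }, 0)
  best <- max(matched)
  score <- best / len
  if (score < min_score) return(list(id = NA_character_, score = NA_real_))
  hits <- which(matched == best)
  if (length(hits) > 1) return(list(id = NA_character_, score = NA_real_))
  list(id = names(ref_seqs)[hits], score = score)
}

# the permissive PFM disruption rule, written independently from the text
oracle_disruption <- function(col, ref, alt, vmin = 0.3, rmin = 2,
                              eps = 1e-3) {
  pr <- col[ref]; pa <- col[alt]
  big <- max(pr, pa); small <- min(pr, pa)
  if (small < eps) small <- eps
  (big > vmin) && (big / small > rmin)
}

# direct-product motif scoring of every placement covering the window center
oracle_scan <- function(window, pfm_mat, eps = 1e-3) {
  w <- ncol(pfm_mat)
  wlen <- nchar(window)
  center <- (wlen + 1) / 2
  bases <- strsplit(window, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- NULL
  for (strand in c("+", "-")) {
    for (o in 1:(wlen - w + 1)) {
      if (!(o <= center && center <= o + w - 1)) next
      seg <- bases[o:(o + w - 1)]
      if (strand == "-") seg <- rev(unname(comp[seg]))
      sc <- 0
      for (j in seq_len(w)) {
        p <- pfm_mat[seg[j], j]
        if (p < eps) p <- eps
        sc <- sc + log(p / 0.25)
      }
      out <- rbind(out, data.frame(strand = strand, offset = o, score = sc))
    }
  }
  out
}

# O(n*m) double-loop target nomination oracle
oracle_targets <- function(davs, bundle, cfg) {
  res <- list()
  half_anchor <- floor(cfg$loop_anchor_width / 2)
  for (i in seq_len(nrow(davs))) {
    v <- davs[i, ]
    for (g in seq_len(nrow(bundle$genes))) {
      gn <- bundle$genes[g, ]
      if (gn$chrom == v$chrom && abs(v$pos - gn$tss) <= cfg$proximal_tss_window)
        res[[length(res) + 1]] <- data.frame(variant_id = v$variant_id,
                                             gene_id = gn$gene_id,
                                             method = "proximal")
    }
    for (l in seq_len(nrow(bundle$loops))) {
      lp <- bundle$loops[l, ]
      m1 <- floor((lp$start1 + lp$end1) / 2); m2 <- floor((lp$start2 + lp$end2) / 2)
      a1 <- c(max(1, m1 - half_anchor), m1 + half_anchor)
      a2 <- c(max(1, m2 - half_anchor), m2 + half_anchor)
      v_in1 <- v$chrom == lp$chrom1 && v$pos >= a1[1] && v$pos <= a1[2]
      v_in2 <- v$chrom == lp$chrom2 && v$pos >= a2[1] && v$pos <= a2[2]
      if (!v_in1 && !v_in2) next
      for (g in seq_len(nrow(bundle$genes))) {
        gn <- bundle$genes[g, ]
        ps <- max(1, gn$tss - cfg$tss_pad); pe <- gn$tss + cfg$tss_pad
        g_in1 <- gn$chrom == lp$chrom1 && pe >= a1[1] && ps <= a1[2]
        g_in2 <- gn$chrom == lp$chrom2 && pe >= a2[1] && ps <= a2[2]
        if ((v_in1 && g_in2) || (v_in2 && g_in1))
          res[[length(res) + 1]] <- data.frame(variant_id = v$variant_id,
                                               gene_id = gn$gene_id,
                                               method = "loop")
      }
    }
    for (l in seq_len(nrow(bundle$coaccess))) {
      ca <- bundle$coaccess[l, ]
      if (!(ca$score > cfg$coaccess_min)) next
      m1 <- floor((ca$start1 + ca$end1) / 2); m2 <- floor((ca$start2 + ca$end2) / 2)
      a1 <- c(max(1, m1 - cfg$coaccess_halfwidth), m1 + cfg$coaccess_halfwidth)
      a2 <- c(max(1, m2 - cfg$coaccess_halfwidth), m2 + cfg$coaccess_halfwidth)
      v_in1 <- v$chrom == ca$chrom1 && v$pos >= a1[1] && v$pos <= a1[2]
      v_in2 <- v$chrom == ca$chrom2 && v$pos >= a2[1] && v$pos <= a2[2]
      if (!v_in1 && !v_in2) next
      for (g in seq_len(nrow(bundle$genes))) {
        gn <- bundle$genes[g, ]
        g_in1 <- gn$chrom == ca$chrom1 && gn$tss >= a1[1] && gn$tss <= a1[2]
        g_in2 <- gn$chrom == ca$chrom2 && gn$tss >= a2[1] && gn$tss <= a2[2]
        if ((v_in1 && g_in2) || (v_in2 && g_in1))
          res[[length(res) + 1]] <- data.frame(variant_id = v$variant_id,
                                               gene_id = gn$gene_id,
                                               method = "coaccess")
      }
    }
    for (e in seq_len(nrow(bundle$eqtls))) {
      eq <- bundle$eqtls[e, ]
      if (isTRUE(eq$significant) && eq$variant_id == v$variant_id)
        res[[length(res) + 1]] <- data.frame(variant_id = v$variant_id,
                                             gene_id = eq$gene,
                                             method = "eqtl")
    }
  }
  if (!length(res)) return(data.frame(variant_id = character(0),
                                      gene_id = character(0),
                                      method = character(0)))
  unique(do.call(rbind, res))
}

# the sgRNA dominance rule applied literally to one count vector
oracle_assign <- function(counts, k = 3) {
  if (sum(counts) == 0) return(NA_character_)
  top <- max(counts)
  if (sum(counts == top) > 1) return(NA_character_)
  s <- which.max(counts)
  if (counts[s] >= k * sum(counts[-s])) names(counts)[s] else NA_character_
}

# key for comparing nomination tables as sets
pair_key <- function(df) sort(paste(df$variant_id, df$gene_id, df$method))

tiny_library <- function(n_variants = 30, seed = 11, ...) {
  p <- sim_params(n_variants = n_variants, barcodes_per_allele = 5,
                  bc_sdlog = 0, depth = 50, seed = seed, ...)
  make_library(p)
}
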