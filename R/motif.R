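#' Construct a position frequency matrix object
#'
#' @param mat 4 x w numeric matrix, rows A, C, G, T; columns are normalized
#'   to probabilities.
#' @param motif_id identifier.
#' @param name optional TF name.
#' @return list of class `mpra_pfm`.
#' @export
pfm <- function(mat, motif_id, name = motif_id) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, ncol(mat) >= 4, all(mat >= 0))
  rownames(mat) <- DNA_BASES
  cs <- colSums(mat)
  stopifnot(all(cs > 0))
  mat <- sweep(mat, 2, cs, "/")
  stopifnot(all(abs(colSums(mat) - 1) < 1e-6))
  structure(list(motif_id = motif_id, name = name, mat = mat),
            class = "mpra_pfm")
}

#' @export
print.mpra_pfm <- function(x, ...) {
  cat("PFM", x$motif_id, "(", x$name, "), width", ncol(x$mat), "\n")
  invisible(x)
}

pfm_width <- function(p) ncol(p$mat)

#' Read JASPAR-format PFM files
#'
#' Parses the four-row `A [ counts... ]` layout under `>ID NAME` headers and
#' normalizes counts to per-column probabilities.
#'
#' @param path JASPAR file.
#' @return named list of `mpra_pfm` objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR records in ", path)
  out <- list()
  for (i in seq_along(hdr)) {
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    block <- lines[(hdr[i] + 1):to]
    meta <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]]
    rows <- lapply(block[1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.eE+-]+", sub("^[ACGT]", "", l)))[[1]]
      as.numeric(nums)
    })
    bases <- toupper(substr(trimws(block[1:4]), 1, 1))
    mat <- do.call(rbind, rows)[match(DNA_BASES, bases), , drop = FALSE]
    id <- meta[1]
    out[[id]] <- pfm(mat, id, if (length(meta) > 1) meta[2] else id)
  }
  out
}

#' Write PFMs in JASPAR format
#'
#' @param pfms list of `mpra_pfm`.
#' @param path output path.
#' @export
write_jaspar <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", p$motif_id, " ", p$name), con)
    for (b in DNA_BASES)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(formatC(p$mat[b, ], format = "f", digits = 6),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Random synthetic PFMs
#'
#' Each column has one dominant base, giving informative motifs for the
#' scanner and disruption rule.
#'
#' @param n number of motifs (default 8).
#' @param width_range inclusive motif-width range (default 6-12).
#' @param dominance range of the dominant-base probability (default
#'   0.6-0.95).
#' @param seed RNG seed.
#' @return named list of `mpra_pfm` objects.
#' @export
random_pfms <- function(n = 8L, width_range = c(6L, 12L),
                        dominance = c(0.6, 0.95), seed = 1L) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n)) {
    w <- sample(width_range[1]:width_range[2], 1)
    mat <- matrix(0, 4, w)
    for (j in seq_len(w)) {
      d <- runif(1, dominance[1], dominance[2])
      rest <- runif(3)
      col <- rep((1 - d) * rest / sum(rest), 1)
      mat[, j] <- append(col, d, after = sample(0:3, 1))[1:4] # dominant slot
      mat[, j] <- mat[, j] / sum(mat[, j])
    }
    id <- sprintf("MA%04d.1", i)
    out[[id]] <- pfm(mat, id, sprintf("SYNTF%02d", i))
  }
  out
}

# log-odds score of a window segment under a PFM with uniform background
# and an epsilon floor; strand "-" scores the reverse complement.
pfm_logodds <- function(p, seg, strand = "+", eps = 1e-3) {
  if (strand == "-") seg <- revcomp(seg)
  bases <- strsplit(seg, "", fixed = TRUE)[[1]]
  probs <- pmax(p$mat[cbind(match(bases, DNA_BASES), seq_along(bases))], eps)
  sum(log(probs / 0.25))
}

pfm_max_score <- function(p, eps = 1e-3) {
  sum(log(pmax(apply(p$mat, 2, max), eps) / 0.25))
}

# PFM column index aligned to a window position for a placement
# (offset = 1-based motif start in the window). On the minus strand the
# motif is read right-to-left with complemented bases.
snp_column <- function(offset, center, width, strand) {
  if (strand == "+") center - offset + 1L else width - (center - offset)
}

#' Scan allele windows for motif matches covering the variant
#'
#' Builds the reference- and alternative-substituted windows of
#' `2 * cfg$motif_halfwidth + 1` bases centered on the variant, scores every
#' placement of the PFM that covers the center position on both strands,
#' and keeps placements whose log-odds score (uniform background) reaches
#' `cfg$motif_score_frac` of the motif's maximum achievable score in either
#' allele's window.
#'
#' @param variant one-row data.frame/list with `chrom`, `pos`, `ref`, `alt`.
#' @param genome named character vector of chromosome sequences.
#' @param pfm_obj an `mpra_pfm`.
#' @param cfg an [mpra_config()].
#' @return data.table (motif_id, strand, offset, snp_col, score_ref,
#'   score_alt, rel_ref, rel_alt, match); empty when the window is truncated
#'   by the contig edge (with a warning).
#' @export
scan_variant_window <- function(variant, genome, pfm_obj,
                                cfg = mpra_config()) {
  hw <- cfg$motif_halfwidth
  wlen <- 2L * hw + 1L
  chromseq <- genome[[variant$chrom]]
  if (variant$pos - hw < 1 || variant$pos + hw > nchar(chromseq)) {
    warning("window truncated by contig edge for variant at ",
            variant$chrom, ":", variant$pos, "; skipped")
    return(data.table())
  }
  win <- substr(chromseq, variant$pos - hw, variant$pos + hw)
  center <- hw + 1L
  win_ref <- win; substr(win_ref, center, center) <- variant$ref
  win_alt <- win; substr(win_alt, center, center) <- variant$alt
  w <- pfm_width(pfm_obj)
  offsets <- max(1L, center - w + 1L):min(center, wlen - w + 1L)
  smax <- pfm_max_score(pfm_obj, cfg$pfm_eps)
  # numeric core: per-column log-odds looked up by base index; the minus
  # strand scores the reverse complement via index arithmetic (5 - idx)
  lp <- log(pmax(pfm_obj$mat, cfg$pfm_eps) / 0.25)
  ir <- match(strsplit(win_ref, "", fixed = TRUE)[[1]], DNA_BASES)
  ia <- match(strsplit(win_alt, "", fixed = TRUE)[[1]], DNA_BASES)
  k <- length(offsets)
  strands <- rep(c("+", "-"), each = k)
  offs <- rep(offsets, 2L)
  sr <- sa <- numeric(2L * k)
  cols <- integer(2L * k)
  jj <- seq_len(w)
  for (i in seq_along(offs)) {
    o <- offs[i]
    if (strands[i] == "+") {
      sel <- cbind(ir[o + jj - 1L], jj)
      sela <- cbind(ia[o + jj - 1L], jj)
    } else {
      sel <- cbind(5L - ir[o + w - jj], jj)
      sela <- cbind(5L - ia[o + w - jj], jj)
    }
    sr[i] <- sum(lp[sel])
    sa[i] <- sum(lp[sela])
    cols[i] <- snp_column(o, center, w, strands[i])
  }
  data.table(motif_id = pfm_obj$motif_id, strand = strands, offset = offs,
             snp_col = cols, score_ref = sr, score_alt = sa,
             rel_ref = sr / smax, rel_alt = sa / smax,
             match = pmax(sr, sa) >= cfg$motif_score_frac * smax)
}

#' Apply the permissive motif-disruption rule
#'
#' Reads the PFM column aligned to the variant (complemented bases, columns
#' right-to-left on the minus strand) and flags the motif as interrupted
#' when either allele's PFM value exceeds `cfg$pfm_value_min` and the
#' larger-to-smaller ratio (smaller floored at `cfg$pfm_eps`) exceeds
#' `cfg$pfm_ratio_min`.
#'
#' @param pfm_obj an `mpra_pfm`.
#' @param snp_col PFM column (1-based) aligned to the variant.
#' @param strand "+" or "-".
#' @param ref_base,alt_base the two alleles (plus-strand bases).
#' @param cfg an [mpra_config()].
#' @return one-row data.table (motif_id, strand, snp_col, p_ref, p_alt,
#'   interrupted).
#' @export
call_disruption <- function(pfm_obj, snp_col, strand, ref_base, alt_base,
                            cfg = mpra_config()) {
  if (strand == "-") {
    ref_base <- comp_base(ref_base)
    alt_base <- comp_base(alt_base)
  }
  pr <- pfm_obj$mat[ref_base, snp_col]
  pa <- pfm_obj$mat[alt_base, snp_col]
  hi <- max(pr, pa)
  lo <- max(min(pr, pa), cfg$pfm_eps)
  data.table(motif_id = pfm_obj$motif_id, strand = strand,
             snp_col = snp_col, p_ref = pr, p_alt = pa,
             interrupted = hi > cfg$pfm_value_min &
               hi / lo > cfg$pfm_ratio_min)
}

#' Motif disruption calls for a variant set
#'
#' Scans every variant against every PFM and applies the disruption rule at
#' each matching placement; a motif is reported interrupted for a variant if
#' any matching placement is interrupted.
#'
#' @param variants data.table (variant_id, chrom, pos, ref, alt).
#' @param genome named character vector.
#' @param pfms list of `mpra_pfm`.
#' @param cfg an [mpra_config()].
#' @return data.table (variant_id, motif_id, n_matches, interrupted).
#' @export
disruption_calls <- function(variants, genome, pfms, cfg = mpra_config()) {
  variants <- as.data.table(variants)
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i]
    for (p in pfms) {
      sc <- scan_variant_window(v, genome, p, cfg)
      if (!nrow(sc)) next
      sc <- sc[match == TRUE]
      if (!nrow(sc)) {
        out[[length(out) + 1L]] <- data.table(
          variant_id = v$variant_id, motif_id = p$motif_id,
          n_matches = 0L, interrupted = FALSE)
        next
      }
      # inline disruption rule over matching placements (strand-aware column)
      rb <- ifelse(sc$strand == "-", comp_base(v$ref), v$ref)
      ab <- ifelse(sc$strand == "-", comp_base(v$alt), v$alt)
      pr <- p$mat[cbind(match(rb, DNA_BASES), sc$snp_col)]
      pa <- p$mat[cbind(match(ab, DNA_BASES), sc$snp_col)]
      hi <- pmax(pr, pa)
      lo <- pmax(pmin(pr, pa), cfg$pfm_eps)
      out[[length(out) + 1L]] <- data.table(
        variant_id = v$variant_id, motif_id = p$motif_id,
        n_matches = nrow(sc),
        interrupted = any(hi > cfg$pfm_value_min &
                            hi / lo > cfg$pfm_ratio_min))
    }
  }
  rbindlist(out)
}

#' Likelihood agreement ratio between allele windows
#'
#' Ratio of PFM likelihoods (product of epsilon-floored column
#' probabilities) of the alternative window over the reference window at a
#' given placement: how many fold better the alternative allele agrees with
#' the motif consensus.
#'
#' @param window_ref,window_alt equal-length allele windows.
#' @param pfm_obj an `mpra_pfm`.
#' @param offset 1-based placement of the motif in the window.
#' @param strand "+" or "-".
#' @param eps probability floor (default 1e-3).
#' @return positive scalar.
#' @export
allele_agreement_ratio <- function(window_ref, window_alt, pfm_obj,
                                   offset, strand = "+", eps = 1e-3) {
  stopifnot(nchar(window_ref) == nchar(window_alt))
  w <- pfm_width(pfm_obj)
  lik <- function(win) {
    exp(pfm_logodds(pfm_obj, substr(win, offset, offset + w - 1L),
                    strand, eps))
  }
  lik(window_alt) / lik(window_ref)
}

#' Motif enrichment of DAVs versus background
#'
#' Per motif, Fisher's exact test on the 2x2 table of disrupting versus
#' non-disrupting variants among DAVs versus background variants, BH
#' adjusted; enriched motifs have `padj < cfg$motif_enrich_padj`.
#'
#' @param dav_calls [disruption_calls()] for the DAV set.
#' @param background_calls [disruption_calls()] for the background set
#'   (e.g. all tested variants).
#' @param cfg an [mpra_config()].
#' @return data.table (motif_id, dav_disrupt, dav_total, bg_disrupt,
#'   bg_total, odds_ratio, p, padj, enriched).
#' @export
motif_enrichment <- function(dav_calls, background_calls,
                             cfg = mpra_config()) {
  dav_calls <- as.data.table(dav_calls)
  background_calls <- as.data.table(background_calls)
  if (nrow(dav_calls) == 0 || length(unique(dav_calls$variant_id)) == 0)
    stop("empty DAV set")
  n_dav <- length(unique(dav_calls$variant_id))
  n_bg <- length(unique(background_calls$variant_id))
  motifs <- unique(c(dav_calls$motif_id, background_calls$motif_id))
  rows <- lapply(motifs, function(m) {
    a <- dav_calls[motif_id == m & interrupted == TRUE,
                   length(unique(variant_id))]
    c_ <- background_calls[motif_id == m & interrupted == TRUE,
                           length(unique(variant_id))]
    tab <- matrix(c(a, n_dav - a, c_, n_bg - c_), 2, byrow = TRUE)
    ft <- fisher.test(tab)
    data.table(motif_id = m, dav_disrupt = a, dav_total = n_dav,
               bg_disrupt = c_, bg_total = n_bg,
               odds_ratio = (a * (n_bg - c_)) /
                 max(1e-12, (n_dav - a) * c_),
               p = ft$p.value)
  })
  out <- rbindlist(rows)
  out[, padj := bh_adjust(p)]
  out[, enriched := padj < cfg$motif_enrich_padj]
  out[]
}
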