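#' Build the CROP-seq pseudo-gene reference
#'
#' One record per sgRNA: a fixed upstream segment (U6 promoter context),
#' the 20-base protospacer, and a fixed downstream segment (LTR context),
#' 500 bases in total with the default flank lengths. Duplicate protospacer
#' sequences are an error.
#'
#' @param sgrnas data.table (sgrna_id, sequence).
#' @param flank_up upstream segment (default: deterministic 250-base
#'   synthetic U6 stand-in).
#' @param flank_down downstream segment (default: deterministic 230-base
#'   synthetic LTR stand-in).
#' @return list: `fasta` (named character vector of records), `annotation`
#'   (data.table sgrna_id, length, sgrna_start, sgrna_end).
#' @export
build_pseudogene_reference <- function(sgrnas,
                                       flank_up = NULL,
                                       flank_down = NULL) {
  sgrnas <- as.data.table(sgrnas)
  if (anyDuplicated(sgrnas$sequence))
    stop("duplicate sgRNA sequence in whitelist")
  if (is.null(flank_up)) {
    set.seed(104729L)  # fixed: synthetic U6/LTR stand-ins, not real sequence
    flank_up <- random_dna(1, 250L)
    flank_down <- random_dna(1, 230L)
  }
  rec <- paste0(flank_up, sgrnas$sequence, flank_down)
  names(rec) <- sgrnas$sgrna_id
  ann <- data.table(sgrna_id = sgrnas$sgrna_id,
                    length = nchar(rec),
                    sgrna_start = nchar(flank_up) + 1L,
                    sgrna_end = nchar(flank_up) + nchar(sgrnas$sequence))
  list(fasta = rec, annotation = ann)
}

#' Extract sgRNA identity from enrichment reads
#'
#' Finds the fixed search sequence preceding the protospacer, takes the
#' following 20 bases and matches the whitelist exactly (optional
#' one-mismatch rescue).
#'
#' @param reads character vector.
#' @param whitelist data.table (sgrna_id, sequence).
#' @param search_seq fixed sequence preceding the sgRNA.
#' @param allow_mismatch rescue 20-mers at Hamming distance 1 from a unique
#'   whitelist entry (default FALSE).
#' @return character vector of sgRNA ids (`NA` where not found), with a
#'   `qc` attribute.
#' @export
extract_sgrna <- function(reads, whitelist, search_seq = SGRNA_SEARCH_SEQ,
                          allow_mismatch = FALSE) {
  whitelist <- as.data.table(whitelist)
  a <- find_adapter(reads, search_seq, max_mm = 0L)
  raw <- ifelse(is.na(a), NA_character_, substr(reads, a, a + 19L))
  raw[!is.na(raw) & nchar(raw) < 20L] <- NA_character_
  id <- whitelist$sgrna_id[match(raw, whitelist$sequence)]
  if (allow_mismatch) {
    miss <- which(!is.na(raw) & is.na(id))
    for (i in miss) {
      d <- vapply(whitelist$sequence, function(s) str_mismatches(raw[i], s), 0L)
      hit <- which(d == 1L)
      if (length(hit) == 1L) id[i] <- whitelist$sgrna_id[hit]
    }
  }
  attr(id, "qc") <- data.table(
    metric = c("reads_in", "search_seq_found", "whitelist_matched"),
    n = c(length(reads), sum(!is.na(raw)), sum(!is.na(id))))
  id
}

#' Assign cells to sgRNAs by the dominance rule
#'
#' A cell is assigned to sgRNA s iff `count_s >= k * sum(other counts)`
#' (boundary counts as dominant) and s is the unique maximum; otherwise the
#' cell is unassigned with reason `no_reads` or `ambiguous`. Assignment is
#' scale-invariant per cell.
#'
#' @param mat cells x sgRNAs count matrix.
#' @param k dominance factor (default 3).
#' @return data.table (cell_id, sgrna_id, reason) with reason in
#'   dominant / no_reads / ambiguous.
#' @export
assign_cells <- function(mat, k = 3) {
  mat <- as.matrix(mat)
  stopifnot(!is.null(colnames(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("cell", seq_len(nrow(mat)))
  tot <- rowSums(mat)
  top <- apply(mat, 1, max)
  n_top <- rowSums(mat == top & mat > 0)
  dominant <- tot > 0 & n_top == 1 & top >= k * (tot - top)
  sg <- colnames(mat)[max.col(mat, ties.method = "first")]
  out <- data.table(
    cell_id = rownames(mat),
    sgrna_id = ifelse(dominant, sg, NA_character_),
    reason = fcase(tot == 0, "no_reads",
                   dominant, "dominant",
                   default = "ambiguous"))
  out[]
}

#' Test nominated target genes for knockdown
#'
#' Expression is depth-normalized (`log1p(count / cell_total * scale)`,
#' scale `cfg$scale_factor`). For each (sgRNA, gene) pair, a Welch t-test
#' compares the gene's normalized expression in cells assigned to that
#' sgRNA against all other assigned cells; unassigned cells are excluded.
#' BH across tested pairs gives q; pairs are `significant` at
#' `q < cfg$de_q`, `suggestive` at `p < cfg$de_p_suggestive`, else `ns`.
#' Pairs whose sgRNA has fewer than `cfg$min_cells_per_sgrna` assigned
#' cells are skipped and reported.
#'
#' @param expr cells x genes count matrix.
#' @param assignment an [assign_cells()] table.
#' @param pairs data.table (sgrna_id, gene_id).
#' @param cfg an [mpra_config()].
#' @return list: `results` (sgrna_id, gene_id, n_cells, lfc, p, q, class),
#'   `skipped` (pairs below the cell minimum).
#' @export
target_de <- function(expr, assignment, pairs, cfg = mpra_config()) {
  expr <- as.matrix(expr)
  assignment <- as.data.table(assignment)
  pairs <- as.data.table(pairs)
  assigned <- assignment[!is.na(sgrna_id)]
  expr <- expr[assigned$cell_id, , drop = FALSE]
  norm <- log1p(expr / pmax(rowSums(expr), 1) * cfg$scale_factor)
  res <- list(); skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$sgrna_id[i]; g <- pairs$gene_id[i]
    if (!g %in% colnames(norm)) next
    grp <- assigned$sgrna_id == s
    if (sum(grp) < cfg$min_cells_per_sgrna || sum(!grp) < 2) {
      skipped[[length(skipped) + 1L]] <-
        data.table(sgrna_id = s, gene_id = g, n_cells = sum(grp))
      next
    }
    x <- norm[grp, g]; y <- norm[!grp, g]
    w <- row_welch(matrix(x, 1), matrix(y, 1))
    res[[length(res) + 1L]] <- data.table(
      sgrna_id = s, gene_id = g, n_cells = sum(grp),
      lfc = w$diff, p = w$p)
  }
  results <- rbindlist(res)
  if (nrow(results)) {
    results[, q := bh_adjust(p)]
    results[, class := fcase(q < cfg$de_q, "significant",
                             p < cfg$de_p_suggestive, "suggestive",
                             default = "ns")]
  }
  list(results = results,
       skipped = if (length(skipped)) rbindlist(skipped) else data.table())
}
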