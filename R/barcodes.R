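#' Build an oligo mapping reference
#'
#' The first `map_len` bases of each synthesized oligo insert form the
#' mapping reference. A byte matrix and an exact-match hash are precomputed
#' so queries can be scored quickly.
#'
#' @param oligo_seqs named character vector (oligo_id -> insert sequence,
#'   or full synthesized oligo — a leading 5' oligo adapter is stripped) or
#'   an `mpra_library`.
#' @param map_len reference length (default 107).
#' @return list of class `oligo_reference`.
#' @export
oligo_reference <- function(oligo_seqs, map_len = 107L) {
  if (inherits(oligo_seqs, "mpra_library"))
    oligo_seqs <- setNames(oligo_seqs$oligos$insert, oligo_seqs$oligos$oligo_id)
  if (length(oligo_seqs) == 0) stop("empty oligo reference")
  if (anyDuplicated(names(oligo_seqs))) stop("duplicate oligo ids")
  if (all(startsWith(oligo_seqs, OLIGO_ADAPTER_5)))
    oligo_seqs <- substr(oligo_seqs, nchar(OLIGO_ADAPTER_5) + 1L,
                         nchar(oligo_seqs))
  seqs <- substr(oligo_seqs, 1L, map_len)
  if (any(nchar(seqs) < map_len))
    stop("all reference oligos must be at least ", map_len, " bases")
  tmat <- matrix(unlist(lapply(seqs, charToRaw), use.names = FALSE),
                 nrow = map_len, ncol = length(seqs))
  hash <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) assign(seqs[[i]], names(seqs)[i], envir = hash)
  structure(list(ids = names(seqs), seqs = unname(seqs), tmat = tmat,
                 hash = hash, map_len = map_len),
            class = "oligo_reference")
}

#' Trim pairing-library read pairs
#'
#' R1: locate the fixed adapter (at most `cfg$adapter_mismatch`
#' substitutions, no indels) and keep the suffix; discard reads without the
#' adapter or with suffixes shorter than `cfg$min_trimmed_len`. R2: locate
#' its adapter and keep the following `cfg$barcode_len` bases. A pair is
#' retained only if both reads survive.
#'
#' @param r1,r2 character vectors of raw read sequences.
#' @param cfg an [mpra_config()].
#' @return list: `oligo_query`, `barcode` (NA where discarded), `keep`
#'   logical, `qc` data.table of discard reasons.
#' @export
trim_pairing_pair <- function(r1, r2, cfg = mpra_config()) {
  stopifnot(length(r1) == length(r2))
  a1 <- find_adapter(r1, ADAPTER_PAIRING_R1, cfg$adapter_mismatch)
  oligo <- ifelse(is.na(a1), NA_character_, substr(r1, a1, nchar(r1)))
  short <- !is.na(oligo) & nchar(oligo) < cfg$min_trimmed_len
  oligo[short] <- NA_character_

  a2 <- find_adapter(r2, ADAPTER_PAIRING_R2, cfg$adapter_mismatch)
  bc <- ifelse(is.na(a2), NA_character_,
               substr(r2, a2, a2 + cfg$barcode_len - 1L))
  bc[!is.na(bc) & nchar(bc) < cfg$barcode_len] <- NA_character_

  qc <- data.table(
    reason = c("r1_untrimmed", "r1_too_short", "r2_untrimmed", "kept"),
    n = c(sum(is.na(a1)), sum(short), sum(is.na(bc)),
          sum(!is.na(oligo) & !is.na(bc))))
  list(oligo_query = oligo, barcode = bc,
       keep = !is.na(oligo) & !is.na(bc), qc = qc)
}

#' Map oligo queries to the reference
#'
#' Mapping score = matched bases / total bases over the first
#' `min(length(query), map_len)` bases. An exact-match hash serves as fast
#' path; everything else is scored by an exhaustive Hamming scan over all
#' references, so the result equals the brute-force oracle by construction.
#' Queries whose best score is below `cfg$map_score_min` (a score of exactly
#' the cutoff is kept) or that tie between distinct oligos return `NA`.
#'
#' @param queries character vector (each at least 80 bases).
#' @param ref an [oligo_reference()].
#' @param cfg an [mpra_config()].
#' @return data.table (oligo_id, score); `NA` rows for dropped queries.
#' @export
map_oligo <- function(queries, ref, cfg = mpra_config()) {
  stopifnot(inherits(ref, "oligo_reference"))
  L <- ref$map_len
  n <- length(queries)
  out_id <- rep(NA_character_, n)
  out_score <- rep(NA_real_, n)
  if (n == 0) return(data.table(oligo_id = out_id, score = out_score))
  q107 <- substr(queries, 1L, L)
  exact <- !is.na(queries) & nchar(q107) == L &
    vapply(q107, function(s) !is.null(get0(s, envir = ref$hash)), logical(1))
  out_id[exact] <- vapply(q107[exact], function(s) get(s, envir = ref$hash), "")
  out_score[exact] <- 1
  n_ref <- ncol(ref$tmat)
  for (i in which(!exact & !is.na(queries))) {
    len <- min(nchar(queries[i]), L)
    qr <- charToRaw(substr(queries[i], 1L, len))
    tm <- if (len == L) ref$tmat else ref$tmat[seq_len(len), , drop = FALSE]
    mism <- .colSums(tm != qr, len, n_ref)
    matched <- len - mism
    best <- max(matched)
    score <- best / len
    if (score < cfg$map_score_min) next
    hits <- which(matched == best)
    if (length(hits) > 1L) next      # ambiguous tie between distinct oligos
    out_id[i] <- ref$ids[hits]
    out_score[i] <- score
  }
  data.table(oligo_id = out_id, score = out_score)
}

#' Build the barcode-oligo map
#'
#' Deduplicates identical (oligo, barcode) pairs, counts their support, and
#' removes any barcode observed with two or more distinct oligos so that
#' every retained barcode maps to exactly one oligo.
#'
#' @param pairs data.table/data.frame with columns `oligo_id`, `barcode`.
#' @return data.table (barcode, oligo_id, variant_id, allele, support) with
#'   a `qc` attribute (pairs in, duplicates removed, multi-oligo barcodes
#'   removed).
#' @export
build_barcode_map <- function(pairs) {
  pairs <- as.data.table(pairs)[!is.na(oligo_id) & !is.na(barcode)]
  if (nrow(pairs) == 0) {
    out <- data.table(barcode = character(0), oligo_id = character(0),
                      variant_id = character(0), allele = character(0),
                      support = integer(0))
    setattr(out, "qc", data.table(metric = c("pairs_in", "dup_pairs_removed",
                                             "multi_oligo_barcodes_removed"),
                                  n = c(0L, 0L, 0L)))
    return(out)
  }
  n_in <- nrow(pairs)
  dedup <- pairs[, .(support = .N), by = .(barcode, oligo_id)]
  multi <- dedup[, .(n_oligos = .N), by = barcode][n_oligos > 1L, barcode]
  out <- dedup[!barcode %in% multi]
  if (nrow(out)) {
    parts <- tstrsplit(out$oligo_id, ":", fixed = TRUE)
    out[, `:=`(variant_id = parts[[1]], allele = parts[[2]])]
  } else {
    out[, `:=`(variant_id = character(0), allele = character(0))]
  }
  setcolorder(out, c("barcode", "oligo_id", "variant_id", "allele", "support"))
  setattr(out, "qc",
          data.table(metric = c("pairs_in", "dup_pairs_removed",
                                "multi_oligo_barcodes_removed"),
                     n = c(n_in, n_in - nrow(dedup), length(multi))))
  out[]
}

#' Extract barcodes from count-library reads
#'
#' Locates the fixed prefix, takes the following `cfg$barcode_len` bases and
#' returns their reverse complement (the sequenced strand is the reverse
#' complement of the cloned barcode).
#'
#' @param reads character vector.
#' @param cfg an [mpra_config()].
#' @return character vector of barcodes (`NA` where the adapter is absent or
#'   the read is too short).
#' @export
extract_count_barcode <- function(reads, cfg = mpra_config()) {
  a <- find_adapter(reads, ADAPTER_COUNT, cfg$adapter_mismatch)
  raw <- ifelse(is.na(a), NA_character_,
                substr(reads, a, a + cfg$barcode_len - 1L))
  ok <- !is.na(raw) & nchar(raw) == cfg$barcode_len
  out <- rep(NA_character_, length(reads))
  out[ok] <- revcomp(raw[ok])
  out
}

#' Tally barcode counts and aggregate to alleles
#'
#' Counts each known barcode per sample, removes barcodes whose total DNA
#' count is zero, and aggregates to (variant, allele, sample). Input is
#' either one row per read (`barcode`, `sample_id`, `molecule`, optional
#' `condition`) or pre-counted rows carrying a `count` column.
#'
#' @param hits data.table of barcode observations as above.
#' @param map a [build_barcode_map()] table (or the truth `barcodes` table
#'   of an `mpra_library`).
#' @return list: `counts` (allele-aggregated), `barcode_counts`
#'   (barcode-level, zero-DNA filtered), `qc`.
#' @export
tally_counts <- function(hits, map) {
  hits <- as.data.table(hits)
  map <- as.data.table(map)
  stopifnot(all(c("barcode", "sample_id", "molecule") %in% names(hits)),
            all(c("barcode", "variant_id", "allele") %in% names(map)))
  if (!"condition" %in% names(hits)) hits[, condition := "ctrl"]
  n_reads <- if ("count" %in% names(hits)) sum(hits$count) else nrow(hits)
  known <- hits[!is.na(barcode) & barcode %in% map$barcode]
  n_known <- if ("count" %in% names(known)) sum(known$count) else nrow(known)
  bc_counts <- if ("count" %in% names(known)) {
    known[, .(count = sum(count)),
          by = .(barcode, sample_id, molecule, condition)]
  } else {
    known[, .(count = .N), by = .(barcode, sample_id, molecule, condition)]
  }
  # complete the barcode x sample grid with zeros before the DNA filter
  samples <- unique(hits[, .(sample_id, molecule, condition)])
  ubc <- unique(known$barcode)
  grid <- samples[rep(seq_len(.N), each = length(ubc))]
  grid[, barcode := rep(ubc, nrow(samples))]
  bc_counts <- bc_counts[grid, on = c("barcode", "sample_id", "molecule",
                                      "condition")]
  bc_counts[is.na(count), count := 0L]
  dna_tot <- bc_counts[molecule == "DNA", .(dna_total = sum(count)),
                       by = barcode]
  drop_bc <- dna_tot[dna_total == 0L, barcode]
  bc_counts <- bc_counts[!barcode %in% drop_bc]
  bc_counts[map, on = "barcode",
            `:=`(variant_id = i.variant_id, allele = i.allele)]
  counts <- bc_counts[, .(count = sum(count)),
                      by = .(variant_id, allele, sample_id, molecule,
                             condition)]
  setorder(counts, variant_id, allele, sample_id)
  list(counts = counts[], barcode_counts = bc_counts[],
       qc = data.table(metric = c("reads_in", "reads_known_barcode",
                                  "barcodes_dna_zero_removed"),
                       n = c(n_reads, n_known, length(drop_bc))))
}
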