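#' Simulation parameters
#'
#' The stated world of the synthetic MPRA. Defaults emulate the assayed
#' library at desk scale: a two-allele multi-barcode library, four DNA and
#' four RNA replicates per condition, negative-binomial counts over a fixed
#' plasmid pool, and planted activity/allelic effects. The full study scale
#' (5,369 variants, median 714 barcodes per allele) is reachable by raising
#' `n_variants` and `barcodes_per_allele`.
#'
#' @param n_variants number of variants (default 500).
#' @param barcodes_per_allele median barcodes per allele (default 20).
#' @param bc_sdlog log-normal sd of the barcode-count distribution around its
#'   median; 0 gives a constant count (default 0.5). The source assay does
#'   not state its distribution shape; log-normal is an assumption.
#' @param n_dna_reps,n_rna_reps replicates per molecule type (default 4 each).
#' @param depth expected reads per barcode (default 1000).
#' @param nb_dispersion negative-binomial technical dispersion alpha with
#'   variance mu + alpha mu^2; 0 gives Poisson (default 0.001).
#' @param lib_cv coefficient of variation of the fixed per-barcode plasmid
#'   abundance (default 0.5).
#' @param rna_rep_sd per-(variant, allele, replicate) biological noise of RNA
#'   samples, sd on log2 scale (default 0.05).
#' @param sample_depth_sdlog log-normal sd of per-sample sequencing depth
#'   factors (default 0.15).
#' @param frac_active fraction of variants with a planted activity effect
#'   (default 0.2); planted DAVs are drawn from these.
#' @param activity_log2fc planted cDNA/DNA log2 fold change of active
#'   elements (default 2, i.e. 4-fold).
#' @param frac_dav fraction of variants with a planted allelic effect
#'   (default 0.1; must not exceed `frac_active`).
#' @param allelic_log2fc planted |log2 ref/alt| allelic effect, split
#'   symmetrically (+/- fc/2 per allele) so element activity is orthogonal
#'   to allelic skew (default 1).
#' @param error_rate per-base substitution rate of simulated reads
#'   (default 0).
#' @param pairing_coverage pairing-library read pairs per barcode
#'   (default 2).
#' @param n_chroms,chrom_len toy genome shape (default 3 chromosomes of
#'   1 Mb).
#' @param barcode_len,insert_len oligo structure (defaults 20 and 126).
#' @param seed RNG seed.
#'
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_variants = 500L,
                       barcodes_per_allele = 20,
                       bc_sdlog = 0.5,
                       n_dna_reps = 4L,
                       n_rna_reps = 4L,
                       depth = 1000,
                       nb_dispersion = 0.001,
                       lib_cv = 0.5,
                       rna_rep_sd = 0.05,
                       sample_depth_sdlog = 0.15,
                       frac_active = 0.2,
                       activity_log2fc = 2,
                       frac_dav = 0.1,
                       allelic_log2fc = 1,
                       error_rate = 0,
                       pairing_coverage = 2L,
                       n_chroms = 3L,
                       chrom_len = 1e6,
                       barcode_len = 20L,
                       insert_len = 126L,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_variants >= 1, p$barcodes_per_allele >= 1,
            p$n_dna_reps >= 1, p$n_rna_reps >= 1,
            p$depth >= 0, p$nb_dispersion >= 0, p$lib_cv >= 0,
            p$rna_rep_sd >= 0, p$error_rate >= 0, p$error_rate <= 1,
            p$frac_active >= 0, p$frac_active <= 1,
            p$frac_dav >= 0, p$frac_dav <= 1,
            p$frac_dav <= p$frac_active || p$frac_dav == 0,
            p$chrom_len >= 10 * p$insert_len)
  structure(p, class = "sim_params")
}

#' Generate a synthetic MPRA library
#'
#' Builds a toy genome, draws variants, constructs the 170-base oligos
#' (22-base 5' adapter + 126-base insert centered on the allele + 22-base
#' 3' adapter) and assigns distinct 20-base barcodes to each
#' (variant, allele). A fixed per-barcode plasmid abundance (the library
#' composition, shared by every downstream sample) is attached to each
#' barcode.
#'
#' @param params a [sim_params()] object.
#' @return list of class `mpra_library` with elements `variants`, `oligos`,
#'   `barcodes`, `genome`, `params`.
#' @export
make_library <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  half <- params$insert_len %/% 2L          # variant at 1-based index `half`
  margin <- 1000L
  genome <- setNames(
    vapply(seq_len(params$n_chroms),
           function(i) paste(sample(DNA_BASES, params$chrom_len, replace = TRUE),
                             collapse = ""),
           ""),
    paste0("chr", seq_len(params$n_chroms)))

  n <- params$n_variants
  chrom <- sample(names(genome), n, replace = TRUE)
  pos <- integer(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sample((margin + 1L):(params$chrom_len - margin), length(idx))
  }
  ref <- substring(genome[chrom], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), "",
                USE.NAMES = FALSE)
  variants <- data.table(
    variant_id = sprintf("rs%07d", seq_len(n)),
    chrom = chrom, pos = pos, ref = ref, alt = alt)

  oligos <- variants[, .(variant_id, chrom, pos,
                         allele = rep(c("ref", "alt"), each = .N),
                         base = c(ref, alt))]
  setorder(oligos, variant_id, -allele)     # ref before alt per variant
  ins <- substring(genome[oligos$chrom], oligos$pos - half + 1L,
                   oligos$pos - half + params$insert_len)
  substr(ins, half, half) <- oligos$base
  oligos[, `:=`(oligo_id = paste0(variant_id, ":", allele),
                insert = ins,
                oligo = paste0(OLIGO_ADAPTER_5, ins, OLIGO_ADAPTER_3),
                base = NULL)]

  nb <- if (params$bc_sdlog <= 0) {
    rep(max(1L, round(params$barcodes_per_allele)), nrow(oligos))
  } else {
    pmax(1L, round(rlnorm(nrow(oligos),
                          meanlog = log(params$barcodes_per_allele),
                          sdlog = params$bc_sdlog)))
  }
  bc <- random_distinct_dna(sum(nb), params$barcode_len)
  barcodes <- oligos[rep(seq_len(.N), nb),
                     .(oligo_id, variant_id, allele)]
  barcodes[, barcode := bc]
  cv <- params$lib_cv
  barcodes[, lam := if (cv > 0) rgamma(.N, shape = 1 / cv^2, scale = cv^2)
                    else rep(1, .N)]
  structure(list(variants = variants, oligos = oligos[],
                 barcodes = barcodes[], genome = genome, params = params),
            class = "mpra_library")
}

#' @export
print.mpra_library <- function(x, ...) {
  cat("mpra_library:", nrow(x$variants), "variants,",
      nrow(x$oligos), "oligos,", nrow(x$barcodes), "barcodes\n")
  invisible(x)
}

#' Planted effect table
#'
#' Draws which variants carry an activity effect and, among those, which
#' carry an allelic effect (a variant can only be tested for allelic skew if
#' at least one allele is active, so planted DAVs are nested in planted
#' active elements). Allelic effect signs are random.
#'
#' @param library an `mpra_library`.
#' @param params a [sim_params()]; defaults to the library's.
#' @param seed RNG seed (default `params$seed + 1`).
#' @return data.table (variant_id, is_active, activity_log2fc, is_dav,
#'   allelic_log2fc).
#' @export
make_truth <- function(library, params = library$params,
                       seed = params$seed + 1L) {
  set.seed(seed)
  v <- library$variants$variant_id
  n <- length(v)
  n_act <- round(params$frac_active * n)
  n_dav <- round(params$frac_dav * n)
  act <- sample(v, n_act)
  dav <- if (n_dav > 0) sample(act, min(n_dav, n_act)) else character(0)
  truth <- data.table(variant_id = v)
  truth[, is_active := variant_id %in% act]
  truth[, activity_log2fc := ifelse(is_active, params$activity_log2fc, 0)]
  truth[, is_dav := variant_id %in% dav]
  truth[, allelic_log2fc := ifelse(is_dav,
                                   params$allelic_log2fc *
                                     sample(c(-1, 1), n, replace = TRUE), 0)]
  truth[]
}

#' Simulate barcode-level counts
#'
#' DNA counts are negative-binomial around `depth x lambda_b x f_s` where
#' `lambda_b` is the fixed plasmid abundance of barcode `b` and `f_s` a
#' per-sample depth factor. RNA counts scale the same plasmid proportion by
#' `2^activity` and `2^(+/- allelic/2)` per allele, times a per-(variant,
#' allele, replicate) biological noise factor. With zero allelic effect the
#' expected DNA-normalized log2 ref/alt RNA ratio is 0.
#'
#' @param library an `mpra_library`.
#' @param params a [sim_params()]; defaults to the library's.
#' @param truth a [make_truth()] table; generated if missing.
#' @param condition condition label stored in the output (default "ctrl").
#' @param seed RNG seed for the count noise (default `params$seed + 2`);
#'   the plasmid composition itself lives in the library and is shared
#'   across conditions.
#' @return data.table (barcode, oligo_id, variant_id, allele, sample_id,
#'   molecule, condition, count).
#' @export
simulate_counts <- function(library, params = library$params, truth = NULL,
                            condition = "ctrl", seed = params$seed + 2L) {
  stopifnot(inherits(library, "mpra_library"))
  if (is.null(truth)) truth <- make_truth(library, params)
  set.seed(seed)
  samples <- data.table(
    sample_id = c(paste0("DNA_", seq_len(params$n_dna_reps)),
                  paste0("RNA_", seq_len(params$n_rna_reps))),
    molecule = rep(c("DNA", "RNA"), c(params$n_dna_reps, params$n_rna_reps)))
  samples[, sf := rlnorm(.N, 0, params$sample_depth_sdlog)]

  bc <- library$barcodes[truth, on = "variant_id",
                         `:=`(act = i.activity_log2fc,
                              afc = i.allelic_log2fc)]
  on.exit(library$barcodes[, c("act", "afc") := NULL], add = TRUE)
  dt <- bc[rep(seq_len(.N), each = nrow(samples))]
  dt[, `:=`(sample_id = rep(samples$sample_id, nrow(bc)),
            molecule = rep(samples$molecule, nrow(bc)),
            sf = rep(samples$sf, nrow(bc)))]
  # biological replicate noise, one value per (oligo, RNA sample)
  eps <- CJ(oligo_id = library$oligos$oligo_id,
            sample_id = samples[molecule == "RNA", sample_id])
  eps[, eps := rnorm(.N, 0, params$rna_rep_sd)]
  dt[eps, on = c("oligo_id", "sample_id"), eps := i.eps]
  dt[is.na(eps), eps := 0]
  dt[, mu := params$depth * lam * sf]
  dt[molecule == "RNA",
     mu := mu * 2^(act + ifelse(allele == "ref", afc / 2, -afc / 2) + eps)]
  dt[, count := if (params$nb_dispersion > 0)
        rnbinom(.N, mu = mu, size = 1 / params$nb_dispersion)
      else rpois(.N, mu)]
  dt[, condition := condition]
  dt[, .(barcode, oligo_id, variant_id, allele, sample_id, molecule,
         condition, count)]
}

#' Aggregate barcode counts to alleles
#'
#' @param bc_counts barcode-level counts from [simulate_counts()] or
#'   [tally_counts()].
#' @return data.table summed to (variant_id, allele, sample_id, molecule,
#'   condition).
#' @export
aggregate_allele_counts <- function(bc_counts) {
  out <- bc_counts[, .(count = sum(count)),
                   by = .(variant_id, allele, sample_id, molecule, condition)]
  setorder(out, variant_id, allele, sample_id)
  out[]
}

#' Simulate sequencing reads
#'
#' Pairing-library read pairs (R1 = fixed prefix + 126-base oligo insert,
#' R2 = fixed prefix + barcode) and DNA/cDNA count-library reads (fixed
#' prefix + reverse complement of the barcode), with independent
#' substitution errors at `error_rate` and per-read provenance for truth
#' checking. `should_filter` marks pairing reads whose first 107 oligo bases
#' carry enough errors to fail the 0.95 mapping-score cutoff.
#'
#' @param library an `mpra_library`.
#' @param bc_counts optional [simulate_counts()] table; when given,
#'   count-library reads are emitted (exactly `count` reads per barcode and
#'   sample, shuffled).
#' @param error_rate per-base substitution rate (default from params).
#' @param seed RNG seed.
#' @return list with `pairing` (data.table read_id, r1, r2, barcode,
#'   oligo_id, n_err_107, should_filter) and `count_reads` (data.table
#'   sample_id, molecule, condition, seq), plus `map_len` used for truth.
#' @export
simulate_reads <- function(library, bc_counts = NULL,
                           error_rate = library$params$error_rate,
                           seed = library$params$seed + 3L) {
  stopifnot(inherits(library, "mpra_library"))
  set.seed(seed)
  cov <- library$params$pairing_coverage
  bc <- library$barcodes[rep(seq_len(.N), cov)]
  ins <- library$oligos[bc, on = "oligo_id", insert]
  r1 <- apply_seq_errors(paste0(ADAPTER_PAIRING_R1, ins), error_rate)
  r2 <- apply_seq_errors(paste0(ADAPTER_PAIRING_R2, bc$barcode), error_rate)
  map_len <- 107L
  la <- nchar(ADAPTER_PAIRING_R1)
  oligo_part <- substr(r1, la + 1L, la + map_len)
  ref_part <- substr(ins, 1L, map_len)
  n_err <- if (error_rate > 0) {
    mapply(str_mismatches, oligo_part, ref_part, USE.NAMES = FALSE)
  } else rep(0L, length(r1))
  pairing <- data.table(
    read_id = paste0("pair_", seq_along(r1)),
    r1 = r1, r2 = r2, barcode = bc$barcode, oligo_id = bc$oligo_id,
    n_err_107 = as.integer(n_err),
    should_filter = (map_len - n_err) / map_len < 0.95)

  count_reads <- NULL
  if (!is.null(bc_counts)) {
    base_read <- paste0(ADAPTER_COUNT, revcomp(bc_counts$barcode))
    idx <- rep(seq_len(nrow(bc_counts)), bc_counts$count)
    count_reads <- data.table(
      sample_id = bc_counts$sample_id[idx],
      molecule = bc_counts$molecule[idx],
      condition = bc_counts$condition[idx],
      seq = apply_seq_errors(base_read[idx], error_rate))
    count_reads <- count_reads[sample(.N)]
  }
  list(pairing = pairing, count_reads = count_reads, map_len = map_len)
}

#' Write simulated reads to FASTQ files
#'
#' @param reads output of [simulate_reads()].
#' @param dir output directory.
#' @return named character vector of file paths.
#' @export
write_read_files <- function(reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pairing_R1 = file.path(dir, "pairing_R1.fastq"),
    pairing_R2 = file.path(dir, "pairing_R2.fastq"))
  write_fastq(reads$pairing$r1, paths["pairing_R1"], reads$pairing$read_id)
  write_fastq(reads$pairing$r2, paths["pairing_R2"], reads$pairing$read_id)
  if (!is.null(reads$count_reads)) {
    for (s in unique(reads$count_reads$sample_id)) {
      p <- file.path(dir, paste0("counts_", s, ".fastq"))
      write_fastq(reads$count_reads[sample_id == s, seq], p)
      paths[paste0("counts_", s)] <- p
    }
  }
  paths
}
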