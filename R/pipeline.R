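#' Planted truths for a control/stimulation condition pair
#'
#' The stimulation truth derives from the control truth: a fraction of
#' active elements gains extra activity (stimulus-responsive enhancers),
#' some control DAVs lose their allelic effect, and some active non-DAV
#' variants gain one (stimulus-specific DAVs).
#'
#' @param library an `mpra_library`.
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @param frac_responsive fraction of active elements induced under
#'   stimulation (default 0.25, +1 log2).
#' @param frac_dav_lost,frac_dav_gained DAV turnover fractions
#'   (defaults 0.3 of control DAVs lost, 0.05 of variants gained).
#' @return list: `ctrl`, `stim` truth tables, `responsive` variant ids.
#' @export
make_condition_truths <- function(library, params = library$params,
                                  seed = params$seed + 10L,
                                  frac_responsive = 0.25,
                                  frac_dav_lost = 0.3,
                                  frac_dav_gained = 0.05) {
  ctrl <- make_truth(library, params, seed = seed)
  set.seed(seed + 1L)
  stim <- copy(ctrl)
  act <- ctrl[is_active == TRUE, variant_id]
  responsive <- sample(act, round(frac_responsive * length(act)))
  stim[variant_id %in% responsive, activity_log2fc := activity_log2fc + 1]
  davs <- ctrl[is_dav == TRUE, variant_id]
  lost <- sample(davs, round(frac_dav_lost * length(davs)))
  pool <- setdiff(act, davs)
  gained <- sample(pool, min(length(pool),
                             round(frac_dav_gained * nrow(ctrl))))
  stim[variant_id %in% lost, `:=`(is_dav = FALSE, allelic_log2fc = 0)]
  stim[variant_id %in% gained,
       `:=`(is_dav = TRUE,
            allelic_log2fc = params$allelic_log2fc *
              sample(c(-1, 1), length(gained), replace = TRUE))]
  list(ctrl = ctrl, stim = stim, responsive = responsive)
}

active_variant_set <- function(activity_table) {
  dt <- as.data.table(activity_table)[is_enhancer == TRUE]
  unique(tstrsplit(dt$element_id, ":", fixed = TRUE)[[1]])
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates the default synthetic study (library, pairing reads, counts for
#' every cell line and condition, annotations, CROP-seq screen, cohort),
#' runs every analysis stage, and writes each output table under `outdir`.
#'
#' @param outdir output directory.
#' @param seed master seed; every stage derives its own from it.
#' @param params a [sim_params()]; the default uses 500 variants and a
#'   0.001 substitution error rate for the pairing library.
#' @param cell_lines,conditions labels for the simulated contexts.
#' @param cfg an [mpra_config()].
#' @param quiet suppress progress messages.
#' @return invisible list of all in-memory results.
#' @export
run_mpra_pipeline <- function(outdir, seed = 1L,
                              params = sim_params(seed = seed,
                                                  error_rate = 0.001),
                              cell_lines = c("HepG2", "LX2"),
                              conditions = c("ctrl", "stim"),
                              cfg = mpra_config(), quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[mpradav] ", ...)
  emit <- function(dt, name) write_tsv(as.data.table(dt),
                                       file.path(outdir, name))

  say("building library (", params$n_variants, " variants)")
  library <- make_library(params)
  emit(library$variants, "variants.tsv")
  emit(library$oligos[, .(oligo_id, variant_id, allele, oligo)], "oligos.tsv")
  emit(library$barcodes[, .(barcode, oligo_id, variant_id, allele)],
       "barcode_truth.tsv")
  write_fasta(setNames(library$oligos$oligo, library$oligos$oligo_id),
              file.path(outdir, "oligos.fasta"))

  say("recovering barcode-oligo pairings from pairing reads")
  reads <- simulate_reads(library, seed = seed + 3L)
  trim <- trim_pairing_pair(reads$pairing$r1, reads$pairing$r2, cfg)
  ref <- oligo_reference(library, cfg$oligo_map_len)
  mapped <- map_oligo(trim$oligo_query, ref, cfg)
  pairs <- data.table(oligo_id = mapped$oligo_id, barcode = trim$barcode)
  bc_map <- build_barcode_map(pairs[!is.na(oligo_id) & !is.na(barcode)])
  emit(bc_map, "barcode_map.tsv")
  emit(rbind(trim$qc, attr(bc_map, "qc"), use.names = FALSE),
       "pairing_qc.tsv")
  say("barcode map: ", nrow(bc_map), " of ", nrow(library$barcodes),
      " barcodes recovered")

  truths <- acts <- davs <- list()
  counts_all <- list()
  for (cl in cell_lines) {
    cl_seed <- seed + 100L * match(cl, cell_lines)
    tr <- make_condition_truths(library, params, seed = cl_seed)
    truths[[cl]] <- tr
    for (cond in conditions) {
      key <- paste(cl, cond, sep = "_")
      say("simulating and tallying counts: ", key)
      bc_counts <- simulate_counts(
        library, params, truth = tr[[cond]], condition = key,
        seed = cl_seed + match(cond, conditions))
      tl <- tally_counts(
        bc_counts[, .(barcode, sample_id, molecule, condition, count)],
        bc_map)
      counts_all[[key]] <- tl$counts
      emit(tl$counts, paste0("counts_", key, ".tsv"))
      say("calling active elements and DAVs: ", key)
      act <- call_active_elements(tl$counts, cfg)
      acts[[key]] <- act
      emit(act, paste0("activity_", key, ".tsv"))
      av <- active_variant_set(act)
      dv <- call_davs(allelic_ratios(tl$counts, cfg), av, cfg)
      davs[[key]] <- dv
      emit(dv, paste0("dav_", key, ".tsv"))
    }
    k1 <- paste(cl, conditions[1], sep = "_")
    k2 <- paste(cl, conditions[2], sep = "_")
    enh <- union(active_variant_set(acts[[k1]]),
                 active_variant_set(acts[[k2]]))
    resp <- condition_response(counts_all[[k1]], counts_all[[k2]], enh, cfg)
    emit(resp, paste0("response_", cl, ".tsv"))
    emit(classify_context(davs[[k1]], davs[[k2]]),
         paste0("context_", cl, ".tsv"))
  }
  kA <- paste(cell_lines[1], conditions[1], sep = "_")
  kB <- paste(cell_lines[2], conditions[1], sep = "_")
  emit(classify_context(davs[[kA]], davs[[kB]]), "context_celltype.tsv")

  say("motif disruption and enrichment")
  pfms <- random_pfms(seed = seed + 7L)
  write_jaspar(pfms, file.path(outdir, "pfms.jaspar"))
  dav_main <- davs[[kA]][is_dav == TRUE, variant_id]
  bg_calls <- disruption_calls(library$variants, library$genome, pfms, cfg)
  dav_calls <- bg_calls[variant_id %in% dav_main]
  emit(bg_calls, "motif_disruption.tsv")
  if (length(dav_main) > 0) {
    emit(motif_enrichment(dav_calls,
                          bg_calls[!variant_id %in% dav_main], cfg),
         "motif_enrichment.tsv")
  }

  say("annotations, peak enrichment, target genes")
  ann <- make_annotations(library, seed = seed + 4L,
                          truth = truths[[cell_lines[1]]]$ctrl)
  write_bed(ann$peaks, file.path(outdir, "peaks.bed"))
  write_bedpe(ann$loops, file.path(outdir, "loops.bedpe"))
  emit(ann$genes, "genes.tsv")
  emit(ann$eqtls, "eqtls.tsv")
  dav_tab <- library$variants[variant_id %in% dav_main]
  emit(annotate_variants(dav_tab, ann, cfg), "annotation.tsv")
  enr <- rbindlist(lapply(unique(ann$peaks$celltype), function(ct)
    peak_enrichment(dav_tab, library$variants,
                    ann$peaks[celltype == ct], ann$chrom_sizes, cfg,
                    seed = seed + 5L)[, celltype := ct]))
  emit(enr, "peak_enrichment.tsv")
  emit(classify_peaks(ann$peaks, ann$genes, cfg), "peaks_classified.tsv")
  targets <- nominate_targets(dav_tab, ann, cfg)
  emit(targets, "targets.tsv")
  conc <- eqtl_concordance(davs[[kA]][is_dav == TRUE], ann$eqtls)
  emit(conc$labels, "eqtl_concordance.tsv")
  say("eQTL concordance: ",
      round(100 * conc$fraction_concordant, 1), "% of DAV-eQTL pairs")

  say("CROP-seq screen")
  tgt_genes <- targets[method == "eqtl"][!duplicated(variant_id)]
  n_tgt <- min(20L, nrow(tgt_genes))
  panel_genes <- if (n_tgt > 0) tgt_genes$gene_id[seq_len(n_tgt)] else NULL
  if (n_tgt < 20L)
    panel_genes <- c(panel_genes, sprintf("TGT%02d", seq_len(20L - n_tgt)))
  panel <- make_sgrna_panel(target_genes = panel_genes, seed = seed + 8L)
  crop <- simulate_cropseq(sgrnas = panel, seed = seed + 8L)
  write_fasta(build_pseudogene_reference(panel)$fasta,
              file.path(outdir, "pseudogenes.fasta"))
  asg <- assign_cells(crop$sgrna_counts, cfg$sgrna_dominance)
  emit(asg, "cropseq_assignments.tsv")
  de <- target_de(crop$expr, asg, crop$effect_table, cfg)
  emit(de$results, "cropseq_de.tsv")

  say("polygenic risk score")
  cohort <- simulate_cohort(seed = seed + 9L)
  prs <- compute_prs(cohort$dosages, cohort$weights)
  emit(data.table(individual = rownames(cohort$dosages),
                  score = prs$raw, z = prs$z,
                  phenotype = cohort$phenotype), "prs_scores.tsv")
  assoc <- logistic_association(prs$z, cohort$phenotype)
  emit(data.table(beta_per_sd = assoc$beta, se = assoc$se, p = assoc$p,
                  or_per_sd = assoc$or, ci_lo = assoc$ci[1],
                  ci_hi = assoc$ci[2], separation = assoc$separation),
       "prs_association.tsv")
  dec <- decile_odds_ratios(prs$z, cohort$phenotype)
  emit(dec, "prs_deciles.tsv")
  say("top-decile OR = ", round(dec$or[10], 2))

  invisible(list(library = library, barcode_map = bc_map, truths = truths,
                 counts = counts_all, activity = acts, davs = davs,
                 targets = targets, concordance = conc,
                 cropseq = list(sim = crop, assignment = asg, de = de),
                 prs = list(assoc = assoc, deciles = dec)))
}
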