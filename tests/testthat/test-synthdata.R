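test_that("make_library builds the stated oligo structure", {
  p <- sim_params(n_variants = 1, barcodes_per_allele = 2, bc_sdlog = 0,
                  seed = 3)
  lib <- make_library(p)
  expect_equal(nrow(lib$oligos), 2)        # one oligo per allele
  expect_equal(nrow(lib$barcodes), 4)      # 2 barcodes x 2 alleles
  expect_true(all(nchar(lib$oligos$oligo) == 170))
  expect_true(all(startsWith(lib$oligos$oligo, "GAGTACTGTATGGGCGGGTACC")))
  expect_true(all(endsWith(lib$oligos$oligo, "GCTAGCGACAAAAGTGTCAACT")))
  expect_true(all(nchar(lib$oligos$insert) == 126))
  # insert base at the center position equals the named allele
  half <- 126 %/% 2
  v <- lib$variants
  ins <- lib$oligos
  expect_equal(substr(ins[allele == "ref", insert], half, half), v$ref)
  expect_equal(substr(ins[allele == "alt", insert], half, half), v$alt)
  # genomic context flanks the variant
  expect_equal(substr(lib$genome[[v$chrom]], v$pos - 5, v$pos - 1),
               substr(ins$insert[1], half - 5, half - 1))
})

test_that("make_library is deterministic and barcodes are distinct", {
  p <- sim_params(n_variants = 25, seed = 42)
  lib1 <- make_library(p)
  lib2 <- make_library(p)
  expect_identical(lib1$variants, lib2$variants)
  expect_identical(lib1$oligos, lib2$oligos)
  expect_identical(lib1$barcodes, lib2$barcodes)
  expect_false(anyDuplicated(lib1$barcodes$barcode) > 0)
  expect_true(all(lib1$variants$ref != lib1$variants$alt))
})

test_that("collision exhaustion fails explicitly", {
  expect_error(random_distinct_dna(30, 2), "collision exhaustion")
})

test_that("simulate_counts respects depth and scales linearly", {
  lib <- tiny_library(seed = 5)
  tr <- make_truth(lib)
  p0 <- lib$params; p0$depth <- 0
  expect_true(all(simulate_counts(lib, p0, tr)$count == 0))
  c1 <- simulate_counts(lib, lib$params, tr, seed = 9)
  p2 <- lib$params; p2$depth <- p2$depth * 2
  c2 <- simulate_counts(lib, p2, tr, seed = 9)
  expect_lt(abs(sum(c2$count) / sum(c1$count) - 2), 0.1)
  # determinism
  expect_identical(c1, simulate_counts(lib, lib$params, tr, seed = 9))
})

test_that("null allelic effects give centered DNA-normalized RNA ratios", {
  p <- sim_params(n_variants = 2000, barcodes_per_allele = 10, bc_sdlog = 0,
                  depth = 200, frac_active = 0, frac_dav = 0, seed = 21)
  lib <- make_library(p)
  counts <- aggregate_allele_counts(simulate_counts(lib, p))
  rat <- allelic_ratios(counts)
  dna_med <- rat[molecule == "DNA",
                 .(M = median(ratio)), by = variant_id]
  rna <- rat[molecule == "RNA"][dna_med, on = "variant_id"]
  expect_lt(abs(mean(log2(rna$ratio / rna$M))), 0.05)
})

test_that("simulate_reads round-trips truth and records error provenance", {
  lib <- tiny_library(seed = 13)
  reads <- simulate_reads(lib, error_rate = 0)
  expect_true(all(reads$pairing$n_err_107 == 0))
  expect_false(any(reads$pairing$should_filter))
  la <- nchar("GGCCTAACTGGCCGGTACCCTGAGTACTGTATGGGCGGGTACC")
  ins <- lib$oligos[match(reads$pairing$oligo_id, oligo_id), insert]
  expect_equal(substr(reads$pairing$r1, la + 1, la + 126), ins)
  # count-library reads carry revcomp(barcode) right after the fixed prefix
  tr <- make_truth(lib)
  cnt <- simulate_counts(lib, truth = tr)
  rd2 <- simulate_reads(lib, cnt[1:50], error_rate = 0)
  lc <- nchar("CTTGGCAATCCGGTACTTAGCGCATCTAAC")
  expect_true(all(substr(rd2$count_reads$seq, lc + 1, lc + 20) %in%
                    revcomp(lib$barcodes$barcode)))
  # with errors, the filter flag matches the stated 0.95 rule
  rde <- simulate_reads(lib, error_rate = 0.03, seed = 77)
  expect_equal(rde$pairing$should_filter,
               (107 - rde$pairing$n_err_107) / 107 < 0.95)
  ref107 <- substr(lib$oligos[match(rde$pairing$oligo_id, oligo_id), insert],
                   1, 107)
  recount <- mapply(function(r, s) sum(strsplit(r, "")[[1]] != strsplit(s, "")[[1]]),
                    substr(rde$pairing$r1, la + 1, la + 107), ref107)
  expect_equal(unname(recount), rde$pairing$n_err_107)
})

test_that("make_annotations plants verifiable truth", {
  lib <- tiny_library(n_variants = 60, seed = 17)
  tr <- make_truth(lib)
  ann <- make_annotations(lib, truth = tr)
  # all intervals within chromosome bounds
  for (tbl in list(ann$peaks, ann$chromhmm)) {
    expect_true(all(tbl$start >= 1 & tbl$end <= lib$params$chrom_len))
    expect_true(all(tbl$start < tbl$end))
  }
  # planted in-peak variants all overlap a peak of their cell type
  flags <- annotate_variants(lib$variants, ann)
  for (ct in unique(ann$truth$in_peak$celltype)) {
    planted <- ann$truth$in_peak[celltype == ct, variant_id]
    expect_true(all(flags[variant_id %in% planted][[paste0("peak_", ct)]]))
  }
  # concordant-labeled eQTL slopes oppose the planted ref/alt effect sign
  conc <- ann$truth$eqtl_concordant
  if (length(conc)) {
    j <- merge(ann$eqtls[variant_id %in% conc], tr, by = "variant_id")
    expect_true(all(sign(j$slope) == -sign(j$allelic_log2fc)))
  }
})

test_that("simulate_cropseq plants knockdown and ambiguity", {
  crop <- simulate_cropseq(n_cells = 2000, seed = 5)
  crop2 <- simulate_cropseq(n_cells = 2000, seed = 5)
  expect_identical(crop$expr, crop2$expr)
  expect_identical(crop$sgrna_counts, crop2$sgrna_counts)
  # planted effect 0.5: mean expression of the target in perturbed cells
  et <- crop$effect_table[1]
  same_gene <- crop$effect_table[gene_id == et$gene_id, sgrna_id]
  in_cells <- crop$truth[sgrna_id == et$sgrna_id, cell_id]
  out_cells <- crop$truth[!is.na(sgrna_id) & !sgrna_id %in% same_gene,
                          cell_id]
  ratio <- mean(crop$expr[in_cells, et$gene_id]) /
    mean(crop$expr[out_cells, et$gene_id])
  expect_lt(abs(ratio - 0.5), 0.1)
  # generated ambiguous cells all fail the dominance rule
  asg <- assign_cells(crop$sgrna_counts)
  amb <- crop$truth[ambiguous == TRUE, cell_id]
  expect_true(all(is.na(asg[cell_id %in% amb, sgrna_id])))
})

test_that("simulate_cohort responds to prevalence and nulls cleanly", {
  c1 <- simulate_cohort(n = 3000, prevalence = 0.1, seed = 8)
  c2 <- simulate_cohort(n = 3000, prevalence = 0.3, seed = 8)
  c3 <- simulate_cohort(n = 3000, prevalence = 0.6, seed = 8)
  expect_lt(mean(c1$phenotype), mean(c2$phenotype))
  expect_lt(mean(c2$phenotype), mean(c3$phenotype))
  # null effect: decile ORs hover around 1
  c0 <- simulate_cohort(n = 6000, beta_per_sd = 0, prevalence = 0.3, seed = 9)
  prs <- compute_prs(c0$dosages, c0$weights)
  dec <- decile_odds_ratios(prs$z, c0$phenotype)
  expect_true(all(dec$or > 0.6 & dec$or < 1.6))
})
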