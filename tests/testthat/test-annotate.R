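test_that("loop-anchor padding arithmetic is exact", {
  bundle <- list(
    peaks = data.table::data.table(chrom = character(0), start = integer(0),
                                   end = integer(0), celltype = character(0)),
    chromhmm = data.table::data.table(chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      state = character(0)),
    eqtls = data.table::data.table(variant_id = character(0),
                                   gene = character(0), slope = numeric(0),
                                   significant = logical(0)),
    loops = data.table::data.table(chrom1 = "chr1", start1 = 50000L,
                                   end1 = 51000L, chrom2 = "chr1",
                                   start2 = 90000L, end2 = 91000L))
  vs <- data.table::data.table(
    variant_id = c("in_pad", "out_pad"), chrom = "chr1",
    pos = c(51000L + 2400L, 51000L + 2600L))     # 2.4 kb in, 2.6 kb out
  ann <- annotate_variants(vs, bundle)
  expect_true(ann[variant_id == "in_pad", loop_anchor])
  expect_false(ann[variant_id == "out_pad", loop_anchor])
  expect_false(any(ann$eqtl))                    # absent from eQTL table
})

test_that("classify_peaks is strand-aware around the TSS", {
  genes <- data.table::data.table(
    gene_id = c("gp", "gm"), chrom = "chr1",
    tss = c(10000L, 50000L), strand = c("+", "-"))
  peaks <- data.table::data.table(
    chrom = "chr1",
    start = c(9900L, 10400L, 7900L, 7000L, 51900L, 48000L, 200000L),
    end = c(10100L, 10600L, 8100L, 7400L, 52100L, 48500L, 200500L))
  cl <- classify_peaks(peaks, genes)
  # plus strand: [-2000, +500]; peak at +501.. is still promoter if it
  # touches 10500; 7900-8100 overlaps 8000 boundary; 7000-7400 does not
  expect_equal(cl$class,
               c("promoter", "promoter", "promoter", "enhancer",
                 "promoter",      # minus strand: window [49500, 52000]
                 "enhancer",      # 48000-48500 is upstream of the - gene
                 "enhancer"))     # 10 kb from every TSS
})

test_that("nomination boundaries follow the stated conventions", {
  genes <- data.table::data.table(gene_id = c("g1", "g2"), chrom = "chr1",
                                  tss = c(120000L, 300000L),
                                  strand = c("+", "+"))
  bundle <- list(
    genes = genes,
    loops = data.table::data.table(chrom1 = character(0), start1 = integer(0),
                                   end1 = integer(0), chrom2 = character(0),
                                   start2 = integer(0), end2 = integer(0)),
    coaccess = data.table::data.table(
      chrom1 = "chr1", start1 = 99900L, end1 = 100099L,
      chrom2 = "chr1", start2 = 299900L, end2 = 300099L,
      score = c(0.3)),
    eqtls = data.table::data.table(variant_id = character(0),
                                   gene = character(0),
                                   significant = logical(0)))
  davs <- data.table::data.table(variant_id = "d1", chrom = "chr1",
                                 pos = 100000L)
  tg <- nominate_targets(davs, bundle)
  # |100000 - 120000| = 20000 exactly -> proximal (inclusive)
  expect_true(nrow(tg[gene_id == "g1" & method == "proximal"]) == 1)
  # co-accessibility score exactly 0.3 -> excluded (strict >)
  expect_false("coaccess" %in% tg$method)
  bundle$coaccess$score <- 0.31
  tg2 <- nominate_targets(davs, bundle)
  expect_true(nrow(tg2[gene_id == "g2" & method == "coaccess"]) == 1)
})

test_that("nominate_targets equals the brute-force interval oracle", {
  lib <- tiny_library(n_variants = 200, seed = 31)
  ann <- make_annotations(lib, seed = 99)
  cfg <- mpra_config()
  got <- nominate_targets(lib$variants, ann, cfg)
  exp <- oracle_targets(as.data.frame(lib$variants),
                        lapply(ann[c("genes", "loops", "coaccess", "eqtls")],
                               as.data.frame), cfg)
  expect_identical(pair_key(got), pair_key(exp))
})

test_that("eqtl_concordance applies the sign convention", {
  davs <- data.table::data.table(
    variant_id = c("v1", "v2", "v3"), effect = c(-1, 1, 0))
  eqtls <- data.table::data.table(
    variant_id = c("v1", "v2", "v3"), gene = "g",
    slope = c(0.5, 0.5, 0.5), significant = TRUE)
  out <- eqtl_concordance(davs, eqtls)
  expect_true(out$labels[variant_id == "v1", concordant])   # alt-stronger + alt-up
  expect_false(out$labels[variant_id == "v2", concordant])
  expect_false("v3" %in% out$labels$variant_id)             # zero effect excluded
  expect_equal(out$fraction_concordant, 0.5)
})

test_that("peak_enrichment permutation p is bounded and reproducible", {
  lib <- tiny_library(n_variants = 50, seed = 37)
  ann <- make_annotations(lib, seed = 50)
  peaks <- ann$peaks[celltype == "hepatocyte"]
  cfg <- mpra_config(n_permutations = 200)
  davs <- lib$variants[1:15]
  e1 <- peak_enrichment(davs, lib$variants, peaks, ann$chrom_sizes, cfg,
                        seed = 7)
  e2 <- peak_enrichment(davs, lib$variants, peaks, ann$chrom_sizes, cfg,
                        seed = 7)
  expect_identical(e1, e2)
  expect_gte(e1$perm_p, 1 / 201)
  expect_lte(e1$perm_p, 1)
  # every DAV in a peak, peaks tiny: observed beats all permutations
  davs_in <- ann$truth$in_peak[celltype == "hepatocyte"]
  dv <- lib$variants[variant_id %in% davs_in$variant_id][1:10]
  e3 <- peak_enrichment(dv, lib$variants, peaks, ann$chrom_sizes, cfg,
                        seed = 8)
  expect_equal(e3$observed, 10)
  expect_gt(e3$fisher_or, 1)
})

test_that("BED/BEDPE round trip converts coordinates at the boundary", {
  dt <- data.table::data.table(chrom = "chr1", start = 101L, end = 200L,
                               celltype = "hep")
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(dt, path)
  raw <- data.table::fread(path, header = FALSE)
  expect_equal(raw$V2, 100L)                  # 0-based half-open on disk
  back <- read_bed(path, extra_cols = "celltype")
  expect_equal(back$start, 101L)
  expect_equal(back$end, 200L)
  lp <- data.table::data.table(chrom1 = "chr1", start1 = 11L, end1 = 20L,
                               chrom2 = "chr2", start2 = 31L, end2 = 40L,
                               source = "s")
  p2 <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(lp, p2)
  expect_identical(read_bedpe(p2, extra_cols = "source"), lp)
})

test_that("annotation is idempotent and order-independent", {
  lib <- tiny_library(n_variants = 40, seed = 41)
  ann <- make_annotations(lib, seed = 60)
  a1 <- annotate_variants(lib$variants, ann)
  a2 <- annotate_variants(lib$variants[sample(.N)], ann)
  data.table::setkey(a1, variant_id)
  data.table::setkey(a2, variant_id)
  expect_identical(a1, a2)
})
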