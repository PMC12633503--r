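consensus_pfm <- function(seq, id = "M1") {
  w <- nchar(seq)
  mat <- matrix(0.04, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  b <- strsplit(seq, "")[[1]]
  for (j in seq_len(w)) mat[b[j], j] <- 0.88
  pfm(mat, id)
}

revcomp_pfm <- function(p) {
  m <- p$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(p$mat)))]
  rownames(m) <- c("A", "C", "G", "T")
  pfm(m, p$motif_id)
}

test_that("pfm constructor normalizes and validates", {
  m <- matrix(c(2, 1, 1, 0), 4, 5)
  p <- pfm(m, "M0")
  expect_equal(colSums(p$mat), rep(1, 5))
  expect_error(pfm(matrix(1, 3, 5), "bad"))
})

test_that("jaspar round trip preserves probabilities", {
  pfms <- random_pfms(3, seed = 4)
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pfms, path)
  back <- read_jaspar(path)
  expect_equal(names(back), names(pfms))
  for (id in names(pfms))
    expect_equal(back[[id]]$mat, pfms[[id]]$mat, tolerance = 1e-3)
})

test_that("scan_variant_window covers the SNP with every placement", {
  set.seed(15)
  genome <- list(chr1 = random_dna(1, 400))
  v <- list(variant_id = "v1", chrom = "chr1", pos = 200L,
            ref = substr(genome$chr1, 200, 200), alt = "A")
  if (v$ref == "A") v$alt <- "G"
  p5 <- consensus_pfm(random_dna(1, 5))
  sc <- scan_variant_window(v, genome, p5)
  # width 5 => exactly 5 offsets per strand cover the center
  expect_equal(nrow(sc), 10)
  expect_equal(sort(unique(sc$offset)), 17:21)
  # every placement covers position 21 of the 41-base window
  expect_true(all(sc$offset <= 21 & sc$offset + 5 - 1 >= 21))
  # a PFM that is the exact consensus of the ref window scores the maximum
  win_ref <- substr(genome$chr1, 180, 220)
  substr(win_ref, 21, 21) <- v$ref
  pc <- consensus_pfm(substr(win_ref, 19, 26))
  sc2 <- scan_variant_window(v, genome, pc)
  hit <- sc2[offset == 19 & strand == "+"]
  expect_equal(hit$rel_ref, 1)
  expect_true(hit$match)
  # edge variant: truncated window is skipped with a warning
  v_edge <- list(variant_id = "v2", chrom = "chr1", pos = 5L,
                 ref = "A", alt = "C")
  expect_warning(out <- scan_variant_window(v_edge, genome, p5), "truncated")
  expect_equal(nrow(out), 0)
})

test_that("scan matches brute-force scoring on random windows", {
  set.seed(16)
  genome <- list(chr1 = random_dna(1, 5000))
  pfms <- random_pfms(3, seed = 7)
  cfg <- mpra_config()
  for (k in 1:50) {
    pos <- sample(100:4900, 1)
    refb <- substr(genome$chr1, pos, pos)
    v <- list(variant_id = "v", chrom = "chr1", pos = pos, ref = refb,
              alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1))
    p <- pfms[[sample(3, 1)]]
    sc <- scan_variant_window(v, genome, p, cfg)
    win_ref <- substr(genome$chr1, pos - 20, pos + 20)
    substr(win_ref, 21, 21) <- v$ref
    orc <- oracle_scan(win_ref, p$mat)
    got <- sc[order(strand, offset), .(strand, offset, score_ref)]
    orc <- orc[order(orc$strand, orc$offset), ]
    expect_equal(got$offset, orc$offset)
    expect_equal(got$score_ref, orc$score, tolerance = 1e-12)
  }
})

test_that("call_disruption applies the printed rule", {
  colvals <- c(A = 0.05, C = 0.10, G = 0.70, T = 0.15)
  p <- pfm(matrix(colvals, 4, 6,
                  dimnames = list(c("A", "C", "G", "T"), NULL)), "M2")
  d <- call_disruption(p, snp_col = 3, strand = "+", "G", "A")
  expect_equal(d$p_ref, 0.70)
  expect_equal(d$p_alt, 0.05)
  expect_true(d$interrupted)                         # ratio 14 > 2
  expect_false(call_disruption(p, 3, "+", "C", "T")$interrupted) # max 0.15
  p2 <- pfm(matrix(c(0.40, 0.25, 0.2, 0.15), 4, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL)), "M3")
  expect_false(call_disruption(p2, 2, "+", "A", "C")$interrupted) # ratio 1.6
  # minus strand reads the complemented alleles
  dm <- call_disruption(p, 3, "-", "C", "T")          # comp: G vs A
  expect_equal(dm$p_ref, 0.70)
  expect_true(dm$interrupted)
})

test_that("disruption rule matches the oracle on an exhaustive grid", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]            # 12 ordered pairs
  for (g in 1:25) {
    col <- runif(4); col <- col / sum(col)
    names(col) <- bases
    p <- pfm(matrix(col, 4, 4, dimnames = list(bases, NULL)), "G1")
    for (r in seq_len(nrow(pairs))) {
      got <- call_disruption(p, 2, "+", pairs$ref[r], pairs$alt[r])
      expect_identical(got$interrupted,
                       oracle_disruption(p$mat[, 2], pairs$ref[r],
                                         pairs$alt[r]))
    }
  }
})

test_that("strand symmetry: reverse-complemented genome and PFMs agree", {
  set.seed(18)
  L <- 2000
  genome <- list(chr1 = random_dna(1, L))
  genome_rc <- list(chr1 = revcomp(genome$chr1))
  pfms <- random_pfms(2, seed = 9)
  vs <- data.table::data.table(variant_id = paste0("v", 1:10),
                               chrom = "chr1",
                               pos = sample(100:1900, 10))
  vs[, ref := substring(genome$chr1, pos, pos)]
  vs[, alt := vapply(ref, function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")]
  fwd <- disruption_calls(vs, genome, pfms)
  vs_rc <- data.table::copy(vs)
  vs_rc[, `:=`(pos = L - pos + 1L,
               ref = chartr("ACGT", "TGCA", ref),
               alt = chartr("ACGT", "TGCA", alt))]
  rev <- disruption_calls(vs_rc, genome_rc, lapply(pfms, revcomp_pfm))
  expect_equal(fwd$interrupted, rev$interrupted)
  expect_equal(fwd$n_matches, rev$n_matches)
})

test_that("allele agreement ratio reduces to column products", {
  p <- consensus_pfm("ACGTT")
  win <- paste0(strrep("A", 10), "ACGTT", strrep("A", 10))
  expect_equal(allele_agreement_ratio(win, win, p, 11), 1.0)
  # single differing column with probabilities 0.70 vs 0.05 -> ratio 14
  colvals <- matrix(c(0.05, 0.10, 0.70, 0.15), 4, 4,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  p2 <- pfm(colvals, "M4")
  w_ref <- "AAAA"; w_alt <- "AGAA"
  r <- allele_agreement_ratio(w_ref, w_alt, p2, 1)
  expect_equal(r, 0.70 / 0.05)
  expect_equal(allele_agreement_ratio(w_alt, w_ref, p2, 1), 1 / r)
})

test_that("motif_enrichment matches the closed-form OR and exact test", {
  mk_calls <- function(n_disrupt, n_total, motif = "M1") {
    data.table::data.table(
      variant_id = paste0("x", seq_len(n_total)),
      motif_id = motif,
      n_matches = 1L,
      interrupted = c(rep(TRUE, n_disrupt), rep(FALSE, n_total - n_disrupt)))
  }
  enr <- motif_enrichment(mk_calls(10, 100), mk_calls(5, 1000))
  expect_equal(enr$odds_ratio, (10 * 995) / (90 * 5))   # 22.11
  expect_equal(enr$p, fisher.test(matrix(c(10, 90, 5, 995), 2,
                                         byrow = TRUE))$p.value)
  # Fisher p equals the hypergeometric enumeration for a small table
  a <- 4; b <- 6; c_ <- 2; d <- 18
  ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
  probs <- dhyper(0:(a + c_), a + b, c_ + d, a + c_)
  exact <- sum(probs[probs <= dhyper(a, a + b, c_ + d, a + c_) * (1 + 1e-7)])
  expect_equal(ft, exact, tolerance = 1e-9)
  # identical proportions: OR ~ 1 and not enriched
  enr2 <- motif_enrichment(mk_calls(10, 100), mk_calls(100, 1000))
  expect_lt(abs(enr2$odds_ratio - 1), 0.05)
  expect_false(enr2$enriched)
  expect_error(motif_enrichment(mk_calls(0, 0), mk_calls(5, 10)), "empty")
})
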