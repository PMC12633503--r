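DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# Uniform random DNA strings (vectorized over n sequences of length len).
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Draw n distinct k-mers; errors out if the space cannot be filled after a
# bounded number of rounds (collision exhaustion).
random_distinct_dna <- function(n, len, max_rounds = 20L) {
  out <- character(0)
  for (i in seq_len(max_rounds)) {
    need <- n - length(out)
    if (need <= 0) break
    out <- unique(c(out, random_dna(ceiling(need * 1.1) + 8L, len)))
  }
  if (length(out) < n)
    stop("could not draw ", n, " distinct ", len, "-mers (collision exhaustion)")
  out[seq_len(n)]
}

# Independent substitution errors at the given per-base rate. Substituted
# bases are drawn from the three non-matching bases.
apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample.int(lens[i], nerr[i])
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(DNA_BASES, b), 1), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Number of mismatching characters between two equal-length strings.
str_mismatches <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

#' Locate a fixed adapter in reads
#'
#' Finds the leftmost occurrence of `adapter` allowing at most `max_mm`
#' substitutions (no indels), mirroring a 5' (`-g`) adapter trim. Returns the
#' 1-based position of the first base after the adapter, or `NA` when the
#' adapter is absent or does not fit.
#'
#' @param seqs character vector of reads.
#' @param adapter adapter sequence.
#' @param max_mm maximum substitutions (default 2).
#' @return integer vector: position after the adapter, or `NA`.
#' @export
find_adapter <- function(seqs, adapter, max_mm = 2L) {
  la <- nchar(adapter)
  out <- rep(NA_integer_, length(seqs))
  if (length(seqs) == 0) return(out)
  # fast path: adapter at read start, exact
  exact <- startsWith(seqs, adapter)
  out[exact] <- la + 1L
  todo <- which(!exact)
  if (length(todo)) {
    ar <- charToRaw(adapter)
    for (i in todo) {
      r <- charToRaw(seqs[i])
      n <- length(r)
      if (n < la) next
      for (s in 0:(n - la)) {
        if (sum(r[(s + 1):(s + la)] != ar) <= max_mm) {
          out[i] <- s + la + 1L
          break
        }
      }
    }
  }
  out
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (plain or gzip).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write sequences as FASTQ
#'
#' Four-line records with constant quality `I`.
#'
#' @param seqs character vector of sequences.
#' @param path output path.
#' @param ids read identifiers (default `read_1..n`).
#' @export
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n",
                strrep("I", nchar(seqs)))
  writeLines(rec, con)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  writeXStringSet(DNAStringSet(seqs), path)
  invisible(path)
}

# TSV helpers used by the CLI and pipeline.
write_tsv <- function(dt, path) {
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
read_tsv <- function(path) fread(path, sep = "\t")
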