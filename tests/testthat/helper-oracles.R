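# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (loops, enumeration, brute force) and
# never share code with the implementation paths they check.

tiny_design <- function(...) {
  args <- list(...)
  defaults <- list(n_f2 = 52L, chrom_length_bp = 2e6, n_snps = 2000L,
                   causal_pos = 1e6, misphenotype_prob = 0, seed = 99L)
  do.call(cross_design, utils::modifyList(defaults, args))
}

# hand-built pool-site table
make_sites <- function(n, chrom = "chr1", seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      chrom = chrom,
      pos = sort(sample.int(n * 100L, n)),
      ref = "A", alt = "G",
      qual = runif(n, 300, 3000),
      mut_ref = rpois(n, 18), mut_alt = rpois(n, 18),
      wt_ref = rpois(n, 18), wt_alt = rpois(n, 18),
      stringsAsFactors = FALSE
    )
  })
}

# brute-force window enumeration: emit every step-start whose span holds
# at least min_snps SNPs, chromosome by chromosome
oracle_windows <- function(chrom_sizes, window, step, min_snps) {
  out <- list()
  offset <- 0L
  for (ci in seq_along(chrom_sizes)) {
    n <- chrom_sizes[ci]
    s <- 1L
    while (s <= n) {
      e <- min(s + window - 1L, n)
      if (e - s + 1L >= min_snps) {
        out[[length(out) + 1L]] <- c(ci, offset + s, offset + e)
      }
      s <- s + step
    }
    offset <- offset + n
  }
  do.call(rbind, out)
}

# brute-force merge of 1-based inclusive intervals (single chromosome)
oracle_merge <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  res <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) {
      me <- max(me, ends[i])
    } else {
      res <- rbind(res, c(ms, me)); ms <- starts[i]; me <- ends[i]
    }
  }
  rbind(res, c(ms, me))
}

# Levenshtein distance of `sig` to the best-matching substring of `read`,
# by exhaustive enumeration of substrings scored with utils::adist
oracle_substring_dist <- function(sig, read) {
  n <- nchar(read)
  best <- nchar(sig)  # deleting all of sig never beats aligning to ""
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- utils::adist(sig, substr(read, i, j))
      if (d < best) best <- d
    }
  }
  min(best, nchar(sig) + 0)  # sig vs empty substring = nchar(sig)
}

# two-sided exact binomial p-value, minimum-likelihood convention, by
# direct enumeration
oracle_binom_p <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# translate a DNA string codon-by-codon with a literal codon table
oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  tab <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
           CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
           GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
           TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
           ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
           GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
           CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
           AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
           TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
           CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
           GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  paste(tab[codons], collapse = "")
}
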