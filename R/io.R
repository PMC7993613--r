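#' Write a pool-site table as a two-sample VCF
#'
#' Emits a minimal VCF 4.2 file with one sample column per pool (`MUT`,
#' `WT`) carrying `AD` (ref,alt read counts) and `DP`; positions are
#' 1-based as in the input table.
#'
#' @param sites Pool-site `data.frame`.
#' @param path Output path (plain text `.vcf`).
#' @return Invisibly, `path`.
#' @export
write_pool_vcf <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  chroms <- unique(as.character(sites$chrom))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsamap",
    sprintf("##contig=<ID=%s>", chroms),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tMUT\tWT"
  ), con)
  lines <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\t.\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
    sites$chrom, sites$pos, sites$ref, sites$alt, as.character(sites$qual),
    sites$mut_ref, sites$mut_alt, sites$mut_ref + sites$mut_alt,
    sites$wt_ref, sites$wt_alt, sites$wt_ref + sites$wt_alt
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read a two-sample pooled VCF into a pool-site table
#'
#' Uses `VariantAnnotation` to parse the VCF; the first two sample columns
#' are taken as the mutant and wild-type pools and their `AD` fields are
#' unpacked into per-pool ref/alt counts. Multiallelic records keep their
#' comma-separated `alt` string so the biallelic filter can act on them.
#'
#' @param path Path to a VCF file.
#' @param samples Optional length-2 character vector naming the mutant and
#'   wild-type sample columns (defaults to the first two).
#' @return Pool-site `data.frame` with the standard columns.
#' @export
read_pool_vcf <- function(path, samples = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  if (is.null(samples)) samples <- colnames(vcf)[1:2]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  get_counts <- function(sample) {
    x <- ad[, sample]
    list(ref = vapply(x, function(v) as.integer(v[1]), integer(1)),
         alt = vapply(x, function(v) as.integer(sum(v[-1])), integer(1)))
  }
  mut <- get_counts(samples[1])
  wt <- get_counts(samples[2])
  alt_chr <- vapply(as.list(rr$ALT), function(a) {
    paste(as.character(a), collapse = ",")
  }, character(1))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt_chr,
    qual = as.numeric(rr$QUAL),
    mut_ref = mut$ref, mut_alt = mut$alt,
    wt_ref = wt$ref, wt_alt = wt$alt,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a pool-site table as TSV
#'
#' Plain 9-column TSV (`chrom`, `pos`, `ref`, `alt`, `qual`, `mut_ref`,
#' `mut_alt`, `wt_ref`, `wt_alt`); truth columns from the simulator are
#' kept if present.
#'
#' @param sites Pool-site `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pool_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write simulated amplicon reads as FASTQ (with a truth sidecar)
#'
#' Sequences go to a plain-text FASTQ with uniform placeholder qualities;
#' truth labels (`read_id`, `true_isoform`) go to a TSV sidecar next to it
#' when present.
#'
#' @param reads `data.frame` from [simulate_amplicon_reads()] (columns
#'   `read_id`, `sequence`, optionally `true_isoform`).
#' @param path Output FASTQ path.
#' @param truth_path Sidecar TSV path (default `path` with `.truth.tsv`).
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path,
                              truth_path = paste0(path, ".truth.tsv")) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  if (!is.null(reads$true_isoform)) {
    utils::write.table(reads[, c("read_id", "true_isoform")], truth_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read FASTQ sequences into a read table
#'
#' @param path FASTQ path.
#' @return `data.frame` with `read_id`, `sequence`.
#' @export
read_reads_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(seqs), sequence = as.character(seqs),
             row.names = NULL, stringsAsFactors = FALSE)
}
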