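#' Demultiplex reads by exact barcode + adapter prefix
#'
#' A read is assigned to a sample if and only if its first
#' `nchar(barcode) + nchar(adapter)` bases exactly equal that sample's
#' barcode followed by the adapter overhang; anything else (including a
#' single mismatch in the barcode, or a read shorter than the prefix) is
#' `"unassigned"`. Exact matching over barcode plus a 10-bp overhang is a
#' deliberately stringent filter that compensates for the high error rate
#' of nanopore-class reads.
#'
#' @param reads Character vector of read sequences, or a `data.frame` with
#'   a `sequence` column.
#' @param barcodes Named character vector `sample -> 7-char barcode`.
#' @param adapter Adapter overhang sequence (default 10 bp).
#' @return Character vector of sample names (or `"unassigned"`), one per
#'   read.
#' @export
demultiplex <- function(reads, barcodes, adapter = "ACGTACGTAC") {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in configuration")
  if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
    stop("barcodes must be a named vector (sample -> barcode)")
  }
  if (any(nchar(barcodes) != 7L)) stop("barcodes must be exactly 7 characters")
  prefixes <- paste0(barcodes, adapter)
  plen <- nchar(prefixes[1])
  obs <- substr(reads, 1L, plen)
  hit <- match(obs, prefixes)
  out <- names(barcodes)[hit]
  out[is.na(hit) | nchar(reads) < plen] <- "unassigned"
  out
}

# Minimum edit distance between each signature and its best-matching
# substring of each read (semi-global alignment: signature global, read
# local). Unit costs via a 0/-1 substitution matrix and gap penalty 1.
signature_distances <- function(reads, signatures) {
  letters <- c("A", "C", "G", "T", "N")
  submat <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(submat) <- 0
  subj <- Biostrings::DNAStringSet(reads)
  vapply(signatures, function(sig) {
    -Biostrings::pairwiseAlignment(
      pattern = subj, subject = Biostrings::DNAString(sig),
      type = "local-global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 1, scoreOnly = TRUE
    )
  }, numeric(length(reads)))
}

#' Classify reads to isoforms by junction-signature edit distance
#'
#' For each read and each isoform, the edit distance between the isoform's
#' junction signature and its best-matching substring of the read is
#' computed by semi-global alignment. The read is assigned to the isoform
#' with the minimal distance provided that distance is at most
#' `max_dist_fraction` of the signature length; ties between isoforms and
#' distances above the tolerance yield `"unassigned"`.
#'
#' @param reads Character vector of read sequences (or `data.frame` with
#'   `sequence`).
#' @param signatures Named character vector `isoform -> junction
#'   signature`, e.g. from [isoform_table()]; must be pairwise distinct.
#' @param max_dist_fraction Acceptance tolerance as a fraction of each
#'   signature's length (default 0.2, nanopore-class error).
#' @return Character vector of isoform ids (or `"unassigned"`), one per
#'   read.
#' @export
classify_reads <- function(reads, signatures, max_dist_fraction = 0.2) {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (length(signatures) == 0L) stop("empty signature set")
  if (anyDuplicated(signatures)) stop("signatures must be pairwise distinct")
  if (length(reads) == 0L) return(character(0))
  d <- signature_distances(reads, signatures)
  d <- matrix(d, nrow = length(reads))
  limits <- max_dist_fraction * nchar(signatures)
  apply_row <- function(i) {
    di <- d[i, ]
    best <- min(di)
    hits <- which(di == best)
    if (length(hits) != 1L || best > limits[hits]) "unassigned"
    else names(signatures)[hits]
  }
  vapply(seq_along(reads), apply_row, character(1))
}

#' Relative isoform abundance from read assignments
#'
#' Proportions are computed over assigned reads only; unassigned reads are
#' reported separately and never silently folded into the denominator.
#' With a `sample` grouping vector the table is computed per sample.
#'
#' @param assignments Character vector of isoform ids / `"unassigned"`.
#' @param sample Optional grouping vector (same length).
#' @param isoform_levels Optional isoform ids fixing row order (defaults
#'   to the sorted observed ids); isoforms with zero assigned reads get
#'   explicit zero rows.
#' @return `data.frame` with `sample`, `isoform`, `count`, `proportion`,
#'   plus attribute `unassigned` (named count per sample). Empty (with a
#'   warning) if a group has no assigned reads.
#' @export
isoform_abundance <- function(assignments, sample = NULL, isoform_levels = NULL) {
  if (is.null(sample)) sample <- rep("all", length(assignments))
  stopifnot(length(sample) == length(assignments))
  assigned <- assignments != "unassigned"
  if (is.null(isoform_levels)) {
    isoform_levels <- sort(unique(assignments[assigned]))
  }
  groups <- unique(sample)
  out <- list()
  unassigned <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    in_g <- sample == g
    unassigned[g] <- sum(in_g & !assigned)
    n_assigned <- sum(in_g & assigned)
    if (n_assigned == 0L) {
      warning("no assigned reads in group '", g, "'")
      next
    }
    counts <- table(factor(assignments[in_g & assigned], levels = isoform_levels))
    out[[g]] <- data.frame(
      sample = g,
      isoform = isoform_levels,
      count = as.integer(counts),
      proportion = as.numeric(counts) / n_assigned,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(sample = character(0), isoform = character(0),
               count = integer(0), proportion = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "unassigned") <- unassigned
  res
}
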