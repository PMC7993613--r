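#' Build a gene model from genomic sequence and exon coordinates
#'
#' Exon coordinates are 1-based inclusive in genomic orientation (GFF
#' convention), ascending and non-overlapping. Minus-strand genes are
#' reverse-complemented into transcript orientation, so all derived exon
#' and intron sequences read 5' to 3' along the mRNA. Introns whose
#' transcript-oriented sequence does not begin `GT` and end `AG` are
#' flagged as non-canonical but accepted.
#'
#' @param gene_id Identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` or matrix with columns `start`, `end`
#'   (genomic, ascending).
#' @param seq Genomic plus-strand sequence of the region covering all
#'   exons (character or `DNAString`).
#' @param region_start Genomic coordinate of the first base of `seq`.
#' @param cds_offset 1-based position of the first base of the start codon
#'   within the spliced transcript (transcript orientation); `NA` marks a
#'   non-coding model.
#' @return A list of class `gene_model` with `exon_seqs`, `intron_seqs`
#'   (transcript orientation), `exons` (genomic coords), `strand`,
#'   `cds_offset`, `noncanonical_introns` (indices).
#' @export
gene_model <- function(gene_id, strand = "+", exons, seq, region_start = 1L,
                       cds_offset = 1L) {
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)), strand %in% c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons overlap or touch; introns must have positive length")
  }
  seq <- toupper(as.character(seq))
  sub_region <- function(s, e) substr(seq, s - region_start + 1L, e - region_start + 1L)
  n <- nrow(exons)
  exon_seqs <- mapply(sub_region, exons$start, exons$end)
  intron_seqs <- if (n > 1) {
    mapply(sub_region, exons$end[-n] + 1L, exons$start[-1] - 1L)
  } else character(0)
  if (strand == "-") {
    rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    exon_seqs <- rev(vapply(exon_seqs, rc, character(1)))
    intron_seqs <- rev(vapply(intron_seqs, rc, character(1)))
  }
  expected_len <- if (strand == "-") {
    rev(exons$start[-1] - exons$end[-n] - 1L)
  } else {
    exons$start[-1] - exons$end[-n] - 1L
  }
  if (length(intron_seqs) && !all(nchar(intron_seqs) == expected_len)) {
    stop("intron sequence length disagrees with coordinate span")
  }
  noncanon <- which(vapply(unname(intron_seqs), function(x) {
    substr(x, 1, 2) != "GT" || substr(x, nchar(x) - 1, nchar(x)) != "AG"
  }, logical(1), USE.NAMES = FALSE))
  if (length(noncanon)) {
    warning("non-canonical intron boundary at intron ",
            paste(noncanon, collapse = ", "))
  }
  structure(list(
    gene_id = gene_id, strand = strand, exons = exons,
    exon_seqs = unname(exon_seqs), intron_seqs = unname(intron_seqs),
    cds_offset = cds_offset, noncanonical_introns = noncanon
  ), class = "gene_model")
}

# Map a genomic position onto the 1-based offset within an intron, in
# transcript orientation. Returns NA when outside the intron.
intron_offset_of <- function(gene, intron_index, pos) {
  n <- nrow(gene$exons)
  if (intron_index < 1L || intron_index > n - 1L) {
    stop("intron index out of range")
  }
  genomic_idx <- if (gene$strand == "-") n - intron_index else intron_index
  lo <- gene$exons$end[genomic_idx] + 1L
  hi <- gene$exons$start[genomic_idx + 1L] - 1L
  if (pos < lo || pos > hi) return(NA_integer_)
  if (gene$strand == "-") hi - pos + 1L else pos - lo + 1L
}

#' Check whether a variant disrupts a splice-donor site
#'
#' The donor is the first two intronic bases (`GT` for a canonical
#' intron). A variant at donor position +1 or +2 that changes the base
#' away from `G` or `T` respectively disrupts the donor; variants deeper
#' in the intron leave it intact. A reference intron that does not start
#' `GT` is reported as non-canonical.
#'
#' @param gene A `gene_model`.
#' @param intron_index Intron number in transcript order (intron i follows
#'   exon i).
#' @param variant List or one-row `data.frame` with `pos` (genomic), `ref`,
#'   `alt` (plus-strand alleles).
#' @return One of `"intact"`, `"disrupted"`, `"non-canonical"`.
#' @export
check_donor <- function(gene, intron_index, variant) {
  if (intron_index < 1L || intron_index > length(gene$intron_seqs)) {
    stop("intron index out of range")
  }
  intron <- gene$intron_seqs[[intron_index]]
  if (substr(intron, 1, 2) != "GT") return("non-canonical")
  off <- intron_offset_of(gene, intron_index, variant$pos)
  if (is.na(off) || off > 2L) return("intact")
  alt <- toupper(variant$alt)
  if (gene$strand == "-") {
    alt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
  }
  needed <- c("G", "T")[off]
  if (alt != needed) "disrupted" else "intact"
}

#' Scan an intron for cryptic GT donor motifs
#'
#' Returns the 0-based offset of every `GT` dinucleotide in the
#' transcript-oriented intron sequence (overlapping occurrences included).
#' A cryptic donor at offset `k` splices after `k` retained intronic
#' nucleotides; offset 0 is the canonical donor itself.
#'
#' @param intron_seq Intron sequence, 5' to 3'.
#' @return Integer vector of ascending 0-based offsets (possibly empty).
#' @export
scan_cryptic_donors <- function(intron_seq) {
  intron_seq <- toupper(as.character(intron_seq))
  if (nchar(intron_seq) == 0L) stop("empty intron sequence")
  hits <- gregexpr("(?=GT)", intron_seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Construct intron-retention isoforms for a disrupted donor
#'
#' Builds the canonical transcript plus, for each cryptic-donor offset
#' `k`, an isoform retaining the first `k` intronic nucleotides of the
#' given intron. For each isoform the spliced sequence is translated from
#' the annotated start codon to determine frame (`retained_len %% 3 ==
#' 0`), the position of the first stop codon, and whether that stop is
#' premature (before the natural stop for in-frame retentions; any stop in
#' the shifted reading frame for frameshifts). A junction signature — a
#' contiguous window of `2 * flank` nt centered on the novel splice
#' junction — is recorded for read classification.
#'
#' @param gene A coding `gene_model`.
#' @param intron_index Intron retained (transcript order).
#' @param offsets Integer 0-based retained lengths, typically from
#'   [scan_cryptic_donors()]; offset 0 (the canonical donor) is ignored
#'   since the canonical isoform is always emitted first.
#' @param flank Half-width of the junction signature window (default 15).
#' @return List of class `isoform_set`; each element is an
#'   `isoform_model` list with `isoform_id`, `retained_len`,
#'   `junction_signature`, `in_frame`, `premature_stop`, `transcript`,
#'   `stop_aa`, `canonical_stop_aa`, `aa_before_junction`.
#' @export
build_isoforms <- function(gene, intron_index, offsets, flank = 15L) {
  intron <- gene$intron_seqs[[intron_index]]
  offsets <- sort(unique(as.integer(offsets)))
  offsets <- offsets[offsets != 0L]
  if (any(offsets < 0L | offsets > nchar(intron))) {
    stop("cryptic donor offset beyond intron length")
  }
  if (is.na(gene$cds_offset)) stop("gene model has no annotated reading frame")
  upstream <- paste(gene$exon_seqs[seq_len(intron_index)], collapse = "")
  downstream <- paste(gene$exon_seqs[-seq_len(intron_index)], collapse = "")
  first_stop <- function(cds) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1L, 3L * (nchar(cds) %/% 3L))),
      no.init.codon = TRUE))
    pos <- regexpr("*", aa, fixed = TRUE)
    if (pos == -1L) NA_integer_ else as.integer(pos)
  }
  canonical_cds <- substr(paste0(upstream, downstream), gene$cds_offset,
                          nchar(upstream) + nchar(downstream))
  canonical_stop <- first_stop(canonical_cds)
  cds_before_junction <- max(0L, nchar(upstream) - gene$cds_offset + 1L)
  one <- function(k, id) {
    retained <- substr(intron, 1L, k)
    transcript <- paste0(upstream, retained, downstream)
    cds <- substr(transcript, gene$cds_offset, nchar(transcript))
    stop_aa <- first_stop(cds)
    in_frame <- k %% 3L == 0L
    premature <- if (k == 0L) {
      FALSE
    } else if (in_frame) {
      !is.na(stop_aa) && !is.na(canonical_stop) &&
        stop_aa < canonical_stop + k %/% 3L
    } else {
      !is.na(stop_aa)
    }
    left <- paste0(upstream, retained)
    sig <- paste0(
      substr(left, max(1L, nchar(left) - flank + 1L), nchar(left)),
      substr(downstream, 1L, flank)
    )
    structure(list(
      isoform_id = id, retained_len = k, junction_signature = sig,
      in_frame = in_frame, premature_stop = premature,
      transcript = transcript, stop_aa = stop_aa,
      canonical_stop_aa = canonical_stop,
      aa_before_junction = cds_before_junction %/% 3L
    ), class = "isoform_model")
  }
  iso <- c(list(one(0L, "isoform_1")),
           lapply(seq_along(offsets), function(i) {
             one(offsets[i], sprintf("isoform_%d", i + 1L))
           }))
  structure(iso, class = "isoform_set")
}

#' Peptide-level consequence of an intron-retention isoform
#'
#' Classifies the protein outcome: `identity` for the canonical isoform;
#' `insertion` (with `inserted_aa = retained_len / 3`) for an in-frame
#' retention without a premature stop; `truncation` otherwise, reporting
#' the first stop codon's position counted from the first codon after the
#' junction (`truncation_at`, NA for a frameshift that never meets a stop).
#'
#' @param isoform An `isoform_model` from [build_isoforms()].
#' @return List of class `peptide_consequence` with `type` and either
#'   `inserted_aa` or `truncation_at`.
#' @export
peptide_consequence <- function(isoform) {
  if (is.null(isoform$retained_len) || is.null(isoform$in_frame)) {
    stop("isoform lacks frame annotation; build it with build_isoforms()")
  }
  if (isoform$retained_len == 0L) {
    out <- list(type = "identity")
  } else if (isoform$in_frame && !isoform$premature_stop) {
    out <- list(type = "insertion", inserted_aa = isoform$retained_len %/% 3L)
  } else {
    trunc_at <- if (is.na(isoform$stop_aa)) NA_integer_ else {
      as.integer(isoform$stop_aa - isoform$aa_before_junction)
    }
    out <- list(type = "truncation", truncation_at = trunc_at)
  }
  structure(out, class = "peptide_consequence")
}

#' Summarize an isoform set as a table
#'
#' @param isoforms An `isoform_set`.
#' @return `data.frame` with one row per isoform: id, retained length,
#'   frame and stop status, consequence type, and junction signature.
#' @export
isoform_table <- function(isoforms) {
  do.call(rbind, lapply(isoforms, function(x) {
    pc <- peptide_consequence(x)
    data.frame(
      isoform_id = x$isoform_id,
      retained_len = x$retained_len,
      in_frame = x$in_frame,
      premature_stop = x$premature_stop,
      consequence = pc$type,
      inserted_aa = if (pc$type == "insertion") pc$inserted_aa else NA_integer_,
      truncation_at = if (pc$type == "truncation") pc$truncation_at else NA_integer_,
      junction_signature = x$junction_signature,
      stringsAsFactors = FALSE
    )
  }))
}

#' Generate a synthetic coding gene model with planted cryptic donors
#'
#' Builds a random multi-exon coding gene whose target intron starts with
#' a canonical `GT` donor and contains cryptic `GT` motifs at exactly the
#' requested offsets (no accidental `GT` elsewhere in that intron, and no
#' stop codon readable within any planted retained segment, so in-frame
#' retentions translate cleanly). Used by tests and the amplicon
#' simulator; the default offsets mirror the 8/15/221-nt retention
#' pattern of a disrupted mammalian donor site.
#'
#' @param seed Integer seed.
#' @param n_exons Number of exons (>= target intron + 1).
#' @param exon_len Exon length in nt (multiple of 3 keeps junctions at
#'   codon boundaries).
#' @param intron_len Length of every intron; must exceed
#'   `max(gt_offsets) + 2`.
#' @param gt_offsets 0-based cryptic donor offsets planted in the target
#'   intron.
#' @param which_intron Target intron index (transcript order).
#' @param utr5,utr3 Untranslated flank lengths inside first/last exon.
#' @return A `gene_model` (plus attribute `target_intron`).
#' @export
synthetic_gene_model <- function(seed = 1L, n_exons = 4L, exon_len = 90L,
                                 intron_len = 300L, gt_offsets = c(8L, 15L, 221L),
                                 which_intron = 2L, utr5 = 12L, utr3 = 15L) {
  stopifnot(which_intron >= 1L, which_intron < n_exons,
            intron_len > max(gt_offsets) + 2L, exon_len %% 3L == 0L)
  local_seed(seed, {
    no_t <- c("A", "C", "G")
    # coding sequence: start codon, non-stop codons, terminal stop
    n_cds <- n_exons * exon_len - utr5 - utr3
    stopifnot(n_cds %% 3L == 0L, n_cds >= 6L)
    codons <- apply(matrix(sample(c("A", "C", "G", "T"),
                                  3L * (n_cds %/% 3L - 2L), replace = TRUE),
                           nrow = 3L), 2, paste, collapse = "")
    codons[codons %in% c("TAA", "TAG", "TGA")] <- "TGG"
    tx <- paste0(
      paste(sample(no_t, utr5, replace = TRUE), collapse = ""),
      "ATG", paste(codons, collapse = ""), "TAA",
      paste(sample(no_t, utr3, replace = TRUE), collapse = "")
    )
    exon_seqs <- substring(tx, (seq_len(n_exons) - 1L) * exon_len + 1L,
                           seq_len(n_exons) * exon_len)
    make_intron <- function(planted) {
      s <- sample(no_t, intron_len, replace = TRUE)
      for (k in c(0L, planted)) {
        s[k + 1L] <- "G"
        s[k + 2L] <- "T"
        if (k + 3L <= intron_len) s[k + 3L] <- "C"  # no stop readable off this T
      }
      s[intron_len - 1L] <- "A"
      s[intron_len] <- "G"
      paste(s, collapse = "")
    }
    introns <- vapply(seq_len(n_exons - 1L), function(i) {
      make_intron(if (i == which_intron) as.integer(gt_offsets) else integer(0))
    }, character(1))
    # genomic assembly, plus strand
    genomic <- paste0(paste0(exon_seqs[-n_exons], introns, collapse = ""),
                      exon_seqs[n_exons])
    starts <- (seq_len(n_exons) - 1L) * (exon_len + intron_len) + 1L
    g <- gene_model(
      gene_id = sprintf("synth_gene_%d", seed), strand = "+",
      exons = data.frame(start = starts, end = starts + exon_len - 1L),
      seq = genomic, region_start = 1L, cds_offset = utr5 + 1L
    )
    attr(g, "target_intron") <- which_intron
    g
  })
}
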