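#' Construct a gene model
#'
#' A gene model describes one protein-coding gene: its contig, strand, and
#' ordered CDS intervals (1-based inclusive, ascending genomic coordinates),
#' plus the promoter and terminator extents used for feature assignment
#' (promoter = region upstream of the gene start on the coding strand,
#' terminator = region downstream of the gene end).
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals Two-column matrix of `[start, end]` pairs, 1-based
#'   inclusive, sorted ascending and non-overlapping.
#' @param promoter_length Promoter extent in bases upstream of the gene start
#'   (default 1000).
#' @param terminator_length Terminator extent in bases downstream of the gene
#'   end (default 200).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, cds_intervals,
                       promoter_length = 1000L, terminator_length = 200L) {
  cds_intervals <- matrix(as.integer(cds_intervals), ncol = 2)
  if (!strand %in% c("+", "-"))
    stop_mutspectra("gene %s: strand must be '+' or '-'", gene_id)
  if (nrow(cds_intervals) == 0L)
    stop_mutspectra("gene %s: needs at least one CDS interval", gene_id)
  o <- order(cds_intervals[, 1])
  cds_intervals <- cds_intervals[o, , drop = FALSE]
  if (any(cds_intervals[, 2] < cds_intervals[, 1]))
    stop_mutspectra("gene %s: CDS interval end < start", gene_id)
  if (nrow(cds_intervals) > 1 &&
      any(cds_intervals[-1, 1] <= cds_intervals[-nrow(cds_intervals), 2]))
    stop_mutspectra("gene %s: CDS intervals overlap", gene_id)
  structure(
    list(gene_id = as.character(gene_id), contig = as.character(contig),
         strand = strand, cds_intervals = cds_intervals,
         promoter_length = as.integer(promoter_length),
         terminator_length = as.integer(terminator_length)),
    class = "gene_model"
  )
}

#' Construct a genome model
#'
#' Bundles contig sequences with their gene models.  Contig sequences must be
#' plain A/C/G/T (no ambiguity codes); gene CDS intervals must lie within
#' their contig and CDSs of different genes must not overlap.
#'
#' @param contigs Named character vector of contig sequences.
#' @param genes List of [gene_model()] objects (may be empty).
#' @param validate_orfs If `TRUE` (default), check that each spliced CDS is a
#'   valid ORF: length a multiple of 3, starts with ATG, ends with a stop
#'   codon, and has no internal stop codon.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(contigs, genes = list(), validate_orfs = TRUE) {
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    stop_mutspectra("contigs must be a named character vector")
  contigs <- stats::setNames(toupper(contigs), names(contigs))
  if (any(grepl("[^ACGT]", contigs)))
    stop_mutspectra("contig sequences may contain only A/C/G/T")
  genome <- structure(list(contigs = contigs, genes = genes),
                      class = "genome_model")
  validate_genome(genome, validate_orfs = validate_orfs)
  genome
}

validate_genome <- function(genome, validate_orfs = TRUE) {
  for (g in genome$genes) {
    if (!g$contig %in% names(genome$contigs))
      stop_mutspectra("gene %s: unknown contig %s", g$gene_id, g$contig)
    len <- nchar(genome$contigs[[g$contig]])
    if (g$cds_intervals[1, 1] < 1L || max(g$cds_intervals[, 2]) > len)
      stop_mutspectra("gene %s: CDS outside contig bounds", g$gene_id)
  }
  ## pairwise CDS overlap between genes on the same contig
  spans <- lapply(genome$genes, function(g)
    c(g$cds_intervals[1, 1], max(g$cds_intervals[, 2])))
  ctg <- vapply(genome$genes, `[[`, character(1), "contig")
  if (length(genome$genes) > 1) {
    for (cn in unique(ctg)) {
      idx <- which(ctg == cn)
      if (length(idx) < 2) next
      s <- do.call(rbind, spans[idx])
      o <- order(s[, 1])
      s <- s[o, , drop = FALSE]
      if (any(s[-1, 1] <= s[-nrow(s), 2]))
        stop_mutspectra("CDSs of two genes overlap on contig %s", cn)
    }
  }
  if (validate_orfs) {
    for (g in genome$genes) {
      cds <- spliced_cds(genome, g$gene_id)
      if (nchar(cds) %% 3L != 0L)
        stop_mutspectra("gene %s: CDS length %d not a multiple of 3",
                        g$gene_id, nchar(cds))
      aa <- translate_cds(cds)
      n <- nchar(aa)
      if (substr(cds, 1, 3) != "ATG")
        stop_mutspectra("gene %s: CDS does not begin with ATG", g$gene_id)
      if (substr(aa, n, n) != "*")
        stop_mutspectra("gene %s: CDS does not end with a stop codon",
                        g$gene_id)
      if (grepl("\\*", substr(aa, 1, n - 1)))
        stop_mutspectra("gene %s: internal stop codon", g$gene_id)
    }
  }
  invisible(genome)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("Genome model: %d contig(s), %s bp total, %d gene(s)\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              length(x$genes)))
  invisible(x)
}

get_gene <- function(genome, gene_id) {
  for (g in genome$genes) if (g$gene_id == gene_id) return(g)
  stop_mutspectra("unknown gene %s", gene_id)
}

gene_span <- function(g) {
  c(start = g$cds_intervals[1, 1], end = max(g$cds_intervals[, 2]))
}

## Spliced CDS on the coding strand (introns removed; minus-strand genes are
## reverse-complemented and read in transcription order).
spliced_cds <- function(genome, gene_id) {
  g <- if (inherits(gene_id, "gene_model")) gene_id else get_gene(genome, gene_id)
  seq <- genome$contigs[[g$contig]]
  parts <- apply(g$cds_intervals, 1, function(iv) substr(seq, iv[1], iv[2]))
  fwd <- paste(parts, collapse = "")
  if (g$strand == "+") fwd else revcomp(fwd)
}

## Translate a coding-strand nucleotide string with the standard nuclear code.
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}
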