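#' Write a genome model to FASTA
#'
#' @param genome A [genome_model()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a genome model's annotation to GFF3
#'
#' Emits one `gene` record per gene (spanning the CDS extent) and one `CDS`
#' record per CDS interval, 1-based inclusive, with `ID`/`Parent` attributes.
#' Promoter and terminator extents are carried as `promoter_length` /
#' `terminator_length` attributes on the gene records so that a genome model
#' round-trips through FASTA + GFF3.
#'
#' @param genome A [genome_model()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_genome_gff3 <- function(genome, path) {
  if (length(genome$genes) == 0L) {
    gr <- GenomicRanges::GRanges()
    rtracklayer::export(gr, path, format = "GFF3")
    return(invisible(path))
  }
  rows <- list()
  for (g in genome$genes) {
    sp <- gene_span(g)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = g$contig, start = sp["start"], end = sp["end"],
      strand = g$strand, type = "gene", ID = g$gene_id, Parent = NA_character_,
      phase = NA_integer_, promoter_length = g$promoter_length,
      terminator_length = g$terminator_length, stringsAsFactors = FALSE)
    widths <- g$cds_intervals[, 2] - g$cds_intervals[, 1] + 1L
    n_iv <- nrow(g$cds_intervals)
    ## GFF3 phase: bases to skip to reach the next codon start, per interval
    ## in transcription order
    tx_order <- if (g$strand == "+") seq_len(n_iv) else rev(seq_len(n_iv))
    prior <- c(0L, cumsum(widths[tx_order]))[seq_len(n_iv)]
    phase <- integer(n_iv)
    phase[tx_order] <- (3L - prior %% 3L) %% 3L
    for (i in seq_len(n_iv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = g$contig, start = g$cds_intervals[i, 1],
        end = g$cds_intervals[i, 2], strand = g$strand, type = "CDS",
        ID = sprintf("%s.cds%d", g$gene_id, i), Parent = g$gene_id,
        phase = phase[i], promoter_length = NA_integer_,
        terminator_length = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$promoter_length <- df$promoter_length
  S4Vectors::mcols(gr)$terminator_length <- df$terminator_length
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a genome model from FASTA + GFF3
#'
#' Inverse of [write_genome_fasta()] / [write_genome_gff3()].  Gene models are
#' reconstructed from `gene` records and their child `CDS` records; missing
#' `promoter_length` / `terminator_length` attributes default to 1000 and
#' 200 bases.
#'
#' @param fasta Path to the reference FASTA.
#' @param gff3 Path to the GFF3 annotation.
#' @param validate_orfs Passed to [genome_model()].
#' @return A [genome_model()].
#' @export
read_genome <- function(fasta, gff3, validate_orfs = TRUE) {
  ss <- Biostrings::readDNAStringSet(fasta)
  contigs <- stats::setNames(as.character(ss),
                             sub("\\s.*$", "", names(ss)))
  gr <- rtracklayer::import(gff3, format = "GFF3")
  genes <- list()
  if (length(gr)) {
    md <- S4Vectors::mcols(gr)
    is_gene <- md$type == "gene"
    gene_ids <- as.character(md$ID[is_gene])
    parent_of <- function(i) {
      p <- md$Parent[[i]]
      if (length(p) == 0L || identical(p, "")) NA_character_ else as.character(p)[1]
    }
    for (k in which(is_gene)) {
      gid <- as.character(md$ID[k])
      cds_idx <- which(md$type == "CDS" &
                       vapply(seq_along(gr), parent_of, character(1)) == gid)
      if (length(cds_idx) == 0L)
        stop_mutspectra("gene %s has no CDS records", gid)
      ivs <- cbind(GenomicRanges::start(gr)[cds_idx],
                   GenomicRanges::end(gr)[cds_idx])
      pl <- md$promoter_length[k]
      tl <- md$terminator_length[k]
      genes[[length(genes) + 1L]] <- gene_model(
        gid, as.character(GenomicRanges::seqnames(gr)[k]),
        as.character(GenomicRanges::strand(gr)[k]), ivs,
        if (is.na(pl)) 1000L else as.integer(pl),
        if (is.na(tl)) 200L else as.integer(tl))
    }
  }
  genome_model(contigs, genes, validate_orfs = validate_orfs)
}

#' Write variant records to VCF v4.2
#'
#' Writes a sites-style VCF with `QUAL` carrying the Phred-scaled variant
#' quality and INFO fields `DP` (total read depth), `MQ` (Phred-scaled
#' mapping quality) and `VAF` (variant allele fraction).
#'
#' @param records Variant record data.frame (see [read_vcf_records()] for the
#'   column set).
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf_records <- function(records, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mutspectra",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth at the site\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Phred-scaled mapping quality\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- hdr
  if (nrow(records)) {
    records <- records[order(records$contig, records$pos), ]
    info <- sprintf("DP=%d;MQ=%s;VAF=%s", as.integer(records$depth),
                    format(records$mapping_quality, trim = TRUE,
                           scientific = FALSE),
                    format(records$vaf, trim = TRUE, scientific = FALSE))
    lines <- c(lines,
               sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s",
                       records$contig, as.integer(records$pos), records$ref,
                       records$alt,
                       format(records$variant_quality, trim = TRUE,
                              scientific = FALSE),
                       info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read variant records from a VCF
#'
#' Parses a VCF (via \pkg{vcfR}) into the flat variant-record data.frame used
#' throughout the package: one row per allele with columns `contig`, `pos`,
#' `ref`, `alt`, `kind`, `depth`, `variant_quality`, `mapping_quality`,
#' `vaf`, `sample_id`.  Multi-allelic records are split into one row per
#' alternate allele (each allele is filtered independently; site-level INFO
#' annotations are copied to every allele).
#'
#' @param path VCF path.
#' @param sample_id Sample identifier to attach.
#' @return A variant record data.frame.
#' @export
read_vcf_records <- function(path, sample_id = NA_character_) {
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(body) == 0L) return(empty_variant_records())
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  vaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "VAF")))
  qual <- suppressWarnings(as.numeric(fx[, "QUAL"]))
  alt_list <- strsplit(as.character(fx[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  i <- rep(seq_len(nrow(fx)), n_alt)
  out <- data.frame(
    contig = as.character(fx[i, "CHROM"]),
    pos = as.integer(fx[i, "POS"]),
    ref = as.character(fx[i, "REF"]),
    alt = unlist(alt_list),
    stringsAsFactors = FALSE)
  out$kind <- variant_kind(out$ref, out$alt)
  out$depth <- dp[i]
  out$variant_quality <- qual[i]
  out$mapping_quality <- mq[i]
  out$vaf <- vaf[i]
  out$sample_id <- sample_id
  out
}

#' Write / read the simulator truth table
#'
#' @param truth Truth data.frame (`contig`, `pos`, `ref`, `alt`,
#'   `violated_criterion`).
#' @param path TSV path.
#' @return `path` (writer) or the truth data.frame (reader).
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "character", "character"))
}

#' Read a BED mask of excluded intervals
#'
#' BED is 0-based half-open; intervals are converted to the 1-based inclusive
#' coordinates used throughout the package.
#'
#' @param path BED path (columns: contig, start, end; further columns
#'   ignored).
#' @return Data.frame with `contig`, `start`, `end` (1-based inclusive).
#' @export
read_bed_mask <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(contig = as.character(df[[1]]),
             start = as.integer(df[[2]]) + 1L,
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}
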