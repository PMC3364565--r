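#' Generate a random annotated haploid genome
#'
#' Builds a toy genome that stands in for a small annotated haploid reference:
#' random background sequence at a chosen GC content, with non-overlapping
#' protein-coding genes written onto it.  Every gene is a valid ORF (ATG
#' start, single terminal stop, no internal stops); a fraction of genes may
#' carry one spliceosomal-style intron (GT...AG), which splits the CDS into
#' two intervals and exercises the intron feature class downstream.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bases.
#' @param n_genes Total number of genes, distributed round-robin over contigs.
#' @param gc_content Target GC fraction of the background sequence.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param gene_codon_range Range (min, max) of codon counts per gene,
#'   including start and stop codons.
#' @param intron_prob Probability that a gene carries one intron.
#' @param intron_length_range Range of intron lengths in bases.
#' @param promoter_length,terminator_length Feature extents recorded on each
#'   gene (defaults: 1 kb promoter, 200 bp terminator).
#' @param min_gap Minimum spacing in bases between adjacent gene bodies.
#' @return A [genome_model()].
#' @examples
#' g <- generate_genome(1, 20000, 5, gc_content = 0.38, seed = 1)
#' g
#' @export
generate_genome <- function(n_contigs = 1L, contig_length = 50000L,
                            n_genes = 10L, gc_content = 0.38, seed = 1L,
                            gene_codon_range = c(100L, 200L),
                            intron_prob = 0, intron_length_range = c(60L, 120L),
                            promoter_length = 1000L, terminator_length = 200L,
                            min_gap = 20L) {
  stopifnot(n_contigs >= 1L, contig_length >= 1L, n_genes >= 0L,
            gc_content > 0, gc_content < 1)
  with_seed(seed, {
    base_p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
                G = gc_content / 2, T = (1 - gc_content) / 2)
    contig_names <- sprintf("contig%02d", seq_len(n_contigs))
    contigs <- stats::setNames(vapply(contig_names, function(cn) {
      paste(sample(names(base_p), contig_length, replace = TRUE, prob = base_p),
            collapse = "")
    }, character(1)), contig_names)

    gene_contig <- contig_names[((seq_len(n_genes) - 1L) %% n_contigs) + 1L]
    genes <- list()
    gi <- 0L
    for (cn in contig_names) {
      k <- sum(gene_contig == cn)
      if (k == 0L) next
      n_codons <- sample(gene_codon_range[1]:gene_codon_range[2], k,
                         replace = TRUE)
      has_intron <- stats::runif(k) < intron_prob
      intron_len <- ifelse(has_intron,
                           sample(intron_length_range[1]:intron_length_range[2],
                                  k, replace = TRUE), 0L)
      foot <- 3L * n_codons + intron_len
      slack <- contig_length - sum(foot) - (k + 1L) * min_gap
      if (slack < 0L)
        stop_mutspectra(
          "cannot place %d genes (%d bp + gaps) on a %d bp contig %s",
          k, sum(foot), contig_length, cn)
      ## random non-overlapping placement: spread the slack over k+1 gaps
      cuts <- sort(stats::runif(k))
      extra <- floor(diff(c(0, cuts, 1)) * slack)
      starts <- integer(k)
      at <- 0L
      for (j in seq_len(k)) {
        at <- at + min_gap + extra[j]
        starts[j] <- at + 1L
        at <- at + foot[j]
      }
      for (j in seq_len(k)) {
        gi <- gi + 1L
        strand <- sample(c("+", "-"), 1L)
        cds_seq <- random_orf(n_codons[j], base_p)
        if (has_intron[j]) {
          iv_len <- intron_len[j]
          cut <- sample(4:(3L * n_codons[j] - 4L), 1L)  # inside the CDS
          intron <- paste0("GT",
                           paste(sample(names(base_p), iv_len - 4L,
                                        replace = TRUE, prob = base_p),
                                 collapse = ""), "AG")
          tx_seq <- paste0(substr(cds_seq, 1L, cut), intron,
                           substr(cds_seq, cut + 1L, 3L * n_codons[j]))
          ## exon intervals in transcription orientation
          ex1 <- c(1L, cut)
          ex2 <- c(cut + iv_len + 1L, nchar(tx_seq))
          ivs <- rbind(ex1, ex2)
        } else {
          tx_seq <- cds_seq
          ivs <- rbind(c(1L, nchar(tx_seq)))
        }
        genomic_seq <- if (strand == "+") tx_seq else revcomp(tx_seq)
        s0 <- starts[j]
        if (strand == "-") {
          L <- nchar(tx_seq)
          ivs <- cbind(L - ivs[, 2] + 1L, L - ivs[, 1] + 1L)
          ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
        }
        ivs <- ivs + s0 - 1L
        substr(contigs[[cn]], s0, s0 + nchar(genomic_seq) - 1L) <- genomic_seq
        genes[[gi]] <- gene_model(sprintf("gene%03d", gi), cn, strand, ivs,
                                  promoter_length, terminator_length)
      }
    }
    genome_model(contigs, genes)
  })
}

## A random ORF of n_codons codons: ATG + sense codons + stop, with sense
## codons drawn with probability proportional to the product of base
## frequencies (so genome GC bias carries into coding sequence).
random_orf <- function(n_codons, base_p) {
  stopifnot(n_codons >= 3L)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  w <- vapply(strsplit(sense, ""), function(b) prod(base_p[b]), numeric(1))
  body <- sample(sense, n_codons - 2L, replace = TRUE, prob = w)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste(c("ATG", body, stop_codon), collapse = "")
}
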