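# Hand-built deterministic fixtures used across test files.

## A tiny two-gene genome where every codon is known by construction:
##   geneA (+ strand): CDS 11..31, ATG GGA TGG CTG AAA GCC TAA
##                     (M   G   W   L   K   A   *)
##   geneB (- strand): coding-strand CDS ATG CCT GAA TAA split by an intron;
##     laid out on the genome reverse-complemented.
tiny_genome <- function(promoter_length = 5L, terminator_length = 3L) {
  pad <- function(n) paste(rep("T", n), collapse = "")
  geneA <- "ATGGGATGGCTGAAAGCCTAA"           # 21 bp, + strand at 11..31
  ## geneB transcript: exon1 ATGCC (5) + intron GTAAAG (6) + exon2 TGAATAA (7)
  tx <- "ATGCCGTAAAGTGAATAA"
  geneB_genomic <- mutspectra:::revcomp(tx)   # 18 bp, placed at 51..68
  seq <- paste0(pad(10), geneA, pad(19), geneB_genomic, pad(12))
  stopifnot(nchar(seq) == 80)
  gA <- gene_model("geneA", "chr1", "+", rbind(c(11L, 31L)),
                   promoter_length, terminator_length)
  ## genomic coordinates of geneB exons: tx positions 1..5 -> 64..68,
  ## 12..18 -> 51..57 (reverse-complement layout)
  gB <- gene_model("geneB", "chr1", "-", rbind(c(51L, 57L), c(64L, 68L)),
                   promoter_length, terminator_length)
  genome_model(c(chr1 = seq), list(gA, gB))
}

## A clean variant record with optional field overrides.
make_record <- function(contig = "chr1", pos = 1L, ref = "A", alt = "G",
                        depth = 50, variant_quality = 90,
                        mapping_quality = 50, vaf = 1.0,
                        sample_id = "s1", in_parental = FALSE) {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             kind = mutspectra:::variant_kind(ref, alt),
             depth = depth, variant_quality = variant_quality,
             mapping_quality = mapping_quality, vaf = vaf,
             sample_id = sample_id, in_parental = in_parental,
             stringsAsFactors = FALSE)
}

## Six-record set: one clean record plus one violation of each criterion.
waterfall_records <- function() {
  rbind(
    make_record(pos = 10L),                                  # clean
    make_record(pos = 20L, depth = 9),                       # depth
    make_record(pos = 30L, variant_quality = 19.9),          # quality
    make_record(pos = 40L, mapping_quality = 29),            # mapping quality
    make_record(pos = 50L, vaf = 0.90),                      # vaf (boundary)
    make_record(pos = 60L, in_parental = TRUE)               # parental
  )
}

## Build protein-impact records with a given composition, for table tests.
## Amino-acid pairs are chosen so conservation and Gly/Pro involvement are
## unambiguous: (L,M) conservative, (A,W) nonconservative without Gly/Pro,
## (G,V) nonconservative involving Gly.
make_impacts <- function(n_preserved = 0, n_conservative = 0,
                         n_nonconservative = 0, n_glypro_changed = 0,
                         n_stop = 0, codon_positions = NULL) {
  one <- function(effect, ref_aa, alt_aa, conservation, score) {
    data.frame(gene_id = "g", codon_index = 1L, codon_position = 1L,
               ref_codon = "NNN", alt_codon = "NNN",
               ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
               blosum_score = score, conservation = conservation,
               stringsAsFactors = FALSE)
  }
  rows <- c(
    replicate(n_preserved, one("preserved", "A", "A", "not_applicable", NA),
              simplify = FALSE),
    replicate(n_conservative, one("changed", "L", "M", "conservative", 2L),
              simplify = FALSE),
    replicate(n_nonconservative, one("changed", "A", "W", "nonconservative",
                                     -3L), simplify = FALSE),
    replicate(n_glypro_changed, one("changed", "G", "V", "nonconservative",
                                    -3L), simplify = FALSE),
    replicate(n_stop, one("stop_gained", "W", "*", "not_applicable", NA),
              simplify = FALSE)
  )
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- one("preserved", "A", "A", "not_applicable", NA)[0, ]
  if (!is.null(codon_positions)) out$codon_position <- codon_positions
  out
}
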