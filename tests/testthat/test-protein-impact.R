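test_that("codon_effect handles wobble synonymy and stop gain on the tiny genome", {
  g <- tiny_genome()
  ## geneA codon 2 is GGA (Gly) at genomic 14..16; third position 16 A->G
  ## gives GGG, still Gly
  r <- codon_effect(data.frame(contig = "chr1", pos = 16L, ref = "A",
                               alt = "G"), g)
  expect_identical(r$effect, "preserved")
  expect_identical(r$codon_index, 2L)
  expect_identical(r$codon_position, 3L)
  expect_identical(r$ref_aa, "G")
  ## geneA codon 3 is TGG (Trp) at 17..19; TGG->TGA at position 3 gains a stop
  r <- codon_effect(data.frame(contig = "chr1", pos = 19L, ref = "G",
                               alt = "A"), g)
  expect_identical(r$effect, "stop_gained")
  expect_identical(r$alt_aa, "*")
  expect_identical(r$ref_codon, "TGG")
  expect_identical(r$alt_codon, "TGA")
})

test_that("minus-strand genes are handled on the coding strand", {
  g <- tiny_genome()
  ## geneB codon 2 is CCT (Pro); its first base C is tx position 4, genomic
  ## position 69 - 4 = 65 with genomic base G (complement). A genomic G->A
  ## change is a coding-strand C->T: CCT -> TCT, Pro -> Ser.
  r <- codon_effect(data.frame(contig = "chr1", pos = 65L, ref = "G",
                               alt = "A"), g)
  expect_identical(r$gene_id, "geneB")
  expect_identical(r$codon_index, 2L)
  expect_identical(r$codon_position, 1L)
  expect_identical(r$ref_codon, "CCT")
  expect_identical(r$alt_codon, "TCT")
  expect_identical(r$ref_aa, "P")
  expect_identical(r$alt_aa, "S")
  expect_identical(r$effect, "changed")
})

test_that("strand invariance: reverse-complementing the genome preserves impacts", {
  g <- generate_genome(1, 20000, 6, seed = 30, intron_prob = 0.3)
  m <- sample_mutations(g, mutagen_profile("mutator"), 300, seed = 31)
  m <- assign_feature(m, g)
  ex <- m[m$feature == "exon", ]
  imp1 <- codon_effect(ex, g)

  ## build the reverse-complemented genome with remapped annotation
  L <- nchar(g$contigs[[1]])
  rc_genes <- lapply(g$genes, function(gm) {
    ivs <- cbind(L - gm$cds_intervals[, 2] + 1L, L - gm$cds_intervals[, 1] + 1L)
    gene_model(gm$gene_id, gm$contig, if (gm$strand == "+") "-" else "+",
               ivs, gm$promoter_length, gm$terminator_length)
  })
  g_rc <- genome_model(
    stats::setNames(mutspectra:::revcomp(g$contigs[[1]]), names(g$contigs)),
    rc_genes)
  ex_rc <- ex
  ex_rc$pos <- L - ex$pos + 1L
  ex_rc$ref <- mutspectra:::complement_base(ex$ref)
  ex_rc$alt <- mutspectra:::complement_base(ex$alt)
  imp2 <- codon_effect(ex_rc, g_rc)
  for (col in c("gene_id", "codon_index", "codon_position", "ref_codon",
                "alt_codon", "ref_aa", "alt_aa", "effect", "conservation")) {
    expect_identical(imp1[[col]], imp2[[col]])
  }
})

test_that("synonymous closure: all 64 x 9 single-base codon changes match the genetic code", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  code <- sapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd), no.init.codon = TRUE)))
  checked <- 0L
  for (cd in codons) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cd, p, p))) {
        alt_cd <- cd
        substr(alt_cd, p, p) <- b
        ## embed the codon as codon 2 of a synthetic plus-strand gene
        seq <- paste0("TTTTTTTTTT", "ATG", cd, "TGTTAA", "TTTTTTTTTT")
        gm <- gene_model("g1", "c1", "+", rbind(c(11L, 22L)), 2L, 2L)
        genome <- genome_model(c(c1 = seq), list(gm), validate_orfs = FALSE)
        r <- codon_effect(data.frame(contig = "c1", pos = 13L + p,
                                     ref = substr(cd, p, p), alt = b),
                          genome)
        ref_aa <- code[[cd]]
        alt_aa <- code[[alt_cd]]
        expected <- if (ref_aa == alt_aa) "preserved"
                    else if (alt_aa == "*") "stop_gained"
                    else "changed"
        expect_identical(r$effect, expected)
        expect_identical(r$ref_aa, ref_aa)
        expect_identical(r$alt_aa, alt_aa)
        expect_identical(r$codon_position, p)
        checked <- checked + 1L
      }
    }
  }
  expect_identical(checked, 64L * 9L)
})

test_that("conservation calls follow BLOSUM62 with a strict positive threshold", {
  expect_identical(classify_conservation("L", "M")$conservation,
                   "conservative")
  expect_identical(classify_conservation("G", "W")$conservation,
                   "nonconservative")
  expect_identical(classify_conservation("L", "M")$blosum_score, 2L)
  ## zero scores are nonconservative by default, conservative when inclusive
  expect_identical(classify_conservation("A", "G")$conservation,
                   "nonconservative")  # score 0
  expect_identical(classify_conservation("A", "G",
                                         inclusive = TRUE)$conservation,
                   "conservative")
  expect_error(classify_conservation("A", "A"), "differ")
  expect_error(classify_conservation("A", "*"), "invalid")
})

test_that("the shipped BLOSUM62 matrix matches the Biostrings reference copy", {
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  aa <- rownames(BLOSUM62)
  expect_identical(unname(BLOSUM62), unname(ref[aa, aa] + 0L))
})

test_that("protein_table reproduces the published protein-level percentages", {
  ## mutator column: 28 total = 2 preserved + 24 changed (4 conservative,
  ## 20 nonconservative of which 2 involve Gly/Pro) + 2 stops
  mut <- make_impacts(n_preserved = 2, n_conservative = 4,
                      n_nonconservative = 18, n_glypro_changed = 2,
                      n_stop = 2)
  t_mut <- protein_table(mut)
  expect_equal(round(t_mut$changed_pct, 1), 85.7)
  expect_equal(round(t_mut$preserved_pct, 1), 7.1)
  expect_equal(round(t_mut$stop_pct, 1), 7.1)
  expect_equal(round(t_mut$nonconservative_pct, 1), 83.3)
  ## the structure indicator uses (changes + stops) = 26 as denominator
  expect_identical(t_mut$stop_and_glypro, 4L)
  expect_equal(round(t_mut$stop_and_glypro_pct, 1), 15.4)
  expect_equal(t_mut$stop_split_pct, 50.0)
  expect_equal(t_mut$glypro_split_pct, 50.0)

  ## EMS column: 201 = 74 preserved + 123 changed (57 conservative,
  ## 66 nonconservative, none Gly/Pro) + 4 stops
  ems <- make_impacts(n_preserved = 74, n_conservative = 57,
                      n_nonconservative = 66, n_stop = 4)
  t_ems <- protein_table(ems)
  expect_equal(round(t_ems$changed_pct, 1), 61.2)
  expect_equal(round(t_ems$preserved_pct, 1), 36.8)
  expect_equal(round(t_ems$stop_pct, 1), 2.0)
  expect_equal(round(t_ems$conservative_pct, 1), 46.3)
  expect_equal(round(t_ems$stop_and_glypro_pct, 1), 3.1)
  expect_equal(t_ems$stop_split_pct, 100.0)
})

test_that("protein_table invariants hold on arbitrary compositions", {
  set.seed(5)
  for (i in 1:5) {
    imp <- make_impacts(n_preserved = sample(0:20, 1),
                        n_conservative = sample(0:20, 1),
                        n_nonconservative = sample(0:20, 1),
                        n_glypro_changed = sample(0:5, 1),
                        n_stop = sample(0:5, 1))
    imp$codon_position <- sample(1:3, nrow(imp), replace = TRUE)
    tb <- protein_table(imp)
    expect_identical(tb$preserved + tb$changed + tb$stop, tb$total)
    expect_identical(sum(tb$codon_position), tb$total)
    expect_identical(tb$conservative + tb$nonconservative, tb$changed)
    if (tb$total > 0) {
      expect_equal(tb$preserved_pct + tb$changed_pct + tb$stop_pct, 100,
                   tolerance = 0.2)
      expect_equal(sum(tb$codon_position_pct), 100, tolerance = 0.2)
    }
    if (tb$changed > 0)
      expect_equal(tb$conservative_pct + tb$nonconservative_pct, 100,
                   tolerance = 0.2)
  }
})

test_that("degenerate protein tables", {
  ## a single stop-gained record: stop 100%, structure indicator 100%
  one_stop <- make_impacts(n_stop = 1)
  tb <- protein_table(one_stop)
  expect_equal(tb$stop_pct, 100)
  expect_equal(tb$stop_and_glypro_pct, 100)
  ## empty input: all-zero table
  tb0 <- protein_table(make_impacts())
  expect_identical(tb0$total, 0L)
  expect_true(is.na(tb0$changed_pct))
})

test_that("codon_effect rejects non-CDS positions and broken CDSs", {
  g <- tiny_genome()
  expect_error(codon_effect(data.frame(contig = "chr1", pos = 5L, ref = "T",
                                       alt = "A"), g), "not inside any CDS")
  expect_error(codon_effect(data.frame(contig = "chr1", pos = 16L, ref = "C",
                                       alt = "G"), g), "does not match")
  ## CDS length not a multiple of 3
  bad <- genome_model(c(c1 = "TTATGCCTTAAT"),
                      list(gene_model("g", "c1", "+", rbind(c(3L, 12L)))),
                      validate_orfs = FALSE)
  expect_error(codon_effect(data.frame(contig = "c1", pos = 6L, ref = "C",
                                       alt = "G"), bad), "multiple of 3")
})
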