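test_that("generate_genome is deterministic and produces valid ORFs", {
  g1 <- generate_genome(1, 50000, 10, gc_content = 0.38, seed = 1,
                        intron_prob = 0.3)
  g2 <- generate_genome(1, 50000, 10, gc_content = 0.38, seed = 1,
                        intron_prob = 0.3)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(lapply(g1$genes, unclass), lapply(g2$genes, unclass))
  expect_length(g1$genes, 10)

  ## independent ORF oracle: translate each spliced CDS with Biostrings
  for (gm in g1$genes) {
    cds <- mutspectra:::spliced_cds(g1, gm$gene_id)
    expect_identical(nchar(cds) %% 3L, 0L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("generate_genome fails explicitly on infeasible geometry", {
  expect_error(generate_genome(1, 300, 10, seed = 1), "cannot place")
})

test_that("realized GC content is within 3 binomial SD of target", {
  n <- 50000
  gc <- 0.38
  g <- generate_genome(1, n, 0, gc_content = gc, seed = 42)
  obs <- sum(strsplit(g$contigs[[1]], "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(n * gc * (1 - gc))
  expect_lt(abs(obs - n * gc), sd3)
})

test_that("mutagen profiles validate their weights", {
  p <- mutagen_profile("ems")
  expect_equal(sum(p$class_weights), 1, tolerance = 1e-12)
  expect_equal(sum(p$class_weights[TRANSITION_CLASSES]), 0.97)
  p <- mutagen_profile("mutator")
  expect_equal(sum(p$class_weights[!names(p$class_weights) %in%
                                     TRANSITION_CLASSES]), 0.72)
  expect_error(mutagen_profile(class_weights = c("G:C>A:T" = 0.5)),
               "sum to 1")
  expect_error(mutagen_profile(class_weights = c(bogus = 1)), "unknown")
})

test_that("sample_mutations honours a degenerate profile and site classes", {
  g <- generate_genome(1, 20000, 3, seed = 3)
  p <- mutagen_profile(class_weights = c("G:C>A:T" = 1))
  m <- sample_mutations(g, p, 100, seed = 1)
  expect_identical(nrow(m), 100L)
  expect_true(all(m$ref %in% c("G", "C")))
  expect_true(all(paste0(m$ref, m$alt) %in% c("GA", "CT")))
  expect_false(any(duplicated(paste(m$contig, m$pos))))
  ## the planted base actually is the reference base at that site
  bases <- vapply(seq_len(nrow(m)), function(i)
    substr(g$contigs[[m$contig[i]]], m$pos[i], m$pos[i]), character(1))
  expect_identical(bases, m$ref)
})

test_that("sample_mutations recovers the EMS transition fraction (binomial oracle)", {
  g <- generate_genome(1, 50000, 5, seed = 4)
  n <- 1000
  m <- sample_mutations(g, mutagen_profile("ems"), n, seed = 5)
  ti <- sum(is_transition(classify_substitution(m$ref, m$alt)))
  sd3 <- 3 * sqrt(n * 0.97 * 0.03)
  expect_lt(abs(ti - n * 0.97), sd3)
})

test_that("per-class frequencies stay within 4 binomial SD for arbitrary profiles", {
  g <- generate_genome(1, 50000, 5, seed = 6)
  w <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  p <- mutagen_profile(class_weights = setNames(w, SUBSTITUTION_CLASSES))
  n <- 800
  m <- sample_mutations(g, p, n, seed = 7)
  cls <- table(factor(m$class, levels = SUBSTITUTION_CLASSES))
  for (i in seq_along(w)) {
    sd4 <- 4 * sqrt(n * w[i] * (1 - w[i]))
    expect_lt(abs(cls[i] - n * w[i]), sd4)
  }
})

test_that("sample_mutations edge cases", {
  g <- generate_genome(1, 5000, 1, seed = 8)
  expect_identical(nrow(sample_mutations(g, mutagen_profile("ems"), 0)), 0L)
  ## a genome with no G/C sites cannot support G:C-class weight
  at_only <- genome_model(c(chr1 = paste(rep("AT", 50), collapse = "")))
  expect_error(
    sample_mutations(at_only, mutagen_profile(class_weights = c("G:C>A:T" = 1)),
                     5, seed = 1),
    "eligible")
})

test_that("render_variant_calls produces clean recoverable calls", {
  g <- generate_genome(1, 30000, 5, seed = 9)
  m <- sample_mutations(g, mutagen_profile("mutator"), 50, seed = 10)
  rv <- render_variant_calls(m, NULL, noise_model(), n_decoys = 0, seed = 11)
  out <- apply_filters(subtract_parental(rv$sample_calls, rv$parental_calls))
  expect_identical(sum(out$passed), 50L)
  expect_setequal(mutspectra:::variant_key(out[out$passed, ]),
                  mutspectra:::variant_key(m))
})

test_that("decoys are rejected with the matching recorded reason", {
  g <- generate_genome(1, 30000, 5, seed = 12)
  rv <- render_variant_calls(
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0)),
    NULL, noise_model(), n_decoys = 5, seed = 13, genome = g)
  out <- apply_filters(subtract_parental(rv$sample_calls, rv$parental_calls))
  expect_identical(sum(out$passed), 0L)
  expect_identical(nrow(out), 5L)
  truth <- rv$truth
  key_out <- mutspectra:::variant_key(out)
  key_truth <- mutspectra:::variant_key(truth)
  for (i in seq_len(nrow(out))) {
    expected <- truth$violated_criterion[match(key_out[i], key_truth)]
    expect_identical(out$failed_criteria[i], expected)
  }
})

test_that("rendered VCF output is byte-identical under a fixed seed", {
  g <- generate_genome(1, 20000, 3, seed = 14)
  m <- sample_mutations(g, mutagen_profile("ems"), 20, seed = 15)
  render_once <- function() {
    rv <- render_variant_calls(m, NULL, noise_model(), n_decoys = 3,
                               seed = 16, genome = g)
    f <- tempfile(fileext = ".vcf")
    write_vcf_records(rv$sample_calls, f, nchar(g$contigs))
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(render_once(), render_once())
})
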