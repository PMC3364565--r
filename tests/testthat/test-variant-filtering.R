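test_that("subtract_parental matches on the exact allele key", {
  s <- make_record(pos = 100, ref = "A", alt = "T")
  p1 <- make_record(pos = 100, ref = "A", alt = "T", sample_id = "parental")
  p2 <- make_record(pos = 100, ref = "A", alt = "G", sample_id = "parental")
  expect_true(subtract_parental(s, p1)$in_parental)
  expect_false(subtract_parental(s, p2)$in_parental)
  expect_false(subtract_parental(s, p1[0, ])$in_parental)
  ## position-only matching is opt-in
  expect_true(subtract_parental(s, p2, position_only = TRUE)$in_parental)
})

test_that("unknown sample contigs warn and are treated as not-parental", {
  s <- make_record(contig = "chr9", pos = 5)
  p <- make_record(contig = "chr1", pos = 5, sample_id = "parental")
  expect_warning(out <- subtract_parental(s, p), "chr9")
  expect_false(out$in_parental)
})

test_that("threshold boundaries behave as specified", {
  cfg <- filter_config()
  ## all-at-threshold substitution passes (inclusive depth/quality/MQ)
  r <- make_record(depth = 10, variant_quality = 20, mapping_quality = 30,
                   vaf = 0.91)
  expect_true(apply_filters(r, cfg)$passed)
  ## VAF exactly at 0.90 is rejected (strict >)
  r$vaf <- 0.90
  out <- apply_filters(r, cfg)
  expect_false(out$passed)
  expect_identical(out$failed_criteria, "vaf")
  ## indels face the higher quality threshold
  del <- make_record(ref = "AT", alt = "A", variant_quality = 40)
  out <- apply_filters(del, cfg)
  expect_false(out$passed)
  expect_identical(out$failed_criteria, "quality")
  expect_true(apply_filters(make_record(ref = "AT", alt = "A",
                                        variant_quality = 50), cfg)$passed)
})

test_that("the six-record waterfall yields one pass and five named rejections", {
  out <- apply_filters(waterfall_records(), filter_config())
  expect_identical(sum(out$passed), 1L)
  expect_identical(out$failed_criteria[!out$passed],
                   c("depth", "quality", "mapping_quality", "vaf",
                     "in_parental"))
})

test_that("a record violating several criteria lists them all", {
  r <- make_record(depth = 5, variant_quality = 10, vaf = 0.5)
  out <- apply_filters(r)
  expect_identical(out$failed_criteria, "depth;quality;vaf")
})

test_that("missing annotations are an error, not a pass", {
  r <- make_record()
  r$depth <- NA
  expect_error(apply_filters(r), "missing the depth")
  r <- make_record()
  r$vaf <- NULL
  expect_error(apply_filters(r), "missing the vaf")
})

test_that("masked intervals reject calls with reason 'masked'", {
  mask <- data.frame(contig = "chr1", start = 90L, end = 110L)
  cfg <- filter_config(mask = mask)
  out <- apply_filters(rbind(make_record(pos = 100), make_record(pos = 200)),
                       cfg)
  expect_identical(out$passed, c(FALSE, TRUE))
  expect_identical(out$failed_criteria[1], "masked")
})

test_that("apply_filters agrees with a brute-force predicate on random records", {
  set.seed(99)
  n <- 400L
  calls <- data.frame(
    contig = "chr1", pos = seq_len(n),
    ref = ifelse(runif(n) < 0.8, "A", "AT"),
    alt = "G",
    depth = sample(0:30, n, TRUE),
    variant_quality = round(runif(n, 0, 80), 1),
    mapping_quality = round(runif(n, 0, 60), 1),
    vaf = round(runif(n, 0.5, 1), 3),
    sample_id = "s1",
    in_parental = runif(n) < 0.1,
    stringsAsFactors = FALSE)
  calls$kind <- mutspectra:::variant_kind(calls$ref, calls$alt)
  cfg <- filter_config()
  out <- apply_filters(calls, cfg)
  brute <- vapply(seq_len(n), function(i) {
    q <- if (calls$kind[i] == "substitution") 20 else 50
    calls$depth[i] >= 10 && calls$variant_quality[i] >= q &&
      calls$mapping_quality[i] >= 30 && calls$vaf[i] > 0.90 &&
      !calls$in_parental[i]
  }, logical(1))
  expect_identical(out$passed, brute)
  ## partition: passed and rejected cover the input exactly
  expect_identical(sum(out$passed) + sum(!out$passed), n)
  expect_identical(out$passed, out$failed_criteria == "")
})

test_that("raising any threshold never grows the passed set", {
  set.seed(7)
  n <- 200
  calls <- data.frame(
    contig = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    depth = sample(0:30, n, TRUE),
    variant_quality = round(runif(n, 0, 80), 1),
    mapping_quality = round(runif(n, 0, 60), 1),
    vaf = round(runif(n, 0.5, 1), 3),
    sample_id = "s1", in_parental = FALSE, stringsAsFactors = FALSE)
  calls$kind <- "substitution"
  base <- apply_filters(calls, filter_config())
  tweaks <- list(filter_config(min_depth = 15),
                 filter_config(min_quality_substitution = 30),
                 filter_config(min_mapping_quality = 40),
                 filter_config(min_vaf_exclusive = 0.95))
  for (cfg in tweaks) {
    out <- apply_filters(calls, cfg)
    expect_true(all(calls$pos[out$passed] %in% calls$pos[base$passed]))
  }
})

test_that("summarize_counts computes group means, SE and the Welch test", {
  mk <- function(sid, n_snv) {
    if (n_snv == 0) {
      out <- apply_filters(make_record(sample_id = sid, depth = 0))
      return(out)  # zero passed
    }
    do.call(rbind, lapply(seq_len(n_snv), function(i)
      apply_filters(make_record(pos = i, sample_id = sid))))
  }
  snvs <- c(5, 6, 7, 8, 10)
  outcomes <- do.call(rbind, lapply(seq_along(snvs), function(i)
    mk(paste0("a", i), snvs[i])))
  outcomes <- rbind(outcomes,
                    do.call(rbind, lapply(1:5, function(i)
                      mk(paste0("b", i), 50 + i))))
  groups <- c(setNames(rep("mutator", 5), paste0("a", 1:5)),
              setNames(rep("ems", 5), paste0("b", 1:5)))
  s <- summarize_counts(outcomes, groups)
  mut <- s$per_group[s$per_group$group == "mutator", ]
  expect_equal(mut$snv_mean, 7.2)
  expect_equal(mut$snv_se, sd(snvs) / sqrt(5))
  expect_s3_class(s$snv_t_test, "htest")
  expect_equal(unname(s$snv_t_test$estimate),
               c(mean(51:55), 7.2), tolerance = 1e-12)
})

test_that("summarize_counts handles single samples and all-zero counts", {
  one <- apply_filters(make_record(sample_id = "only"))
  s <- summarize_counts(one, c(only = "g1"))
  expect_identical(s$per_group$snv_mean, 1)
  expect_true(is.na(s$per_group$snv_se))
  zero <- apply_filters(make_record(sample_id = "z1", depth = 0))
  zero2 <- apply_filters(make_record(sample_id = "z2", depth = 0))
  s <- summarize_counts(rbind(zero, zero2), c(z1 = "g", z2 = "g"))
  expect_identical(s$per_group$snv_mean, 0)
  expect_identical(s$per_group$snv_se, 0)
})
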