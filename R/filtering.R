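#' Filtering thresholds for variant calls
#'
#' The filter cascade accepts a call as a true induced mutation only if all
#' of the following hold: read depth at the site is at least `min_depth`;
#' variant quality meets the kind-specific Phred threshold
#' (`min_quality_substitution` for substitutions, `min_quality_indel` for
#' indels); mapping quality is at least `min_mapping_quality`; the variant
#' allele fraction strictly exceeds `min_vaf_exclusive`; and the call is not
#' present in the sequenced parental strain.  Depth and quality thresholds
#' are inclusive (`>=`); the VAF threshold is exclusive (`>`), reflecting the
#' usual "exceeds 90\%" phrasing for haploid calls.
#'
#' @param min_depth Minimum read depth (default 10).
#' @param min_quality_substitution Minimum Phred variant quality for
#'   substitutions (default 20).
#' @param min_quality_indel Minimum Phred variant quality for indels
#'   (default 50).
#' @param min_mapping_quality Minimum Phred mapping quality (default 30).
#' @param min_vaf_exclusive VAF must strictly exceed this (default 0.90).
#' @param match_position_only If `TRUE`, parental subtraction matches on
#'   (contig, pos) only instead of the full (contig, pos, ref, alt) key.
#' @param mask Optional excluded-interval data.frame (`contig`, `start`,
#'   `end`, 1-based inclusive; see [read_bed_mask()]); calls inside a masked
#'   interval are rejected with reason `"masked"`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10, min_quality_substitution = 20,
                          min_quality_indel = 50, min_mapping_quality = 30,
                          min_vaf_exclusive = 0.90,
                          match_position_only = FALSE, mask = NULL) {
  vals <- c(min_depth, min_quality_substitution, min_quality_indel,
            min_mapping_quality, min_vaf_exclusive)
  if (any(vals < 0)) stop_mutspectra("filter thresholds must be non-negative")
  structure(list(min_depth = min_depth,
                 min_quality_substitution = min_quality_substitution,
                 min_quality_indel = min_quality_indel,
                 min_mapping_quality = min_mapping_quality,
                 min_vaf_exclusive = min_vaf_exclusive,
                 match_position_only = isTRUE(match_position_only),
                 mask = mask),
            class = "filter_config")
}

#' Flag sample calls present in the parental strain
#'
#' A sample call is flagged `in_parental` when the parental call set contains
#' a call with an identical (contig, pos, ref, alt) key (or identical
#' (contig, pos) when `position_only = TRUE`).  All input records are
#' preserved; only the flag is added.  Contigs seen in the sample but absent
#' from the parental set's contig universe trigger a warning and are treated
#' as not-parental.
#'
#' @param sample_calls,parental_calls Variant record data.frames.
#' @param position_only Match on position alone instead of the full allele
#'   key.
#' @return `sample_calls` with a logical `in_parental` column.
#' @export
subtract_parental <- function(sample_calls, parental_calls,
                              position_only = FALSE) {
  if (nrow(parental_calls) > 0) {
    missing_ctg <- setdiff(unique(sample_calls$contig),
                           unique(parental_calls$contig))
    if (length(missing_ctg))
      warning(sprintf(
        "contig(s) %s present in sample but absent from parental call set; treating their calls as not-parental",
        paste(missing_ctg, collapse = ", ")), call. = FALSE)
  }
  key <- function(df) {
    if (position_only) paste(df$contig, df$pos, sep = ":") else variant_key(df)
  }
  sample_calls$in_parental <- key(sample_calls) %in% key(parental_calls)
  sample_calls
}

#' Apply the filter cascade to variant calls
#'
#' Evaluates every call against all criteria and returns the calls annotated
#' with `passed` and the full set of violated criteria (semicolon-joined in
#' `failed_criteria`, empty string when passed).  A record with a missing
#' depth, quality, mapping-quality or VAF annotation is an error, not a
#' silent pass.
#'
#' @param calls Variant record data.frame; an `in_parental` column (from
#'   [subtract_parental()]) is honoured and defaults to `FALSE` when absent.
#' @param config A [filter_config()].
#' @return The input data.frame with `passed` (logical) and
#'   `failed_criteria` (character) columns.
#' @export
apply_filters <- function(calls, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(calls) == 0L) {
    calls$passed <- logical(0)
    calls$failed_criteria <- character(0)
    return(calls)
  }
  req <- c("depth", "variant_quality", "mapping_quality", "vaf")
  for (col in req) {
    if (is.null(calls[[col]]) || anyNA(calls[[col]])) {
      bad <- if (is.null(calls[[col]])) seq_len(nrow(calls)) else
        which(is.na(calls[[col]]))
      stop_mutspectra("record %s:%d is missing the %s annotation",
                      calls$contig[bad[1]], calls$pos[bad[1]], col)
    }
  }
  if (is.null(calls$kind)) calls$kind <- variant_kind(calls$ref, calls$alt)
  if (is.null(calls$in_parental)) calls$in_parental <- FALSE

  qual_thresh <- ifelse(calls$kind == "substitution",
                        config$min_quality_substitution,
                        config$min_quality_indel)
  fails <- cbind(
    depth = calls$depth < config$min_depth,
    quality = calls$variant_quality < qual_thresh,
    mapping_quality = calls$mapping_quality < config$min_mapping_quality,
    vaf = !(calls$vaf > config$min_vaf_exclusive),
    in_parental = calls$in_parental)
  if (!is.null(config$mask) && nrow(config$mask) > 0) {
    m <- config$mask
    masked <- vapply(seq_len(nrow(calls)), function(i) {
      any(m$contig == calls$contig[i] & m$start <= calls$pos[i] &
            calls$pos[i] <= m$end)
    }, logical(1))
    fails <- cbind(fails, masked = masked)
  }
  calls$passed <- rowSums(fails) == 0L
  calls$failed_criteria <- apply(fails, 1, function(f)
    paste(colnames(fails)[f], collapse = ";"))
  calls
}

#' Summarise accepted mutation counts per sample and per group
#'
#' Counts accepted calls per sample, partitioned into SNVs, insertions and
#' deletions, then aggregates per group as mean and standard error
#' (sample SD / sqrt(n); `NA` for single-sample groups).  When exactly two
#' groups with at least two samples each are present, a Welch two-sample
#' t-test on per-sample SNV counts is included.
#'
#' @param outcomes Data.frame of filter outcomes from [apply_filters()]
#'   (multiple samples distinguished by `sample_id`), or a list of such
#'   data.frames that will be row-bound.
#' @param groups Named character vector mapping `sample_id` to group label.
#' @return An object of class `mutation_count_summary` with components
#'   `per_sample`, `per_group` and `snv_t_test`.
#' @export
summarize_counts <- function(outcomes, groups) {
  if (is.list(outcomes) && !is.data.frame(outcomes))
    outcomes <- do.call(rbind, outcomes)
  samples <- names(groups)
  if (is.null(samples)) stop_mutspectra("groups must be named by sample_id")
  kinds <- c(snv = "substitution", insertion = "insertion",
             deletion = "deletion")
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    df <- outcomes[outcomes$sample_id == s & outcomes$passed, , drop = FALSE]
    data.frame(sample_id = s, group = unname(groups[s]),
               snv = sum(df$kind == "substitution"),
               insertion = sum(df$kind == "insertion"),
               deletion = sum(df$kind == "deletion"),
               stringsAsFactors = FALSE)
  }))
  per_group <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                                     function(d) {
    n <- nrow(d)
    stat <- function(x) {
      c(mean = mean(x),
        se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_)
    }
    out <- data.frame(group = d$group[1], n_samples = n)
    for (k in names(kinds)) {
      s <- stat(d[[k]])
      out[[paste0(k, "_mean")]] <- s[["mean"]]
      out[[paste0(k, "_se")]] <- s[["se"]]
    }
    out
  }))
  rownames(per_group) <- NULL
  tt <- NULL
  gs <- split(per_sample$snv, per_sample$group)
  if (length(gs) == 2 && all(lengths(gs) >= 2) &&
      any(vapply(gs, stats::sd, numeric(1)) > 0)) {
    tt <- stats::t.test(gs[[1]], gs[[2]])
  }
  structure(list(per_sample = per_sample, per_group = per_group,
                 snv_t_test = tt),
            class = "mutation_count_summary")
}

#' @export
print.mutation_count_summary <- function(x, ...) {
  cat("Accepted mutation counts (mean +/- SE per group):\n")
  print(x$per_group, row.names = FALSE, digits = 4)
  if (!is.null(x$snv_t_test))
    cat(sprintf("Welch t-test on per-sample SNV counts: t = %.3f, p = %.4g\n",
                x$snv_t_test$statistic, x$snv_t_test$p.value))
  invisible(x)
}
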