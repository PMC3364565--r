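#' Classify a substitution into its complementary-pooled class
#'
#' Maps a directed single-base substitution onto one of the six pooled
#' classes in [SUBSTITUTION_CLASSES].  A substitution and its reverse
#' complement map to the same class (e.g. `A>C` and `T>G` are both
#' `A:T>C:G`).
#'
#' @param ref,alt Reference and alternate bases (vectors of single
#'   characters in `A`, `C`, `G`, `T`; `ref != alt` elementwise).
#' @return Character vector of pooled class labels.
#' @examples
#' classify_substitution("G", "A")   # "G:C>A:T", a transition
#' classify_substitution(c("A", "T"), c("C", "G"))  # both "A:T>C:G"
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok))
    stop_mutspectra("ref/alt must be single bases in A/C/G/T (got %s>%s)",
                    ref[!ok][1], alt[!ok][1])
  if (any(ref == alt))
    stop_mutspectra("ref and alt must differ")
  ## canonicalise onto the A/G representative strand
  flip <- ref %in% c("T", "C")
  cref <- ref; calt <- alt
  cref[flip] <- complement_base(ref[flip])
  calt[flip] <- complement_base(alt[flip])
  pair <- paste0(cref, calt)
  map <- c(AG = "A:T>G:C", GA = "G:C>A:T", AT = "A:T>T:A",
           AC = "A:T>C:G", GT = "G:C>T:A", GC = "G:C>C:G")
  unname(map[pair])
}

#' Is a pooled substitution class a transition?
#'
#' @param class Vector of pooled class labels.
#' @return Logical vector.
#' @export
is_transition <- function(class) {
  bad <- setdiff(unique(class), SUBSTITUTION_CLASSES)
  if (length(bad))
    stop_mutspectra("unknown substitution class: %s", bad[1])
  class %in% TRANSITION_CLASSES
}

#' Summarise a substitution spectrum
#'
#' Pools accepted SNVs (across the samples of one mutagen group) into the six
#' substitution classes and reports counts, relative frequencies and the
#' transition/transversion fractions.  With
#' `scope = "nonsynonymous_only"` the calls must carry an `effect` column
#' (from [codon_effect()]) and only amino-acid-changing and stop-gaining
#' calls are counted.
#'
#' @param calls Data.frame of substitution calls with `ref` and `alt` (and
#'   `effect` for the nonsynonymous scope).
#' @param scope `"genome_wide"` or `"nonsynonymous_only"`.
#' @return An object of class `spectrum_summary`: a per-class table plus
#'   `transition_fraction`, `transversion_fraction`, `total`, `scope`.
#' @export
spectrum_summary <- function(calls, scope = c("genome_wide",
                                              "nonsynonymous_only")) {
  scope <- match.arg(scope)
  if (nrow(calls) && any(variant_kind(calls$ref, calls$alt) != "substitution"))
    stop_mutspectra("spectrum_summary expects substitution calls only")
  if (scope == "nonsynonymous_only") {
    if (is.null(calls$effect))
      stop_mutspectra(
        "nonsynonymous_only scope requires an 'effect' column (see codon_effect)")
    calls <- calls[calls$effect %in% c("changed", "stop_gained"), ,
                   drop = FALSE]
  }
  cls <- if (nrow(calls)) classify_substitution(calls$ref, calls$alt)
         else character(0)
  counts <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
  total <- sum(counts)
  freq <- if (total > 0) as.numeric(counts) / total else rep(NA_real_, 6)
  tab <- data.frame(class = SUBSTITUTION_CLASSES,
                    is_transition = SUBSTITUTION_CLASSES %in% TRANSITION_CLASSES,
                    count = as.integer(counts), frequency = freq,
                    stringsAsFactors = FALSE)
  ti <- if (total > 0) sum(tab$count[tab$is_transition]) / total else NA_real_
  structure(list(table = tab, total = total,
                 transition_fraction = ti,
                 transversion_fraction = if (total > 0) 1 - ti else NA_real_,
                 scope = scope),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Substitution spectrum (%s), %d SNVs\n", x$scope, x$total))
  print(transform(x$table, frequency = round(frequency, 4)),
        row.names = FALSE)
  if (!is.na(x$transition_fraction))
    cat(sprintf("transitions %.1f%% / transversions %.1f%%\n",
                100 * x$transition_fraction, 100 * x$transversion_fraction))
  invisible(x)
}

## Feature geometry for one gene: list of interval data.frames per feature.
gene_features <- function(g, contig_length) {
  sp <- gene_span(g)
  exons <- data.frame(start = g$cds_intervals[, 1], end = g$cds_intervals[, 2])
  introns <- NULL
  if (nrow(g$cds_intervals) > 1) {
    introns <- data.frame(start = g$cds_intervals[-nrow(g$cds_intervals), 2] + 1L,
                          end = g$cds_intervals[-1, 1] - 1L)
    introns <- introns[introns$end >= introns$start, , drop = FALSE]
  }
  if (g$strand == "+") {
    prom <- c(sp["start"] - g$promoter_length, sp["start"] - 1L)
    term <- c(sp["end"] + 1L, sp["end"] + g$terminator_length)
  } else {
    prom <- c(sp["end"] + 1L, sp["end"] + g$promoter_length)
    term <- c(sp["start"] - g$terminator_length, sp["start"] - 1L)
  }
  clip <- function(iv) {
    s <- max(iv[1], 1L); e <- min(iv[2], contig_length)
    if (e < s) NULL else data.frame(start = s, end = e)
  }
  list(exon = exons, intron = introns,
       promoter = clip(prom), terminator = clip(term), span = sp)
}

#' Assign each SNV to a single gene feature
#'
#' Assigns every call to exactly one of `exon`, `intron`, `promoter`,
#' `terminator` or `intergenic`.  Promoters extend `promoter_length` bases
#' 5' of the gene start on the gene's strand; terminators extend
#' `terminator_length` bases 3' of the gene end.  Overlaps are resolved by
#' the precedence exon > intron > promoter > terminator > intergenic; when a
#' position falls in the promoter/terminator of two genes, the nearer gene
#' wins, with ties broken by the lower gene start coordinate.
#'
#' @param calls Data.frame with `contig` and `pos`.
#' @param genome A [genome_model()].
#' @return `calls` with `feature` and `gene_id` columns appended.
#' @export
assign_feature <- function(calls, genome) {
  stopifnot(inherits(genome, "genome_model"))
  unknown <- setdiff(unique(calls$contig), names(genome$contigs))
  if (length(unknown))
    stop_mutspectra("unknown contig in calls: %s", unknown[1])
  feats <- lapply(genome$genes, function(g)
    gene_features(g, nchar(genome$contigs[[g$contig]])))
  gene_ctg <- vapply(genome$genes, `[[`, character(1), "contig")
  gene_start <- vapply(feats, function(f) unname(f$span["start"]), numeric(1))

  n <- nrow(calls)
  feature <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  prec <- c(exon = 1, intron = 2, promoter = 3, terminator = 4,
            intergenic = 5)
  for (i in seq_len(n)) {
    pos <- calls$pos[i]
    best <- c(prec = 5, dist = Inf, start = Inf)
    best_gene <- NA_character_
    best_feat <- "intergenic"
    for (j in seq_along(genome$genes)) {
      if (gene_ctg[j] != calls$contig[i]) next
      f <- feats[[j]]
      hit <- NULL
      for (ft in c("exon", "intron", "promoter", "terminator")) {
        iv <- f[[ft]]
        if (!is.null(iv) && any(iv$start <= pos & pos <= iv$end)) {
          hit <- ft
          break
        }
      }
      if (is.null(hit)) next
      d <- if (hit %in% c("promoter", "terminator")) {
        min(abs(pos - f$span["start"]), abs(pos - f$span["end"]))
      } else 0
      cand <- c(prec = unname(prec[hit]), dist = unname(d),
                start = gene_start[j])
      if (cand["prec"] < best["prec"] ||
          (cand["prec"] == best["prec"] && cand["dist"] < best["dist"]) ||
          (cand["prec"] == best["prec"] && cand["dist"] == best["dist"] &&
           cand["start"] < best["start"])) {
        best <- cand
        best_gene <- genome$genes[[j]]$gene_id
        best_feat <- hit
      }
    }
    feature[i] <- best_feat
    gene_id[i] <- best_gene
  }
  calls$feature <- feature
  calls$gene_id <- gene_id
  calls
}

#' Tabulate gene-feature frequencies
#'
#' @param calls Output of [assign_feature()].
#' @return Data.frame with per-feature counts and relative frequencies.
#' @export
feature_summary <- function(calls) {
  lv <- c("exon", "intron", "promoter", "terminator", "intergenic")
  counts <- table(factor(calls$feature, levels = lv))
  total <- sum(counts)
  data.frame(feature = lv, count = as.integer(counts),
             frequency = if (total > 0) as.integer(counts) / total
                         else rep(NA_real_, length(lv)),
             stringsAsFactors = FALSE)
}
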