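#' Codon-level consequence of exonic SNVs
#'
#' For each exonic substitution, locates the affected codon on the coding
#' strand (reverse-complementing minus-strand genes first), translates the
#' reference and mutated codons with the standard nuclear genetic code, and
#' classifies the effect as `preserved` (same amino acid, including a stop
#' codon remaining a stop), `changed` (different amino acid, including
#' stop-loss), or `stop_gained` (a new stop codon).  For amino-acid changes
#' the BLOSUM62 score and the conservative/nonconservative call are attached
#' (see [classify_conservation()]); `conservation` is `"not_applicable"`
#' otherwise.
#'
#' @param calls Data.frame of substitution calls with `contig`, `pos`,
#'   `ref`, `alt`; if a `gene_id` column (from [assign_feature()]) is
#'   present it is used, otherwise the containing gene is looked up.
#' @param genome A [genome_model()].
#' @param blosum_threshold Passed to [classify_conservation()].
#' @return Data.frame of protein impact records: `gene_id`, `codon_index`,
#'   `codon_position`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect`, `blosum_score`, `conservation` (one row per call, in input
#'   order).
#' @export
codon_effect <- function(calls, genome, blosum_threshold = 0) {
  stopifnot(inherits(genome, "genome_model"))
  n <- nrow(calls)
  out <- data.frame(
    gene_id = character(n), codon_index = integer(n),
    codon_position = integer(n), ref_codon = character(n),
    alt_codon = character(n), ref_aa = character(n), alt_aa = character(n),
    effect = character(n), blosum_score = rep(NA_integer_, n),
    conservation = character(n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  if (any(variant_kind(calls$ref, calls$alt) != "substitution"))
    stop_mutspectra("codon_effect expects substitution calls only")
  for (i in seq_len(n)) {
    g <- find_cds_gene(genome, calls$contig[i], calls$pos[i],
                       calls$gene_id[i] %||% NA_character_)
    cds <- spliced_cds(genome, g)
    if (nchar(cds) %% 3L != 0L)
      stop_mutspectra("gene %s: CDS length not a multiple of 3", g$gene_id)
    cpos <- cds_position(g, calls$pos[i])
    ref_c <- calls$ref[i]; alt_c <- calls$alt[i]
    if (g$strand == "-") {
      ref_c <- complement_base(ref_c)
      alt_c <- complement_base(alt_c)
    }
    if (substr(cds, cpos, cpos) != ref_c)
      stop_mutspectra("record %s:%d: ref allele %s does not match CDS of %s",
                      calls$contig[i], calls$pos[i], calls$ref[i], g$gene_id)
    ci <- (cpos - 1L) %/% 3L + 1L
    cp <- (cpos - 1L) %% 3L + 1L
    ref_codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    alt_codon <- ref_codon
    substr(alt_codon, cp, cp) <- alt_c
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    effect <- if (ref_aa == alt_aa) "preserved"
              else if (alt_aa == "*") "stop_gained"
              else "changed"
    score <- NA_integer_
    conservation <- "not_applicable"
    if (effect == "changed" && ref_aa != "*" && alt_aa != "*") {
      cc <- classify_conservation(ref_aa, alt_aa, threshold = blosum_threshold)
      score <- cc$blosum_score
      conservation <- cc$conservation
    }
    out[i, ] <- list(g$gene_id, ci, cp, ref_codon, alt_codon, ref_aa, alt_aa,
                     effect, score, conservation)
  }
  out
}

find_cds_gene <- function(genome, contig, pos, gene_id = NA_character_) {
  if (!is.na(gene_id)) return(get_gene(genome, gene_id))
  for (g in genome$genes) {
    if (g$contig == contig &&
        any(g$cds_intervals[, 1] <= pos & pos <= g$cds_intervals[, 2]))
      return(g)
  }
  stop_mutspectra("position %s:%d is not inside any CDS", contig, pos)
}

## Position within the spliced CDS (1-based, coding strand) of a genomic
## position inside one of the gene's CDS intervals.
cds_position <- function(g, pos) {
  ivs <- g$cds_intervals
  widths <- ivs[, 2] - ivs[, 1] + 1L
  k <- which(ivs[, 1] <= pos & pos <= ivs[, 2])
  if (length(k) != 1L)
    stop_mutspectra("position %d is not in a CDS interval of %s", pos,
                    g$gene_id)
  if (g$strand == "+") {
    sum(widths[seq_len(k - 1L)]) + (pos - ivs[k, 1] + 1L)
  } else {
    ## transcription runs right-to-left: count from the rightmost interval end
    sum(widths[seq_along(widths) > k]) + (ivs[k, 2] - pos + 1L)
  }
}

#' Classify an amino-acid change as conservative or nonconservative
#'
#' A substitution is conservative when its BLOSUM62 log-odds score is
#' strictly greater than `threshold` (default 0, i.e. positive score); set
#' `inclusive = TRUE` to treat a score equal to the threshold as
#' conservative.
#'
#' @param ref_aa,alt_aa One-letter amino-acid codes (no stops; must differ).
#' @param threshold BLOSUM62 score cutoff (default 0).
#' @param inclusive Use `>=` instead of `>`.
#' @return A data.frame with `conservation` and `blosum_score`.
#' @examples
#' classify_conservation("L", "M")  # conservative (score 2)
#' classify_conservation("G", "W")  # nonconservative (score -2)
#' @export
classify_conservation <- function(ref_aa, alt_aa, threshold = 0,
                                  inclusive = FALSE) {
  aa <- rownames(BLOSUM62)
  ok <- ref_aa %in% aa & alt_aa %in% aa
  if (!all(ok))
    stop_mutspectra("invalid amino acid code: %s",
                    paste(unique(c(ref_aa, alt_aa)[!c(ok, ok)]), collapse = ", "))
  if (any(ref_aa == alt_aa))
    stop_mutspectra("ref_aa and alt_aa must differ (not an amino-acid change)")
  score <- BLOSUM62[cbind(ref_aa, alt_aa)]
  cons <- if (inclusive) score >= threshold else score > threshold
  data.frame(conservation = ifelse(cons, "conservative", "nonconservative"),
             blosum_score = as.integer(score), stringsAsFactors = FALSE)
}

#' Protein-level mutation table
#'
#' Aggregates protein impact records into the protein-level summary used to
#' compare mutagens: counts and percentages of preserved / changed /
#' stop-gained events, the distribution over codon letter positions 1-3,
#' conservative vs nonconservative changes (percentages of amino-acid
#' changes), and the structure indicator -- events that are stop codons or
#' Gly/Pro substitutions -- as a percentage of amino-acid-level events
#' (changes + stops), with its internal stop vs Gly/Pro split.
#'
#' @param impacts Data.frame from [codon_effect()].
#' @param glypro_direction Count a change as a Gly/Pro substitution when the
#'   reference or substituted amino acid is Gly or Pro (`"either"`, the
#'   default), or only when the substituted (`"to"`) / reference (`"from"`)
#'   amino acid is.
#' @return An object of class `protein_level_table`.
#' @export
protein_table <- function(impacts,
                          glypro_direction = c("either", "to", "from")) {
  glypro_direction <- match.arg(glypro_direction)
  total <- nrow(impacts)
  cnt <- function(x) as.integer(sum(x))
  preserved <- cnt(impacts$effect == "preserved")
  changed <- cnt(impacts$effect == "changed")
  stop_gained <- cnt(impacts$effect == "stop_gained")
  pos_counts <- vapply(1:3, function(p) cnt(impacts$codon_position == p),
                       integer(1))
  conservative <- cnt(impacts$effect == "changed" &
                        impacts$conservation == "conservative")
  nonconservative <- cnt(impacts$effect == "changed" &
                           impacts$conservation == "nonconservative")
  is_gp <- function(aa) aa %in% c("G", "P")
  glypro <- switch(glypro_direction,
    either = impacts$effect == "changed" &
      (is_gp(impacts$ref_aa) | is_gp(impacts$alt_aa)),
    to = impacts$effect == "changed" & is_gp(impacts$alt_aa),
    from = impacts$effect == "changed" & is_gp(impacts$ref_aa))
  n_glypro <- cnt(glypro)
  structure_n <- stop_gained + n_glypro
  aa_events <- changed + stop_gained
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    total = total, preserved = preserved, changed = changed,
    stop = stop_gained,
    preserved_pct = pct(preserved, total),
    changed_pct = pct(changed, total),
    stop_pct = pct(stop_gained, total),
    codon_position = stats::setNames(pos_counts, c("1st", "2nd", "3rd")),
    codon_position_pct = stats::setNames(
      vapply(pos_counts, pct, numeric(1), den = total), c("1st", "2nd", "3rd")),
    conservative = conservative, nonconservative = nonconservative,
    conservative_pct = pct(conservative, changed),
    nonconservative_pct = pct(nonconservative, changed),
    stop_and_glypro = structure_n,
    stop_and_glypro_pct = pct(structure_n, aa_events),
    stop_split_pct = pct(stop_gained, structure_n),
    glypro_split_pct = pct(n_glypro, structure_n),
    glypro = n_glypro, aa_events = aa_events,
    glypro_direction = glypro_direction),
    class = "protein_level_table")
}

#' @export
print.protein_level_table <- function(x, ...) {
  f <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
  cat("Mutations at protein level\n")
  cat(sprintf("  Total mutations        %4d  100\n", x$total))
  cat(sprintf("  Preserved amino acids  %4d  %s\n", x$preserved,
              f(x$preserved_pct)))
  cat(sprintf("  Amino acid changes     %4d  %s\n", x$changed,
              f(x$changed_pct)))
  cat(sprintf("  Stop                   %4d  %s\n", x$stop, f(x$stop_pct)))
  cat("  Changes in codon letter\n")
  for (p in 1:3)
    cat(sprintf("    %s                  %4d  %s\n",
                names(x$codon_position)[p], x$codon_position[p],
                f(x$codon_position_pct[p])))
  cat("  Impact of amino acid change\n")
  cat(sprintf("    Conservative         %4d  %s\n", x$conservative,
              f(x$conservative_pct)))
  cat(sprintf("    Nonconservative      %4d  %s\n", x$nonconservative,
              f(x$nonconservative_pct)))
  cat(sprintf("  Stop and Gly/Pro codons %3d  %s\n", x$stop_and_glypro,
              f(x$stop_and_glypro_pct)))
  cat(sprintf("    Stop                 %4d  %s\n", x$stop,
              f(x$stop_split_pct)))
  cat(sprintf("    Gly/Pro              %4d  %s\n", x$glypro,
              f(x$glypro_split_pct)))
  invisible(x)
}

#' Protein-level table as a tidy data.frame
#'
#' @param x A `protein_level_table`.
#' @param ... Unused.
#' @return Data.frame with `row`, `n`, `percent`.
#' @export
as.data.frame.protein_level_table <- function(x, ...) {
  data.frame(
    row = c("total", "preserved", "changed", "stop",
            "codon_1st", "codon_2nd", "codon_3rd",
            "conservative", "nonconservative",
            "stop_and_glypro", "stop_split", "glypro_split"),
    n = c(x$total, x$preserved, x$changed, x$stop, x$codon_position,
          x$conservative, x$nonconservative, x$stop_and_glypro, x$stop,
          x$glypro),
    percent = c(100, x$preserved_pct, x$changed_pct, x$stop_pct,
                x$codon_position_pct, x$conservative_pct,
                x$nonconservative_pct, x$stop_and_glypro_pct,
                x$stop_split_pct, x$glypro_split_pct),
    stringsAsFactors = FALSE)
}
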