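#' Pooled substitution classes
#'
#' The six complementary-pooled single-base substitution classes.  Because
#' double-stranded DNA makes a substitution and its reverse complement
#' indistinguishable without strand information, the 12 directed substitutions
#' are pooled two-by-two (e.g. A>C and T>G are the same class).  The first two
#' classes are the transitions; the remaining four are transversions.
#'
#' @format Character vector of length 6.
#' @export
SUBSTITUTION_CLASSES <- c("A:T>G:C", "G:C>A:T",
                          "A:T>T:A", "A:T>C:G", "G:C>T:A", "G:C>C:G")

#' @rdname SUBSTITUTION_CLASSES
#' @export
TRANSITION_CLASSES <- SUBSTITUTION_CLASSES[1:2]

#' Construct a mutagen profile
#'
#' A mutagen profile is a probability distribution over the six pooled
#' substitution classes, plus the expected number of small indels per SNV.
#' It drives [sample_mutations()].
#'
#' Two presets encode the aggregate biases of the study conditions this
#' package targets:
#' \describe{
#'   \item{`"ems"`}{EMS chemical mutagenesis, strongly transition-biased:
#'     97\% transitions, split evenly between the two transition classes;
#'     the remaining 3\% spread evenly over the four transversion classes.
#'     Default `indel_rate` 0.06.}
#'   \item{`"mutator"`}{Proofreading-deficient / low-fidelity DNA polymerase
#'     delta mutator, transversion-biased: 72\% transversions spread evenly
#'     over the four transversion classes, 28\% transitions split evenly.
#'     Default `indel_rate` 0.25.}
#' }
#' Only these aggregate transition/transversion fractions are taken from the
#' study; the within-aggregate split is uniform by construction and can be
#' overridden by passing explicit `class_weights`.
#'
#' @param preset `"ems"`, `"mutator"`, or `NULL` to supply `class_weights`.
#' @param class_weights Named numeric vector over [SUBSTITUTION_CLASSES]
#'   (non-negative, summing to 1).
#' @param indel_rate Expected indels per SNV (>= 0).
#' @return An object of class `mutagen_profile`.
#' @examples
#' mutagen_profile("ems")
#' mutagen_profile(class_weights = c("G:C>A:T" = 1))
#' @export
mutagen_profile <- function(preset = NULL, class_weights = NULL,
                            indel_rate = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("ems", "mutator"))
    if (preset == "ems") {
      w <- c(rep(0.97 / 2, 2), rep(0.03 / 4, 4))
      indel_rate <- indel_rate %||% 0.06
    } else {
      w <- c(rep(0.28 / 2, 2), rep(0.72 / 4, 4))
      indel_rate <- indel_rate %||% 0.25
    }
    class_weights <- stats::setNames(w, SUBSTITUTION_CLASSES)
  } else {
    if (is.null(class_weights))
      stop_mutspectra("supply either a preset or class_weights")
    full <- stats::setNames(numeric(6), SUBSTITUTION_CLASSES)
    unknown <- setdiff(names(class_weights), SUBSTITUTION_CLASSES)
    if (length(unknown))
      stop_mutspectra("unknown substitution class: %s",
                      paste(unknown, collapse = ", "))
    full[names(class_weights)] <- class_weights
    class_weights <- full
    indel_rate <- indel_rate %||% 0
  }
  if (any(class_weights < 0))
    stop_mutspectra("class_weights must be non-negative")
  s <- sum(class_weights)
  if (abs(s - 1) > 1e-9)
    stop_mutspectra("class_weights must sum to 1 (got %.6f)", s)
  if (indel_rate < 0) stop_mutspectra("indel_rate must be >= 0")
  structure(list(class_weights = class_weights, indel_rate = indel_rate,
                 preset = preset),
            class = "mutagen_profile")
}

#' @export
print.mutagen_profile <- function(x, ...) {
  cat("Mutagen profile", if (!is.null(x$preset)) sprintf("(preset '%s')", x$preset),
      "\n")
  print(round(x$class_weights, 4))
  ti <- sum(x$class_weights[TRANSITION_CLASSES])
  cat(sprintf("transitions %.1f%% / transversions %.1f%%; indel rate %.2f per SNV\n",
              100 * ti, 100 * (1 - ti), x$indel_rate))
  invisible(x)
}

## class -> (canonical ref on the A/G representative strand, alt)
class_alt_for_ref <- function(class, ref) {
  ## canonical mapping for refs A and G; T/C sites use the complement
  canon <- c("A:T>G:C" = "G", "G:C>A:T" = "A",
             "A:T>T:A" = "T", "A:T>C:G" = "C",
             "G:C>T:A" = "T", "G:C>C:G" = "C")
  alt <- canon[class]
  flip <- ref %in% c("T", "C")
  alt[flip] <- complement_base(alt[flip])
  unname(alt)
}

#' Sample true mutations from a mutagen profile
#'
#' Draws `n_mutations` single-base substitutions at unique genome positions.
#' Each mutation's pooled class is drawn from the profile's class weights;
#' A:T-class mutations are placed only at A/T sites, G:C-class mutations only
#' at G/C sites, and the alternate allele is determined by the class and the
#' reference base at the chosen site.
#'
#' @param genome A [genome_model()].
#' @param profile A [mutagen_profile()].
#' @param n_mutations Number of substitutions to draw.
#' @param seed Integer seed.
#' @return A data.frame with columns `contig`, `pos`, `ref`, `alt`, `class`.
#' @export
sample_mutations <- function(genome, profile, n_mutations, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(profile, "mutagen_profile"), n_mutations >= 0)
  if (n_mutations == 0L) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  ## site pools, indexed by the reference base pair
  pool <- list()
  for (cn in names(genome$contigs)) {
    b <- strsplit(genome$contigs[[cn]], "", fixed = TRUE)[[1]]
    at <- which(b %in% c("A", "T"))
    gc <- which(b %in% c("G", "C"))
    pool$AT <- rbind(pool$AT,
                     data.frame(contig = rep(cn, length(at)), pos = at,
                                ref = b[at], stringsAsFactors = FALSE))
    pool$GC <- rbind(pool$GC,
                     data.frame(contig = rep(cn, length(gc)), pos = gc,
                                ref = b[gc], stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    classes <- sample(SUBSTITUTION_CLASSES, n_mutations, replace = TRUE,
                      prob = profile$class_weights)
    is_at <- startsWith(classes, "A:T")
    for (grp in c("AT", "GC")) {
      need <- if (grp == "AT") sum(is_at) else sum(!is_at)
      have <- nrow(pool[[grp]] %||% data.frame())
      if (need > have)
        stop_mutspectra(
          "profile asks for %d %s-class mutations but only %d eligible %s sites exist",
          need, if (grp == "AT") "A:T" else "G:C", have, grp)
    }
    idx_at <- if (any(is_at)) sample.int(nrow(pool$AT), sum(is_at)) else integer(0)
    idx_gc <- if (any(!is_at)) sample.int(nrow(pool$GC), sum(!is_at)) else integer(0)
    out <- data.frame(contig = character(n_mutations), pos = integer(n_mutations),
                      ref = character(n_mutations), alt = character(n_mutations),
                      class = classes, stringsAsFactors = FALSE)
    out[is_at, c("contig", "pos", "ref")] <- pool$AT[idx_at, ]
    out[!is_at, c("contig", "pos", "ref")] <- pool$GC[idx_gc, ]
    out$alt <- class_alt_for_ref(out$class, out$ref)
    out <- out[order(out$contig, out$pos), ]
    rownames(out) <- NULL
    out
  })
}

#' Sample small indels
#'
#' Draws `n_indels` one-base insertions or deletions at unique positions,
#' formatted VCF-style with the anchor base included (e.g. ref `A`, alt `AT`
#' for an insertion; ref `AT`, alt `A` for a deletion).
#'
#' @inheritParams sample_mutations
#' @param n_indels Number of indels to draw.
#' @return A data.frame with columns `contig`, `pos`, `ref`, `alt`, `class`
#'   (class is `"insertion"` or `"deletion"`).
#' @export
sample_indels <- function(genome, n_indels, seed = 1L) {
  stopifnot(n_indels >= 0)
  out <- data.frame(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    class = character(0), stringsAsFactors = FALSE)
  if (n_indels == 0L) return(out)
  with_seed(seed, {
    lens <- nchar(genome$contigs)
    cn <- sample(names(lens), n_indels, replace = TRUE,
                 prob = lens / sum(lens))
    rows <- lapply(seq_len(n_indels), function(i) {
      L <- lens[[cn[i]]]
      pos <- sample.int(L - 1L, 1L)
      anchor <- substr(genome$contigs[[cn[i]]], pos, pos)
      nxt <- substr(genome$contigs[[cn[i]]], pos + 1L, pos + 1L)
      if (stats::runif(1) < 0.5) {
        data.frame(contig = cn[i], pos = pos, ref = anchor,
                   alt = paste0(anchor, sample(c("A", "C", "G", "T"), 1L)),
                   class = "insertion", stringsAsFactors = FALSE)
      } else {
        data.frame(contig = cn[i], pos = pos, ref = paste0(anchor, nxt),
                   alt = anchor, class = "deletion", stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, rows)
    out <- out[!duplicated(paste(out$contig, out$pos)), ]
    rownames(out) <- NULL
    out
  })
}
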