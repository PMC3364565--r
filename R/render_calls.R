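#' Construct a noise model for rendering variant calls
#'
#' Describes the statistical structure of the variant evidence the simulator
#' attaches to calls: sequencing depth (negative-binomial, overdispersed),
#' variant and mapping qualities, and variant allele fractions.  True calls
#' are rendered "clean" (evidence comfortably above the default filter
#' thresholds, allele fraction at `clean_vaf`); decoy calls are rendered to
#' violate exactly one named filter criterion each.
#'
#' @param mean_depth Mean read depth at a site.
#' @param depth_dispersion Negative-binomial dispersion (0 = Poisson-like;
#'   larger = more overdispersed).
#' @param clean_vaf Variant allele fraction of true haploid calls (default 1).
#' @param contaminant_vaf_range VAF interval for `vaf`-violating decoys
#'   (upper end at most 0.90, the exclusive filter threshold).
#' @param min_clean_depth Guaranteed minimum depth of clean calls.
#' @param clean_qual_range,clean_mq_range Uniform ranges for variant quality
#'   and mapping quality of clean calls.
#' @param low_depth_range,low_qual_range,low_mq_range Uniform ranges used for
#'   the corresponding decoy classes.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(mean_depth = 40, depth_dispersion = 0.15,
                        clean_vaf = 1.0, contaminant_vaf_range = c(0.30, 0.90),
                        min_clean_depth = 10L,
                        clean_qual_range = c(60, 220),
                        clean_mq_range = c(40, 60),
                        low_depth_range = c(1L, 9L),
                        low_qual_range = c(0, 19),
                        low_mq_range = c(0, 29)) {
  stopifnot(mean_depth > 0, depth_dispersion >= 0,
            clean_vaf >= 0, clean_vaf <= 1,
            all(contaminant_vaf_range >= 0), all(contaminant_vaf_range <= 1))
  structure(list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 clean_vaf = clean_vaf,
                 contaminant_vaf_range = contaminant_vaf_range,
                 min_clean_depth = as.integer(min_clean_depth),
                 clean_qual_range = clean_qual_range,
                 clean_mq_range = clean_mq_range,
                 low_depth_range = low_depth_range,
                 low_qual_range = low_qual_range,
                 low_mq_range = low_mq_range),
            class = "noise_model")
}

FILTER_CRITERIA <- c("depth", "quality", "mapping_quality", "vaf", "in_parental")

## Clean evidence columns for n calls.
render_clean <- function(n, noise) {
  extra <- stats::rnbinom(n, mu = max(noise$mean_depth - noise$min_clean_depth,
                                      1e-6),
                          size = 1 / max(noise$depth_dispersion, 1e-9))
  data.frame(
    depth = noise$min_clean_depth + extra,
    variant_quality = round(stats::runif(n, noise$clean_qual_range[1],
                                         noise$clean_qual_range[2]), 1),
    mapping_quality = round(stats::runif(n, noise$clean_mq_range[1],
                                         noise$clean_mq_range[2]), 1),
    vaf = rep(noise$clean_vaf, n)
  )
}

#' Render true mutations and decoys as noisy variant calls
#'
#' Turns a set of true mutations into per-sample variant call records with
#' simulated depth/quality/VAF evidence, appends the parental variant set
#' (the sequenced clone inherits its parent's differences from the
#' reference), and optionally adds decoy calls, each constructed to violate
#' exactly one named filter criterion.  The returned truth table records the
#' violated criterion for every call (`"none"` for true calls), so filtering
#' behaviour can be checked record-by-record.
#'
#' @param true_mutations Data.frame with `contig`, `pos`, `ref`, `alt`
#'   (substitutions and/or indels).
#' @param parental_variants Data.frame of the parental strain's variants
#'   against the reference (same columns), or `NULL`.
#' @param noise A [noise_model()].
#' @param n_decoys Number of decoy calls, cycled over the criteria
#'   `depth`, `quality`, `mapping_quality`, `vaf`, `in_parental`.
#' @param seed Integer seed.
#' @param sample_id Sample identifier attached to sample calls.
#' @param genome A [genome_model()]; required when `n_decoys > 0` to place
#'   decoys at real reference positions.
#' @return A list with elements `sample_calls`, `parental_calls` (variant
#'   record data.frames) and `truth` (contig, pos, ref, alt,
#'   violated_criterion).
#' @export
render_variant_calls <- function(true_mutations, parental_variants = NULL,
                                 noise = noise_model(), n_decoys = 0L,
                                 seed = 1L, sample_id = "sample1",
                                 genome = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (n_decoys > 0L && is.null(genome))
    stop_mutspectra("genome is required to place decoy calls")
  parental_variants <- parental_variants %||%
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
  with_seed(seed, {
    used <- paste(c(true_mutations$contig, parental_variants$contig),
                  c(true_mutations$pos, parental_variants$pos))

    mk <- function(df, ev, sid) {
      if (nrow(df) == 0L) return(empty_variant_records())
      data.frame(contig = df$contig, pos = as.integer(df$pos),
                 ref = df$ref, alt = df$alt,
                 kind = variant_kind(df$ref, df$alt),
                 depth = ev$depth, variant_quality = ev$variant_quality,
                 mapping_quality = ev$mapping_quality, vaf = ev$vaf,
                 sample_id = sid, stringsAsFactors = FALSE)
    }

    sample_calls <- mk(true_mutations, render_clean(nrow(true_mutations), noise),
                       sample_id)
    truth <- data.frame(contig = true_mutations$contig,
                        pos = as.integer(true_mutations$pos),
                        ref = true_mutations$ref, alt = true_mutations$alt,
                        violated_criterion = rep("none", nrow(true_mutations)),
                        stringsAsFactors = FALSE)

    ## the sample inherits the parental variants; they are rendered clean in
    ## both call sets and removed downstream by parental subtraction
    parental_calls <- mk(parental_variants,
                         render_clean(nrow(parental_variants), noise),
                         "parental")
    inherited <- mk(parental_variants,
                    render_clean(nrow(parental_variants), noise), sample_id)
    sample_calls <- rbind(sample_calls, inherited)

    if (n_decoys > 0L) {
      crit <- rep_len(FILTER_CRITERIA, n_decoys)
      lens <- nchar(genome$contigs)
      dc <- data.frame(contig = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       stringsAsFactors = FALSE)
      while (nrow(dc) < n_decoys) {
        cn <- sample(names(lens), 1L, prob = lens / sum(lens))
        pos <- sample.int(lens[[cn]], 1L)
        if (paste(cn, pos) %in% used) next
        ref <- substr(genome$contigs[[cn]], pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        dc <- rbind(dc, data.frame(contig = cn, pos = pos, ref = ref,
                                   alt = alt, stringsAsFactors = FALSE))
        used <- c(used, paste(cn, pos))
      }
      ev <- render_clean(n_decoys, noise)
      for (i in seq_len(n_decoys)) {
        switch(crit[i],
          depth = ev$depth[i] <- sample(noise$low_depth_range[1]:
                                        noise$low_depth_range[2], 1L),
          quality = ev$variant_quality[i] <-
            round(stats::runif(1, noise$low_qual_range[1],
                               noise$low_qual_range[2]), 1),
          mapping_quality = ev$mapping_quality[i] <-
            round(stats::runif(1, noise$low_mq_range[1],
                               noise$low_mq_range[2]), 1),
          vaf = ev$vaf[i] <- round(stats::runif(1,
                                   noise$contaminant_vaf_range[1],
                                   noise$contaminant_vaf_range[2]), 3),
          in_parental = NULL)
      }
      decoy_calls <- mk(dc, ev, sample_id)
      sample_calls <- rbind(sample_calls, decoy_calls)
      ## in_parental decoys are also planted in the parental call set
      ip <- which(crit == "in_parental")
      if (length(ip)) {
        parental_calls <- rbind(parental_calls,
                                mk(dc[ip, ], render_clean(length(ip), noise),
                                   "parental"))
      }
      truth <- rbind(truth,
                     data.frame(contig = dc$contig, pos = dc$pos,
                                ref = dc$ref, alt = dc$alt,
                                violated_criterion = crit,
                                stringsAsFactors = FALSE))
    }

    o <- order(sample_calls$contig, sample_calls$pos)
    sample_calls <- sample_calls[o, ]
    rownames(sample_calls) <- NULL
    o <- order(parental_calls$contig, parental_calls$pos)
    parental_calls <- parental_calls[o, ]
    rownames(parental_calls) <- NULL
    truth <- truth[order(truth$contig, truth$pos), ]
    rownames(truth) <- NULL
    list(sample_calls = sample_calls, parental_calls = parental_calls,
         truth = truth)
  })
}
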