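#' Pipeline configuration
#'
#' Bundles the file paths and parameters needed by [run_pipeline()]: the
#' reference FASTA + GFF3, the parental VCF, the per-sample VCFs with their
#' mutagen group labels, the filter thresholds, and per-group generation
#' counts for rate estimation.  Configurations round-trip through a flat
#' YAML file for command-line use.
#'
#' @param reference_fasta,annotation_gff3,parental_vcf Input paths.
#' @param sample_vcfs Named character vector: `sample_id = path`.
#' @param groups Named character vector: `sample_id = group label`.
#' @param filter A [filter_config()].
#' @param generations Named numeric vector of cell divisions per group used
#'   for per-site rates (e.g. `c(mutator = 30, ems = 1)`); groups missing
#'   from it default to 1.
#' @param output_dir Where [run_pipeline()] writes its report files.
#' @param seed Integer seed recorded with the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_fasta, annotation_gff3, parental_vcf,
                            sample_vcfs, groups, filter = filter_config(),
                            generations = c(mutator = 30, ems = 1),
                            output_dir = "mutspectra_report", seed = 1L) {
  if (is.null(names(sample_vcfs)) || is.null(names(groups)))
    stop_mutspectra("sample_vcfs and groups must be named by sample_id")
  if (!setequal(names(sample_vcfs), names(groups)))
    stop_mutspectra("every sample needs both a VCF path and a group label")
  for (p in c(reference_fasta, annotation_gff3, parental_vcf,
              unname(sample_vcfs))) {
    if (!file.exists(p))
      stop_mutspectra("configuration error: input file does not exist: %s", p)
  }
  structure(list(reference_fasta = reference_fasta,
                 annotation_gff3 = annotation_gff3,
                 parental_vcf = parental_vcf,
                 sample_vcfs = sample_vcfs, groups = groups,
                 filter = filter, generations = generations,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$filter <- unclass(x$filter)
  x$filter$mask <- NULL
  ## named vectors must become maps, not sequences, to survive YAML
  for (f in c("sample_vcfs", "groups", "generations"))
    x[[f]] <- as.list(x[[f]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  fc <- do.call(filter_config, x$filter %||% list())
  pipeline_config(x$reference_fasta, x$annotation_gff3, x$parental_vcf,
                  unlist(x$sample_vcfs), unlist(x$groups), fc,
                  unlist(x$generations %||% c(mutator = 30, ems = 1)),
                  x$output_dir %||% "mutspectra_report", x$seed %||% 1L)
}

#' Simulate a full mutagenesis sequencing study
#'
#' Generates an annotated toy genome, a parental variant set against the
#' reference, and two groups of mutagenised clones (`mutator` and `ems`,
#' `k` clones each) whose induced mutations are drawn from the corresponding
#' mutagen profiles and rendered as noisy variant calls.  Everything is
#' written to `out_dir` (FASTA, GFF3, parental VCF, per-sample VCFs, truth
#' TSVs) and a ready-to-run [pipeline_config()] is returned.  Output is
#' deterministic for a fixed seed.
#'
#' Defaults mirror a small-scale version of the study design this package
#' targets: 5 clones per mutagen, a mean of 7.2 SNVs per mutator clone and
#' 55.8 per EMS clone (Poisson-distributed across clones), indel rates tied
#' to the profiles, and a parental strain carrying its own set of
#' differences from the reference.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param k Clones per group.
#' @param genome A [genome_model()], or `NULL` to generate one.
#' @param n_parental Number of parental variants vs the reference.
#' @param mutator_mean_snvs,ems_mean_snvs Mean induced SNVs per clone.
#' @param mutator_profile,ems_profile [mutagen_profile()]s for the groups.
#' @param noise A [noise_model()].
#' @param n_decoys Decoy calls per sample (each violating one filter
#'   criterion; 0 for clean bundles).
#' @param generations Named generations-per-group vector (see
#'   [pipeline_config()]).
#' @param ... Passed to [generate_genome()] when `genome` is `NULL`.
#' @return A `pipeline_config` (invisibly also written as `config.yaml`).
#' @export
simulate_study <- function(out_dir, seed = 1L, k = 5L, genome = NULL,
                           n_parental = 150L,
                           mutator_mean_snvs = 7.2, ems_mean_snvs = 55.8,
                           mutator_profile = mutagen_profile("mutator"),
                           ems_profile = mutagen_profile("ems"),
                           noise = noise_model(), n_decoys = 0L,
                           generations = c(mutator = 30, ems = 1), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(genome))
    genome <- generate_genome(n_contigs = 1L, contig_length = 60000L,
                              n_genes = 20L, gc_content = 0.38,
                              seed = child_seed(seed, 1L),
                              intron_prob = 0.2, ...)
  fasta <- file.path(out_dir, "reference.fa")
  gff3 <- file.path(out_dir, "annotation.gff3")
  write_genome_fasta(genome, fasta)
  write_genome_gff3(genome, gff3)
  contig_lengths <- nchar(genome$contigs)

  ## parental variants: spontaneous-like, flat over the six classes
  parental_prof <- mutagen_profile(
    class_weights = stats::setNames(rep(1 / 6, 6), SUBSTITUTION_CLASSES))
  parental <- sample_mutations(genome, parental_prof, n_parental,
                               seed = child_seed(seed, 2L))

  groups <- c(stats::setNames(rep("mutator", k), sprintf("mutator%d", seq_len(k))),
              stats::setNames(rep("ems", k), sprintf("ems%d", seq_len(k))))
  sample_vcfs <- character(0)
  parental_vcf <- file.path(out_dir, "parental.vcf")
  parental_written <- FALSE
  i <- 0L
  for (sid in names(groups)) {
    i <- i + 1L
    grp <- groups[[sid]]
    prof <- if (grp == "mutator") mutator_profile else ems_profile
    mean_snv <- if (grp == "mutator") mutator_mean_snvs else ems_mean_snvs
    s <- child_seed(seed, 10L + i)
    n_snv <- with_seed(s, stats::rpois(1, mean_snv))
    muts <- sample_mutations(genome, prof, n_snv, seed = s + 1L)
    ## avoid colliding with parental positions
    muts <- muts[!paste(muts$contig, muts$pos) %in%
                   paste(parental$contig, parental$pos), , drop = FALSE]
    n_indel <- with_seed(s + 2L, stats::rpois(1, n_snv * prof$indel_rate))
    indels <- sample_indels(genome, n_indel, seed = s + 3L)
    indels <- indels[!paste(indels$contig, indels$pos) %in%
                       c(paste(parental$contig, parental$pos),
                         paste(muts$contig, muts$pos)), , drop = FALSE]
    true_set <- rbind(muts[, c("contig", "pos", "ref", "alt")],
                      indels[, c("contig", "pos", "ref", "alt")])
    rv <- render_variant_calls(true_set, parental, noise = noise,
                               n_decoys = n_decoys, seed = s + 4L,
                               sample_id = sid, genome = genome)
    vcf <- file.path(out_dir, paste0(sid, ".vcf"))
    write_vcf_records(rv$sample_calls, vcf, contig_lengths)
    write_truth_table(rv$truth, file.path(out_dir, paste0(sid, ".truth.tsv")))
    sample_vcfs[sid] <- vcf
    if (!parental_written) {
      write_vcf_records(rv$parental_calls, parental_vcf, contig_lengths)
      parental_written <- TRUE
    } else if (n_decoys > 0L) {
      ## append this sample's planted in_parental decoys to the parental VCF
      existing <- read_vcf_records(parental_vcf, "parental")
      merged <- rbind(existing, rv$parental_calls)
      merged <- merged[!duplicated(variant_key(merged)), ]
      write_vcf_records(merged, parental_vcf, contig_lengths)
    }
  }
  cfg <- pipeline_config(fasta, gff3, parental_vcf, sample_vcfs, groups,
                         generations = generations,
                         output_dir = file.path(out_dir, "report"),
                         seed = seed)
  write_pipeline_config(cfg, file.path(out_dir, "config.yaml"))
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_mutspectra("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))
  })
}

#' Run the full profiling pipeline
#'
#' Executes parental subtraction, the filter cascade, feature assignment,
#' substitution-spectrum classification, codon-level protein impact and the
#' frequency/rate summaries over all configured samples, pooling results by
#' mutagen group.  Every table is written to `config$output_dir` as TSV, a
#' per-stage log records record counts in and out, and the full report
#' bundle is returned.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `mutation_report`: list with `counts`
#'   (per-sample / per-group accepted mutation counts), `features`,
#'   `spectra_genome_wide`, `spectra_nonsynonymous`, `protein_tables`,
#'   `per_site_rates` (all keyed by group), plus `outcomes` (all filter
#'   outcomes) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  say <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
  }

  genome <- stage("read_genome",
                  read_genome(config$reference_fasta, config$annotation_gff3))
  say("read_genome: %d contig(s), %d gene(s)", length(genome$contigs),
      length(genome$genes))
  parental <- stage("read_parental",
                    read_vcf_records(config$parental_vcf, "parental"))
  say("read_parental: %d records", nrow(parental))

  outcomes <- list()
  for (sid in names(config$sample_vcfs)) {
    calls <- stage("read_sample",
                   read_vcf_records(config$sample_vcfs[[sid]], sid))
    calls <- stage("subtract_parental", subtract_parental(
      calls, parental, position_only = config$filter$match_position_only))
    out <- stage("apply_filters", apply_filters(calls, config$filter))
    say("filter[%s]: %d in, %d passed, %d rejected", sid, nrow(out),
        sum(out$passed), sum(!out$passed))
    outcomes[[sid]] <- out
  }
  all_outcomes <- do.call(rbind, outcomes)
  counts <- stage("summarize_counts",
                  summarize_counts(all_outcomes, config$groups))

  passed <- all_outcomes[all_outcomes$passed, , drop = FALSE]
  passed_snv <- passed[passed$kind == "substitution", , drop = FALSE]
  passed_snv <- stage("assign_feature", assign_feature(passed_snv, genome))

  by_group <- split(passed_snv,
                    factor(unname(config$groups[passed_snv$sample_id]),
                           levels = unique(unname(config$groups))))
  features <- list(); spectra_gw <- list(); spectra_ns <- list()
  prot <- list(); impacts <- list()
  for (grp in names(by_group)) {
    calls <- by_group[[grp]]
    features[[grp]] <- feature_summary(calls)
    spectra_gw[[grp]] <- stage("spectrum_summary", spectrum_summary(calls))
    ex <- calls[calls$feature == "exon", , drop = FALSE]
    imp <- stage("codon_effect", codon_effect(ex, genome))
    impacts[[grp]] <- cbind(ex[, c("contig", "pos", "ref", "alt",
                                   "sample_id")], imp)
    ex$effect <- imp$effect
    spectra_ns[[grp]] <- spectrum_summary(ex, scope = "nonsynonymous_only")
    prot[[grp]] <- stage("protein_table", protein_table(imp))
    say("group[%s]: %d SNVs, %d exonic, %d aa-changing", grp, nrow(calls),
        nrow(ex), sum(imp$effect == "changed"))
  }

  ## per-site rates on callable genome (all simulated sites are callable in
  ## the toy setting; callable_sites = genome size)
  gsize <- sum(nchar(genome$contigs))
  rates <- list()
  for (grp in names(by_group)) {
    d <- counts$per_sample[counts$per_sample$group == grp, , drop = FALSE]
    gen <- config$generations[[grp]] %||% 1
    rates[[grp]] <- per_site_rate(d$snv, rep(gsize, nrow(d)), gen)
  }

  report <- structure(list(counts = counts, features = features,
                           spectra_genome_wide = spectra_gw,
                           spectra_nonsynonymous = spectra_ns,
                           protein_tables = prot, impacts = impacts,
                           per_site_rates = rates, outcomes = all_outcomes,
                           log = log, output_dir = config$output_dir),
                      class = "mutation_report")
  write_report(report, config)
  report
}

write_report <- function(report, config) {
  od <- config$output_dir
  w <- function(df, name) {
    utils::write.table(df, file.path(od, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(report$counts$per_sample, "counts_per_sample.tsv")
  w(report$counts$per_group, "counts_per_group.tsv")
  bind_groups <- function(lst, f) {
    do.call(rbind, lapply(names(lst), function(g)
      cbind(group = g, f(lst[[g]]))))
  }
  w(bind_groups(report$features, identity), "feature_frequencies.tsv")
  w(bind_groups(report$spectra_genome_wide, function(s) s$table),
    "spectrum_genome_wide.tsv")
  w(bind_groups(report$spectra_nonsynonymous, function(s) s$table),
    "spectrum_nonsynonymous.tsv")
  w(bind_groups(report$protein_tables, as.data.frame),
    "protein_level_table.tsv")
  rej <- report$outcomes[!report$outcomes$passed,
                         c("sample_id", "contig", "pos", "ref", "alt",
                           "failed_criteria")]
  w(rej, "rejected_records.tsv")
  passed <- report$outcomes[report$outcomes$passed, , drop = FALSE]
  write_vcf_records(passed, file.path(od, "passed_calls.vcf"))
  writeLines(report$log, file.path(od, "pipeline.log"))
  invisible(od)
}

#' @export
print.mutation_report <- function(x, ...) {
  cat("Mutation profiling report\n")
  cat("=========================\n")
  print(x$counts)
  for (g in names(x$spectra_genome_wide)) {
    cat(sprintf("\n[%s] ", g))
    print(x$spectra_genome_wide[[g]])
  }
  cat(sprintf("\nTables written to %s\n", x$output_dir))
  invisible(x)
}
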