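# mutspectra

Genome-wide mutation-spectrum profiling for microbial mutagenesis
experiments.

When a haploid microorganism is mutagenised — chemically (e.g. EMS) or
genetically (e.g. a plasmid-borne proofreading-deficient, low-fidelity DNA
polymerase δ "mutator" allele) — resequencing the mutagenised clones against
the parental strain reveals *what kind* of mutations each method produces,
not just how many. `mutspectra` implements the full analysis that turns
per-clone variant calls into that characterisation, for geneticists and
strain engineers comparing mutagenesis protocols:

* **Variant filtering with parental subtraction.** A call is accepted as an
  induced mutation only if read depth ≥ 10, Phred variant quality ≥ 20
  (substitutions) or ≥ 50 (indels), mapping quality ≥ 30, variant allele
  fraction > 90 % (haploid calls should be near-homozygous), and the variant
  is absent from the sequenced parental strain. Every rejection carries its
  named criteria.
* **Substitution spectra.** Accepted SNVs are pooled into the six
  complementary-pooled classes (A:T→G:C, G:C→A:T transitions; A:T→T:A,
  A:T→C:G, G:C→T:A, G:C→C:G transversions) and summarised as
  transition/transversion fractions, genome-wide and restricted to
  nonsynonymous exonic changes.
* **Gene-feature assignment.** Each SNV is placed in exactly one of exon,
  intron, promoter (1 kb upstream, strand-aware), terminator (200 bp
  downstream) or intergenic space.
* **Protein-level impact.** Codon-level consequences (preserved / amino-acid
  change / stop gained), the mutated codon letter (1st/2nd/3rd),
  conservative vs nonconservative changes by the BLOSUM62 criterion
  (score > 0 is conservative), and the structure indicator — stop codons
  plus Gly/Pro substitutions as a fraction of amino-acid-level events.
* **Rates.** Mutant frequencies from colony counts
  (resistant / (total × dilution)), fold elevations over controls,
  per-site base-substitution rates `r_i = n_i / (sites_i × generations)`
  averaged across strains with a standard error, and forward mutation rates
  by Luria–Delbrück fluctuation analysis: the p0 method
  (`m = −ln p̂₀`) and the Ma–Sandri–Sarkar maximum-likelihood estimator
  built on the recursion

  ```
  p₀ = e^(−m),   p_k = (m/k) · Σ_{i=0}^{k−1} p_i / (k − i + 1)
  ```

  with a profile-likelihood confidence interval and `μ = m / N_final`.
* **A synthetic-data generator.** Annotated toy genomes (valid ORFs,
  optional introns), mutagen profiles over the six classes (presets:
  `"ems"`, 97 % transitions; `"mutator"`, 72 % transversions), and noisy
  VCF rendering with per-criterion decoys — so the entire pipeline is
  testable end-to-end with no external data.

Standard formats throughout: FASTA + GFF3 for the annotated reference, VCF
v4.2 for calls, BED for masks, TSV/YAML for tables and configuration.

## Worked example

Simulate a study — 5 mutator clones and 5 EMS clones over a 60 kb annotated
toy genome with a parental variant set — then run the whole pipeline:

```r
library(mutspectra)

cfg <- simulate_study(file.path(tempdir(), "demo"), seed = 1, k = 5)
rep <- run_pipeline(cfg)
print(rep)
```

```
Mutation profiling report
=========================
Accepted mutation counts (mean +/- SE per group):
   group n_samples snv_mean snv_se insertion_mean insertion_se deletion_mean
     ems         5     51.8  1.855            2.4       0.8718           1.8
 mutator         5      7.6  1.030            1.6       0.5099           1.0
Welch t-test on per-sample SNV counts: t = 20.836, p = 5.166e-07

[mutator] Substitution spectrum (genome_wide), 38 SNVs
   class is_transition count frequency
 A:T>G:C          TRUE     5    0.1316
 G:C>A:T          TRUE     5    0.1316
 A:T>T:A         FALSE     8    0.2105
 A:T>C:G         FALSE     6    0.1579
 G:C>T:A         FALSE    10    0.2632
 G:C>C:G         FALSE     4    0.1053
transitions 26.3% / transversions 73.7%

[ems] Substitution spectrum (genome_wide), 259 SNVs
   class is_transition count frequency
 A:T>G:C          TRUE   128    0.4942
 G:C>A:T          TRUE   115    0.4440
 ...
transitions 93.8% / transversions 6.2%
```

The EMS group is transition-dominated and the mutator group
transversion-dominated, matching the profiles the clones were simulated
from; per-clone SNV means (51.8 vs 7.6) recover the configured study design.
`rep$protein_tables`, `rep$features` and the TSVs under `cfg$output_dir`
hold the protein-level table, feature frequencies and spectra per group.

Fluctuation analysis of a mutant-count experiment:

```r
counts <- rluria(12, m = 4, final_population = 2e8, seed = 7)
#>  [1]  40   5  13 119   3   1   7   7   9  19   8   7
fluctuation_rate(counts, final_population = 2e8)
#> Fluctuation analysis (mss_mle), 12 cultures
#>   m  = 3.685 mutations/culture (95% CI 2.282 - 5.413)
#>   mu = 1.843e-08 per cell division (N_final = 2e+08)
```

The heavy-tailed counts (note the jackpot culture with 119 mutants) are the
Luria–Delbrück signature; the MLE recovers the simulated m = 4 within its
confidence interval.

A thin command-line wrapper over these functions ships in
`inst/cli/mutspectra.R` (subcommands `simulate`, `run`, `filter`,
`spectrum`, `protein`, `rates`).

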