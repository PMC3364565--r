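---
title: "Methods: mutation-spectrum profiling of mutagenised haploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-spectrum profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The analysis problem

Comparing mutagenesis protocols — say, EMS treatment against a
proofreading-deficient/low-fidelity DNA polymerase δ mutator plasmid in
haploid *S. cerevisiae* — requires more than counting mutants on selective
plates. Two protocols with similar apparent mutant frequencies can differ
radically in the *kind* of DNA changes they induce, and therefore in the
diversity of protein variants they can reach. `mutspectra` implements the
computational half of such a comparison: it consumes per-clone variant
calls against a reference genome (plus the parental strain's calls), and
produces the accepted-mutation counts, substitution spectra, gene-feature
distributions, protein-level impact tables, and mutation-rate estimates on
which the comparison rests.

This vignette documents the models and conventions the package commits to,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was genuinely
open.

# Variant filtering

A raw variant call is accepted as an induced mutation only if **all** of the
following hold (`filter_config()` defaults in parentheses):

| criterion          | rule                                      | default |
|--------------------|-------------------------------------------|--------|
| depth              | total read depth at the site, inclusive    | ≥ 10   |
| quality            | Phred variant quality; substitutions / indels | ≥ 20 / ≥ 50 |
| mapping quality    | Phred mapping quality, inclusive           | ≥ 30   |
| VAF                | variant allele fraction, **strict**        | > 0.90 |
| parental subtraction | call absent from the parental strain     | —      |

Conventions worth making explicit:

* **Inclusive vs strict thresholds.** Depth, quality and mapping quality are
  minima and inclusive (`≥`); the allele-fraction rule is "exceeds 90%" and
  strict (`>`), so a VAF of exactly 0.90 is rejected. In a haploid a true
  mutation should be supported by essentially all reads; sub-90% support
  indicates mixed colonies, mismapping or contamination. The
  mapping-quality convention (inclusive) is configurable, as the common
  phrasing "meets a mapping quality of 30" is ambiguous.
* **Parental matching key.** A sample call is `in_parental` when the
  parental set has a call with the identical (contig, pos, ref, alt). This
  allele-exact key is the conservative reading of "not present in the
  parental strain": a different allele at the same site is still an induced
  change. Position-only matching is available behind a flag.
* **Multi-allelic records** are split into one record per alternate allele
  on VCF read and filtered independently — the natural treatment for a
  haploid, where a genuine site has one true allele.
* **Repetitive regions.** Read-level repeat removal happens upstream
  (alignment); at this stage an optional BED mask of excluded intervals
  stands in for it, rejecting calls with the distinct reason `masked` so
  the audit trail stays complete.
* Missing annotations (depth/quality/VAF) are an **error**, never a silent
  pass, and every rejected record lists *all* violated criteria.

Two invariants are enforced by tests: accepted ∪ rejected partition the
input, and raising any threshold can only shrink the accepted set.

# Substitution spectra

Double-stranded DNA makes a substitution and its reverse complement
indistinguishable without strand information, so the 12 directed single-base
changes are pooled into 6 classes, two transitions (A:T>G:C, G:C>A:T) and
four transversions. `classify_substitution()` canonicalises onto the A/G
representative strand; the pooling makes every spectrum invariant under
reverse-complementing the genome and all calls, which is tested as a
property.

Spectra are reported as per-class counts and relative frequencies with
transition/transversion fractions, pooled across the clones of one mutagen
group (clone identity carries no information about class frequencies under
the pooling model). The `nonsynonymous_only` scope keeps amino-acid-changing
and stop-gaining calls only, mirroring the common practice of asking what
the mutagen does *within coding space that matters for protein diversity*.

# Gene features

Each SNV is assigned to exactly one feature: `exon` (inside a CDS interval),
`intron` (between CDS intervals of one gene), `promoter`
(`promoter_length` = 1 kb upstream of the gene start, on the gene's strand),
`terminator` (`terminator_length` = 200 bp downstream), else `intergenic`.
Because a single category per SNV is wanted, overlaps need a rule; the
package uses

* precedence `exon > intron > promoter > terminator > intergenic` — coding
  impact dominates regulatory proximity;
* among promoters/terminators of different genes, the nearest gene wins,
  ties broken deterministically by the lower gene start coordinate.

These conventions are choices, not facts of nature; they are centralised in
`assign_feature()` and exercised directly by tests so any alternative rule
would be a one-function change.

# Protein-level impact

For an exonic substitution the affected codon is located on the coding
strand (minus-strand genes are reverse-complemented first; the codon letter
position 1–3 is likewise reported on the coding strand), and translated with
the standard nuclear genetic code. Effects:

* `preserved` — same amino acid, including a stop codon remaining a stop;
* `stop_gained` — the new codon is a stop;
* `changed` — any other amino-acid change, *including* stop-loss and
  start-loss (the three-way classification has no better bucket for them,
  and they are rare single events in practice).

Amino-acid changes are split into conservative vs nonconservative by the
BLOSUM62 matrix: **conservative iff score > 0** (strictly positive). Zero
scores (e.g. A↔G) count as nonconservative by default; an inclusive `≥`
variant is available. The matrix ships with the package as a plain integer
constant and is verified against the Biostrings reference copy in the test
suite.

The **structure indicator** counts events likely to disturb protein
structure: stop-gained records plus changes in which either the reference
or the substituted amino acid is Gly or Pro ("either" direction by default,
`to`/`from` variants configurable). Its denominator is amino-acid-level
events — changes + stops — not total mutations: the indicator asks "of the
events that altered the protein, how many are structurally drastic?", and
this denominator is also the only one consistent with reporting the
indicator alongside its internal stop vs Gly/Pro split.

The codon machinery is validated exhaustively: all 64 codons × 9 single-base
changes against an independent translation oracle, and strand invariance on
reverse-complemented genomes.

# Rates

* **Mutant frequency** = resistant colonies / (non-selective colonies ×
  dilution factor). **Fold elevations** are ratios of frequencies; reported
  values round half-up to integers (so 17.5 reports as 18), matching how
  such tables are conventionally printed.
* **Per-site base-substitution rate**: per strain,
  `r_i = n_i / (s_i × generations)` with `n_i` accepted SNVs and `s_i`
  callable sites (sites meeting the depth criterion); the estimate is the
  *mean of per-strain rates* (not the ratio of pooled sums), with
  SE = sd(r)/√n. Strain-level averaging keeps the strain as the unit of
  replication, which is what the SE is about. `generations = 1` gives a
  per-treatment rate (one-shot chemical exposure); a continuously mutating
  strain grown for ~30 generations uses `generations = 30` for a
  per-division rate.
* **Fluctuation analysis.** The expected mutations per culture `m` is
  estimated from parallel-culture mutant counts either by the p0 method
  (`m = −ln p̂₀`, requiring at least one zero-mutant culture) or by maximum
  likelihood under the Luria–Delbrück distribution computed with the
  Ma–Sandri–Sarkar recursion (default; appropriate for the usual 5–100
  cultures). The per-division rate is `μ = m / N_final`.

## Numerical choices in the MLE

* The recursion is evaluated up to `max_k` (default 1000); larger observed
  counts are lumped into the distribution's upper tail probability. This is
  the standard treatment of "jackpot" cultures, whose exact size carries
  almost no information about `m` beyond "large".
* The log-likelihood is **extremely flat and low** for `m` far above the
  optimum once jackpot counts inflate the naive search interval
  (`max(counts) + 5` can be 10⁷). A plain golden-section search over that
  interval can stall on the plateau, so the optimiser first brackets the
  maximum on an 80-point log-spaced grid and then runs R's `optimize()`
  (tolerance 10⁻⁶) inside the bracket. Unimodality on the bracketed region
  is checked numerically in the tests.
* Confidence intervals on `m` are profile-likelihood intervals (χ²₁ drop of
  1.92 for 95%); the p0 method transforms the exact binomial interval for
  the zero fraction. Simulation at m ∈ {0.5, 2, 4} with 50 cultures gives
  92–96% empirical coverage for the nominal 95% intervals.
* All-zero counts give `m = 0` with a degenerate-data warning under the MLE
  (and exactly `m = 0` under p0).
* `rluria()` simulates the process *without* the recursion (Poisson number
  of mutational events; each event founds a clone of final size ⌊1/U⌋ under
  deterministic growth, capped at `N_final`), so estimator and simulator
  are independent routes that cross-validate each other in the tests.

# The synthetic-data generator

The generator exists so that every downstream stage is testable, with known
truth, from nothing but a seed. It emulates:

* a small annotated haploid genome — by default one 60 kb contig at 38% GC
  (yeast-like) carrying 20 non-overlapping genes of 100–200 codons, each a
  valid ORF (ATG start, single terminal stop, no internal stops), a fifth
  of them carrying one GT…AG intron;
* a parental strain with its own variant set against the reference (default
  150 spontaneous-spectrum variants — a desk-scale stand-in for the
  thousands of differences a real working strain accumulates relative to
  the community reference);
* mutagen-specific induced mutations: a `mutagen_profile()` is a
  probability vector over the six pooled classes. The presets encode only
  the two aggregate fractions that characterise the protocols this package
  targets — EMS 97% transitions, mutator 72% transversions — with the split
  *within* each aggregate uniform, because only the aggregates are robustly
  established; per-class weights are user-overridable.
  Default study design: 5 clones per group, mean 55.8 SNVs per EMS clone
  and 7.2 per mutator clone (Poisson across clones), indel rates of 0.06
  and 0.25 indels per SNV respectively, consistent with the relative indel
  loads such experiments observe;
* noisy variant evidence: negative-binomial depth (mean 40, clean calls
  floored at depth 10), uniform quality draws comfortably above thresholds
  for true calls, VAF 1.0 for clean haploid calls; decoy calls violate
  exactly one named criterion each (low depth, low quality, low mapping
  quality, VAF drawn in [0.30, 0.90], or planted in the parental set), with
  the violated criterion recorded as truth.

What it deliberately does **not** emulate: read-level errors and alignment
(it produces call records, not FASTQ), genotype likelihoods, repetitive
sequence, trinucleotide context biases, clustered mutations, and any
correlation between substitution class and codon position. Passing tests
therefore demonstrate that the *analysis* is correct on data whose
statistical structure matches its assumptions — not that any particular
laboratory dataset satisfies those assumptions.

Seeds are explicit arguments everywhere; there is no hidden global RNG
state (callers' RNG streams are restored), and fixed seeds reproduce output
files byte-for-byte.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the statistical assertions have clear error bounds rather than for speed
alone: genomes of 10–60 kb, spectra of n = 1000 draws checked within 4
binomial SDs over 20 seeds, the exhaustive 576-case codon oracle,
fluctuation recovery with 50 cultures × 50 replicates per `m`, and full
pipeline runs with 2 × 5 clones. Genome-scale quantities that depend on a
specific laboratory's raw sequencing data (parental variant inventories,
callable-site censuses) are represented by the generator's scaled-down
defaults, with printed experimental inputs (colony counts, callable-site
totals, per-clone means) used where the originals are published numbers.

# Known limitations

* Indels are counted in the per-clone summaries but excluded from spectra
  and protein-level tables (no frameshift annotation).
* No splice-site consequence prediction; an intronic SNV is just `intron`.
* No trinucleotide-context (96-class) signatures or signature
  decomposition.
* Fluctuation analysis assumes complete plating and no phenotypic lag; no
  plating-efficiency correction is applied.
* Feature assignment is single-label by design; analyses that want
  multi-counting of overlapping features need the per-gene geometry, which
  `assign_feature()` does not expose.
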