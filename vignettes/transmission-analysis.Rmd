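---
title: "DNA-to-RNA SNP transmission analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA-to-RNA SNP transmission analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the procedure

Allotetraploid *Brassica napus* carries two ancestral subgenomes, An (from
*B. rapa*) and Cn (from *B. oleracea*). The two subgenomes are asymmetric:
An tends to carry more sequence variation and to express its genes more
strongly — "subgenome dominance". `snptransmit` implements one lens on that
asymmetry: of the homozygous SNPs a line carries in its genome (DNA-level
calls from resequencing), which fraction is observed again in its
transcriptome (RNA-level calls from RNA-seq)? A SNP present — with identical
chromosome, position, reference and alternate allele, and a homozygous-alt
genotype — in both call sets is *transmitted*. Per gene,

$$\text{transmission ratio} \;=\; \frac{\#\,\text{transmitted SNPs in the gene}}
{\#\,\text{genomic SNPs detected in the gene}},$$

and a homozygous RNA-level SNP absent from the DNA-level set is a *novel*
RNA variation. The same matching applies between lines: parent DNA to
offspring DNA, and the two-step chain parent DNA → offspring DNA →
offspring RNA.

The pipeline stages are:

1. **Read and filter** (`read_vcf`, `hard_filter`): per line and level,
   VCF records are reduced to bi-allelic SNP observations and hard-filtered
   with GATK-style rules — a quality expression
   (`QUAL < 30 || MQ < 50 || QD < 2`) and a cluster rule (≥ 3 SNPs within
   any 10 bp window).
2. **Classify** (`classify_effects`, `summarize_annotations`): each SNP is
   placed as intergenic / intronic / exonic against a GFF3 annotation
   (gene body only — upstream/downstream intervals of length 0), and coding
   SNPs are called synonymous or missense by codon translation.
3. **Match** (`hom_set`, `match_transmitted`, `chain_transmitted`,
   `novel_variants`, `per_gene_transmission`): exact set operations on
   `(chrom, pos, ref, alt)` keys over homozygous, filter-passing records.
4. **Subgenome statistics** (`assign_subgenome`, `snp_density`,
   `partition_counts`, `syntenic_ratio_test`, `window_scan`): densities in
   SNPs/kb, An/Cn partitions, and a two-tailed t-test of transmission ratios
   across syntenic (homoeologous) gene pairs.
5. **Expression** (`merge_tpm`, `bin_genes`, `fit_binned_regression`,
   `compare_syntenic_expression`): genes are binned by transmission ratio or
   by SNP count, and ordinary least squares fits the binned linear model
   $y_i = a x_i + b$, where $y_i$ is the mean TPM of bin $i$ and $x_i$ the
   bin ordinal.

`run_pipeline()` sequences all stages from one configuration and writes a
deterministic JSON report.

# Key definitions and their consequences

**Homozygosity on both sides.** "Common homozygous SNP" is read strictly:
the same site *and* allele, homozygous-alt in both call sets. A site that is
homozygous for different alternate alleles in the two sets is not
transmitted. Heterozygous calls never enter the matching.

**The denominator.** Because only homozygous SNPs can be transmitted under
this definition, `per_gene_transmission(denominator = "hom")` (the default)
counts only homozygous source SNPs, guaranteeing ratios in $[0, 1]$.
`denominator = "all"` reproduces the looser reading in which every detected
genomic SNP in the gene counts; ratios then understate transmission for
het-rich genes.

**Genes without source SNPs** have no defined ratio. They are excluded from
every ratio analysis and reported as a separate zero-SNP gene list, so
downstream t-tests and regressions never see synthetic zeros.

**Filter ordering.** The cluster rule is evaluated on all records of a
(line, level) call set *before* quality filtering, mirroring GATK
VariantFiltration, and a record carries one worst status with cluster taking
precedence. Missing quality metrics pass their clause — a comparison against
a missing value cannot fail. `hard_filter` is idempotent.

**Coordinates.** VCF and GFF3 are 1-based inclusive and the implementation
keeps that convention internally (it is the native convention of
IRanges/GenomicRanges, on which the interval math is built). The only
conversion to 0-based half-open happens in the bedGraph writer.

**Effect classes.** Within a CDS, the reference codon and the alt codon are
translated on the coding strand: same amino acid → synonymous, different →
missense, except that any change creating or destroying a stop codon is
classed `other`. Exonic-but-UTR SNPs are `other` as well. This matches
summary tables in which missense + synonymous percentages do not sum to
100%. Stop changes are deliberately *not* counted as missense. Single
transcripts per gene are assumed. When a SNP's REF disagrees with the genome
sequence the record keeps its region class but gets no effect class, with a
warning.

**Statistics.** `syntenic_ratio_test` defaults to Welch's unequal-variance
two-sample t-test — the safer default when only "two-tailed t-test" is
specified — with `mode = "paired"` available to respect the pair structure.
Numerically constant inputs are handled explicitly: identical vectors give
$t = 0, p = 1$; a constant non-zero difference gives $p = 0$ with a warning
(below machine precision) rather than an error.

**Binning.** Ratio bins are right-open except the last
($[0,0.1), \ldots, [0.9,1.0]$ at width 0.1), so completely transmitted genes
(ratio 1) land in the top bin. Count bins are $[1,w], [w{+}1,2w], \ldots$;
genes with zero variations are excluded by default (`include_zero` restores
them as bin 0). Empty bins are dropped before fitting and at least 3
non-empty bins are required. The regressor is the bin ordinal over non-empty
bins, matching the "group number" formulation; `x = "midpoint"` switches to
bin midpoints. Bin width is a parameter, not a constant: at genome scale a
width of 10 (or 20 for SNP-rich call sets) is the natural choice, while the
synthetic toy scale uses width 1 because genes carry only a few SNPs each.
TPM is used as provided — no renormalisation, no log transform.

# The synthetic-data generator

`sim_config()` + `simulate_dataset()` build a complete, verifiable input
set: FASTA genome, GFF3 annotation, four VCFs (parent/offspring ×
DNA/RNA), syntenic-pair table, per-line TPM tables, and the planted truth
tables used by the tests.

What it emulates, and the defaults chosen as the study conditions:

- **Two subgenomes with unequal SNP density**: chromosomes `chrA*`/`chrC*`;
  `dna_snp_density_A = 2.0`, `dna_snp_density_C = 1.0` SNPs/kb. The 2:1
  ratio mirrors the observed pattern of An density roughly twice Cn; the
  absolute scale is of the order of genome-wide densities (≈1–2 SNPs/kb) in
  *B. napus* resequencing.
- **Per-subgenome transmission probabilities**: each homozygous DNA SNP
  reappears in the RNA calls with `transmit_prob_A = 0.55` /
  `transmit_prob_C = 0.43`, the asymmetry reported for syntenic genes
  (55.43% vs 43.21%).
- **Genotype mixture**: `het_fraction = 0.3` of DNA SNPs are heterozygous;
  heterozygous SNPs are never transmitted in the truth model, since the
  transmission definition requires homozygosity at both levels.
- **Novel RNA variation** at `novel_rna_rate = 0.2` SNPs/kb, disjoint from
  the DNA sites, so every RNA SNP is exactly one of {transmitted, novel}.
- **Parent/offspring structure**: the offspring inherits each parental
  homozygous SNP with `inherit_prob = 0.5` and adds private SNPs at half the
  subgenome density, giving the parent→offspring and two-step chains
  non-trivial planted values (and, like the real offspring line, a larger
  total SNP set).
- **Expression coupling**: mean TPM per gene is
  $\max(0,\; \text{baseline} + \text{tpm\_slope}\cdot\text{ratio} +
  \text{tpm\_count\_slope}\cdot n_\text{source} + \varepsilon)$, replicated
  over `n_tissues` columns with independent noise. The positive ratio
  coupling (`tpm_slope = 40` TPM per unit ratio) and negative SNP-count
  coupling (`tpm_count_slope = -0.5` TPM per SNP) encode the two directions
  the analysis is meant to recover: expression rising with transmission
  ratio and falling with variant load. Setting `tpm_count_slope = 0`
  recovers the pure ratio-linear model.

Uniform SNP placement (without replacement, so positions are distinct within
a chromosome) is an assumption, not an inference: no placement distribution
is specified for the real data. Alt alleles are uniform over the three
non-reference bases — no transition/transversion bias. Quality metrics are
written as passing values (`QUAL 100, MQ 60, QD 25`) unless `fail_fraction`
plants failing records for filter tests.

What it does **not** emulate: read-level noise (no FASTQ/BAM, no
coverage-dependent genotype error), linkage disequilibrium, indels or
multi-allelic truth sites, transposable elements, methylation, alternative
splicing, or any dependence of transmission on expression itself (in the
generator the causality is one-way, ratio → TPM). Passing tests therefore
show that the *procedure* recovers planted structure exactly or within
sampling error — they do not show that real RNA-seq variant calls are free
of the artefacts the generator omits.

Determinism: the same config (including `seed`) reproduces every output file
byte for byte; the three generator stages draw from seeds derived as
`seed`, `seed + 1`, `seed + 2`, so regenerating a later stage does not
disturb an earlier one.

# Numerical and edge-case choices

- Percentages in summary tables are rounded to 2 decimals, the precision at
  which such tables are printed; with zero exonic SNPs the percentages are
  `NA` (undefined), never 0.
- The window scan tiles non-overlapping windows from position 1; the last
  partial window is counted, so the total is
  $\sum_c \lceil L_c / w \rceil$. "Exceeding" is strict
  (count $> 10$ for the 150 bp RNA-read check).
- The cluster filter is a two-pointer sweep over sorted unique positions per
  (line, level, chromosome); tests compare it against a literal
  every-window-start recount.
- `run_pipeline` records statistics that are undefined on
  empty or degenerate data (too few pairs, too few bins) as `note` entries
  in the report instead of aborting: a zero-density simulation still yields
  a complete all-zero report. Genuine input errors abort with the stage
  name.
- Multi-allelic VCF rows are split per alternate allele with the genotype
  recomputed against that allele (hom-alt only if both called alleles equal
  it); non-SNP rows are skipped and counted.

# Problem sizes

The test suite verifies oracle equivalence at $10^4$ random keys/SNPs for
the set-intersection and hard-filter operations, 100 random SNPs per strand
for the codon classifier against a full-CDS retranslation oracle, 100
seeded replicates of ≥ 2000 syntenic pairs for the Welch-test power check,
and toy genomes of 2–4 chromosomes × 20–100 kb for end-to-end runs. The
acceptance script simulates 4 × 1 Mb chromosomes with 1,600 genes. These
sizes make every check exact or tightly banded while keeping the whole
suite fast; all of them are configuration values, not limits of the
implementation.

# Known limitations

- Single-transcript gene models; no canonical-transcript selection, no
  splice-region or up/downstream effect classes, no HGVS notation.
- Overlapping genes: a SNP is annotated against the first overlapping gene
  for its effect class, but counted in *every* overlapping gene by
  `per_gene_transmission` (and once in genome-wide summaries).
- Whether the published two-tailed test was pooled, Welch or paired is not
  derivable from its description; both Welch and paired are provided, and at
  the planted effect size the qualitative conclusion is insensitive to the
  choice.
- The transmission ratio treats RNA-seq variant calling as a detector of
  genomic alleles; allele-specific expression, RNA editing and
  coverage-driven dropout are all confounded in "not transmitted". The
  package quantifies the pattern; it cannot by itself separate those
  mechanisms.
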