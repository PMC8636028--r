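#' Simulation configuration for the synthetic transmission dataset
#'
#' Defines a toy allotetraploid genome (two subgenomes, chromosomes named
#' `chrA01...` and `chrC01...`), DNA-level SNP sets per line, RNA-level call
#' sets derived from them by per-subgenome transmission probabilities, and a
#' TPM expression table coupled to the planted per-gene transmission ratio.
#'
#' The defaults encode the asymmetry the simulator is meant to emulate in
#' *Brassica napus*: the An subgenome carries a higher SNP density than Cn and
#' transmits a larger fraction of its homozygous DNA SNPs to the RNA level
#' (0.55 vs 0.43), and expression rises with the transmission ratio while
#' falling with the raw SNP load of a gene.
#'
#' @param n_chrom_A,n_chrom_C Chromosomes per subgenome.
#' @param chrom_length Chromosome length in bases.
#' @param n_genes_per_chrom Genes laid out per chromosome (non-overlapping).
#' @param gene_length Genomic span of each gene, bases.
#' @param exons_per_gene Exons per gene; introns of 100 bp separate them.
#' @param dna_snp_density_A,dna_snp_density_C DNA-level SNP density, SNPs/kb.
#' @param transmit_prob_A,transmit_prob_C Probability that a homozygous DNA
#'   SNP is observed again in the same line's RNA-level calls.
#' @param het_fraction Fraction of DNA SNPs that are heterozygous (a
#'   heterozygous DNA SNP is never transmitted: transmission is defined on
#'   homozygous genotypes at both levels).
#' @param novel_rna_rate Density of RNA-only ("novel") homozygous SNPs, SNPs/kb.
#' @param inherit_prob Probability that a homozygous parent DNA SNP is also
#'   present (homozygous) in the offspring line's DNA calls.
#' @param tpm_slope TPM gained per unit transmission ratio.
#' @param tpm_count_slope TPM change per DNA SNP in the gene (negative by
#'   default: expression falls as variant load rises).
#' @param tpm_baseline Baseline TPM for a gene with ratio 0 and no SNPs.
#' @param tpm_noise_sd Gaussian noise SD on TPM (gene level and tissue level).
#' @param n_tissues Number of tissue columns in the TPM table.
#' @param fail_fraction Fraction of DNA SNP records written with a failing
#'   QUAL so hard-filter behaviour can be exercised; 0 writes passing
#'   metrics everywhere.
#' @param seed Integer seed; the same seed and config reproduce the dataset
#'   byte for byte.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chrom_A = 2L, n_chrom_C = 2L,
                       chrom_length = 100000L,
                       n_genes_per_chrom = 25L,
                       gene_length = 1800L,
                       exons_per_gene = 3L,
                       dna_snp_density_A = 2.0,
                       dna_snp_density_C = 1.0,
                       transmit_prob_A = 0.55,
                       transmit_prob_C = 0.43,
                       het_fraction = 0.3,
                       novel_rna_rate = 0.2,
                       inherit_prob = 0.5,
                       tpm_slope = 40,
                       tpm_count_slope = -0.5,
                       tpm_baseline = 10,
                       tpm_noise_sd = 2,
                       n_tissues = 4L,
                       fail_fraction = 0,
                       seed = 1L) {
  cfg <- list(
    n_chrom_A = as.integer(n_chrom_A), n_chrom_C = as.integer(n_chrom_C),
    chrom_length = as.integer(chrom_length),
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    gene_length = as.integer(gene_length),
    exons_per_gene = as.integer(exons_per_gene),
    dna_snp_density_A = dna_snp_density_A,
    dna_snp_density_C = dna_snp_density_C,
    transmit_prob_A = transmit_prob_A,
    transmit_prob_C = transmit_prob_C,
    het_fraction = het_fraction,
    novel_rna_rate = novel_rna_rate,
    inherit_prob = inherit_prob,
    tpm_slope = tpm_slope,
    tpm_count_slope = tpm_count_slope,
    tpm_baseline = tpm_baseline,
    tpm_noise_sd = tpm_noise_sd,
    n_tissues = as.integer(n_tissues),
    fail_fraction = fail_fraction,
    seed = as.integer(seed)
  )
  probs <- c("transmit_prob_A", "transmit_prob_C", "het_fraction",
             "inherit_prob", "fail_fraction")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || is.na(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("'", p, "' must be a probability in [0, 1]")
  }
  for (d in c("dna_snp_density_A", "dna_snp_density_C", "novel_rna_rate")) {
    if (cfg[[d]] < 0) stop("'", d, "' must be >= 0")
  }
  if (cfg$chrom_length <= 0 || cfg$gene_length <= 0)
    stop("lengths must be > 0")
  if (cfg$n_chrom_A < 0 || cfg$n_chrom_C < 0 || cfg$n_genes_per_chrom < 0)
    stop("counts must be >= 0")
  if (cfg$exons_per_gene < 1) stop("'exons_per_gene' must be >= 1")
  if (cfg$tpm_noise_sd < 0) stop("'tpm_noise_sd' must be >= 0")
  if (cfg$n_tissues < 1) stop("'n_tissues' must be >= 1")
  structure(cfg, class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_chrom_A + x$n_chrom_C, "chromosomes x", x$chrom_length, "bp,",
      x$n_genes_per_chrom, "genes/chrom\n")
  cat(sprintf("  DNA density A/C: %.2f / %.2f SNPs/kb; transmit A/C: %.2f / %.2f\n",
              x$dna_snp_density_A, x$dna_snp_density_C,
              x$transmit_prob_A, x$transmit_prob_C))
  cat(sprintf("  het fraction %.2f, novel RNA rate %.2f/kb, seed %d\n",
              x$het_fraction, x$novel_rna_rate, x$seed))
  invisible(x)
}
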