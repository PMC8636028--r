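#' Homozygous SNP key set of a call set
#'
#' A SNP can only be "transmitted" between two call sets when it is
#' homozygous-alt in both; this extracts the identity keys of the
#' homozygous-alt, filter-passing records.
#'
#' @param records Variant-record data.frame (run [hard_filter()] first;
#'   non-passing records are dropped here as a safety net).
#' @return Character vector of unique [snp_key()] strings.
#' @export
hom_set <- function(records) {
  r <- records[records$genotype == "hom_alt" &
                 records$filter_status == "pass", , drop = FALSE]
  unique(snp_key(r$chrom, r$pos, r$ref, r$alt))
}

#' Transmitted SNPs between a source and a target call set
#'
#' Two call sets sharing a common homozygous SNP — identical chromosome,
#' position, reference and alternate allele, homozygous-alt in both — are
#' regarded as having transmitted it. Symmetric in its arguments.
#'
#' @param source_keys,target_keys Homozygous key sets from [hom_set()].
#' @return Character vector: the exact intersection.
#' @export
match_transmitted <- function(source_keys, target_keys) {
  intersect(source_keys, target_keys)
}

#' Two-step transmission chain
#'
#' SNPs transmitted from a parent's DNA to the offspring's DNA and conserved
#' at the offspring's RNA level: the triple intersection of the three
#' homozygous sets.
#'
#' @param parent_dna,offspring_dna,offspring_rna Homozygous key sets.
#' @return Character vector of keys present in all three sets.
#' @export
chain_transmitted <- function(parent_dna, offspring_dna, offspring_rna) {
  match_transmitted(match_transmitted(parent_dna, offspring_dna),
                    offspring_rna)
}

#' Novel RNA variants
#'
#' Homozygous SNPs present at the RNA level but absent from the same line's
#' DNA calls — variation that arises during transcription rather than being
#' transmitted from the genome.
#'
#' @param dna_keys,rna_keys Homozygous key sets of one line.
#' @return Character vector: `rna_keys` minus `dna_keys`.
#' @export
novel_variants <- function(dna_keys, rna_keys) {
  setdiff(rna_keys, dna_keys)
}

#' Per-gene transmission counts and ratios
#'
#' For every gene, counts the homozygous source-level SNPs inside its
#' transcript span (`n_source`), how many of them are in the transmitted set
#' (`n_transmitted`), and the novel RNA SNPs it contains; the transmission
#' ratio is `n_transmitted / n_source`. Genes without source SNPs have no
#' defined ratio and are reported separately (`zero_snp_genes`). A SNP
#' overlapping several genes counts in each of them. Transmitted keys mapping
#' to no gene are tallied as intergenic, not an error.
#'
#' @param source_records Filter-passing source-level variant records.
#' @param transmitted_keys Keys from [match_transmitted()] or
#'   [chain_transmitted()].
#' @param novel_keys Keys from [novel_variants()] (optional).
#' @param genes A [gene_models()] object.
#' @param chain Label stored on every row, e.g. `"DNA->RNA"`.
#' @param denominator `"hom"` counts only homozygous source SNPs in
#'   `n_source` (only those can be transmitted, so ratios stay in [0, 1]);
#'   `"all"` counts every detected source SNP in the gene.
#' @return list of class `transmission_summary`: `per_gene` (one row per gene
#'   with `n_source >= 1`), `zero_snp_genes`, and `n_intergenic_transmitted`.
#' @export
per_gene_transmission <- function(source_records, transmitted_keys,
                                  novel_keys = character(), genes,
                                  chain = "DNA->RNA",
                                  denominator = c("hom", "all")) {
  denominator <- match.arg(denominator)
  src <- pass_records(source_records)
  if (denominator == "hom")
    src <- src[src$genotype == "hom_alt", , drop = FALSE]
  src_keys <- snp_key(src$chrom, src$pos, src$ref, src$alt)

  spans <- gene_spans(genes)
  src_gr <- GenomicRanges::GRanges(src$chrom,
                                   IRanges::IRanges(src$pos, src$pos))
  hits <- GenomicRanges::findOverlaps(src_gr, spans, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  g <- genes$genes
  n_source <- tabulate(sh, nbins = nrow(g))
  n_trans <- tabulate(sh[src_keys[qh] %in% transmitted_keys], nbins = nrow(g))

  nv <- parse_snp_key(novel_keys)
  n_novel <- integer(nrow(g))
  if (nrow(nv)) {
    nv_gr <- GenomicRanges::GRanges(nv$chrom, IRanges::IRanges(nv$pos, nv$pos))
    nh <- GenomicRanges::findOverlaps(nv_gr, spans, ignore.strand = TRUE)
    n_novel <- tabulate(S4Vectors::subjectHits(nh), nbins = nrow(g))
  }

  # transmitted keys falling in no gene span
  tr <- parse_snp_key(transmitted_keys)
  n_intergenic <- if (nrow(tr)) {
    tr_gr <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$pos, tr$pos))
    sum(GenomicRanges::countOverlaps(tr_gr, spans, ignore.strand = TRUE) == 0L)
  } else 0L

  keep <- n_source >= 1L
  per_gene <- data.frame(
    gene_id = g$gene_id[keep], chrom = g$chrom[keep],
    subgenome = g$subgenome[keep], chain = rep(chain, sum(keep)),
    n_source = n_source[keep], n_transmitted = n_trans[keep],
    ratio = ifelse(n_source[keep] > 0, n_trans[keep] / n_source[keep],
                   NA_real_),
    n_novel_rna = n_novel[keep],
    stringsAsFactors = FALSE)
  structure(list(per_gene = per_gene,
                 zero_snp_genes = g$gene_id[!keep],
                 n_intergenic_transmitted = n_intergenic),
            class = "transmission_summary")
}

#' @exportS3Method base::print
print.transmission_summary <- function(x, ...) {
  pg <- x$per_gene
  cat("transmission_summary (", pg$chain[1], "): ", nrow(pg),
      " genes with source SNPs, ", length(x$zero_snp_genes),
      " without; mean ratio ", round(mean(pg$ratio), 4), "\n", sep = "")
  invisible(x)
}

#' Write a per-gene transmission table as TSV
#'
#' @param summary A `transmission_summary` from [per_gene_transmission()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transmission_tsv <- function(summary, path) {
  write_tsv(summary$per_gene, path)
}
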