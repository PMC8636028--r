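# Shared fixtures: all built in code at test time.

# Small simulation config; overrides via ...
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_chrom_A = 1L, n_chrom_C = 1L, chrom_length = 20000L,
                   n_genes_per_chrom = 8L, gene_length = 1500L,
                   exons_per_gene = 2L, n_tissues = 2L, seed = 42L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Bare variant-record table from parallel vectors; metrics pass by default.
make_records <- function(chrom, pos, ref = "A", alt = "G",
                         genotype = "hom_alt", qual = 100, mq = 60, qd = 25,
                         level = "DNA", line = "L1",
                         filter_status = "pass") {
  n <- max(length(chrom), length(pos))
  data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n), mq = rep_len(mq, n), qd = rep_len(qd, n),
    genotype = rep_len(genotype, n), level = rep_len(level, n),
    line = rep_len(line, n), filter_status = rep_len(filter_status, n),
    region_class = rep_len(NA_character_, n),
    effect_class = rep_len(NA_character_, n),
    gene_id = rep_len(NA_character_, n), stringsAsFactors = FALSE)
}

# Write a VCF from raw body lines (header supplied), return the path.
write_vcf_text <- function(body, contig = "chr1", contig_len = 100000L,
                           sample = "S1") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="MQ">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="QD">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    body), path)
  path
}

# One toy gene on a random chromosome; returns list(genome, genes).
# The gene spans [201, 201+len-1] with a single exon and a CDS inset by
# utr bases at both ends (CDS length trimmed to a codon multiple).
toy_gene <- function(len = 600L, strand = "+", utr = 30L, seed = 1L,
                     chrom = "chrA01", chrom_len = 2000L) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- chrom
  tx_start <- 201L; tx_end <- tx_start + len - 1L
  cds_len0 <- len - 2L * utr
  cds_len <- cds_len0 - cds_len0 %% 3L
  genes <- gene_models(
    data.frame(gene_id = "g1", chrom = chrom, strand = strand,
               tx_start = tx_start, tx_end = tx_end,
               stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "g1", start = tx_start, end = tx_end),
    cds = data.frame(gene_id = "g1", start = tx_start + utr,
                     end = tx_start + utr + cds_len - 1L))
  list(genome = genome, genes = genes)
}

# Independent full-CDS retranslation oracle: rebuild the chromosome with the
# alt base substituted, extract and translate the whole CDS before and after,
# and classify from the two protein strings.
retranslate_effect <- function(genome, genes, chrom, pos, alt) {
  g <- genes$genes
  hit <- which(g$chrom == chrom & pos >= g$tx_start & pos <= g$tx_end)
  if (length(hit) == 0L) return("not_applicable")
  gid <- g$gene_id[hit[1L]]
  ex <- genes$exons[genes$exons$gene_id == gid, ]
  if (!any(pos >= ex$start & pos <= ex$end)) return("not_applicable")  # intron
  cd <- genes$cds[genes$cds$gene_id == gid, ]
  if (!any(pos >= cd$start & pos <= cd$end)) return("other")  # UTR
  chrom_seq <- as.character(genome[[chrom]])
  mutated <- chrom_seq
  substr(mutated, pos, pos) <- alt
  extract_protein <- function(s) {
    parts <- substring(s, cd$start, cd$end)
    cds <- paste(parts, collapse = "")
    if (g$strand[hit[1L]] == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  p_ref <- extract_protein(chrom_seq)
  p_alt <- extract_protein(mutated)
  if (p_ref == p_alt) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1L]] != strsplit(p_alt, "")[[1L]])
  aa <- c(substr(p_ref, d, d), substr(p_alt, d, d))
  if (any(aa == "*")) "other" else "missense"
}

# Brute-force cluster oracle: slide a window over every possible start and
# flag all positions covered by a window holding >= size SNPs.
brute_cluster <- function(pos, size = 3L, window = 10L) {
  pos <- sort(unique(pos))
  if (length(pos) == 0L) return(integer())
  fail <- logical(length(pos))
  for (s in seq(max(1L, min(pos) - window + 1L), max(pos))) {
    inside <- pos >= s & pos <= s + window - 1L
    if (sum(inside) >= size) fail <- fail | inside
  }
  pos[fail]
}

# Hand-rolled Welch statistics for the cross-check against t.test.
welch_oracle <- function(x, y) {
  v1 <- stats::var(x) / length(x); v2 <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
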