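#' Classify SNPs by genomic region and coding consequence
#'
#' Assigns each SNP a region (`intergenic`, `exon`, `intron` — gene body only,
#' no upstream/downstream classes) and, for SNPs inside a CDS, a coding
#' consequence by translating the reference and alternate codon on the coding
#' strand: same amino acid is `synonymous`, a different amino acid is
#' `missense`, and any change creating or destroying a stop codon is `other`.
#' Exonic SNPs outside the CDS (UTRs) are `other`; intronic and intergenic
#' SNPs are `not_applicable`.
#'
#' When a SNP overlaps several genes it is annotated against the first by
#' genomic position; per-gene counting downstream assigns it to every
#' overlapping gene.
#'
#' @param records Variant-record data.frame.
#' @param genes A [gene_models()] object.
#' @param genome DNAStringSet covering every chromosome in `records`.
#' @return `records` with `region_class`, `effect_class` and `gene_id` filled
#'   in. SNPs whose REF disagrees with the genome keep their region but get
#'   `effect_class = "not_applicable"` (with a warning).
#' @export
classify_effects <- function(records, genes, genome) {
  if (nrow(records) == 0L) return(records)
  missing_chrom <- setdiff(unique(records$chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))

  records$region_class <- "intergenic"
  records$effect_class <- "not_applicable"
  records$gene_id <- NA_character_

  snp_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$pos, records$pos))
  spans <- gene_spans(genes)
  hits <- GenomicRanges::findOverlaps(snp_gr, spans, ignore.strand = TRUE)
  if (length(hits) == 0L) return(records)
  # first overlapping gene (spans are in genomic order within chromosome)
  first <- !duplicated(S4Vectors::queryHits(hits))
  qi <- S4Vectors::queryHits(hits)[first]
  gi <- S4Vectors::subjectHits(hits)[first]
  records$region_class[qi] <- "intron"
  records$gene_id[qi] <- genes$genes$gene_id[gi]

  # ref-vs-genome check
  genome_base <- rep(NA_character_, nrow(records))
  for (chrom in unique(records$chrom[qi])) {
    sel <- which(records$chrom == chrom)
    genome_base[sel] <- substring(as.character(genome[[chrom]]),
                                  records$pos[sel], records$pos[sel])
  }
  mismatch <- qi[records$ref[qi] != genome_base[qi]]
  if (length(mismatch))
    warning(length(mismatch),
            " SNP(s) whose REF disagrees with the genome; region kept, ",
            "effect not assigned")

  exons_by_gene <- split(genes$exons, genes$exons$gene_id)
  cds_by_gene <- split(genes$cds, genes$cds$gene_id)
  strand_by_gene <- structure(genes$genes$strand, names = genes$genes$gene_id)

  cds_cache <- new.env(parent = emptyenv())
  for (k in seq_along(qi)) {
    i <- qi[k]
    gid <- records$gene_id[i]
    ex <- exons_by_gene[[gid]]
    in_exon <- any(records$pos[i] >= ex$start & records$pos[i] <= ex$end)
    if (!in_exon) next  # stays intron
    records$region_class[i] <- "exon"
    if (i %in% mismatch) next
    records$effect_class[i] <- "other"  # UTR default, refined below if in CDS
    cd <- cds_by_gene[[gid]]
    seg <- which(records$pos[i] >= cd$start & records$pos[i] <= cd$end)
    if (length(seg) == 0L) next
    strand <- strand_by_gene[[gid]]
    chrom <- records$chrom[i]
    if (!exists(gid, envir = cds_cache)) {
      assign(gid, cds_sequence(cd, strand, genome[[chrom]]), envir = cds_cache)
    }
    cds_seq <- get(gid, envir = cds_cache)
    cpos <- cds_coordinate(cd, strand, records$pos[i])
    records$effect_class[i] <-
      codon_effect(cds_seq, cpos,
                   if (strand == "+") records$alt[i]
                   else complement_base(records$alt[i]))
  }
  records
}

# Spliced CDS sequence in translation order (reverse-complemented on -).
cds_sequence <- function(cds, strand, chrom_seq) {
  parts <- substring(as.character(chrom_seq), cds$start, cds$end)
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# 1-based position within the spliced CDS, in translation order.
cds_coordinate <- function(cds, strand, pos) {
  w <- cds$end - cds$start + 1L
  seg <- which(pos >= cds$start & pos <= cds$end)
  if (strand == "+") {
    sum(w[seq_len(seg - 1L)]) + (pos - cds$start[seg] + 1L)
  } else {
    n <- nrow(cds)
    after <- if (seg < n) sum(w[(seg + 1L):n]) else 0L
    after + (cds$end[seg] - pos + 1L)
  }
}

# Consequence of substituting `alt_base` (already on the coding strand) at
# CDS position `cpos`.
codon_effect <- function(cds_seq, cpos, alt_base) {
  ci <- (cpos - 1L) %/% 3L
  codon <- substr(cds_seq, 3L * ci + 1L, 3L * ci + 3L)
  off <- (cpos - 1L) %% 3L + 1L
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_base
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[alt_codon])
  if (is.na(aa_ref) || is.na(aa_alt)) return("other")
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_ref == "*" || aa_alt == "*") return("other")
  "missense"
}

#' Summarize annotation classes per line and level
#'
#' Counts genic/intergenic and exon/intron SNPs and reports missense and
#' synonymous fractions of exonic SNPs as percentages to two decimals, the
#' form such annotation tables are printed in. With no exonic SNPs the
#' percentages are `NA` (undefined), never 0.
#'
#' @param records Classified variant-record data.frame.
#' @return data.frame with one row per (line, level): counts `n_total`,
#'   `n_genic`, `n_intergenic`, `n_exon`, `n_intron`, `n_missense`,
#'   `n_synonymous`, `n_other_exonic` and percentages `pct_missense`,
#'   `pct_synonymous` (of exonic SNPs).
#' @export
summarize_annotations <- function(records) {
  grp <- unique(records[c("line", "level")])
  rows <- lapply(seq_len(nrow(grp)), function(k) {
    r <- records[records$line == grp$line[k] & records$level == grp$level[k], ]
    n_exon <- sum(r$region_class == "exon")
    n_mis <- sum(r$effect_class == "missense")
    n_syn <- sum(r$effect_class == "synonymous")
    data.frame(
      line = grp$line[k], level = grp$level[k],
      n_total = nrow(r),
      n_genic = sum(r$region_class != "intergenic"),
      n_intergenic = sum(r$region_class == "intergenic"),
      n_exon = n_exon,
      n_intron = sum(r$region_class == "intron"),
      n_missense = n_mis,
      n_synonymous = n_syn,
      n_other_exonic = n_exon - n_mis - n_syn,
      pct_missense = pct2(n_mis, n_exon),
      pct_synonymous = pct2(n_syn, n_exon),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
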