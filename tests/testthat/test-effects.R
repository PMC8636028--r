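# Classification against hand-built codons: the toy gene's CDS starts at
# tx_start + 30 on the + strand, so codon bases sit at known offsets.
test_that("codon substitutions classify as synonymous/missense/other", {
  tg <- toy_gene(strand = "+")
  cds_start <- 231L
  chrom_seq <- as.character(tg$genome[["chrA01"]])
  # force the first codon to CTT (Leu), the second to ATG (Met)
  substr(chrom_seq, cds_start, cds_start + 5L) <- "CTTATG"
  genome <- Biostrings::DNAStringSet(chrom_seq); names(genome) <- "chrA01"
  r <- make_records("chrA01",
                    c(cds_start + 2L,  # CTT -> CTC (Leu->Leu)
                      cds_start + 5L), # ATG -> ATA (Met->Ile)
                    ref = c("T", "G"), alt = c("C", "A"))
  out <- classify_effects(r, tg$genes, genome)
  expect_equal(out$region_class, c("exon", "exon"))
  expect_equal(out$effect_class, c("synonymous", "missense"))
  expect_equal(out$gene_id, c("g1", "g1"))
})

test_that("stop-involving changes are 'other', UTR and intergenic fall through", {
  tg <- toy_gene(strand = "+")
  cds_start <- 231L
  chrom_seq <- as.character(tg$genome[["chrA01"]])
  substr(chrom_seq, cds_start, cds_start + 2L) <- "TAC"  # Tyr
  genome <- Biostrings::DNAStringSet(chrom_seq); names(genome) <- "chrA01"
  r <- make_records("chrA01",
                    c(cds_start + 2L,  # TAC -> TAA: stop gained -> other
                      210L,            # exonic but upstream of CDS: UTR
                      50L),            # intergenic
                    ref = c("C", substr(chrom_seq, 210L, 210L),
                            substr(chrom_seq, 50L, 50L)),
                    alt = c("A", "A", "A"))
  r$alt[r$ref == "A"] <- "G"
  out <- classify_effects(r, tg$genes, genome)
  expect_equal(out$effect_class[1], "other")
  expect_equal(out$region_class[2], "exon")
  expect_equal(out$effect_class[2], "other")
  expect_equal(out$region_class[3], "intergenic")
  expect_equal(out$effect_class[3], "not_applicable")
})

test_that("intronic SNPs get region intron and no effect", {
  cfg <- tiny_config()
  ref <- generate_reference(cfg)
  g <- ref$genes$genes[1, ]
  ex <- ref$genes$exons[ref$genes$exons$gene_id == g$gene_id, ]
  intron_pos <- ex$end[1] + 5L  # inside the 100 bp intron
  base <- substring(as.character(ref$genome[[g$chrom]]), intron_pos, intron_pos)
  r <- make_records(g$chrom, intron_pos, ref = base,
                    alt = setdiff(c("A", "C", "G", "T"), base)[1])
  out <- classify_effects(r, ref$genes, ref$genome)
  expect_equal(out$region_class, "intron")
  expect_equal(out$effect_class, "not_applicable")
  expect_equal(out$gene_id, g$gene_id)
})

test_that("a REF/genome disagreement keeps the region but drops the effect", {
  tg <- toy_gene()
  pos <- 300L
  base <- substring(as.character(tg$genome[["chrA01"]]), pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), base)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(base, wrong))[1]
  r <- make_records("chrA01", pos, ref = wrong, alt = alt)
  expect_warning(out <- classify_effects(r, tg$genes, tg$genome),
                 "disagrees")
  expect_equal(out$region_class, "exon")
  expect_equal(out$effect_class, "not_applicable")
})

test_that("a chromosome absent from the genome is an input error", {
  tg <- toy_gene()
  r <- make_records("chrZ99", 100L)
  expect_error(classify_effects(r, tg$genes, tg$genome), "absent")
})

test_that("classification equals full-CDS retranslation on random SNPs, both strands", {
  for (strand in c("+", "-")) {
    tg <- toy_gene(strand = strand, seed = if (strand == "+") 3L else 4L)
    set.seed(17L)
    pos <- sample(150:900, 100L)
    chrom_seq <- as.character(tg$genome[["chrA01"]])
    refb <- substring(chrom_seq, pos, pos)
    altb <- vapply(refb, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
    r <- make_records("chrA01", pos, ref = refb, alt = altb)
    out <- classify_effects(r, tg$genes, tg$genome)
    expected <- mapply(retranslate_effect, pos, altb,
                       MoreArgs = list(genome = tg$genome, genes = tg$genes,
                                       chrom = "chrA01"))
    # the oracle does not distinguish exon-intron region, only effects
    expect_equal(out$effect_class[out$region_class == "exon"],
                 unname(expected[out$region_class == "exon"]),
                 label = paste("strand", strand))
  }
})

test_that("annotation summaries count and percentage correctly", {
  r <- rbind(
    make_records("chrA01", 1:10),
    make_records("chrA01", 11:14, level = "RNA"))
  r$region_class <- c(rep("exon", 5), rep("intron", 3), rep("intergenic", 2),
                      rep("intergenic", 4))
  r$effect_class <- c("missense", "missense", "synonymous", "other", "other",
                      rep("not_applicable", 9))
  s <- summarize_annotations(r)
  dna <- s[s$level == "DNA", ]
  expect_equal(dna$n_total, 10L)
  expect_equal(dna$n_genic, 8L)
  expect_equal(dna$n_intergenic, 2L)
  expect_equal(dna$n_exon, 5L)
  expect_equal(dna$n_intron, 3L)
  expect_equal(dna$pct_missense, 40.00)
  expect_equal(dna$pct_synonymous, 20.00)
  # genic + intergenic = total; exon + intron = genic
  expect_equal(dna$n_genic + dna$n_intergenic, dna$n_total)
  expect_equal(dna$n_exon + dna$n_intron, dna$n_genic)
  # all-intergenic level: undefined percentages, not zero
  rna <- s[s$level == "RNA", ]
  expect_true(is.na(rna$pct_missense))
  expect_true(is.na(rna$pct_synonymous))
})
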