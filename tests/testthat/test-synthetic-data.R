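test_that("reference layout matches the configured counts and pairing", {
  cfg <- tiny_config(n_chrom_A = 2L, n_chrom_C = 2L, n_genes_per_chrom = 10L)
  ref <- generate_reference(cfg)
  expect_equal(names(ref$genome),
               c("chrA01", "chrA02", "chrC01", "chrC02"))
  expect_equal(nrow(ref$genes$genes), 40L)
  expect_equal(nrow(ref$pairs), 20L)
  # non-overlapping genes per chromosome
  g <- ref$genes$genes
  for (chrom in unique(g$chrom)) {
    d <- g[g$chrom == chrom, ]
    d <- d[order(d$tx_start), ]
    expect_true(all(d$tx_start[-1] > d$tx_end[-nrow(d)]))
  }
  # CDS length divisible by 3 is enforced by the container; spot-check one
  cds1 <- ref$genes$cds[ref$genes$cds$gene_id == g$gene_id[1], ]
  expect_equal(sum(cds1$end - cds1$start + 1L) %% 3L, 0L)
})

test_that("degenerate configs give empty gene sets, not errors", {
  cfg <- tiny_config(n_genes_per_chrom = 0L)
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$genes$genes), 0L)
  expect_equal(nrow(ref$pairs), 0L)
})

test_that("impossible gene layout is a configuration error", {
  expect_error(generate_reference(
    tiny_config(chrom_length = 5000L, n_genes_per_chrom = 4L,
                gene_length = 2000L)),
    "configuration error")
})

test_that("the generator is byte-deterministic in its seed", {
  cfg <- tiny_config(seed = 99L)
  d1 <- file.path(tempdir(), "sim_det1")
  d2 <- file.path(tempdir(), "sim_det2")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero densities produce empty variant sets", {
  cfg <- tiny_config(dna_snp_density_A = 0, dna_snp_density_C = 0,
                     novel_rna_rate = 0)
  ref <- generate_reference(cfg)
  var <- simulate_variants(cfg, ref)
  for (ln in names(var$dna)) {
    expect_equal(nrow(var$dna[[ln]]), 0L)
    expect_equal(nrow(var$rna[[ln]]), 0L)
  }
})

test_that("forced transmission gives ratio 1 for every A-gene with SNPs", {
  cfg <- tiny_config(transmit_prob_A = 1, transmit_prob_C = 1,
                     het_fraction = 0, novel_rna_rate = 0)
  ref <- generate_reference(cfg)
  var <- simulate_variants(cfg, ref)
  rna_keys <- with(var$rna$parent, snp_key(chrom, pos, ref, alt))
  dna <- var$dna$parent
  dna_keys <- with(dna[dna$genotype == "hom_alt", ],
                   snp_key(chrom, pos, ref, alt))
  expect_true(all(dna_keys %in% rna_keys))
  tt <- var$gene_truth
  withsnp <- tt[tt$line == "parent" & tt$n_source >= 1, ]
  expect_true(all(withsnp$ratio == 1))
})

test_that("empirical transmitted fraction sits in the 99% binomial band", {
  # >= 10,000 homozygous A-subgenome DNA SNPs, transmit_prob_A = 0.55
  cfg <- sim_config(n_chrom_A = 1L, n_chrom_C = 1L, chrom_length = 500000L,
                    n_genes_per_chrom = 0L, dna_snp_density_A = 25,
                    dna_snp_density_C = 1, het_fraction = 0,
                    novel_rna_rate = 0, transmit_prob_A = 0.55, seed = 11L)
  ref <- generate_reference(cfg)
  var <- simulate_variants(cfg, ref)
  dna <- var$dna$parent
  a_hom <- dna[dna$genotype == "hom_alt" & startsWith(dna$chrom, "chrA"), ]
  expect_gt(nrow(a_hom), 10000L)
  rna_keys <- with(var$rna$parent, snp_key(chrom, pos, ref, alt))
  n_trans <- sum(with(a_hom, snp_key(chrom, pos, ref, alt)) %in% rna_keys)
  band <- stats::qbinom(c(0.005, 0.995), nrow(a_hom), 0.55)
  expect_gte(n_trans, band[1])
  expect_lte(n_trans, band[2])
})

test_that("every RNA SNP is transmitted or novel, never a third thing", {
  cfg <- tiny_config()
  ref <- generate_reference(cfg)
  var <- simulate_variants(cfg, ref)
  expect_true(all(var$snp_truth$origin %in% c("transmitted", "novel")))
  for (ln in c("parent", "offspring")) {
    rna <- var$rna[[ln]]
    keys <- with(rna, snp_key(chrom, pos, ref, alt))
    truth <- var$snp_truth[var$snp_truth$line == ln, ]
    expect_setequal(keys, truth$key)
    dna_keys <- with(var$dna[[ln]], snp_key(chrom, pos, ref, alt))
    expect_true(all(truth$key[truth$origin == "transmitted"] %in% dna_keys))
    expect_false(any(truth$key[truth$origin == "novel"] %in% dna_keys))
  }
})

test_that("realized DNA density is within 3 SE of the configured density", {
  cfg <- sim_config(n_chrom_A = 1L, n_chrom_C = 1L, chrom_length = 400000L,
                    n_genes_per_chrom = 0L, dna_snp_density_A = 2,
                    dna_snp_density_C = 1, seed = 5L)
  ref <- generate_reference(cfg)
  var <- simulate_variants(cfg, ref)
  dna <- var$dna$parent
  for (sg in c("A", "C")) {
    dens_cfg <- if (sg == "A") 2 else 1
    L <- cfg$chrom_length
    n <- sum(startsWith(dna$chrom, paste0("chr", sg)))
    p <- dens_cfg / 1000
    se <- sqrt(L * p * (1 - p))
    expect_lt(abs(n - L * p), 3 * se)
  }
})

test_that("expression follows the planted linear model when noise is off", {
  cfg <- tiny_config(tpm_noise_sd = 0, tpm_slope = 100, tpm_count_slope = 0,
                     tpm_baseline = 7)
  ref <- generate_reference(cfg)
  var <- simulate_variants(cfg, ref)
  tpm <- simulate_expression(cfg, var$gene_truth)
  tt <- var$gene_truth[var$gene_truth$line == "parent", ]
  expected <- 7 + 100 * ifelse(is.na(tt$ratio), 0, tt$ratio)
  got <- tpm$parent[match(tt$gene_id, tpm$parent$gene_id), ]
  for (col in grep("^tissue", names(got), value = TRUE)) {
    expect_equal(got[[col]], expected)
  }
  # zero slope collapses everything to the baseline
  cfg0 <- tiny_config(tpm_noise_sd = 0, tpm_slope = 0, tpm_count_slope = 0,
                      tpm_baseline = 3)
  tpm0 <- simulate_expression(cfg0, var$gene_truth)
  expect_true(all(tpm0$parent$tissue1 == 3))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(transmit_prob_A = 1.2), "probability")
  expect_error(sim_config(dna_snp_density_A = -1), ">= 0")
  expect_error(sim_config(chrom_length = 0), "> 0")
  expect_error(sim_config(exons_per_gene = 0), "exons_per_gene")
})
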