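test_that("chromosome and scaffold names map to subgenomes", {
  expect_equal(assign_subgenome(c("chrA03", "chrC02", "Unn_random",
                                  "scaffold A10_random", "A07_random",
                                  "chrA01", "mito")),
               c("An", "Cn", "other", "An", "An", "An", "other"))
})

test_that("densities per chromosome and subgenome are SNPs per kb", {
  r <- make_records("chrA01", 1:10)
  d <- snp_density(r, c(chrA01 = 5000))
  expect_equal(d$per_chrom$density, 2.0)
  expect_equal(d$per_subgenome$density[d$per_subgenome$subgenome == "An"], 2.0)
  # zero SNPs is density 0, not an error
  d0 <- snp_density(make_records(character(), integer()),
                    c(chrA01 = 5000, chrC01 = 2000))
  expect_equal(d0$per_chrom$n_snps, c(0L, 0L))
  expect_equal(d0$per_chrom$density, c(0, 0))
  # count-based entry point gives the same numbers
  dc <- snp_density(counts = c(chrA01 = 10), chrom_lengths = c(chrA01 = 5000))
  expect_equal(dc$per_chrom$density, 2.0)
  expect_error(snp_density(r, c(chrC01 = 1000)), "chrA01")
})

test_that("window track counts equal a direct per-window recount", {
  set.seed(13L)
  lens <- c(chrA01 = 3001, chrC01 = 1500)
  r <- make_records(sample(names(lens), 400L, TRUE),
                    sample.int(1500L, 400L, TRUE))
  d <- snp_density(r, lens, window = 100L)
  for (chrom in names(lens)) {
    tr <- d$track[d$track$chrom == chrom, ]
    expect_equal(nrow(tr), ceiling(lens[[chrom]] / 100))
    pos <- r$pos[r$chrom == chrom]
    brute <- vapply(seq_len(nrow(tr)), function(i)
      sum(pos >= tr$start[i] & pos <= tr$end[i]), 0L)
    expect_equal(tr$count, brute)
  }
  # per-chromosome counts add up to the total
  expect_equal(sum(d$per_chrom$n_snps), nrow(r))
})

test_that("partition percentages are of the full total and sum to 100", {
  p <- partition_counts(c(rep("An", 3), rep("Cn", 1)))
  expect_equal(p$pct, c(75, 25, 0))
  p1 <- partition_counts(rep("An", 4))
  expect_equal(p1$pct, c(100, 0, 0))
  set.seed(3L)
  labels <- sample(c("An", "Cn", "other"), 997L, TRUE)
  pr <- partition_counts(labels)
  expect_equal(sum(pr$n), 997)
  expect_lt(abs(sum(pr$pct) - 100), 0.03)  # rounding slack only
})

test_that("the Welch test matches a closed-form hand computation", {
  pg <- data.frame(gene_id = c(paste0("a", 1:3), paste0("c", 1:3)),
                   ratio = c(1, 2, 3, 2, 4, 6) / 10,
                   stringsAsFactors = FALSE)
  pairs <- data.frame(gene_An = paste0("a", 1:3), gene_Cn = paste0("c", 1:3))
  res <- syntenic_ratio_test(pg, pairs, mode = "welch")
  oracle <- welch_oracle(c(1, 2, 3) / 10, c(2, 4, 6) / 10)
  expect_equal(res$t, oracle$t)
  expect_equal(res$df, oracle$df)
  expect_equal(res$p, oracle$p)
  expect_equal(res$n_pairs, 3L)
})

test_that("degenerate ratio vectors take the documented paths", {
  pg <- data.frame(gene_id = c(paste0("a", 1:10), paste0("c", 1:10)),
                   ratio = c(rep(0.4, 10), rep(0.4, 10)))
  pairs <- data.frame(gene_An = paste0("a", 1:10), gene_Cn = paste0("c", 1:10))
  same <- syntenic_ratio_test(pg, pairs)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  pg$ratio <- c(rep(1, 10), rep(0, 10))
  expect_warning(sep <- syntenic_ratio_test(pg, pairs), "machine precision")
  expect_equal(sep$p, 0)
  expect_gt(sep$t, 0)
  # undefined sides are dropped; too few pairs is an error
  pg$ratio[1:9] <- NA
  expect_error(suppressMessages(syntenic_ratio_test(pg, pairs)),
               "statistics error")
})

test_that("paired mode tests pair differences", {
  set.seed(21L)
  n <- 50L
  base <- runif(n, 0.2, 0.8)
  shift <- rnorm(n, 0.05, 0.02)
  pg <- data.frame(gene_id = c(paste0("a", 1:n), paste0("c", 1:n)),
                   ratio = c(base + shift, base))
  pairs <- data.frame(gene_An = paste0("a", 1:n), gene_Cn = paste0("c", 1:n))
  res <- syntenic_ratio_test(pg, pairs, mode = "paired")
  ht <- t.test(shift)  # one-sample test on differences is the paired test
  expect_equal(res$t, unname(ht$statistic))
  expect_equal(res$p, ht$p.value)
  # a constant non-zero difference is the degenerate path, not an error
  pg$ratio <- c(base + 0.05, base)
  expect_warning(deg <- syntenic_ratio_test(pg, pairs, mode = "paired"),
                 "machine precision")
  expect_equal(deg$p, 0)
})

test_that("window scan counts exceeding windows strictly and tiles fully", {
  lens <- c(chrA01 = 1000)
  r11 <- make_records("chrA01", 1:11)
  expect_equal(window_scan(r11, lens, 150L, 10L)$n_windows_exceeding, 1L)
  r10 <- make_records("chrA01", 1:10)
  expect_equal(window_scan(r10, lens, 150L, 10L)$n_windows_exceeding, 0L)
  # totals: sum of ceil(length / window) over chromosomes
  lens2 <- c(chrA01 = 1000, chrC01 = 301, Unn_random = 149)
  ws <- window_scan(make_records(character(), integer()), lens2, 150L, 10L)
  expect_equal(ws$n_windows_total,
               sum(ceiling(lens2 / 150)))
  # random recount oracle
  set.seed(19L)
  r <- make_records("chrA01", sample.int(1000L, 200L, TRUE))
  ws2 <- window_scan(r, lens, 7L, 2L)
  brute <- 0L
  for (s in seq(1L, 1000L, by = 7L))
    brute <- brute + (sum(r$pos >= s & r$pos <= s + 6L) > 2L)
  expect_equal(ws2$n_windows_exceeding, brute)
})

test_that("bedGraph tracks are written 0-based half-open", {
  tr <- data.frame(chrom = "chrA01", start = c(1L, 151L), end = c(150L, 300L),
                   count = c(3L, 0L))
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  lines <- readLines(path)
  expect_equal(lines[2], "chrA01\t0\t150\t3")
  expect_equal(lines[3], "chrA01\t150\t300\t0")
})
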