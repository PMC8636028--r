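#' Generate a toy reference genome, gene annotation, and syntenic pairs
#'
#' Lays out `n_genes_per_chrom` non-overlapping genes per chromosome on random
#' sequence. Chromosomes are named `chrA01..` / `chrC01..` so the two
#' subgenomes of an allotetraploid are distinguishable by name. The i-th gene
#' on the i-th A chromosome is paired with the i-th gene on the i-th C
#' chromosome (up to the smaller count), mimicking a syntenic homoeolog table.
#'
#' @param config A [sim_config()].
#' @return list with `genome` (DNAStringSet), `genes` ([gene_models()]) and
#'   `pairs` (data.frame `gene_An`, `gene_Cn`).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- c(sprintf("chrA%02d", seq_len(config$n_chrom_A)),
              sprintf("chrC%02d", seq_len(config$n_chrom_C)))
  L <- config$chrom_length
  genome <- Biostrings::DNAStringSet(vapply(
    chroms,
    function(.) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = ""),
    ""))
  names(genome) <- chroms

  n_g <- config$n_genes_per_chrom
  glen <- config$gene_length
  if (n_g > 0) {
    slot <- L %/% n_g
    if (glen + 2L > slot)
      stop("configuration error: gene_length ", glen,
           " does not fit ", n_g, " genes on a ", L, " bp chromosome")
  }
  genes_l <- list(); exons_l <- list(); cds_l <- list()
  for (chrom in chroms) {
    for (i in seq_len(n_g)) {
      slot <- L %/% n_g
      offset <- sample.int(slot - glen - 1L, 1L)
      tx_start <- (i - 1L) * slot + offset
      gid <- sprintf("%s.g%03d", chrom, i)
      strand <- sample(c("+", "-"), 1L)
      st <- gene_structure(tx_start, glen, config$exons_per_gene)
      genes_l[[gid]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        tx_start = tx_start, tx_end = tx_start + glen - 1L,
        stringsAsFactors = FALSE)
      exons_l[[gid]] <- cbind(gene_id = gid, st$exons)
      cds_l[[gid]] <- cbind(gene_id = gid, st$cds)
    }
  }
  if (length(genes_l)) {
    genes <- gene_models(do.call(rbind, c(genes_l, make.row.names = FALSE)),
                         do.call(rbind, c(exons_l, make.row.names = FALSE)),
                         do.call(rbind, c(cds_l, make.row.names = FALSE)))
  } else {
    empty <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), tx_start = integer(),
                        tx_end = integer(), stringsAsFactors = FALSE)
    iv <- data.frame(gene_id = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
    genes <- gene_models(empty, iv, iv)
  }

  g <- genes$genes
  a_chr <- chroms[startsWith(chroms, "chrA")]
  c_chr <- chroms[startsWith(chroms, "chrC")]
  pairs_l <- list()
  for (k in seq_len(min(length(a_chr), length(c_chr)))) {
    ga <- g$gene_id[g$chrom == a_chr[k]]
    gc <- g$gene_id[g$chrom == c_chr[k]]
    m <- min(length(ga), length(gc))
    if (m > 0)
      pairs_l[[k]] <- data.frame(gene_An = ga[seq_len(m)],
                                 gene_Cn = gc[seq_len(m)],
                                 stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs_l)) do.call(rbind, pairs_l) else
    data.frame(gene_An = character(), gene_Cn = character(),
               stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(genome = genome, genes = genes, pairs = pairs)
}

# Exon/CDS layout for one gene: k exons separated by 100 bp introns,
# 30 bp UTRs at both transcript ends, CDS trimmed so its length is a
# multiple of 3.
gene_structure <- function(tx_start, gene_length, k) {
  intron <- if (k > 1) 100L else 0L
  exon_total <- gene_length - (k - 1L) * intron
  if (exon_total < k * 70L + 60L)
    stop("configuration error: gene_length too small for ", k, " exons")
  w <- rep(exon_total %/% k, k)
  w[k] <- w[k] + exon_total %% k
  starts <- tx_start + cumsum(c(0L, head(w, -1L) + intron))
  exons <- data.frame(start = starts, end = starts + w - 1L)
  # CDS: drop 30 bp from each transcript end, then trim the 3' end to a
  # multiple of 3 (strand handled downstream; trimming both ends keeps the
  # layout strand-symmetric)
  cds_len0 <- exon_total - 60L
  cds_len <- cds_len0 - cds_len0 %% 3L
  cds <- transcript_window_to_genomic(exons, 31L, 30L + cds_len)
  list(exons = exons, cds = cds)
}

# Map a [from, to] window in exon-concatenated (5'->3' on + strand)
# coordinates to genomic intervals.
transcript_window_to_genomic <- function(exons, from, to) {
  w <- exons$end - exons$start + 1L
  offs <- cumsum(c(0L, head(w, -1L)))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(from, offs[i] + 1L)
    hi <- min(to, offs[i] + w[i])
    if (lo <= hi)
      out[[length(out) + 1L]] <- data.frame(
        start = exons$start[i] + (lo - offs[i] - 1L),
        end = exons$start[i] + (hi - offs[i] - 1L))
  }
  do.call(rbind, out)
}

#' Simulate DNA- and RNA-level SNP call sets for a parent and offspring line
#'
#' DNA SNP positions are drawn uniformly (without replacement) per chromosome
#' at the subgenome's density; each is homozygous-alt with probability
#' `1 - het_fraction`, else heterozygous. Each homozygous DNA SNP reappears in
#' the same line's RNA calls with its subgenome's transmission probability;
#' RNA-only ("novel") homozygous SNPs are added at `novel_rna_rate`. The
#' offspring's DNA set inherits each parental homozygous SNP with
#' `inherit_prob` and adds private SNPs of its own, so parent-to-offspring
#' transmission chains have planted structure too.
#'
#' @param config A [sim_config()].
#' @param reference Output of [generate_reference()].
#' @return list with per-line record tables `dna` and `rna` (named lists of
#'   variant-record data.frames), `gene_truth` (planted per-gene counts and
#'   ratios per line) and `snp_truth` (per RNA SNP: transmitted or novel).
#' @export
simulate_variants <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genome <- reference$genome
  chroms <- names(genome)
  L <- config$chrom_length
  lines <- c("parent", "offspring")

  draw_sites <- function(chrom, n, exclude = integer()) {
    if (n <= 0)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE))
    avail <- setdiff(seq_len(L), exclude)
    pos <- sort(sample(avail, min(n, length(avail))))
    ref <- substring(as.character(genome[[chrom]]), pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  "", USE.NAMES = FALSE)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }

  dna <- list(); rna <- list()
  for (ln in lines) dna[[ln]] <- rna[[ln]] <- list()

  for (chrom in chroms) {
    dens <- if (startsWith(chrom, "chrA")) config$dna_snp_density_A else
      config$dna_snp_density_C
    tp <- if (startsWith(chrom, "chrA")) config$transmit_prob_A else
      config$transmit_prob_C

    n_parent <- stats::rbinom(1L, L, min(1, dens / 1000))
    parent_sites <- draw_sites(chrom, n_parent)
    parent_sites$genotype <- ifelse(
      stats::runif(nrow(parent_sites)) < config$het_fraction, "het", "hom_alt")

    hom_parent <- parent_sites[parent_sites$genotype == "hom_alt", ]
    inherit <- hom_parent[stats::runif(nrow(hom_parent)) < config$inherit_prob, ]
    n_private <- stats::rbinom(1L, L, min(1, 0.5 * dens / 1000))
    private <- draw_sites(chrom, n_private, exclude = parent_sites$pos)
    private$genotype <- ifelse(
      stats::runif(nrow(private)) < config$het_fraction, "het", "hom_alt")
    inherit$genotype <- rep("hom_alt", nrow(inherit))
    offspring_sites <- rbind(inherit, private)
    offspring_sites <- offspring_sites[order(offspring_sites$pos), ]

    line_sites <- list(parent = parent_sites, offspring = offspring_sites)
    for (ln in lines) {
      s <- line_sites[[ln]]
      dna[[ln]][[chrom]] <- s
      hom <- s[s$genotype == "hom_alt", ]
      transmitted <- hom[stats::runif(nrow(hom)) < tp, ]
      n_novel <- stats::rbinom(1L, L, min(1, config$novel_rna_rate / 1000))
      novel <- draw_sites(chrom, n_novel, exclude = s$pos)
      r <- rbind(
        if (nrow(transmitted))
          cbind(transmitted[c("chrom", "pos", "ref", "alt")],
                genotype = "hom_alt", origin = "transmitted"),
        if (nrow(novel))
          cbind(novel[c("chrom", "pos", "ref", "alt")],
                genotype = "hom_alt", origin = "novel"))
      if (is.null(r))
        r <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        genotype = character(), origin = character(),
                        stringsAsFactors = FALSE)
      rna[[ln]][[chrom]] <- r[order(r$pos), ]
    }
  }

  finish <- function(per_chrom, ln, level, keep_origin = FALSE) {
    df <- do.call(rbind, c(per_chrom, make.row.names = FALSE))
    if (is.null(df) || nrow(df) == 0L) {
      df <- empty_records()
      if (keep_origin) df$origin <- character()
      return(df)
    }
    origin <- if (keep_origin) df$origin else NULL
    out <- data.frame(
      chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
      qual = 100, mq = 60, qd = 25,
      genotype = df$genotype, level = level, line = ln,
      filter_status = "pass", region_class = NA_character_,
      effect_class = NA_character_, gene_id = NA_character_,
      stringsAsFactors = FALSE)
    if (config$fail_fraction > 0 && level == "DNA") {
      fail <- stats::runif(nrow(out)) < config$fail_fraction
      out$qual[fail] <- 10
    }
    if (!is.null(origin)) out$origin <- origin
    out
  }

  dna_rec <- list(); rna_rec <- list()
  for (ln in lines) {
    dna_rec[[ln]] <- finish(dna[[ln]], ln, "DNA")
    rna_rec[[ln]] <- finish(rna[[ln]], ln, "RNA", keep_origin = TRUE)
  }

  gene_truth <- planted_gene_truth(config, reference$genes, dna_rec, rna_rec)
  snp_truth <- do.call(rbind, c(lapply(lines, function(ln) {
    r <- rna_rec[[ln]]
    if (nrow(r) == 0L)
      return(data.frame(line = character(), key = character(),
                        origin = character(), stringsAsFactors = FALSE))
    data.frame(line = ln, key = snp_key(r$chrom, r$pos, r$ref, r$alt),
               origin = r$origin, stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  for (ln in lines) rna_rec[[ln]]$origin <- NULL

  list(dna = dna_rec, rna = rna_rec,
       gene_truth = gene_truth, snp_truth = snp_truth)
}

# Planted per-gene counts: source = homozygous DNA SNPs in the gene span,
# transmitted = those present in the line's RNA set, novel = RNA-only SNPs in
# the span.
planted_gene_truth <- function(config, genes, dna_rec, rna_rec) {
  g <- genes$genes
  out <- list()
  for (ln in names(dna_rec)) {
    d <- dna_rec[[ln]]; r <- rna_rec[[ln]]
    d_hom <- d[d$genotype == "hom_alt", ]
    d_keys <- snp_key(d_hom$chrom, d_hom$pos, d_hom$ref, d_hom$alt)
    r_keys <- snp_key(r$chrom, r$pos, r$ref, r$alt)
    novel <- r[r$origin == "novel", ]
    for (i in seq_len(nrow(g))) {
      in_gene <- d_hom$chrom == g$chrom[i] &
        d_hom$pos >= g$tx_start[i] & d_hom$pos <= g$tx_end[i]
      n_source <- sum(in_gene)
      n_trans <- sum(d_keys[in_gene] %in% r_keys)
      n_novel <- sum(novel$chrom == g$chrom[i] &
                       novel$pos >= g$tx_start[i] & novel$pos <= g$tx_end[i])
      out[[length(out) + 1L]] <- data.frame(
        line = ln, gene_id = g$gene_id[i], subgenome = g$subgenome[i],
        n_source = n_source, n_transmitted = n_trans,
        ratio = if (n_source > 0) n_trans / n_source else NA_real_,
        n_novel_rna = n_novel, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(line = character(), gene_id = character(),
                      subgenome = character(), n_source = integer(),
                      n_transmitted = integer(), ratio = numeric(),
                      n_novel_rna = integer(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate a per-line TPM expression table
#'
#' Per gene, the expected TPM is
#' `max(0, tpm_baseline + tpm_slope * ratio + tpm_count_slope * n_source +
#' gene-level Gaussian noise)`; each tissue column adds independent noise and
#' is clamped at 0. Genes with no DNA SNPs (undefined ratio) contribute
#' `ratio = 0` to the mean.
#'
#' @param config A [sim_config()].
#' @param gene_truth `gene_truth` table from [simulate_variants()].
#' @return Named list (one element per line) of data.frames with `gene_id`
#'   plus `n_tissues` TPM columns.
#' @export
simulate_expression <- function(config, gene_truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  out <- list()
  for (ln in unique(gene_truth$line)) {
    tt <- gene_truth[gene_truth$line == ln, ]
    ratio <- ifelse(is.na(tt$ratio), 0, tt$ratio)
    mu <- pmax(0, config$tpm_baseline + config$tpm_slope * ratio +
                 config$tpm_count_slope * tt$n_source +
                 stats::rnorm(nrow(tt), 0, config$tpm_noise_sd))
    mat <- vapply(seq_len(config$n_tissues), function(.)
      pmax(0, mu + stats::rnorm(nrow(tt), 0, config$tpm_noise_sd)),
      numeric(nrow(tt)))
    if (nrow(tt) == 1L) mat <- matrix(mat, nrow = 1L)
    df <- data.frame(gene_id = tt$gene_id, mat, stringsAsFactors = FALSE)
    names(df) <- c("gene_id", sprintf("tissue%d", seq_len(config$n_tissues)))
    out[[ln]] <- df
  }
  out
}

#' Run the full simulation and write every artifact to disk
#'
#' Writes `genome.fa`, `genes.gff3`, `synteny_pairs.tsv`, per line/level VCFs
#' (`dna_parent.vcf`, `rna_parent.vcf`, ...), per-line TPM tables
#' (`tpm_parent.tsv`, ...), and the planted truth tables
#' (`truth_genes.tsv`, `truth_snps.tsv`). Output is a pure function of the
#' config (including its seed): re-running reproduces identical bytes.
#'
#' @param config A [sim_config()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the simulation objects (`reference`, `variants`, `tpm`).
#' @export
simulate_dataset <- function(config, dir) {
  ref <- generate_reference(config)
  var <- simulate_variants(config, ref)
  tpm <- simulate_expression(config, var$gene_truth)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  write_gff3(ref$genes, file.path(dir, "genes.gff3"))
  write_tsv(ref$pairs, file.path(dir, "synteny_pairs.tsv"))
  for (ln in names(var$dna)) {
    write_vcf(var$dna[[ln]], file.path(dir, sprintf("dna_%s.vcf", ln)),
              sample = ln, contigs = ref$genome)
    write_vcf(var$rna[[ln]], file.path(dir, sprintf("rna_%s.vcf", ln)),
              sample = ln, contigs = ref$genome)
    write_tsv(tpm[[ln]], file.path(dir, sprintf("tpm_%s.tsv", ln)))
  }
  write_tsv(var$gene_truth, file.path(dir, "truth_genes.tsv"))
  write_tsv(var$snp_truth, file.path(dir, "truth_snps.tsv"))
  invisible(list(reference = ref, variants = var, tpm = tpm))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
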