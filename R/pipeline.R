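#' Run the full transmission analysis from one configuration
#'
#' Sequences every stage — simulate (or load) inputs, read and hard-filter
#' variants, classify effects, match homozygous SNPs across levels and lines,
#' per-gene transmission, subgenome statistics, window scan, syntenic tests,
#' TPM merge and binned regressions — and returns one machine-readable run
#' report. Re-running the same configuration reproduces the identical report.
#'
#' @param config Either a [sim_config()] (a synthetic dataset is generated
#'   under `out_dir/inputs`) or a named list of input paths with elements
#'   `dna_vcf` (named character vector, one per line), `rna_vcf` (idem),
#'   `gff3`, `fasta`, `pairs_tsv`, `tpm_tsv` (named per line), plus optional
#'   analysis settings below.
#' @param out_dir Output directory; created if needed. Tables and the JSON
#'   report are written beneath it.
#' @param denominator Passed to [per_gene_transmission()].
#' @param test_mode Passed to [syntenic_ratio_test()].
#' @param ratio_bin_width,count_bin_width Bin widths for the expression fits.
#'   The count default (1) suits the simulated scale of a few SNPs per gene;
#'   genome-scale runs with tens of SNPs per gene would pass 10 or 20.
#' @param scan_window,scan_threshold Passed to [window_scan()].
#' @return The run report (list), invisibly; also written as
#'   `report.json` under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         denominator = "hom",
                         test_mode = "welch",
                         ratio_bin_width = 0.1,
                         count_bin_width = 1,
                         scan_window = 150L,
                         scan_threshold = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (inherits(config, "sim_config")) {
    input_dir <- file.path(out_dir, "inputs")
    stage("simulate", simulate_dataset(config, input_dir))
    lines <- c("parent", "offspring")
    paths <- list(
      dna_vcf = structure(file.path(input_dir, sprintf("dna_%s.vcf", lines)),
                          names = lines),
      rna_vcf = structure(file.path(input_dir, sprintf("rna_%s.vcf", lines)),
                          names = lines),
      gff3 = file.path(input_dir, "genes.gff3"),
      fasta = file.path(input_dir, "genome.fa"),
      pairs_tsv = file.path(input_dir, "synteny_pairs.tsv"),
      tpm_tsv = structure(file.path(input_dir, sprintf("tpm_%s.tsv", lines)),
                          names = lines))
  } else {
    paths <- config
    need <- c("dna_vcf", "rna_vcf", "gff3", "fasta", "pairs_tsv", "tpm_tsv")
    if (!all(need %in% names(paths)))
      stop("config must provide: ", paste(need, collapse = ", "))
    lines <- names(paths$dna_vcf)
  }

  genome <- stage("load_reference",
                  Biostrings::readDNAStringSet(paths$fasta))
  names(genome) <- sub(" .*", "", names(genome))
  genes <- stage("load_annotation", read_gff3(paths$gff3))
  pairs <- stage("load_pairs",
                 utils::read.delim(paths$pairs_tsv,
                                   stringsAsFactors = FALSE))
  chrom_lengths <- structure(Biostrings::width(genome), names = names(genome))

  report <- list(lines = lines, stages = list())
  records <- list()
  for (ln in lines) {
    for (lv in c("DNA", "RNA")) {
      p <- if (lv == "DNA") paths$dna_vcf[[ln]] else paths$rna_vcf[[ln]]
      r <- stage(paste0("read_", ln, "_", lv),
                 suppressMessages(read_vcf(p, level = lv, line = ln)))
      r <- stage("hard_filter", hard_filter(r))
      r <- stage("classify", classify_effects(r, genes, genome))
      records[[paste(ln, lv, sep = "_")]] <- r
      report$stages[[paste0(ln, "_", lv)]] <- list(
        n_read = nrow(r), n_skipped = attr(r, "n_skipped"),
        n_pass = sum(r$filter_status == "pass"),
        n_fail_expression = sum(r$filter_status == "fail_expression"),
        n_fail_cluster = sum(r$filter_status == "fail_cluster"))
    }
  }
  all_records <- do.call(rbind, c(records, make.row.names = FALSE))
  report$annotation_summary <- summarize_annotations(all_records)

  # homozygous sets and transmissions
  hs <- lapply(records, function(r) hom_set(pass_records(r)))
  parent <- lines[1L]; offspring <- lines[2L]
  transmissions <- list()
  for (ln in lines) {
    d <- hs[[paste0(ln, "_DNA")]]; r <- hs[[paste0(ln, "_RNA")]]
    tr <- match_transmitted(d, r)
    nv <- novel_variants(d, r)
    pg <- per_gene_transmission(records[[paste0(ln, "_DNA")]], tr, nv, genes,
                                chain = "DNA->RNA", denominator = denominator)
    write_transmission_tsv(pg, file.path(out_dir,
                                         sprintf("transmission_%s.tsv", ln)))
    transmissions[[ln]] <- pg
    report$transmission[[ln]] <- list(
      n_dna_hom = length(d), n_rna_hom = length(r),
      n_transmitted = length(tr), n_novel = length(nv),
      partition = partition_counts(assign_subgenome(parse_snp_key(tr)$chrom)))
  }
  chain_keys <- chain_transmitted(hs[[paste0(parent, "_DNA")]],
                                  hs[[paste0(offspring, "_DNA")]],
                                  hs[[paste0(offspring, "_RNA")]])
  report$chain <- list(
    n_parent_to_offspring = length(
      match_transmitted(hs[[paste0(parent, "_DNA")]],
                        hs[[paste0(offspring, "_DNA")]])),
    n_chain = length(chain_keys),
    partition = partition_counts(assign_subgenome(parse_snp_key(chain_keys)$chrom)))

  # subgenome statistics
  dens <- snp_density(all_records[all_records$filter_status == "pass", ],
                      chrom_lengths)
  report$density <- dens[c("per_chrom", "per_subgenome")]
  scan <- window_scan(all_records[all_records$level == "RNA" &
                                    all_records$filter_status == "pass", ],
                      chrom_lengths, scan_window, scan_threshold)
  write_bedgraph(scan$track, file.path(out_dir, "rna_window_counts.bedgraph"))
  report$window_scan <- scan[c("n_windows_total", "n_windows_exceeding")]

  # statistics that are undefined on empty/degenerate data are recorded as
  # notes, not treated as pipeline failures (a zero-SNP run is still a run)
  try_stat <- function(expr) {
    tryCatch(suppressMessages(suppressWarnings(expr)),
             error = function(e) list(note = conditionMessage(e)))
  }
  report$syntenic_ratio_test <- lapply(transmissions, function(pg)
    try_stat(syntenic_ratio_test(pg, pairs, mode = test_mode)))

  # expression
  for (ln in lines) {
    tt <- stage("load_tpm", utils::read.delim(paths$tpm_tsv[[ln]],
                                              stringsAsFactors = FALSE))
    merged <- merge_tpm(tt)
    pg <- transmissions[[ln]]$per_gene
    tpm_of <- merged$tpm$mean_tpm[match(pg$gene_id, merged$tpm$gene_id)]
    fits <- list(
      ratio = try_stat(
        fit_binned_regression(pg$ratio, tpm_of, mode = "ratio",
                              bin_width = ratio_bin_width,
                              covariate = "transmission_ratio")),
      dna_count = try_stat(
        fit_binned_regression(pg$n_source, tpm_of, mode = "count",
                              bin_width = count_bin_width,
                              covariate = "dna_snp_count")))
    report$expression[[ln]] <- list(
      n_unexpressed = length(merged$unexpressed),
      syntenic_tpm_test = try_stat(
        compare_syntenic_expression(merged$tpm, pairs, mode = test_mode)),
      fits = lapply(fits, function(f)
        if (inherits(f, "binned_fit"))
          f[c("covariate", "bin_width", "slope", "intercept", "r_squared")]
        else f))
    report$expression[[ln]]$unexpressed <- merged$unexpressed
  }
  report$expression$shared_unexpressed <- shared_unexpressed(
    report$expression[[lines[1]]]$unexpressed,
    report$expression[[lines[2]]]$unexpressed)
  for (ln in lines) report$expression[[ln]]$unexpressed <- NULL

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, dataframe = "rows")
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}
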