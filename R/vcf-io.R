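#' Write variant records as a single-sample VCF v4.2
#'
#' @param records Variant-record data.frame (columns `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `mq`, `qd`, `genotype`; extra columns ignored).
#' @param path Output file.
#' @param sample Sample name for the genotype column.
#' @param contigs Optional DNAStringSet or named length vector used to emit
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample = "sample", contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=snptransmit")
  if (!is.null(contigs)) {
    lens <- if (methods::is(contigs, "DNAStringSet"))
      structure(Biostrings::width(contigs), names = names(contigs)) else contigs
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(lens), as.integer(lens)))
  }
  hdr <- c(hdr,
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  body <- if (nrow(records)) {
    ord <- order(records$chrom, records$pos)
    r <- records[ord, ]
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tMQ=%s;QD=%s\tGT\t%s",
            r$chrom, r$pos, r$ref, r$alt,
            format(r$qual, trim = TRUE), format(r$mq, trim = TRUE),
            format(r$qd, trim = TRUE), gt[r$genotype])
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a single-sample VCF into a variant-record table
#'
#' Non-SNP records (indels, symbolic alleles) are skipped and counted.
#' Multi-allelic SNP records are split into one record per alternate allele
#' with the genotype recomputed against that allele: homozygous-alt only when
#' both called alleles equal it, heterozygous when exactly one does,
#' homozygous-ref otherwise; missing calls stay missing.
#'
#' @param path VCF file (v4.x, exactly one sample column unless `sample`
#'   names one).
#' @param level `"DNA"` or `"RNA"`.
#' @param line Line (sample) identifier stored on each record.
#' @param sample Optional sample column to use when the file has several.
#' @return Variant-record data.frame; the number of skipped non-SNP records
#'   is attached as `attr(, "n_skipped")`.
#' @export
read_vcf <- function(path, level = c("DNA", "RNA"), line = "sample",
                     sample = NULL) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    out <- empty_records()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  gt_cols <- colnames(vcf@gt)[-1L]
  if (length(gt_cols) == 0L) stop("VCF has no sample column: ", path)
  if (is.null(sample)) {
    if (length(gt_cols) > 1L)
      stop("VCF has ", length(gt_cols),
           " samples; pick one with 'sample = '")
    sample <- gt_cols[1L]
  } else if (!sample %in% gt_cols) {
    stop("sample '", sample, "' not present in ", path)
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")[, sample]
  mq <- suppressWarnings(vcfR::extract.info(vcf, "MQ", as.numeric = TRUE))
  qd <- suppressWarnings(vcfR::extract.info(vcf, "QD", as.numeric = TRUE))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  bases <- c("A", "C", "G", "T")
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (!ref %in% bases) { n_skipped <- n_skipped + 1L; next }
    snp_alts <- which(alts %in% bases & alts != ref)
    if (length(snp_alts) == 0L) { n_skipped <- n_skipped + 1L; next }
    alleles <- strsplit(sub(":.*", "", gt_raw[i]), "[/|]")[[1L]]
    for (ai in snp_alts) {
      geno <- if (anyNA(alleles) || any(alleles == ".") ||
                  length(alleles) != 2L) "missing" else {
        n_alt <- sum(alleles == as.character(ai))
        c("hom_ref", "het", "hom_alt")[n_alt + 1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alts[ai],
        qual = qual[i], mq = mq[i], qd = qd[i],
        genotype = geno, level = level, line = line,
        filter_status = "pass", region_class = NA_character_,
        effect_class = NA_character_, gene_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else empty_records()
  if (n_skipped > 0L)
    message(n_skipped, " non-SNP record(s) skipped in ", basename(path))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a set of SNP keys as a site-list VCF
#'
#' @param keys Character keys from [snp_key()].
#' @param path Output file.
#' @param sample Sample name.
#' @return `path`, invisibly.
#' @export
write_site_vcf <- function(keys, path, sample = "sites") {
  df <- parse_snp_key(keys)
  df$qual <- "."; df$mq <- "."; df$qd <- "."
  df$genotype <- "hom_alt"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=snptransmit",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  body <- if (nrow(df)) {
    ord <- order(df$chrom, df$pos)
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t1/1",
            df$chrom[ord], df$pos[ord], df$ref[ord], df$alt[ord])
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
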