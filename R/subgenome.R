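#' Assign a chromosome or scaffold to a subgenome
#'
#' Names beginning with `chrA`/`A` (after an optional `"scaffold "` prefix)
#' map to the An subgenome, `chrC`/`C` to Cn, and anything else (e.g.
#' `Unn_random`) to `other`. `_random` scaffolds follow their letter:
#' `A10_random` is An.
#'
#' @param chrom Character vector of chromosome/scaffold names.
#' @return Character vector over `{"An", "Cn", "other"}`.
#' @export
assign_subgenome <- function(chrom) {
  stripped <- sub("^scaffold[ _]?", "", chrom)
  stripped <- sub("^chr", "", stripped)
  ifelse(startsWith(stripped, "A"), "An",
         ifelse(startsWith(stripped, "C"), "Cn", "other"))
}

#' SNP density per chromosome and subgenome
#'
#' Densities in SNPs/kb, per chromosome and aggregated per subgenome;
#' optionally also a non-overlapping fixed-width window track for density
#' plots along chromosomes.
#'
#' @param records Variant-record data.frame, or `NULL` when `counts` is given.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases;
#'   every chromosome carrying SNPs must be present.
#' @param window Optional window width (bases) for the per-window track.
#' @param counts Optional named per-chromosome SNP counts, used instead of
#'   `records` when only tallies are available.
#' @return list with `per_chrom` and `per_subgenome` summary data.frames
#'   (`n_snps`, `length_kb`, `density`), and `track` (data.frame of window
#'   counts) when `window` is given.
#' @export
snp_density <- function(records = NULL, chrom_lengths, window = NULL,
                        counts = NULL) {
  if (is.null(counts)) {
    stopifnot(is.data.frame(records))
    missing_chrom <- setdiff(unique(records$chrom), names(chrom_lengths))
    if (length(missing_chrom))
      stop("chromosome(s) missing from 'chrom_lengths': ",
           paste(missing_chrom, collapse = ", "))
    counts <- table(factor(records$chrom, levels = names(chrom_lengths)))
    counts <- structure(as.integer(counts), names = names(chrom_lengths))
  } else {
    missing_chrom <- setdiff(names(counts), names(chrom_lengths))
    if (length(missing_chrom))
      stop("chromosome(s) missing from 'chrom_lengths': ",
           paste(missing_chrom, collapse = ", "))
    counts <- structure(
      as.numeric(counts)[match(names(chrom_lengths), names(counts))],
      names = names(chrom_lengths))
    counts[is.na(counts)] <- 0
  }
  per_chrom <- data.frame(
    chrom = names(chrom_lengths),
    subgenome = assign_subgenome(names(chrom_lengths)),
    n_snps = unname(counts),
    length_kb = unname(chrom_lengths) / 1000,
    stringsAsFactors = FALSE)
  per_chrom$density <- per_chrom$n_snps / per_chrom$length_kb

  agg <- lapply(split(per_chrom, per_chrom$subgenome), function(d) {
    data.frame(subgenome = d$subgenome[1], n_snps = sum(d$n_snps),
               length_kb = sum(d$length_kb),
               density = sum(d$n_snps) / sum(d$length_kb),
               stringsAsFactors = FALSE)
  })
  per_subgenome <- do.call(rbind, c(agg, make.row.names = FALSE))

  out <- list(per_chrom = per_chrom, per_subgenome = per_subgenome)
  if (!is.null(window)) {
    stopifnot(!is.null(records))
    out$track <- window_counts(records, chrom_lengths, window)
  }
  out
}

# Non-overlapping windows tiled from position 1; the last (partial) window is
# kept.
window_counts <- function(records, chrom_lengths, window) {
  rows <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    n_win <- ceiling(len / window)
    start <- (seq_len(n_win) - 1L) * window + 1L
    end <- pmin(start + window - 1L, len)
    pos <- records$pos[records$chrom == chrom]
    cnt <- tabulate((pos - 1L) %/% window + 1L, nbins = n_win)
    data.frame(chrom = chrom, start = start, end = end, count = cnt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Counts and percentages per subgenome
#'
#' Percentages are of the full total (An + Cn + other), to two decimals, the
#' way subgenome partitions are printed in genome papers; `other` is reported
#' on its own row.
#'
#' @param subgenomes Character vector of subgenome labels (`"An"`, `"Cn"`,
#'   `"other"`), one per item (SNP, gene, ...). Alternatively a named count
#'   vector (`c(An = ..., Cn = ..., other = ...)`).
#' @return data.frame with `subgenome`, `n`, `pct`.
#' @export
partition_counts <- function(subgenomes) {
  if (!is.null(names(subgenomes)) && is.numeric(subgenomes)) {
    counts <- subgenomes
  } else {
    counts <- table(factor(subgenomes, levels = c("An", "Cn", "other")))
  }
  lv <- c("An", "Cn", "other")
  n <- structure(numeric(3), names = lv)
  n[names(counts)] <- as.numeric(counts)
  total <- sum(n)
  data.frame(subgenome = lv, n = unname(n),
             pct = pct2(unname(n), total),
             stringsAsFactors = FALSE)
}

#' Compare An vs Cn transmission ratios over syntenic gene pairs
#'
#' Joins per-gene transmission ratios onto a syntenic-pair table and compares
#' the two subgenomes with a two-tailed t-test: Welch's unequal-variance test
#' by default, or a paired test on pair differences. Pairs with an undefined
#' ratio on either side (no source SNPs in that gene) are dropped and counted.
#'
#' @param per_gene `per_gene` table from [per_gene_transmission()] (or its
#'   `transmission_summary`), with columns `gene_id` and `ratio`.
#' @param pairs data.frame with columns `gene_An`, `gene_Cn`.
#' @param mode `"welch"` or `"paired"`.
#' @param values Optional: name of the column in `per_gene` to compare
#'   (default `"ratio"`); set to `"mean_tpm"` etc. to reuse the machinery for
#'   expression.
#' @return list: `mean_An`, `mean_Cn`, `t`, `df`, `p` (two-sided), `n_pairs`
#'   used and `n_dropped`.
#' @export
syntenic_ratio_test <- function(per_gene, pairs, mode = c("welch", "paired"),
                                values = "ratio") {
  mode <- match.arg(mode)
  if (inherits(per_gene, "transmission_summary")) per_gene <- per_gene$per_gene
  x <- per_gene[[values]][match(pairs$gene_An, per_gene$gene_id)]
  y <- per_gene[[values]][match(pairs$gene_Cn, per_gene$gene_id)]
  ok <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " pair(s) dropped: ratio undefined on one side")
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop("statistics error: fewer than 2 usable syntenic pairs")

  # t.test refuses (numerically) constant data; that is a legitimate
  # degenerate input here — identical ratio vectors mean p = 1, a constant
  # non-zero difference means p below anything representable
  degenerate_result <- function() {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      list(t = 0, df = length(x) - 1, p = 1)
    } else {
      warning("zero variance with unequal means; p below machine precision")
      list(t = sign(mean(x) - mean(y)) * Inf, df = length(x) - 1, p = 0)
    }
  }
  res <- tryCatch({
    ht <- if (mode == "paired")
      stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
    else
      stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
  }, error = function(e) degenerate_result())
  list(mean_An = mean(x), mean_Cn = mean(y),
       t = res$t, df = res$df, p = res$p,
       n_pairs = length(x), n_dropped = n_dropped, mode = mode)
}

#' Scan the genome in fixed windows and count SNP-dense windows
#'
#' Tiles every chromosome with non-overlapping windows from position 1 (the
#' last partial window counts) and reports how many contain strictly more
#' than `threshold` SNPs — the check used to rule out mismatch-read pile-ups
#' as the source of dense RNA variation.
#'
#' @param records Variant-record data.frame.
#' @param chrom_lengths Named chromosome lengths, bases.
#' @param window Window width in bases (150 = one RNA-seq read length).
#' @param threshold Window flagged when SNP count > threshold (strict).
#' @return list: `n_windows_total`, `n_windows_exceeding`, and the `track`.
#' @export
window_scan <- function(records, chrom_lengths, window = 150L,
                        threshold = 10L) {
  stopifnot(window > 0, threshold >= 0)
  track <- window_counts(records, chrom_lengths, window)
  list(n_windows_total = nrow(track),
       n_windows_exceeding = sum(track$count > threshold),
       track = track)
}

#' Write a per-window count track as bedGraph
#'
#' @param track `track` data.frame from [window_scan()] or [snp_density()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- c("track type=bedGraph name=snp_count",
             sprintf("%s\t%d\t%d\t%d", track$chrom,
                     track$start - 1L, track$end, track$count))
  writeLines(lines, path)
  invisible(path)
}
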