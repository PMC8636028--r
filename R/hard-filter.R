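#' GATK-style hard filter: quality expression plus SNP-cluster rule
#'
#' A record fails the quality expression when `QUAL < qual_min`, `MQ < mq_min`
#' or `QD < qd_min`; a missing metric passes its clause (the comparison cannot
#' be evaluated, as in GATK VariantFiltration). A record fails the cluster
#' rule when it lies in any window of `cluster_window` bases containing at
#' least `cluster_size` SNPs of the same line/level call set; the cluster rule
#' is evaluated on all records (before quality filtering) and takes precedence
#' when both fail. The operation is idempotent: statuses are recomputed from
#' scratch on every call.
#'
#' @param records Variant-record data.frame.
#' @param qual_min,mq_min,qd_min Quality-expression thresholds.
#' @param cluster_size,cluster_window Cluster rule: at least `cluster_size`
#'   SNPs within any `cluster_window`-base window.
#' @return `records` with `filter_status` set to `"pass"`,
#'   `"fail_expression"` or `"fail_cluster"`.
#' @export
hard_filter <- function(records, qual_min = 30.0, mq_min = 50.0, qd_min = 2.0,
                        cluster_size = 3L, cluster_window = 10L) {
  if (nrow(records) == 0L) return(records)
  fail_expr <- (!is.na(records$qual) & records$qual < qual_min) |
    (!is.na(records$mq) & records$mq < mq_min) |
    (!is.na(records$qd) & records$qd < qd_min)

  fail_clust <- logical(nrow(records))
  grp <- interaction(records$line, records$level, records$chrom, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    pos <- sort(unique(records$pos[idx]))
    if (length(pos) < cluster_size) next
    in_cluster <- cluster_positions(pos, cluster_size, cluster_window)
    fail_clust[idx] <- records$pos[idx] %in% pos[in_cluster]
  }
  records$filter_status <- ifelse(fail_clust, "fail_cluster",
                                  ifelse(fail_expr, "fail_expression", "pass"))
  records
}

# Which of the sorted unique positions lie in some window of `window` bases
# holding >= size SNPs. Two-pointer sweep over windows anchored at each SNP.
cluster_positions <- function(pos, size, window) {
  n <- length(pos)
  flag <- logical(n)
  j <- 1L
  for (i in seq_len(n)) {
    # widest window starting at pos[i]
    while (j < n && pos[j + 1L] - pos[i] + 1L <= window) j <- j + 1L
    while (pos[j] - pos[i] + 1L > window) j <- j - 1L
    if (j - i + 1L >= size) flag[i:j] <- TRUE
    if (j < i) j <- i
  }
  flag
}

#' Keep only records that pass the hard filter
#'
#' @param records Filtered variant-record data.frame.
#' @return Subset with `filter_status == "pass"`.
#' @export
pass_records <- function(records) {
  records[records$filter_status == "pass", , drop = FALSE]
}
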