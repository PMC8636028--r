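#' Merge TPM tables across tissues into a per-gene mean
#'
#' Takes one or more gene-by-tissue TPM tables (first column `gene_id`,
#' remaining columns tissues/replicates), outer-joins their gene universes
#' (genes absent from a table are treated as 0 with a warning) and averages
#' over all tissue columns with equal weight. A gene is "unexpressed" when
#' its mean TPM is exactly 0.
#'
#' @param ... TPM data.frames, or a single list of them.
#' @return list: `tpm` (data.frame `gene_id`, `mean_tpm`) and
#'   `unexpressed` (character vector of gene ids).
#' @export
merge_tpm <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1L]]) &&
      !is.data.frame(tables[[1L]]))
    tables <- tables[[1L]]
  stopifnot(length(tables) >= 1L)
  for (t in tables) {
    if (names(t)[1L] != "gene_id" || ncol(t) < 2L)
      stop("each TPM table needs a leading 'gene_id' column and >=1 tissue")
  }
  universe <- unique(unlist(lapply(tables, function(t) t$gene_id)))
  filled <- FALSE
  sums <- numeric(length(universe)); n_cols <- 0L
  for (t in tables) {
    m <- as.matrix(t[, -1L, drop = FALSE])
    idx <- match(t$gene_id, universe)
    add <- matrix(0, length(universe), ncol(m))
    add[idx, ] <- m
    if (nrow(t) < length(universe)) filled <- TRUE
    sums <- sums + rowSums(add)
    n_cols <- n_cols + ncol(m)
  }
  if (filled)
    warning("gene universes differ across TPM tables; missing values = 0")
  tpm <- data.frame(gene_id = universe, mean_tpm = sums / n_cols,
                    stringsAsFactors = FALSE)
  list(tpm = tpm, unexpressed = tpm$gene_id[tpm$mean_tpm == 0])
}

#' Genes unexpressed in both of two lines
#'
#' @param unexpressed_a,unexpressed_b Character vectors of unexpressed gene
#'   ids from [merge_tpm()].
#' @return Character vector: the shared unexpressed genes.
#' @export
shared_unexpressed <- function(unexpressed_a, unexpressed_b) {
  intersect(unexpressed_a, unexpressed_b)
}

#' Assign genes to bins by transmission ratio or variation count
#'
#' Ratio mode bins `[0, 0.1), [0.1, 0.2), ..., [0.9, 1.0]` for width 0.1 (the
#' last bin is closed so a fully transmitted gene lands in bin 10). Count
#' mode bins `[1, 10], [11, 20], ...` for width 10; genes with 0 variations
#' get bin `NA` (excluded from count-binned fits) unless `include_zero` puts
#' them in bin 0.
#'
#' @param values Per-gene ratios in [0, 1] or non-negative integer counts.
#' @param mode `"ratio"` or `"count"`.
#' @param bin_width Bin width: ratio units (default 0.1) or count units.
#' @param include_zero Count mode only: keep zero-variation genes as bin 0.
#' @return Integer bin indices, same length as `values`.
#' @export
bin_genes <- function(values, mode = c("ratio", "count"), bin_width = NULL,
                      include_zero = FALSE) {
  mode <- match.arg(mode)
  if (is.null(bin_width)) bin_width <- if (mode == "ratio") 0.1 else 10
  if (mode == "ratio") {
    if (any(values < 0 | values > 1, na.rm = TRUE))
      stop("ratio values must lie in [0, 1]")
    n_bins <- ceiling(1 / bin_width)
    pmin(floor(values / bin_width) + 1L, n_bins)
  } else {
    if (any(values < 0 | values != floor(values), na.rm = TRUE))
      stop("count values must be non-negative integers")
    bin <- as.integer(ceiling(values / bin_width))
    if (!include_zero) bin[values == 0] <- NA_integer_
    bin
  }
}

#' Fit the binned linear model of expression on bin ordinal
#'
#' Genes are binned, the mean TPM of each non-empty bin is taken, and
#' ordinary least squares fits `y_i = a * x_i + b` where `y_i` is the i-th
#' bin's mean TPM and `x_i` is the bin's ordinal (1..k over the non-empty
#' bins, the default) or its midpoint.
#'
#' @param values Per-gene covariate (ratio or count; see [bin_genes()]).
#' @param mean_tpm Per-gene mean TPM, same order as `values`.
#' @param mode `"ratio"` or `"count"`.
#' @param bin_width Bin width (default 0.1 for ratio, 10 for count).
#' @param x `"ordinal"` (default) regresses on 1..k; `"midpoint"` on bin
#'   midpoints.
#' @param include_zero Passed to [bin_genes()].
#' @param covariate Label stored on the result.
#' @return list of class `binned_fit`: `covariate`, `bin_width`, `bins`
#'   (data.frame `bin`, `lower`, `upper`, `n_genes`, `mean_tpm`, `x`),
#'   `slope`, `intercept`, `r_squared`.
#' @export
fit_binned_regression <- function(values, mean_tpm,
                                  mode = c("ratio", "count"),
                                  bin_width = NULL,
                                  x = c("ordinal", "midpoint"),
                                  include_zero = FALSE,
                                  covariate = NULL) {
  mode <- match.arg(mode)
  x <- match.arg(x)
  if (is.null(bin_width)) bin_width <- if (mode == "ratio") 0.1 else 10
  keep <- !is.na(values) & !is.na(mean_tpm)
  bin <- bin_genes(values[keep], mode, bin_width, include_zero)
  tpm <- mean_tpm[keep][!is.na(bin)]
  bin <- bin[!is.na(bin)]
  if (length(bin) == 0L) stop("fit error: no binnable genes")
  tab <- sort(unique(bin))
  bins <- data.frame(
    bin = tab,
    lower = if (mode == "ratio") (tab - 1L) * bin_width else
      (tab - 1L) * bin_width + 1L,
    upper = tab * bin_width,
    n_genes = as.integer(table(factor(bin, levels = tab))),
    mean_tpm = as.numeric(tapply(tpm, factor(bin, levels = tab), mean)))
  if (include_zero && mode == "count" && 0L %in% tab)
    bins$lower[bins$bin == 0L] <- 0
  if (nrow(bins) < 3L)
    stop("fit error: fewer than 3 non-empty bins (", nrow(bins), ")")
  bins$x <- if (x == "ordinal") seq_len(nrow(bins)) else
    (bins$lower + bins$upper) / 2
  if (stats::var(bins$mean_tpm) == 0) {
    warning("zero variance in bin means; R^2 reported as 0")
    fitted <- list(slope = 0, intercept = bins$mean_tpm[1], r2 = 0)
  } else {
    fit <- stats::lm(mean_tpm ~ x, data = bins)
    # summary() warns on an exactly collinear fit; a perfect line is a
    # legitimate input here (noise-free bins), not a modelling problem
    fitted <- list(slope = unname(stats::coef(fit)[2L]),
                   intercept = unname(stats::coef(fit)[1L]),
                   r2 = suppressWarnings(summary(fit)$r.squared))
  }
  structure(list(covariate = covariate %||% mode, bin_width = bin_width,
                 bins = bins, slope = fitted$slope,
                 intercept = fitted$intercept, r_squared = fitted$r2),
            class = "binned_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.binned_fit <- function(x, ...) {
  cat(sprintf(
    "binned_fit [%s, width %s]: %d bins, TPM = %.3f * x + %.3f, R^2 = %.3f\n",
    x$covariate, format(x$bin_width), nrow(x$bins), x$slope, x$intercept,
    x$r_squared))
  invisible(x)
}

#' Compare An vs Cn expression over syntenic gene pairs
#'
#' Same two-tailed test machinery as [syntenic_ratio_test()], applied to mean
#' TPM instead of transmission ratios.
#'
#' @param tpm data.frame `gene_id`, `mean_tpm` from [merge_tpm()].
#' @param pairs data.frame `gene_An`, `gene_Cn`.
#' @param mode `"welch"` or `"paired"`.
#' @return As [syntenic_ratio_test()].
#' @export
compare_syntenic_expression <- function(tpm, pairs,
                                        mode = c("welch", "paired")) {
  if (nrow(pairs) == 0L) stop("statistics error: empty pair list")
  syntenic_ratio_test(tpm, pairs, mode = match.arg(mode),
                      values = "mean_tpm")
}
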