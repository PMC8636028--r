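#' @keywords internal
"_PACKAGE"

#' Build SNP identity keys
#'
#' A SNP observation is identified by the exact tuple (chrom, pos, ref, alt);
#' two call sets share a SNP only when all four fields agree. Keys are plain
#' strings (`"chrom:pos:ref>alt"`) so set operations stay fast and readable.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Single-base reference and alternate alleles.
#' @return Character vector of keys, one per input SNP.
#' @export
snp_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

#' Parse SNP keys back into a data frame
#'
#' @param keys Character keys as produced by [snp_key()].
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_snp_key <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(keys, regexec("^(.+):([0-9]+):([ACGTN])>([ACGTN])$", keys))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("malformed SNP key(s): ", paste(keys[bad][1], collapse = ", "))
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    pos   = as.integer(vapply(m, `[`, "", 3L)),
    ref   = vapply(m, `[`, "", 4L),
    alt   = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

# Percentage to 2 decimals, as printed in genome-annotation summary tables.
pct2 <- function(count, total) {
  p <- round(100 * count / total, 2)
  p[!is.finite(p)] <- NA_real_
  p
}

# Empty variant-record data.frame; single definition so every reader/filter
# agrees on the schema.
empty_records <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    qual = numeric(), mq = numeric(), qd = numeric(),
    genotype = character(), level = character(), line = character(),
    filter_status = character(), region_class = character(),
    effect_class = character(), gene_id = character(),
    stringsAsFactors = FALSE
  )
}

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}
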