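#' Gene model collection
#'
#' Container for single-transcript gene models: a gene table (span, strand,
#' subgenome) plus exon and CDS interval tables. All coordinates are 1-based
#' inclusive, as in GFF3 and VCF.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end` (and optionally `subgenome`; assigned from the
#'   chromosome name when absent).
#' @param exons data.frame with `gene_id`, `start`, `end`.
#' @param cds data.frame with `gene_id`, `start`, `end`; the per-gene total
#'   CDS length must be divisible by 3 and every CDS interval must lie within
#'   an exon of the same gene.
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(genes)))
    stop("'genes' must have columns: ", paste(need, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(genes$subgenome))
    genes$subgenome <- assign_subgenome(genes$chrom)
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  cds <- cds[order(match(cds$gene_id, genes$gene_id), cds$start), ]
  # structural invariants, checked per gene
  for (g in unique(cds$gene_id)) {
    ce <- cds[cds$gene_id == g, ]
    ee <- exons[exons$gene_id == g, ]
    len <- sum(ce$end - ce$start + 1L)
    if (len %% 3L != 0L)
      stop("CDS length of gene ", g, " is not divisible by 3")
    ir_c <- IRanges::IRanges(ce$start, ce$end)
    ir_e <- IRanges::IRanges(ee$start, ee$end)
    if (length(ir_c) && !all(IRanges::overlapsAny(ir_c, ir_e, type = "within")))
      stop("CDS of gene ", g, " extends outside its exons")
    if (length(ir_e) > 1 &&
        any(IRanges::start(ir_e)[-1] <= IRanges::end(ir_e)[-length(ir_e)]))
      stop("exons of gene ", g, " overlap or are unsorted")
  }
  rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' @exportS3Method base::print
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosomes (",
      sum(x$genes$subgenome == "An"), "An /",
      sum(x$genes$subgenome == "Cn"), "Cn )\n")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Expects the conventional gene/mRNA/exon/CDS hierarchy with one transcript
#' per gene; exon and CDS features are attached to their gene through the
#' `Parent` chain.
#'
#' @param path GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  gene_rows <- df[df$type == "gene", ]
  mrna_rows <- df[df$type == "mRNA", ]
  # map transcript ID -> gene ID
  tx2gene <- structure(unlist(lapply(mrna_rows$Parent, `[`, 1L)),
                       names = mrna_rows$ID)
  feat_gene <- function(rows) {
    parent <- unlist(lapply(rows$Parent, `[`, 1L))
    gid <- ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)
    data.frame(gene_id = unname(gid), start = rows$start, end = rows$end,
               stringsAsFactors = FALSE)
  }
  genes <- data.frame(
    gene_id = gene_rows$ID, chrom = gene_rows$seqnames,
    strand = gene_rows$strand, tx_start = gene_rows$start,
    tx_end = gene_rows$end, stringsAsFactors = FALSE
  )
  gene_models(genes,
              exons = feat_gene(df[df$type == "exon", ]),
              cds = feat_gene(df[df$type == "CDS", ]))
}

#' Write gene models to GFF3
#'
#' @param models A [gene_models()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    row <- function(type, start, end, attrs, frame = ".") {
      sprintf("%s\tsnptransmit\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom[i], type, start, end, g$strand[i], frame, attrs)
    }
    lines <- c(lines,
               row("gene", g$tx_start[i], g$tx_end[i], paste0("ID=", gid)),
               row("mRNA", g$tx_start[i], g$tx_end[i],
                   paste0("ID=", tid, ";Parent=", gid)))
    ex <- models$exons[models$exons$gene_id == gid, ]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, row("exon", ex$start[j], ex$end[j],
                            paste0("ID=", tid, ".exon", j, ";Parent=", tid)))
    cd <- models$cds[models$cds$gene_id == gid, ]
    # phase: bases to skip before the first full codon, in translation order
    if (nrow(cd)) {
      widths <- cd$end - cd$start + 1L
      ord <- if (g$strand[i] == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
      phase <- integer(nrow(cd))
      done <- 0L
      for (j in ord) {
        phase[j] <- (3L - done %% 3L) %% 3L
        done <- done + widths[j]
      }
      for (j in seq_len(nrow(cd)))
        lines <- c(lines, row("CDS", cd$start[j], cd$end[j],
                              paste0("ID=", tid, ".cds;Parent=", tid),
                              frame = phase[j]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# GRanges of gene transcript spans, keeping gene order.
gene_spans <- function(models) {
  g <- models$genes
  GenomicRanges::GRanges(g$chrom,
                         IRanges::IRanges(g$tx_start, g$tx_end),
                         strand = g$strand, gene_id = g$gene_id,
                         subgenome = g$subgenome)
}
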