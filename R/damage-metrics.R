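#' Count lesion positions per gene and sample
#'
#' Counts the distinct lesion positions of one lesion type that fall in each
#' gene's territory: the exon union (`region_mode = "exon"`) or the full gene
#' span including introns (`region_mode = "whole_gene"`). Both strands are
#' pooled by default; `strand_mode` can restrict counting to the template or
#' non-template strand relative to each gene's orientation (the template
#' strand of a `+` gene is the `-` strand). A lesion inside the territory of
#' several genes is counted for every such gene unless
#' `overlap = "unique_gene"`.
#'
#' @param lesions lesion tibble (one lesion type; may hold many samples).
#' @param genes gene-model tibble.
#' @param region_mode `"exon"` or `"whole_gene"`.
#' @param strand_mode `"both"` (default), `"template"` or `"nontemplate"`.
#' @param overlap `"all_genes"` (default) or `"unique_gene"` (lesions hitting
#'   more than one gene are discarded).
#' @param sample_ids optional sample order for the output columns; defaults
#'   to the sorted samples present in `lesions`. Samples with no lesions get
#'   zero counts.
#' @return A counts tibble: `gene_id` plus one integer column per sample.
#' @export
count_lesions <- function(lesions, genes,
                          region_mode = c("exon", "whole_gene"),
                          strand_mode = c("both", "template", "nontemplate"),
                          overlap = c("all_genes", "unique_gene"),
                          sample_ids = NULL) {
  region_mode <- match.arg(region_mode)
  strand_mode <- match.arg(strand_mode)
  overlap <- match.arg(overlap)
  validate_gene_models(genes)
  if (is.null(sample_ids)) sample_ids <- sort(unique(lesions$sample_id))

  lesions <- distinct(lesions, .data$sample_id, .data$chrom, .data$position,
                      .data$strand)
  territory <- genes_as_granges(genes, region_mode)

  counts <- matrix(0L, nrow = nrow(genes), ncol = length(sample_ids),
                   dimnames = list(genes$gene_id, sample_ids))
  if (nrow(lesions) > 0) {
    les_gr <- GenomicRanges::GRanges(
      seqnames = lesions$chrom,
      ranges = IRanges::IRanges(start = lesions$position + 1L, width = 1L)
    )
    hits <- GenomicRanges::findOverlaps(les_gr, territory, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    gid <- territory$gene_id[S4Vectors::subjectHits(hits)]
    keep <- rep(TRUE, length(qi))
    if (strand_mode != "both") {
      gene_strand <- genes$strand[match(gid, genes$gene_id)]
      lesion_strand <- lesions$strand[qi]
      # template strand is the reverse complement of the gene's orientation
      on_template <- lesion_strand != gene_strand
      keep <- if (strand_mode == "template") on_template else !on_template
    }
    if (overlap == "unique_gene") {
      # number of distinct genes hit per lesion record
      multi <- tapply(gid, qi, function(g) length(unique(g)))
      ambiguous <- as.integer(names(multi)[multi > 1L])
      keep <- keep & !(qi %in% ambiguous)
    }
    qi <- qi[keep]
    gid <- gid[keep]
    if (length(qi) > 0) {
      # a lesion may fall in several exons of the same gene only if exons
      # overlapped, which the union-merge excludes, so (record, gene) pairs
      # are unique and tabulation is a plain count
      tab <- tibble(sample_id = lesions$sample_id[qi], gene_id = gid) |>
        count(.data$sample_id, .data$gene_id)
      tab <- tab[tab$sample_id %in% sample_ids, ]
      counts[cbind(
        match(tab$gene_id, genes$gene_id),
        match(tab$sample_id, sample_ids)
      )] <- tab$n
    }
  }
  bind_cols(tibble(gene_id = genes$gene_id), as_tibble(counts))
}

#' Lesions per kb per million (LPKM)
#'
#' The per-gene lesion density: `value(i, j) = R_ij * scale / (L_i * N_j)`,
#' where `R_ij` is the number of distinct lesion positions of sample `j` in
#' gene `i`'s territory, `L_i` the territory length in bp (exon-union length
#' in exon mode, span length in whole-gene mode) and `N_j` the sample's total
#' distinct lesion positions. The default `scale = 1e9` gives "per kb of
#' territory per million total positions" semantics. Any fixed positive scale
#' is rank-preserving, so downstream gene selection and modeling do not
#' depend on it.
#'
#' @param counts counts tibble from [count_lesions()] (`gene_id` + samples).
#' @param genes gene-model tibble covering every gene in `counts`.
#' @param totals tibble with `sample_id`, `total_positions` (see
#'   [lesion_totals()]), covering every sample column.
#' @param region_mode length term: `"exon"` uses `exon_union_length`,
#'   `"whole_gene"` uses `span_length`.
#' @param scale positive scale constant, default `1e9`.
#' @return A feature-matrix tibble (`gene_id` + one numeric column per
#'   sample).
#' @export
compute_lpkm <- function(counts, genes, totals,
                         region_mode = c("exon", "whole_gene"),
                         scale = 1e9) {
  region_mode <- match.arg(region_mode)
  stopifnot(scale > 0)
  validate_gene_models(genes)
  sample_ids <- names(counts)[-1]
  n <- totals$total_positions[match(sample_ids, totals$sample_id)]
  if (anyNA(n)) {
    abort(paste0(
      "no lesion totals for sample(s): ",
      paste(sample_ids[is.na(n)], collapse = ", ")
    ))
  }
  if (any(n <= 0)) {
    abort(paste0(
      "zero total lesion positions for sample(s): ",
      paste(sample_ids[n <= 0], collapse = ", ")
    ))
  }
  idx <- match(counts$gene_id, genes$gene_id)
  if (anyNA(idx)) abort("counts contain genes absent from the annotation")
  len <- if (region_mode == "exon") {
    genes$exon_union_length[idx]
  } else {
    genes$span_length[idx]
  }
  r <- fm_values(counts)
  vals <- r * scale / (len %o% as.double(n))
  bind_cols(tibble(gene_id = counts$gene_id), as_tibble(vals))
}

#' Gene-level TPM from read counts
#'
#' Naive gene-level transcripts-per-million: length-normalized rates
#' `count / exon_union_length` rescaled so every sample column sums to 1e6.
#' No isoform-level expectation-maximization and no fragment-length
#' correction are applied.
#'
#' @param read_counts counts tibble (`gene_id` + one column per sample).
#' @param genes gene-model tibble; effective length is the exon-union length.
#' @return A feature-matrix tibble of TPM values.
#' @export
compute_tpm <- function(read_counts, genes) {
  validate_gene_models(genes)
  idx <- match(read_counts$gene_id, genes$gene_id)
  if (anyNA(idx)) abort("counts contain genes absent from the annotation")
  len <- genes$exon_union_length[idx]
  m <- fm_values(read_counts)
  if (any(m < 0)) abort("read counts must be non-negative")
  rate <- m / len
  colsum <- colSums(rate)
  if (any(colsum == 0)) {
    abort(paste0(
      "all-zero counts for sample(s): ",
      paste(colnames(m)[colsum == 0], collapse = ", ")
    ))
  }
  tpm <- sweep(rate, 2, colsum, "/") * 1e6
  bind_cols(tibble(gene_id = read_counts$gene_id), as_tibble(tpm))
}

#' Filter genes by fraction of samples with a nonzero value
#'
#' Keeps genes whose fraction of samples with value > 0 is at least
#' `min_nonzero_fraction`, pooled over all samples. The study defaults are
#' 0.40 for TPM and 0.20 for LPKM metrics; row order is preserved.
#'
#' @param fm feature-matrix tibble.
#' @param min_nonzero_fraction required fraction in (0, 1].
#' @return The filtered feature-matrix tibble.
#' @export
filter_genes <- function(fm, min_nonzero_fraction) {
  stopifnot(min_nonzero_fraction > 0, min_nonzero_fraction <= 1)
  m <- fm_values(fm)
  frac <- rowMeans(m > 0)
  keep <- frac >= min_nonzero_fraction
  if (!any(keep)) {
    abort("no genes pass the nonzero-fraction filter; lower the threshold")
  }
  fm[keep, , drop = FALSE]
}
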