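#' Gene models: exon unions with 0-based half-open coordinates
#'
#' A gene-model table is a tibble with one row per gene and columns
#' `gene_id`, `chrom`, `strand`, `exon_starts`, `exon_ends` (integer
#' list-columns, 0-based half-open, union-merged), `span_start`, `span_end`,
#' `exon_union_length` and `span_length`. It is the unit of featurization:
#' lesion counting uses either the exon union or the full gene span, and
#' LPKM/TPM use the matching length.
#'
#' @param gene_id character vector of gene identifiers (unique).
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param exon_starts,exon_ends list of integer vectors per gene, 0-based
#'   half-open. Overlapping or adjacent intervals are merged.
#' @return A gene-model tibble as described above.
#' @examples
#' gene_models("g1", "chr1", "+", list(c(100L, 300L)), list(c(200L, 400L)))
#' @export
gene_models <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  if (anyDuplicated(gene_id) > 0) {
    abort("duplicate gene_id in gene models")
  }
  if (!all(strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  merged <- map2(exon_starts, exon_ends, merge_intervals)
  starts <- map(merged, "start")
  ends <- map(merged, "end")
  ulen <- map_int(merged, function(m) sum(m$end - m$start))
  if (any(ulen < 1L)) {
    abort(paste0(
      "genes with zero exon length: ",
      paste(gene_id[ulen < 1L], collapse = ", ")
    ))
  }
  tibble(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exon_starts = starts,
    exon_ends = ends,
    span_start = map_int(starts, function(s) s[1]),
    span_end = map_int(ends, function(e) e[length(e)]),
    exon_union_length = ulen
  ) |>
    mutate(span_length = .data$span_end - .data$span_start)
}

# Union-merge 0-based half-open intervals; adjacent intervals are joined so
# the result is sorted, non-overlapping and non-adjacent.
merge_intervals <- function(starts, ends) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0L) {
    return(list(start = integer(), end = integer()))
  }
  if (any(ends <= starts)) abort("interval with end <= start")
  o <- order(starts, ends)
  starts <- as.integer(starts[o])
  ends <- as.integer(ends[o])
  out_s <- starts[1]
  out_e <- ends[1]
  k <- 1L
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], ends[i])
    } else {
      k <- k + 1L
      out_s[k] <- starts[i]
      out_e[k] <- ends[i]
    }
  }
  list(start = out_s, end = out_e)
}

validate_gene_models <- function(genes) {
  need <- c(
    "gene_id", "chrom", "strand", "exon_starts", "exon_ends",
    "span_start", "span_end", "exon_union_length", "span_length"
  )
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "not a gene-model table; missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(genes)
}

# GRanges of the counting territory for one region mode (strand-free; lesion
# counting pools both strands unless a strand filter is applied upstream).
genes_as_granges <- function(genes, region_mode = c("exon", "whole_gene")) {
  region_mode <- match.arg(region_mode)
  if (region_mode == "whole_gene") {
    GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$span_start + 1L, end = genes$span_end),
      gene_id = genes$gene_id
    )
  } else {
    n_exon <- lengths(genes$exon_starts)
    GenomicRanges::GRanges(
      seqnames = rep(genes$chrom, n_exon),
      ranges = IRanges::IRanges(
        start = unlist(genes$exon_starts) + 1L,
        end = unlist(genes$exon_ends)
      ),
      gene_id = rep(genes$gene_id, n_exon)
    )
  }
}
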