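#' Read gene models from a GTF file
#'
#' Reads exon features from a GTF file (1-based, inclusive coordinates) and
#' returns one gene model per `gene_id`, with exons converted to 0-based
#' half-open coordinates and union-merged. Transcript structure is ignored:
#' a gene's territory is the union of all its exons.
#'
#' @param path path to a GTF file.
#' @return A gene-model tibble (see [gene_models()]).
#' @seealso [write_gtf()]
#' @export
read_gtf <- function(path) {
  lines <- readr::read_lines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  if (any(nfield < 9L)) {
    bad <- which(body)[which(nfield < 9L)[1]]
    abort(paste0("malformed GTF line ", bad, ": expected 9 tab-separated fields"))
  }
  if (!any(body)) {
    warn(paste0("empty GTF file: ", path))
    return(gene_models(character(), character(), character(),
                       list(), list())[0, ])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) abort("GTF contains no exon features")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    abort("GTF exon features must carry a gene_id attribute")
  }
  ex <- tibble(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    # 1-based inclusive -> 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  bad <- ex |>
    group_by(.data$gene_id) |>
    summarise(n_chrom = n_distinct(.data$chrom), .groups = "drop") |>
    filter(.data$n_chrom > 1L)
  if (nrow(bad) > 0) {
    abort(paste0(
      "genes with exons on multiple chromosomes: ",
      paste(bad$gene_id, collapse = ", ")
    ))
  }
  if (any(!ex$strand %in% c("+", "-"))) {
    abort("GTF exon features must have strand '+' or '-'")
  }
  by_gene <- ex |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      starts = list(.data$start),
      ends = list(.data$end),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id)
  gene_models(by_gene$gene_id, by_gene$chrom, by_gene$strand,
              by_gene$starts, by_gene$ends)
}

#' Write gene models to a GTF file
#'
#' Writes one exon row per merged exon (1-based inclusive coordinates), so
#' `read_gtf(write_gtf(x))` reproduces `x`.
#'
#' @param genes a gene-model tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  validate_gene_models(genes)
  n_exon <- lengths(genes$exon_starts)
  lines <- sprintf(
    "%s\tbreakclock\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    rep(genes$chrom, n_exon),
    unlist(genes$exon_starts) + 1L,
    unlist(genes$exon_ends),
    rep(genes$strand, n_exon),
    rep(genes$gene_id, n_exon)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a lesion map from a BED file
#'
#' Each BED record is one detected lesion (SSB or AP site) at a single
#' nucleotide: `end` must equal `start + 1` and the strand column must be
#' present. Records are deduplicated on (chrom, position, strand) because
#' lesion densities count distinct positions, not reads; the number of
#' duplicates dropped is reported.
#'
#' @param path path to a BED6 file.
#' @param sample_id sample identifier attached to every record.
#' @param lesion_type `"SSB"` or `"AP"`.
#' @return A lesion tibble with columns `sample_id`, `lesion_type`, `chrom`,
#'   `position` (0-based), `strand`.
#' @export
read_lesion_bed <- function(path, sample_id, lesion_type = c("SSB", "AP")) {
  lesion_type <- match.arg(lesion_type)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) {
    return(tibble(
      sample_id = character(), lesion_type = character(),
      chrom = character(), position = integer(), strand = character()
    ))
  }
  if (any(GenomicRanges::width(gr) != 1L)) {
    abort(paste0(
      "lesion records must be single-nucleotide (end = start + 1) in ", path
    ))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    abort(paste0("lesion records must carry a strand in ", path))
  }
  out <- tibble(
    sample_id = sample_id,
    lesion_type = lesion_type,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,
    strand = strand
  )
  dedup <- distinct(out, .data$chrom, .data$position, .data$strand,
                    .keep_all = TRUE)
  n_dup <- nrow(out) - nrow(dedup)
  if (n_dup > 0) {
    inform(paste0(sample_id, ": dropped ", n_dup, " duplicate lesion record(s)"))
  }
  dedup
}

#' Write a lesion map to a BED file
#'
#' @param lesions a lesion tibble for one sample and lesion type.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lesion_bed <- function(lesions, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t.\t0\t%s",
    lesions$chrom, lesions$position, lesions$position + 1L, lesions$strand
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Per-sample totals of distinct lesion positions
#'
#' The LPKM depth denominator: the number of distinct (chrom, position,
#' strand) records per sample.
#'
#' @param lesions a lesion tibble (any number of samples, one lesion type).
#' @return tibble with `sample_id`, `total_positions`.
#' @export
lesion_totals <- function(lesions) {
  lesions |>
    distinct(.data$sample_id, .data$chrom, .data$position, .data$strand) |>
    count(.data$sample_id, name = "total_positions")
}

#' Read sample metadata
#'
#' @param path TSV with header and columns `sample_id`, `age_months`,
#'   `tissue`.
#' @param ages allowed age labels (months); `NULL` skips the check.
#' @param tissues allowed tissue labels; `NULL` skips the check.
#' @return tibble with `sample_id` (character), `age_months` (numeric) and
#'   `tissue` (character).
#' @export
read_metadata <- function(path, ages = c(3, 12, 19, 22, 24), tissues = NULL) {
  md <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      age_months = readr::col_double(),
      tissue = readr::col_character()
    )
  )
  validate_metadata(md, ages = ages, tissues = tissues)
}

validate_metadata <- function(md, ages = NULL, tissues = NULL) {
  need <- c("sample_id", "age_months", "tissue")
  if (!all(need %in% names(md))) {
    abort(paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyNA(md$age_months) || anyNA(md$tissue) || anyNA(md$sample_id)) {
    abort("metadata must not contain missing values")
  }
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(ages) && !all(md$age_months %in% ages)) {
    bad <- setdiff(unique(md$age_months), ages)
    abort(paste0(
      "unknown age label(s): ", paste(bad, collapse = ", "),
      "; allowed: ", paste(ages, collapse = ", ")
    ))
  }
  if (!is.null(tissues) && !all(md$tissue %in% tissues)) {
    bad <- setdiff(unique(md$tissue), tissues)
    abort(paste0(
      "unknown tissue label(s): ", paste(bad, collapse = ", "),
      "; allowed: ", paste(tissues, collapse = ", ")
    ))
  }
  n_strata <- nrow(distinct(md, .data$age_months, .data$tissue))
  inform(paste0(
    nrow(md), " samples in ", n_strata, " (age, tissue) strata"
  ))
  as_tibble(md)
}

#' Write sample metadata
#' @param metadata metadata tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}

#' Read / write a feature matrix
#'
#' Feature matrices are tibbles with a `gene_id` column followed by one
#' numeric column per sample (genes as rows). The writer serializes doubles
#' with 17 significant digits (the IEEE-754 round-trip guarantee), so
#' `read_feature_matrix(write_feature_matrix(x))` is bit-exact.
#'
#' @param fm feature-matrix tibble.
#' @param path file path.
#' @return `read_feature_matrix` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(names(fm)[1] == "gene_id")
  if (anyNA(fm)) abort("feature matrix must not contain NA")
  out <- fm
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  # parse numbers with base R's strtod, which is exact to the last bit;
  # fast approximate float parsers break the bit-exact round-trip contract
  fm <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (names(fm)[1] != "gene_id") abort("feature matrix must start with gene_id")
  fm[-1] <- lapply(fm[-1], as.double)
  if (anyNA(fm)) abort("feature matrix must not contain NA")
  fm
}

# genes x samples numeric matrix view of a feature-matrix tibble
fm_values <- function(fm) {
  m <- as.matrix(fm[, -1, drop = FALSE])
  rownames(m) <- fm$gene_id
  m
}
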