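# Small in-code fixtures shared across test files.

# two-gene annotation used by the counting and LPKM tests
tiny_genes <- function() {
  gene_models(
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    exon_starts = list(c(100L, 300L), 1000L),
    exon_ends = list(c(200L, 400L), 2000L)
  )
}

tiny_lesions <- function(sample_id = "s1", lesion_type = "SSB") {
  tibble::tibble(
    sample_id = sample_id,
    lesion_type = lesion_type,
    chrom = "chr1",
    position = c(150L, 150L, 250L, 399L),
    strand = c("+", "-", "+", "+")
  )
}

# balanced metadata for model tests: n_per_cell replicates of ages x tissues
balanced_metadata <- function(ages = c(3, 12, 19, 22, 24),
                              tissues = c("t1", "t2"),
                              n_per_cell = 2) {
  md <- expand.grid(
    age_months = ages, tissue = tissues, rep = seq_len(n_per_cell),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(nrow(md))),
    age_months = md$age_months,
    tissue = md$tissue
  )
}

# feature matrix with optional planted linear age signal in the first
# `n_signal` genes
random_fm <- function(metadata, n_genes = 50, n_signal = 0, effect = 2,
                      seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(metadata)
    m <- matrix(rpois(n_genes * n, 50), n_genes, n)
    if (n_signal > 0) {
      a <- (metadata$age_months - min(metadata$age_months)) /
        diff(range(metadata$age_months))
      for (i in seq_len(n_signal)) {
        m[i, ] <- rpois(n, 50 * exp(effect * a))
      }
    }
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)), metadata$sample_id)
    dplyr::bind_cols(
      tibble::tibble(gene_id = rownames(m)),
      tibble::as_tibble(m + 0.0)
    )
  })
}

# small, fast synthetic config for generator tests
small_config <- function(seed = 3, ...) {
  synthetic_config(
    seed = seed, n_genes = 120, n_age_pos = 8, n_age_neg = 4,
    n_tissue_markers = 12, lesion_depth = 1.5e4, expression_depth = 1.2e5,
    lesion_types = "SSB", ...
  )
}
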