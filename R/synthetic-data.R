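#' Configuration for the synthetic breakome generator
#'
#' Defines the study design the generator emulates: five age groups by six
#' tissues with 2-3 replicates per cell (83 samples), per-gene lesion counts
#' with planted positively and negatively age-correlated genes, planted
#' tissue-marker genes, and background noise. Lesion counts per gene are
#' Poisson with per-sample rates renormalized to `lesion_depth` (lesions are
#' rare events at single positions); expression counts are negative binomial
#' (overdispersed). Age enters effects min-max scaled to `[0, 1]` so
#' `age_effect` has a depth-free log-rate interpretation.
#'
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param ages age groups in months.
#' @param tissues tissue labels.
#' @param replicates_per_cell replicates for each (age, tissue) cell.
#' @param old_age_replicates replicates in the oldest age group (the study
#'   design has one fewer animal there).
#' @param drop_one_sample drop one young-brain replicate so the default
#'   design has 83 samples (one sample was lost to quality control in the
#'   emulated design); set `FALSE` for a full factorial.
#' @param n_genes number of genes.
#' @param gene_length_range gene span length range in bp.
#' @param n_age_pos,n_age_neg planted genes whose lesion (and expression)
#'   rates increase / decrease with age.
#' @param n_tissue_markers planted genes elevated in exactly one tissue
#'   (spread evenly across tissues).
#' @param age_effect log-rate slope per unit scaled age (beta), applied with
#'   the gene's sign.
#' @param tissue_effect log-rate elevation of a marker gene in its tissue
#'   (gamma).
#' @param lesion_depth expected total lesion positions per sample per lesion
#'   type.
#' @param expression_depth expected total reads per sample.
#' @param nb_dispersion negative-binomial dispersion of expression counts
#'   (variance = mu + dispersion * mu^2).
#' @param lesion_types lesion types to simulate.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             ages = c(3, 12, 19, 22, 24),
                             tissues = c("brain", "marrow", "heart",
                                         "liver", "pbmc", "sperm"),
                             replicates_per_cell = 3L,
                             old_age_replicates = 2L,
                             drop_one_sample = TRUE,
                             n_genes = 2000L,
                             gene_length_range = c(1000L, 10000L),
                             n_age_pos = 65L,
                             n_age_neg = 35L,
                             n_tissue_markers = 120L,
                             age_effect = 1.0,
                             tissue_effect = 3.0,
                             lesion_depth = 2e5,
                             expression_depth = 2e6,
                             nb_dispersion = 0.1,
                             lesion_types = c("SSB", "AP")) {
  stopifnot(
    n_genes >= 1, lesion_depth > 0, expression_depth > 0,
    age_effect >= 0, tissue_effect >= 0,
    n_age_pos + n_age_neg + n_tissue_markers <= n_genes,
    all(lesion_types %in% c("SSB", "AP"))
  )
  structure(
    list(
      seed = as.integer(seed), ages = ages, tissues = tissues,
      replicates_per_cell = as.integer(replicates_per_cell),
      old_age_replicates = as.integer(old_age_replicates),
      drop_one_sample = isTRUE(drop_one_sample),
      n_genes = as.integer(n_genes),
      gene_length_range = as.integer(gene_length_range),
      n_age_pos = as.integer(n_age_pos), n_age_neg = as.integer(n_age_neg),
      n_tissue_markers = as.integer(n_tissue_markers),
      age_effect = age_effect, tissue_effect = tissue_effect,
      lesion_depth = lesion_depth, expression_depth = expression_depth,
      nb_dispersion = nb_dispersion, lesion_types = lesion_types
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic gene annotation
#'
#' Tiles `n_genes` non-overlapping genes across four synthetic chromosomes.
#' Each gene has 1-5 exons; the first exon starts at the span start and the
#' last ends at the span end, with introns of at least 20 bp between them.
#'
#' @param config a [synthetic_config()].
#' @return a gene-model tibble.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    span <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                   n, replace = TRUE)
    n_exons <- sample(1:5, n, replace = TRUE)
    chrom <- paste0("chrS", (seq_len(n) - 1L) %% 4L + 1L)
    gap <- sample(500:2000, n, replace = TRUE)
    start <- integer(n)
    offset <- c(chrS1 = 0L, chrS2 = 0L, chrS3 = 0L, chrS4 = 0L)
    for (i in seq_len(n)) {
      start[i] <- offset[chrom[i]] + gap[i]
      offset[chrom[i]] <- start[i] + span[i]
    }
    exons <- map(seq_len(n), function(i) {
      k <- n_exons[i]
      if (k == 1L) {
        return(list(start = start[i], end = start[i] + span[i]))
      }
      # 2k - 1 alternating exon/intron segments; each at least 20 bp
      n_seg <- 2L * k - 1L
      cuts <- sort(sample.int(span[i] - 20L * n_seg, n_seg - 1L))
      seg_len <- diff(c(0L, cuts, span[i] - 20L * n_seg)) + 20L
      bounds <- start[i] + cumsum(c(0L, seg_len))
      idx <- seq(1L, n_seg, by = 2L)
      list(start = bounds[idx], end = bounds[idx + 1L])
    })
    gene_models(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = chrom,
      strand = sample(c("+", "-"), n, replace = TRUE),
      exon_starts = map(exons, "start"),
      exon_ends = map(exons, "end")
    )
  })
}

# sample metadata for the configured design
design_metadata <- function(config) {
  cells <- tidyr::expand_grid(
    age_months = config$ages,
    tissue = config$tissues
  )
  old <- max(config$ages)
  md <- cells |>
    mutate(reps = if_else(.data$age_months == old,
                          config$old_age_replicates,
                          config$replicates_per_cell)) |>
    tidyr::uncount(.data$reps, .id = "replicate")
  if (config$drop_one_sample) {
    drop <- which(
      md$age_months == min(config$ages) &
        md$tissue == config$tissues[1] &
        md$replicate == config$replicates_per_cell
    )[1]
    if (!is.na(drop)) md <- md[-drop, ]
  }
  md |>
    mutate(sample_id = sprintf("s%03d", dplyr::row_number()), .before = 1) |>
    select("sample_id", "age_months", "tissue")
}

#' Generate a synthetic dataset with a ground-truth manifest
#'
#' Draws, deterministically from the config seed: sample metadata for the
#' configured design; per-sample lesion maps for each lesion type (per-gene
#' Poisson counts whose log-rates carry the planted age and tissue effects,
#' realized as uniform positions within the gene's exon union with random
#' strand, then deduplicated on position and strand); an expression count
#' matrix (negative binomial with the same planted effects); and a truth
#' manifest naming each gene's role.
#'
#' @param config a [synthetic_config()].
#' @param annotation gene-model tibble from [generate_annotation()]; built
#'   from `config` when `NULL`.
#' @return list with `annotation`, `metadata`, `lesions` (tibble over all
#'   samples and lesion types), `read_counts` (gene x sample tibble),
#'   `truth` (per-gene `role`, `sign`, `marker_tissue`).
#' @export
generate_dataset <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(annotation)) annotation <- generate_annotation(config)
  validate_gene_models(annotation)
  n <- nrow(annotation)
  md <- design_metadata(config)

  withr::with_seed(config$seed + 1L, {
    # gene roles
    roles <- rep("null", n)
    pool <- sample.int(n)
    i1 <- config$n_age_pos
    i2 <- i1 + config$n_age_neg
    i3 <- i2 + config$n_tissue_markers
    roles[pool[seq_len(i1)]] <- "age_pos"
    roles[pool[(i1 + 1):i2]] <- "age_neg"
    if (config$n_tissue_markers > 0) roles[pool[(i2 + 1):i3]] <- "tissue_marker"
    sign <- ifelse(roles == "age_pos", 1L, ifelse(roles == "age_neg", -1L, 0L))
    marker_tissue <- rep(NA_character_, n)
    marker_tissue[roles == "tissue_marker"] <-
      rep_len(config$tissues, config$n_tissue_markers)
    truth <- tibble(
      gene_id = annotation$gene_id, role = roles, sign = sign,
      marker_tissue = marker_tissue,
      age_effect = ifelse(sign != 0L, config$age_effect * sign, 0),
      tissue_effect = ifelse(roles == "tissue_marker", config$tissue_effect, 0)
    )

    # baseline weights: territory size times a lognormal gene factor
    base_lesion <- annotation$exon_union_length * rlnorm(n, 0, 0.5)
    base_expr <- rlnorm(n, 0, 1)

    age_scaled <- (md$age_months - min(config$ages)) /
      (max(config$ages) - min(config$ages))
    log_effect <- function(sample_i) {
      e <- truth$age_effect * age_scaled[sample_i]
      mk <- !is.na(truth$marker_tissue) &
        truth$marker_tissue == md$tissue[sample_i]
      e[mk] <- e[mk] + config$tissue_effect
      e
    }

    # expression counts: NB, per-sample rates renormalized to the depth
    counts <- vapply(seq_len(nrow(md)), function(s) {
      u <- base_expr * exp(log_effect(s))
      mu <- config$expression_depth * u / sum(u)
      rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    }, numeric(n))
    colnames(counts) <- md$sample_id
    zero_frac <- mean(rowSums(counts) == 0)
    if (zero_frac > 0.5) {
      warn(paste0(
        round(100 * zero_frac), "% of genes have all-zero counts; ",
        "expression_depth may be too low"
      ))
    }
    read_counts <- bind_cols(
      tibble(gene_id = annotation$gene_id),
      as_tibble(counts)
    )

    # lesion maps: Poisson counts per gene realized as positions in the
    # exon union, sampled with replacement then deduplicated
    exon_index <- annotation |>
      select("gene_id", "chrom", "exon_starts", "exon_ends") |>
      mutate(gene_idx = dplyr::row_number()) |>
      tidyr::unnest(c("exon_starts", "exon_ends"))
    exon_index <- exon_index |>
      group_by(.data$gene_idx) |>
      mutate(cum_start = cumsum(c(
        0L, head(.data$exon_ends - .data$exon_starts, -1)
      ))) |>
      ungroup()
    big <- 2^31
    exon_key <- exon_index$gene_idx * big + exon_index$cum_start
    ulen <- annotation$exon_union_length

    n_dup_total <- 0L
    lesions <- map(config$lesion_types, function(lt) {
      per_sample <- map(seq_len(nrow(md)), function(s) {
        u <- base_lesion * exp(log_effect(s))
        mu <- config$lesion_depth * u / sum(u)
        r <- rpois(n, mu)
        gene_idx <- rep.int(seq_len(n), r)
        offs <- floor(runif(length(gene_idx)) * ulen[gene_idx])
        row <- findInterval(gene_idx * big + offs, exon_key)
        pos <- exon_index$exon_starts[row] +
          (offs - exon_index$cum_start[row])
        out <- tibble(
          sample_id = md$sample_id[s],
          lesion_type = lt,
          chrom = exon_index$chrom[row],
          position = as.integer(pos),
          strand = sample(c("+", "-"), length(gene_idx), replace = TRUE)
        )
        dedup <- distinct(out, .data$chrom, .data$position, .data$strand,
                          .keep_all = TRUE)
        n_dup_total <<- n_dup_total + (nrow(out) - nrow(dedup))
        dedup
      })
      list_rbind(per_sample)
    }) |> list_rbind()
    inform(paste0(
      "lesion position duplication rate: ",
      signif(n_dup_total / (n_dup_total + nrow(lesions)), 3)
    ))

    list(
      annotation = annotation,
      metadata = md,
      lesions = lesions,
      read_counts = read_counts,
      truth = truth
    )
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes `annotation.gtf`, per-sample BED files under `ssb/` and `ap/`,
#' `counts.tsv`, `metadata.tsv` and `truth.json` into `dir`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(dataset$annotation, file.path(dir, "annotation.gtf"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_feature_matrix(dataset$read_counts, file.path(dir, "counts.tsv"))
  for (lt in unique(dataset$lesions$lesion_type)) {
    sub <- file.path(dir, tolower(lt))
    dir.create(sub, showWarnings = FALSE)
    les <- filter(dataset$lesions, .data$lesion_type == lt)
    for (sid in unique(les$sample_id)) {
      write_lesion_bed(
        filter(les, .data$sample_id == sid),
        file.path(sub, paste0(sid, ".bed"))
      )
    }
  }
  jsonlite::write_json(
    dataset$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}

#' Featurize a synthetic (or real) dataset into LPKM matrices
#'
#' Convenience wrapper: counts lesions of one type per gene, computes the
#' per-sample totals and returns the LPKM feature matrix.
#'
#' @param lesions lesion tibble (all samples, possibly both types).
#' @param annotation gene-model tibble.
#' @param lesion_type `"SSB"` or `"AP"`.
#' @param region_mode `"exon"` or `"whole_gene"`.
#' @param sample_ids column order; defaults to sorted samples present.
#' @param scale LPKM scale constant.
#' @return feature-matrix tibble of LPKM values.
#' @export
featurize_lesions <- function(lesions, annotation,
                              lesion_type = c("SSB", "AP"),
                              region_mode = c("exon", "whole_gene"),
                              sample_ids = NULL, scale = 1e9) {
  lesion_type <- match.arg(lesion_type)
  region_mode <- match.arg(region_mode)
  les <- filter(lesions, .data$lesion_type == !!lesion_type)
  counts <- count_lesions(les, annotation, region_mode = region_mode,
                          sample_ids = sample_ids)
  compute_lpkm(counts, annotation, lesion_totals(les),
               region_mode = region_mode, scale = scale)
}
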