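#' Default supporting-lineage cell types and planted marker programs
#'
#' Builds the per-type marker-gene table used by [simulate_config()]: ten
#' fetal-gonad cell types (pre-supporting PS1/PS2, cycling pre-supporting,
#' pre-Sertoli, Sertoli, granulosa, supporting-like cells, gonad progenitors,
#' Leydig and germ cells), each with a disjoint set of planted marker genes
#' carrying a common natural-log fold change.
#'
#' @param markers_per_type number of planted marker genes per cell type.
#' @param effect natural-log fold change applied to a marker gene's mean in
#'   cells of its own type (1.5 ln-units is approximately 4.5-fold, the scale
#'   of canonical markers such as Sox9/Amh in Sertoli or Foxl2/Fst in
#'   granulosa cells).
#' @return data.frame with columns `gene_id`, `cell_type`, `effect`.
#' @export
default_marker_table <- function(markers_per_type = 50, effect = 1.5) {
  types <- c("PS1", "PS2", "CycPS", "preSertoli", "Sertoli", "granulosa",
             "SLC", "progenitor", "Leydig", "germ")
  data.frame(
    gene_id = sprintf("%s_m%02d", rep(types, each = markers_per_type),
                      rep(seq_len(markers_per_type), length(types))),
    cell_type = rep(types, each = markers_per_type),
    effect = effect,
    stringsAsFactors = FALSE
  )
}

#' Uniform genotype/stage mixture
#'
#' Every (genotype, stage) sample draws its cells uniformly over the given
#' cell types. Used when a balanced per-type cell count is wanted, e.g. for
#' marker-recovery benchmarks.
#'
#' @param cell_types character vector of type names.
#' @param genotypes,stages levels to cross.
#' @return data.frame with one row per (genotype, stage) and one proportion
#'   column per cell type, rows summing to 1.
#' @export
uniform_mixture <- function(cell_types,
                            genotypes = c("XX_WT", "XY_WT", "XY_Zdel"),
                            stages = c(11.5, 12.5, 14.5)) {
  grid <- expand.grid(genotype = genotypes, stage = stages,
                      stringsAsFactors = FALSE)
  p <- matrix(1 / length(cell_types), nrow(grid), length(cell_types),
              dimnames = list(NULL, cell_types))
  cbind(grid, as.data.frame(p))
}

#' Stage- and genotype-structured mixture of gonadal cell types
#'
#' Emulates the broad compositional shifts of fetal gonad development:
#' progenitors and pre-supporting cells dominate at 11.5 dpc; Sertoli cells
#' expand in XY wild-type gonads and granulosa cells in XX gonads by
#' 14.5 dpc; XY Znrf3-null gonads acquire granulosa cells at the expense of
#' Sertoli cells (partial sex reversal); Leydig cells appear late in
#' testes. Proportions are design choices, not estimates.
#'
#' @return data.frame as in [uniform_mixture()].
#' @export
default_mixture <- function() {
  types <- c("PS1", "PS2", "CycPS", "preSertoli", "Sertoli", "granulosa",
             "SLC", "progenitor", "Leydig", "germ")
  row <- function(genotype, stage, p) {
    stopifnot(abs(sum(p) - 1) < 1e-9)
    out <- data.frame(genotype = genotype, stage = stage)
    out[types] <- as.list(p)
    out
  }
  rbind(
    row("XX_WT",   11.5, c(.22, .18, .12, .02, .00, .04, .06, .24, .00, .12)),
    row("XY_WT",   11.5, c(.22, .18, .12, .08, .02, .00, .06, .20, .00, .12)),
    row("XY_Zdel", 11.5, c(.22, .18, .12, .06, .02, .02, .06, .20, .00, .12)),
    row("XX_WT",   12.5, c(.14, .12, .10, .02, .00, .22, .08, .16, .00, .16)),
    row("XY_WT",   12.5, c(.10, .08, .08, .10, .24, .00, .08, .14, .02, .16)),
    row("XY_Zdel", 12.5, c(.10, .08, .08, .08, .14, .12, .08, .14, .02, .16)),
    row("XX_WT",   14.5, c(.06, .06, .06, .02, .00, .40, .10, .10, .00, .20)),
    row("XY_WT",   14.5, c(.04, .04, .04, .06, .40, .00, .08, .08, .06, .20)),
    row("XY_Zdel", 14.5, c(.04, .04, .04, .04, .24, .20, .08, .08, .04, .20))
  )
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic fetal-gonad
#' scRNA-seq generator. Counts follow a negative binomial with per-gene mean
#' `nb_mean` (marker genes have their mean multiplied by `exp(effect)` in
#' cells of their type) and dispersion `nb_dispersion` (variance
#' `mu + dispersion * mu^2`). Per-cell library size varies log-normally.
#' A `dp_fraction` of Sertoli and granulosa cells are converted to latent
#' double-positive (DP) cells expressing both the Sertoli and the granulosa
#' program at `dp_attenuation` of the full effect.
#'
#' @param n_cells_per_type target mean number of cells per type over the
#'   whole dataset (total cells = `n_cells_per_type * n types`).
#' @param marker_table data.frame(gene_id, cell_type, effect) of planted
#'   markers; defaults to [default_marker_table()].
#' @param n_background_genes uninformative genes added on top of markers.
#' @param nb_mean baseline expected count per gene per cell.
#' @param nb_dispersion negative-binomial dispersion (1/size); > 0.
#' @param dp_fraction fraction of Sertoli/granulosa cells drawn as DP.
#' @param dp_attenuation multiplier applied to both programs in DP cells.
#' @param mixture data.frame mapping (genotype, stage) to cell-type
#'   proportions; defaults to [default_mixture()].
#' @param n_samples_per_group replicate samples per (genotype, stage).
#' @param libsize_sigma sd of the per-cell log-normal library-size factor.
#' @param mito_fraction_range range of the per-cell mitochondrial fraction.
#' @param n_mito_genes number of "mt-" genes carrying that fraction.
#' @param allow_marker_overlap if FALSE (default), overlapping Sertoli and
#'   granulosa marker sets are rejected.
#' @param seed integer seed; generation is reproducible given the config.
#' @return object of class `sim_config`.
#' @export
simulate_config <- function(n_cells_per_type = 200,
                            marker_table = default_marker_table(),
                            n_background_genes = 1500,
                            nb_mean = 0.2,
                            nb_dispersion = 0.5,
                            dp_fraction = 0.1,
                            dp_attenuation = 0.7,
                            mixture = default_mixture(),
                            n_samples_per_group = 2,
                            libsize_sigma = 0.3,
                            mito_fraction_range = c(0.02, 0.10),
                            n_mito_genes = 13,
                            allow_marker_overlap = FALSE,
                            seed = 1L) {
  stopifnot(n_cells_per_type > 0, n_background_genes >= 0,
            nb_mean > 0, nb_dispersion > 0,
            dp_fraction >= 0, dp_fraction <= 1, dp_attenuation >= 0,
            libsize_sigma >= 0, length(mito_fraction_range) == 2,
            all(mito_fraction_range >= 0), all(mito_fraction_range <= 1),
            all(is.finite(marker_table$effect)))
  types <- setdiff(colnames(mixture), c("genotype", "stage"))
  if (!all(marker_table$cell_type %in% types))
    stop("marker_table contains cell types absent from the mixture table")
  psum <- rowSums(mixture[types])
  if (any(abs(psum - 1) > 1e-9))
    stop("mixture proportions must sum to 1 per (genotype, stage) row")
  if (!allow_marker_overlap) {
    s <- marker_table$gene_id[marker_table$cell_type == "Sertoli"]
    g <- marker_table$gene_id[marker_table$cell_type == "granulosa"]
    if (length(intersect(s, g)))
      stop("Sertoli and granulosa marker sets overlap; ",
           "set allow_marker_overlap = TRUE to permit this")
  }
  if (anyDuplicated(marker_table$gene_id))
    stop("duplicate gene_id in marker_table")
  structure(list(
    n_cells_per_type = as.integer(n_cells_per_type),
    marker_table = marker_table, n_background_genes = n_background_genes,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    dp_fraction = dp_fraction, dp_attenuation = dp_attenuation,
    mixture = mixture, cell_types = types,
    n_samples_per_group = as.integer(n_samples_per_group),
    libsize_sigma = libsize_sigma,
    mito_fraction_range = mito_fraction_range,
    n_mito_genes = as.integer(n_mito_genes), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a fetal-gonad scRNA-seq dataset
#'
#' Draws a sparse gene-by-cell count matrix, per-cell metadata and a ground
#' truth table from a [simulate_config()]. Each sample is one (genotype,
#' stage, replicate); its cells' types are multinomial draws from the
#' configured mixture. Marker genes of a cell's type have their negative
#' binomial mean multiplied by `exp(effect)`; latent DP cells carry both the
#' Sertoli and the granulosa program at attenuated effect, but keep their
#' original cell-type label (the truth table records `true_type` and
#' `is_dp_truth`).
#'
#' @param config a `sim_config`.
#' @return list with `counts` (dgCMatrix, genes x cells), `cells`
#'   (data.frame: cell_id, sample_id, genotype, stage, cell_type,
#'   total_counts, n_genes_expressed, pct_mito, true_type, is_dp_truth) and
#'   `truth` (the marker table).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mt <- config$marker_table
  types <- config$cell_types
  n_types <- length(types)
  total_cells <- config$n_cells_per_type * n_types
  if (total_cells <= 0) stop("zero cells requested")

  mito_genes <- if (config$n_mito_genes > 0)
    sprintf("mt-%d", seq_len(config$n_mito_genes)) else character()
  bg_genes <- if (config$n_background_genes > 0)
    sprintf("gene%05d", seq_len(config$n_background_genes)) else character()
  gene_ids <- c(mt$gene_id, bg_genes, mito_genes)
  stopifnot(!anyDuplicated(gene_ids))
  n_genes <- length(gene_ids)

  # baseline mean vector; effect multipliers applied per cell class below
  base_mu <- rep(config$nb_mean, n_genes)
  names(base_mu) <- gene_ids
  marker_idx <- split(match(mt$gene_id, gene_ids), mt$cell_type)
  marker_eff <- split(mt$effect, mt$cell_type)
  mito_idx <- match(mito_genes, gene_ids)

  n_groups <- nrow(config$mixture)
  n_samples <- n_groups * config$n_samples_per_group
  cells_per_sample <- rep(floor(total_cells / n_samples), n_samples)
  rem <- total_cells - sum(cells_per_sample)
  if (rem > 0) cells_per_sample[seq_len(rem)] <- cells_per_sample[seq_len(rem)] + 1

  cell_meta <- vector("list", n_samples)
  trip_i <- vector("list", n_samples)  # MTX-style triplets per sample
  trip_j <- vector("list", n_samples)
  trip_x <- vector("list", n_samples)
  size <- 1 / config$nb_dispersion
  cell_offset <- 0L
  samp <- 0L
  for (g in seq_len(n_groups)) {
    props <- as.numeric(config$mixture[g, types])
    for (r in seq_len(config$n_samples_per_group)) {
      samp <- samp + 1L
      nc <- cells_per_sample[samp]
      sample_id <- sprintf("%s_%s_r%d", config$mixture$genotype[g],
                           config$mixture$stage[g], r)
      ct <- sample(types, nc, replace = TRUE, prob = props)
      is_dp <- ct %in% c("Sertoli", "granulosa") &
        stats::runif(nc) < config$dp_fraction
      lib <- stats::rlnorm(nc, 0, config$libsize_sigma)
      mito_frac <- stats::runif(nc, config$mito_fraction_range[1],
                                config$mito_fraction_range[2])
      m <- matrix(0L, n_genes, nc)
      for (k in seq_len(nc)) {
        mu <- base_mu
        if (is_dp[k]) {
          for (tt in c("Sertoli", "granulosa"))
            mu[marker_idx[[tt]]] <- mu[marker_idx[[tt]]] *
              exp(config$dp_attenuation * marker_eff[[tt]])
        } else if (!is.null(marker_idx[[ct[k]]])) {
          mu[marker_idx[[ct[k]]]] <- mu[marker_idx[[ct[k]]]] *
            exp(marker_eff[[ct[k]]])
        }
        if (length(mito_idx)) {
          # scale mito means so their expected share of the cell total
          # matches the drawn mitochondrial fraction
          non_mito <- sum(mu[-mito_idx])
          mu[mito_idx] <- mito_frac[k] / (1 - mito_frac[k]) *
            non_mito / length(mito_idx)
        }
        m[, k] <- stats::rnbinom(n_genes, size = size, mu = mu * lib[k])
      }
      nz <- which(m != 0L, arr.ind = TRUE)
      trip_i[[samp]] <- nz[, 1]
      trip_j[[samp]] <- nz[, 2] + cell_offset
      trip_x[[samp]] <- m[nz]
      cell_meta[[samp]] <- data.frame(
        cell_id = sprintf("cell%06d", cell_offset + seq_len(nc)),
        sample_id = sample_id,
        genotype = config$mixture$genotype[g],
        stage = config$mixture$stage[g],
        cell_type = ct,
        total_counts = colSums(m),
        n_genes_expressed = colSums(m > 0L),
        pct_mito = if (length(mito_idx))
          100 * colSums(m[mito_idx, , drop = FALSE]) / pmax(colSums(m), 1)
          else NA_real_,
        true_type = ifelse(is_dp, "DP", ct),
        is_dp_truth = is_dp,
        stringsAsFactors = FALSE
      )
      cell_offset <- cell_offset + nc
    }
  }
  cells <- do.call(rbind, cell_meta)
  rownames(cells) <- NULL
  counts <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n_genes, total_cells),
    dimnames = list(gene_ids, cells$cell_id)
  )
  list(counts = counts, cells = cells, truth = mt)
}

#' Write a count matrix and cell table as a plain-text fixture
#'
#' Writes the CellRanger-style triplet `matrix.mtx` (MatrixMarket coordinate
#' integer), `features.tsv`, `barcodes.tsv`, plus `cells.tsv` with the
#' per-cell metadata. Round-trips with [read_fixture()].
#'
#' @param counts genes x cells integer sparse/dense matrix with dimnames.
#' @param cells per-cell metadata data.frame (cell_id first column);
#'   NULL to skip.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(counts, cells = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cells)) {
    stopifnot(identical(colnames(counts), cells$cell_id))
    utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  m <- methods::as(methods::as(counts, "generalMatrix"), "TsparseMatrix")
  # Matrix::writeMM emits a "real" header; the fixture format is integer
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x))
    writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  close(con)
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir directory holding matrix.mtx / features.tsv / barcodes.tsv and
#'   optionally cells.tsv.
#' @return list(counts, cells) — `cells` is NULL when cells.tsv is absent.
#' @export
read_fixture <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  dimnames(counts) <- list(readLines(file.path(dir, "features.tsv")),
                           readLines(file.path(dir, "barcodes.tsv")))
  cells_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cells_path))
    utils::read.table(cells_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  list(counts = counts, cells = cells)
}
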