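#' Quality-control percentile thresholds
#'
#' Per-sample filters remove cells falling strictly below the low or strictly
#' above the high percentile of total counts, genes expressed and percent
#' mitochondrial RNA; a global filter then removes cells in the bottom
#' `global_count_pct` percentile of total counts across all retained cells.
#' Percentiles are linear-interpolation quantiles (type 7).
#'
#' @param count_pct,genes_pct,mito_pct length-2 (low, high) percentile pairs.
#' @param global_count_pct low percentile of the dataset-wide count filter.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(count_pct = c(2, 98),
                          genes_pct = c(2, 98),
                          mito_pct = c(2, 95),
                          global_count_pct = 5) {
  chk <- function(p) stopifnot(length(p) == 2, p[1] >= 0, p[1] < p[2],
                               p[2] <= 100)
  chk(count_pct); chk(genes_pct); chk(mito_pct)
  stopifnot(global_count_pct >= 0, global_count_pct <= 100)
  structure(list(count_pct = count_pct, genes_pct = genes_pct,
                 mito_pct = mito_pct, global_count_pct = global_count_pct),
            class = "qc_thresholds")
}

#' Remove low-quality cells
#'
#' Applies the percentile filters of [qc_thresholds()] first per sample
#' (total counts, genes expressed, percent mitochondrial RNA), then the
#' global bottom-percentile count filter over the retained cells. Removal is
#' strict: a cell is dropped when its value is < the low-percentile value or
#' > the high-percentile value. Samples with fewer than `min_sample_cells`
#' cells skip the per-sample filters (warning). If a logical `is_doublet`
#' column is present, flagged cells are removed first.
#'
#' @param counts genes x cells count matrix.
#' @param cells per-cell metadata with `cell_id`, `sample_id` and (if
#'   absent, computed here) `total_counts`, `n_genes_expressed`; `pct_mito`
#'   optional — the mito filter is skipped with a warning when missing.
#' @param thresholds a [qc_thresholds()].
#' @param min_sample_cells minimum sample size for per-sample percentiles.
#' @return list(counts, cells, report) — report rows give (rule, sample,
#'   n_removed).
#' @export
filter_cells <- function(counts, cells, thresholds = qc_thresholds(),
                         min_sample_cells = 10) {
  stopifnot(identical(colnames(counts), cells$cell_id),
            !is.null(cells$sample_id))
  if (is.null(cells$total_counts))
    cells$total_counts <- Matrix::colSums(counts)
  if (is.null(cells$n_genes_expressed))
    cells$n_genes_expressed <- Matrix::colSums(counts > 0)
  report <- data.frame(rule = character(), sample = character(),
                       n_removed = integer(), stringsAsFactors = FALSE)
  add <- function(rule, sample, n)
    rbind(report, data.frame(rule = rule, sample = sample, n_removed = n))
  keep <- rep(TRUE, nrow(cells))

  if (!is.null(cells$is_doublet)) {
    drop <- keep & cells$is_doublet %in% TRUE
    report <- add("doublet", "all", sum(drop))
    keep[drop] <- FALSE
  }

  pct_band <- function(x, p) {
    lo <- stats::quantile(x, p[1] / 100, type = 7, names = FALSE)
    hi <- stats::quantile(x, p[2] / 100, type = 7, names = FALSE)
    x < lo | x > hi
  }
  have_mito <- !is.null(cells$pct_mito) && !all(is.na(cells$pct_mito))
  if (!have_mito)
    warning("pct_mito not available; mitochondrial filter skipped")

  for (s in unique(cells$sample_id)) {
    in_s <- which(keep & cells$sample_id == s)
    if (length(in_s) < min_sample_cells) {
      warning(sprintf("sample %s has %d cells; per-sample filters skipped",
                      s, length(in_s)))
      next
    }
    rules <- list(counts = list(cells$total_counts, thresholds$count_pct),
                  genes  = list(cells$n_genes_expressed, thresholds$genes_pct))
    if (have_mito)
      rules$mito <- list(cells$pct_mito, thresholds$mito_pct)
    for (rn in names(rules)) {
      in_s <- in_s[keep[in_s]]
      bad <- pct_band(rules[[rn]][[1]][in_s], rules[[rn]][[2]])
      report <- add(paste0("sample_", rn), s, sum(bad))
      keep[in_s[bad]] <- FALSE
    }
  }
  retained <- which(keep)
  lo <- stats::quantile(cells$total_counts[retained],
                        thresholds$global_count_pct / 100,
                        type = 7, names = FALSE)
  bad <- cells$total_counts[retained] < lo
  report <- add("global_counts", "all", sum(bad))
  keep[retained[bad]] <- FALSE

  list(counts = counts[, keep, drop = FALSE],
       cells = cells[keep, , drop = FALSE],
       report = report)
}

#' Library-size normalisation with highly-expressed genes excluded
#'
#' Scales each cell to a target sum of 10,000 counts, where the per-cell
#' size factor is computed from the counts of genes *outside* the top 5%
#' most highly expressed (by total count across cells), then applies
#' log(1 + x). Excluded genes are still scaled and logged; they are only
#' left out of the size-factor sums. Cells whose non-excluded sum is zero
#' fall back to the total sum (warning).
#'
#' @param counts genes x cells count matrix (sparse ok), nonempty.
#' @param target_sum target scaled sum per cell.
#' @param exclude_top_frac fraction of genes excluded from size-factor sums.
#' @return list(values [sparse, log1p-scaled], size_factors, excluded_genes).
#' @export
normalize_counts <- function(counts, target_sum = 1e4,
                             exclude_top_frac = 0.05) {
  stopifnot(nrow(counts) > 0, ncol(counts) > 0)
  counts <- methods::as(counts, "CsparseMatrix")
  gene_tot <- Matrix::rowSums(counts)
  n_excl <- floor(exclude_top_frac * nrow(counts))
  excluded <- if (n_excl > 0)
    rownames(counts)[order(gene_tot, decreasing = TRUE)[seq_len(n_excl)]]
    else character()
  incl <- !(rownames(counts) %in% excluded)
  sums <- Matrix::colSums(counts[incl, , drop = FALSE])
  zero <- sums == 0
  if (any(zero)) {
    warning(sprintf(
      "%d cell(s) with zero non-excluded counts; size factor from total sum",
      sum(zero)))
    sums[zero] <- Matrix::colSums(counts)[zero]
    sums[sums == 0] <- 1  # all-zero cell: leave values at 0
  }
  sf <- sums / target_sum
  values <- counts %*% Matrix::Diagonal(x = 1 / sf)
  values@x <- log1p(values@x)
  dimnames(values) <- dimnames(counts)
  list(values = methods::as(values, "CsparseMatrix"),
       size_factors = stats::setNames(sf, colnames(counts)),
       excluded_genes = excluded)
}

#' Module score: mean expression of a gene set minus bin-matched controls
#'
#' @noRd
module_score <- function(values, genes, n_bins, n_ctrl) {
  genes <- intersect(genes, rownames(values))
  if (!length(genes)) stop("gene set has no genes present in the matrix")
  avg <- Matrix::rowMeans(values)
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  ctrl <- unique(unlist(lapply(genes, function(g) {
    pool <- setdiff(rownames(values)[bin == bin[match(g, rownames(values))]],
                    genes)
    if (!length(pool)) return(character())
    pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
  })))
  set_mean <- Matrix::colMeans(values[genes, , drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    Matrix::colMeans(values[ctrl, , drop = FALSE]) else 0
  set_mean - ctrl_mean
}

#' Assign cell-cycle phases from S and G2/M gene-set scores
#'
#' Computes a module score per set — mean log-normalised expression of the
#' set genes minus the mean of control genes drawn from matching average
#' expression bins — and calls the phase: S when the S score exceeds the
#' G2/M score and is positive, G2M when the G2/M score is at least the S
#' score and positive, else G1. Run per sample when `sample_id` is given.
#'
#' @param values genes x cells log-normalised matrix.
#' @param s_genes,g2m_genes disjoint character vectors of cycle genes.
#' @param n_bins expression bins for control matching (default 25).
#' @param n_ctrl control genes drawn per set gene (default 100).
#' @param sample_id optional per-cell sample factor; scoring is then done
#'   within each sample.
#' @param seed integer seed for the control draws.
#' @return data.frame(cell_id, s_score, g2m_score, phase).
#' @export
assign_cell_cycle <- function(values, s_genes, g2m_genes, n_bins = 25,
                              n_ctrl = 100, sample_id = NULL, seed = 1L) {
  if (!length(s_genes) || !length(g2m_genes)) stop("empty cycle gene set")
  if (length(intersect(s_genes, g2m_genes)))
    stop("s_genes and g2m_genes must be disjoint")
  score_block <- function(v) {
    set.seed(seed)
    s <- module_score(v, s_genes, n_bins, n_ctrl)
    g2m <- module_score(v, g2m_genes, n_bins, n_ctrl)
    data.frame(cell_id = colnames(v), s_score = s, g2m_score = g2m,
               stringsAsFactors = FALSE)
  }
  out <- if (is.null(sample_id)) score_block(values) else {
    stopifnot(length(sample_id) == ncol(values))
    do.call(rbind, lapply(split(seq_len(ncol(values)), sample_id),
                          function(i) score_block(values[, i, drop = FALSE])))
  }
  out <- out[match(colnames(values), out$cell_id), ]
  rownames(out) <- NULL
  out$phase <- ifelse(out$s_score > out$g2m_score & out$s_score > 0, "S",
                      ifelse(out$g2m_score >= out$s_score &
                               out$g2m_score > 0, "G2M", "G1"))
  out
}
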