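#' Per-sample cell-type proportions
#'
#' Computes, per sample, the proportion of each included cell type
#' (excluded types — e.g. blood, immune, mesothelial, endothelial clusters —
#' are dropped before renormalising). Types with zero cells in a sample are
#' kept with proportion 0; samples left with zero included cells are
#' dropped with a warning.
#'
#' @param cells metadata with sample_id, genotype, stage, cell_type.
#' @param exclude cell types to exclude.
#' @return data.frame(sample_id, genotype, stage, cell_type, n_cells,
#'   proportion) of class `proportion_table`.
#' @export
cell_type_proportions <- function(cells, exclude = character()) {
  stopifnot(all(c("sample_id", "cell_type") %in% names(cells)))
  keep <- !(cells$cell_type %in% exclude)
  types <- sort(unique(cells$cell_type[keep]))
  out <- lapply(split(which(keep), cells$sample_id[keep], drop = TRUE),
                function(i) {
    n <- table(factor(cells$cell_type[i], levels = types))
    data.frame(sample_id = cells$sample_id[i[1]],
               genotype = if ("genotype" %in% names(cells))
                 cells$genotype[i[1]] else NA,
               stage = if ("stage" %in% names(cells))
                 cells$stage[i[1]] else NA,
               cell_type = types, n_cells = as.integer(n),
               proportion = as.numeric(n) / length(i),
               stringsAsFactors = FALSE)
  })
  dropped <- setdiff(unique(cells$sample_id), names(out))
  if (length(dropped))
    warning("samples with no included cells dropped: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("proportion_table", "data.frame")
  out
}

#' Pairwise chi-square tests of cell-type proportions between genotypes
#'
#' For each cell type and pair of genotype levels, counts are pooled across
#' samples (within each genotype) into a 2x2 table of (in-type, out-of-type)
#' cells and tested by chi-square (no continuity correction by default), or
#' Fisher's exact test when any expected count is below 5 (flagged).
#' Benjamini-Hochberg q-values are computed across all tests in the run.
#'
#' @param pt a [cell_type_proportions()] table (counts are used, not
#'   proportions).
#' @param compare_on grouping column whose levels are compared (default
#'   genotype).
#' @param correct Yates continuity correction.
#' @return data.frame(cell_type, group1, group2, statistic, p, method, q).
#' @export
compare_proportions <- function(pt, compare_on = "genotype",
                                correct = FALSE) {
  stopifnot(inherits(pt, "data.frame"), compare_on %in% names(pt))
  groups <- sort(unique(as.character(pt[[compare_on]])))
  if (length(groups) < 2) stop("need >= 2 groups to compare")
  totals <- tapply(pt$n_cells, pt[[compare_on]], sum)
  res <- list()
  for (ct in sort(unique(pt$cell_type))) {
    in_type <- tapply(pt$n_cells[pt$cell_type == ct],
                      pt[[compare_on]][pt$cell_type == ct], sum)
    for (i in seq_len(length(groups) - 1))
      for (j in seq(i + 1, length(groups))) {
        g1 <- groups[i]; g2 <- groups[j]
        a <- if (g1 %in% names(in_type)) in_type[[g1]] else 0
        b <- if (g2 %in% names(in_type)) in_type[[g2]] else 0
        m <- rbind(c(a, totals[[g1]] - a), c(b, totals[[g2]] - b))
        t2 <- test_2x2(m, correct = correct)
        res[[length(res) + 1]] <- data.frame(
          cell_type = ct, group1 = g1, group2 = g2,
          statistic = t2$statistic, p = t2$p, method = t2$method,
          stringsAsFactors = FALSE)
      }
  }
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' PCA of per-sample cell-type proportions
#'
#' Centred (unscaled) principal component analysis of the sample x cell-type
#' proportion matrix, summarising compositional variation across samples.
#'
#' @param pt a [cell_type_proportions()] table (>= 3 samples).
#' @return list(coordinates = sample x PC matrix, explained_variance =
#'   per-component fraction, sample_info = genotype/stage per sample).
#' @export
pca_proportions <- function(pt) {
  wide <- stats::xtabs(proportion ~ sample_id + cell_type, data = pt)
  m <- matrix(wide, nrow(wide), ncol(wide), dimnames = dimnames(wide))
  if (nrow(m) < 3) stop("need at least 3 samples for PCA")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  info <- unique(pt[c("sample_id", "genotype", "stage")])
  list(coordinates = pc$x,
       explained_variance = if (sum(ev) > 0) ev / sum(ev) else ev * 0,
       sample_info = info[match(rownames(pc$x), info$sample_id), ])
}

#' Wilcoxon rank-sum comparisons of identity scores between groups
#'
#' Two-sided unpaired Wilcoxon tests of each score column between all pairs
#' of group levels: exact when both groups have <= `exact_max` observations
#' and there are no ties, normal approximation with continuity correction
#' otherwise. Benjamini-Hochberg q-values across all comparisons in the run.
#'
#' @param scores data.frame with cell_id and the score columns.
#' @param cells metadata aligned by cell_id with the grouping column.
#' @param group_col grouping column name (e.g. "genotype").
#' @param score_cols score columns to compare (default sci and gci).
#' @param exact_max largest per-group n for the exact test.
#' @return data.frame(score, group1, group2, statistic, p, q).
#' @export
compare_scores <- function(scores, cells, group_col = "genotype",
                           score_cols = c("sci", "gci"), exact_max = 25) {
  g <- cells[[group_col]][match(scores$cell_id, cells$cell_id)]
  groups <- sort(unique(as.character(g)))
  res <- list()
  for (sc in score_cols) for (i in seq_len(length(groups) - 1))
    for (j in seq(i + 1, length(groups))) {
      x <- scores[[sc]][g == groups[i]]
      y <- scores[[sc]][g == groups[j]]
      if (length(x) < 2 || length(y) < 2)
        stop("each group needs >= 2 cells")
      w <- stats::wilcox.test(x, y, alternative = "two.sided",
                              exact = length(x) <= exact_max &
                                length(y) <= exact_max,
                              correct = TRUE)
      res[[length(res) + 1]] <- data.frame(
        score = sc, group1 = groups[i], group2 = groups[j],
        statistic = unname(w$statistic), p = w$p.value,
        stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
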