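#' Fit the double-positive hyperbola boundary
#'
#' The boundary `b` is the 97.5th percentile (linear interpolation) of GCI
#' among reference cells — by default wild-type XX granulosa cells at
#' 14.5 dpc — and `a` is a fixed scaling factor of 10. A cell is called
#' double positive when it lies inside the rectangular-hyperbola region
#' `sci * gci >= a * b` (see [is_double_positive()]).
#'
#' @param scores data.frame(cell_id, sci, gci) from [score_cells()].
#' @param cells per-cell metadata aligned by cell_id.
#' @param reference named list of metadata filters selecting the reference
#'   cells.
#' @param a scaling factor (default 10).
#' @param pct percentile of reference GCI defining `b` (default 97.5).
#' @param min_reference_cells minimum reference population size.
#' @return object of class `dp_params`: a, b, reference, pct, n_reference.
#' @export
fit_dp_boundary <- function(scores, cells,
                            reference = list(genotype = "XX_WT",
                                             stage = 14.5,
                                             cell_type = "granulosa"),
                            a = 10, pct = 97.5, min_reference_cells = 20) {
  stopifnot(a > 0)
  use <- rep(TRUE, nrow(cells))
  for (col in names(reference)) use <- use & cells[[col]] %in% reference[[col]]
  if (!any(use))
    stop("no reference cells match: ",
         paste(names(reference), sapply(reference, paste, collapse = "/"),
               sep = "=", collapse = ", "))
  if (sum(use) < min_reference_cells)
    stop(sprintf("only %d reference cells (< %d required)",
                 sum(use), min_reference_cells))
  gci <- scores$gci[match(cells$cell_id[use], scores$cell_id)]
  b <- stats::quantile(gci, pct / 100, type = 7, names = FALSE)
  if (b <= 0) stop("reference GCI percentile is not positive")
  structure(list(a = a, b = b, reference = reference, pct = pct,
                 n_reference = sum(use)), class = "dp_params")
}

#' Is a cell inside the double-positive region?
#'
#' TRUE when `sci * gci >= a * b`: the region above a rectangular hyperbola
#' whose asymptotes are the axes, so cells scoring 0 on either identity are
#' never double positive, and jointly elevated, similar SCI and GCI are.
#' Boundary equality counts as inside. Vectorised.
#'
#' @param sci,gci identity scores in \[0, 100\].
#' @param params a [fit_dp_boundary()] result (or any list with a, b).
#' @return logical vector.
#' @export
is_double_positive <- function(sci, gci, params) {
  stopifnot(params$a > 0, params$b > 0)
  sci * gci >= params$a * params$b
}

#' Double-positive proportions per group with chi-square comparisons
#'
#' Tabulates the DP proportion per group (default genotype x stage x
#' cell_type) and tests pairwise genotype differences within each
#' (stage, cell_type) stratum with a 2x2 chi-square on (DP, non-DP) counts,
#' Benjamini-Hochberg corrected across all comparisons. When any expected
#' count is below 5 the comparison switches to Fisher's exact test and is
#' flagged.
#'
#' @param cells metadata with `is_dp` plus the grouping columns.
#' @param group_by columns defining groups.
#' @param compare_on column whose levels are compared pairwise (within the
#'   remaining group_by strata).
#' @param correct Yates continuity correction for the chi-square.
#' @return list(proportions, comparisons).
#' @export
dp_proportions <- function(cells, group_by = c("genotype", "stage",
                                               "cell_type"),
                           compare_on = "genotype", correct = FALSE) {
  stopifnot(!is.null(cells$is_dp), all(group_by %in% names(cells)))
  grp <- interaction(cells[group_by], drop = TRUE, sep = ":")
  tab <- do.call(rbind, lapply(split(seq_len(nrow(cells)), grp), function(i) {
    out <- cells[i[1], group_by, drop = FALSE]
    out$n <- length(i)
    out$n_dp <- sum(cells$is_dp[i])
    out$proportion <- out$n_dp / out$n
    out
  }))
  rownames(tab) <- NULL
  tab <- tab[tab$n > 0, , drop = FALSE]

  strata_cols <- setdiff(group_by, compare_on)
  strata <- if (length(strata_cols))
    interaction(tab[strata_cols], drop = TRUE, sep = ":")
    else factor(rep("all", nrow(tab)))
  cmp <- list()
  for (s in levels(strata)) {
    rows <- tab[strata == s, , drop = FALSE]
    lv <- unique(rows[[compare_on]])
    if (length(lv) < 2) next
    for (i in seq_len(length(lv) - 1)) for (j in seq(i + 1, length(lv))) {
      r1 <- rows[rows[[compare_on]] == lv[i], ][1, ]
      r2 <- rows[rows[[compare_on]] == lv[j], ][1, ]
      m <- rbind(c(r1$n_dp, r1$n - r1$n_dp), c(r2$n_dp, r2$n - r2$n_dp))
      res <- test_2x2(m, correct = correct)
      cmp[[length(cmp) + 1]] <- data.frame(
        stratum = s, group1 = lv[i], group2 = lv[j],
        statistic = res$statistic, p = res$p, method = res$method,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(cmp)) do.call(rbind, cmp) else
    data.frame(stratum = character(), group1 = character(),
               group2 = character(), statistic = numeric(), p = numeric(),
               method = character())
  comparisons$q <- stats::p.adjust(comparisons$p, method = "BH")
  list(proportions = tab, comparisons = comparisons)
}

# 2x2 association test: chi-square, or Fisher when any expected count < 5
test_2x2 <- function(m, correct = FALSE) {
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    list(statistic = NA_real_, p = stats::fisher.test(m)$p.value,
         method = "fisher")
  } else {
    t <- suppressWarnings(stats::chisq.test(m, correct = correct))
    list(statistic = unname(t$statistic), p = t$p.value,
         method = if (correct) "chisq_yates" else "chisq")
  }
}
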