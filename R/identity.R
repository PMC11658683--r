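#' ROC AUC by the exact Mann-Whitney rank-sum formula
#'
#' Returns P(X_pos > X_neg) + 0.5 P(X_pos = X_neg), computed from rank sums
#' with midranks for ties — identical to the area under the empirical ROC
#' curve of `values` as a classifier for `labels`.
#'
#' @param values numeric scores, one per observation.
#' @param labels logical (or 0/1) class membership; both classes nonempty.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be nonempty")
  r <- rank(values, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# binomial GLM fit without the formula interface; returns coefficients
# (intercept first) with NAs for aliased columns
glm_fit_quiet <- function(x, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                   family = stats::binomial()))
  fit$coefficients
}

glm_predict <- function(coefs, x) {
  coefs[is.na(coefs)] <- 0
  stats::plogis(drop(cbind(1, x) %*% coefs))
}

#' Rank genes by single-gene discrimination of a target cell type
#'
#' Within a scope (e.g. the XY samples for Sertoli, the XX samples for
#' granulosa), each expressed gene is scored by how well it separates target
#' cells from all other cells. With `method = "glm"` a single-predictor
#' binomial GLM is fitted per gene and the AUC of its fitted scores is used;
#' `method = "rank"` computes the Mann-Whitney AUC of the raw expression
#' directly. The two are equivalent for ranking: the GLM's fitted
#' probability is a monotone transform of expression, so its AUC equals the
#' raw AUC (or its complement when the slope is negative), and genes are
#' ranked by |AUC - 0.5| either way.
#'
#' @param values genes x cells log-normalised matrix.
#' @param cells per-cell metadata with `cell_type` (and columns named in
#'   `scope`).
#' @param target target cell type (the positive class).
#' @param scope optional named list of metadata filters, e.g.
#'   `list(genotype = c("XY_WT"))`; cells failing any filter are dropped.
#' @param min_cells genes expressed in fewer scoped cells are excluded.
#' @param method "glm" (as described) or "rank" (fast equivalent).
#' @return data.frame(gene_id, auc, direction, rank) of class
#'   `gene_ranking`, sorted by |auc - 0.5| descending; `auc` is the raw
#'   expression AUC, `direction` is "positive" when auc > 0.5.
#' @export
rank_genes <- function(values, cells, target, scope = NULL, min_cells = 3,
                       method = c("glm", "rank")) {
  method <- match.arg(method)
  stopifnot(identical(colnames(values), cells$cell_id))
  use <- rep(TRUE, nrow(cells))
  for (col in names(scope)) use <- use & cells[[col]] %in% scope[[col]]
  v <- values[, use, drop = FALSE]
  lab <- cells$cell_type[use] == target
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop("need at least 2 target and 2 non-target cells in scope")
  expressed <- Matrix::rowSums(v > 0) >= min_cells
  v <- as.matrix(v[expressed, , drop = FALSE])
  auc <- apply(v, 1, function(x) {
    if (method == "glm") {
      coefs <- glm_fit_quiet(matrix(x), lab)
      coefs[is.na(coefs)] <- 0
      # AUC of the fitted scores: plogis(a + b x) is monotone in sign(b) x,
      # so score it as sign(b) x — same AUC in exact arithmetic, without
      # the float rounding (or plogis saturation) that a + b x can inject
      fit_auc <- compute_auc(sign(coefs[2]) * x, lab)
      if (coefs[2] < 0) 1 - fit_auc else fit_auc
    } else compute_auc(x, lab)
  })
  ord <- order(abs(auc - 0.5), decreasing = TRUE)
  out <- data.frame(gene_id = rownames(v)[ord], auc = auc[ord],
                    direction = ifelse(auc[ord] > 0.5, "positive",
                                       "negative"),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "scope") <- scope
  class(out) <- c("gene_ranking", "data.frame")
  out
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stop("a class has fewer members than folds; cannot stratify")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

cv_auc <- function(x, labels, fold, k) {
  mean(vapply(seq_len(k), function(f) {
    tr <- fold != f
    coefs <- glm_fit_quiet(x[tr, , drop = FALSE], labels[tr])
    compute_auc(glm_predict(coefs, x[!tr, , drop = FALSE]), labels[!tr])
  }, numeric(1)))
}

#' Build a cell-identity scoring model by cross-validated stepwise selection
#'
#' Walks the gene ranking in order; each candidate gene is added to the
#' current logistic model and the mean held-out ROC AUC over stratified
#' k-fold cross-validation is compared with the running best (an empty
#' model has AUC 0.5). The gene is accepted only when the CV AUC improves
#' by more than `tol`. Selection stops at `max_genes` accepted genes, when
#' the ranking is exhausted, or after `patience` consecutive rejections.
#' The final model is refitted on all scoped cells with the accepted genes.
#'
#' @param values genes x cells log-normalised matrix.
#' @param cells per-cell metadata (as in [rank_genes()]).
#' @param ranking a `gene_ranking` (its target/scope are reused).
#' @param max_genes cap on the number of signature genes (default 50).
#' @param k_folds stratified CV folds (default 5).
#' @param tol minimum CV AUC improvement to accept a gene (default 1e-4).
#' @param patience consecutive rejections before early stop (default 20).
#' @param seed seed for fold assignment.
#' @return object of class `identity_model`: target, selected_genes,
#'   coefficients, intercept, cv_auc (final), trace (gene_id, cv_auc,
#'   accepted), training_spec.
#' @export
build_identity_model <- function(values, cells, ranking, max_genes = 50,
                                 k_folds = 5, tol = 1e-4, patience = 20,
                                 seed = 1L) {
  stopifnot(inherits(ranking, "gene_ranking"), nrow(ranking) > 0)
  target <- attr(ranking, "target")
  scope <- attr(ranking, "scope")
  use <- rep(TRUE, nrow(cells))
  for (col in names(scope)) use <- use & cells[[col]] %in% scope[[col]]
  lab <- cells$cell_type[use] == target
  x_all <- t(as.matrix(values[ranking$gene_id, use, drop = FALSE]))

  set.seed(seed)
  fold <- stratified_folds(lab, k_folds)
  best <- 0.5
  selected <- character()
  trace <- vector("list", nrow(ranking))
  rejections <- 0L
  for (i in seq_len(nrow(ranking))) {
    cand <- c(selected, ranking$gene_id[i])
    score <- cv_auc(x_all[, cand, drop = FALSE], lab, fold, k_folds)
    accepted <- is.finite(score) && score > best + tol
    trace[[i]] <- data.frame(gene_id = ranking$gene_id[i], cv_auc = score,
                             accepted = accepted, stringsAsFactors = FALSE)
    if (accepted) {
      selected <- cand
      best <- score
      rejections <- 0L
    } else {
      rejections <- rejections + 1L
    }
    if (length(selected) >= max_genes || rejections >= patience) break
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  if (!length(selected))
    stop("empty model: no gene improved the cross-validated AUC")
  coefs <- glm_fit_quiet(x_all[, selected, drop = FALSE], lab)
  structure(list(
    target = target,
    selected_genes = selected,
    coefficients = stats::setNames(coefs[-1], selected),
    intercept = unname(coefs[1]),
    cv_auc = best,
    trace = trace,
    training_spec = list(scope = scope, positive = target,
                         negative = "all other scoped cells",
                         k_folds = k_folds, tol = tol, seed = seed)
  ), class = "identity_model")
}

#' @export
print.identity_model <- function(x, ...) {
  cat(sprintf("identity_model for '%s': %d genes, CV AUC %.4f\n",
              x$target, length(x$selected_genes), x$cv_auc))
  invisible(x)
}

#' Score every cell for Sertoli and granulosa identity
#'
#' SCI = 100 x logistic(intercept + sum coef * expression) under the Sertoli
#' model; GCI likewise under the granulosa model. All cells are scored,
#' including genotypes absent from training. Model genes missing from the
#' matrix are imputed as zero expression (warning).
#'
#' @param values genes x cells log-normalised matrix.
#' @param sertoli,granulosa fitted [build_identity_model()] objects.
#' @return data.frame(cell_id, sci, gci), both in \[0, 100\].
#' @export
score_cells <- function(values, sertoli, granulosa) {
  one <- function(model) {
    coefs <- model$coefficients
    coefs[is.na(coefs)] <- 0
    present <- names(coefs) %in% rownames(values)
    if (!all(present))
      warning(sprintf("%d model gene(s) missing from matrix; imputed as 0",
                      sum(!present)))
    x <- matrix(0, ncol(values), length(coefs))
    if (any(present))
      x[, present] <- t(as.matrix(
        values[names(coefs)[present], , drop = FALSE]))
    100 * stats::plogis(model$intercept + drop(x %*% coefs))
  }
  data.frame(cell_id = colnames(values),
             sci = one(sertoli), gci = one(granulosa),
             stringsAsFactors = FALSE)
}
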