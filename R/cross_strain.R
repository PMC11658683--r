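#' Fit an ICA model for cross-dataset projection
#'
#' Centres the data on the per-gene mean, whitens to `k` dimensions via SVD
#' and runs the symmetric fixed-point independent component analysis with
#' the logcosh contrast. The stored centre, whitening matrix and orthogonal
#' rotation let a second dataset be projected into the same component space
#' with [project_ica()]: scores = rotation %*% whitening %*% (x - centre).
#'
#' @param values genes x cells log-normalised matrix (the training data;
#'   restrict beforehand to the gene space shared with the query dataset).
#' @param k number of independent components.
#' @param seed seed for the random rotation initialisation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return object of class `ica_model`: gene_ids, centre, whitening (k x
#'   genes), rotation (k x k orthogonal), scores (cells x k), converged,
#'   iterations.
#' @export
fit_ica <- function(values, k = 30, seed = 1L, max_iter = 200, tol = 1e-4) {
  x <- t(as.matrix(values))            # cells x genes
  n <- nrow(x); p <- ncol(x)
  if (k > min(n, p)) stop("k exceeds min(genes, cells)")
  centre <- colMeans(x)
  xc <- sweep(x, 2, centre)
  sv <- svd(xc, nu = k, nv = k)
  if (any(sv$d[seq_len(k)] < 1e-12))
    stop("data rank below k; reduce the number of components")
  # whitening: z = xc %*% t(K) has identity covariance
  K <- t(sv$v[, seq_len(k), drop = FALSE] %*%
           diag(sqrt(n - 1) / sv$d[seq_len(k)], k))
  z <- xc %*% t(K)

  set.seed(seed)
  W <- matrix(stats::rnorm(k * k), k, k)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- z %*% t(W)                    # cells x k
    g <- tanh(s)
    W1 <- t(g) %*% z / n - diag(colMeans(1 - g^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("ICA did not converge in %d iterations (delta %.2e); ",
                    iter, delta), "returning the current rotation")
  structure(list(gene_ids = rownames(values), centre = centre,
                 whitening = K, rotation = W,
                 scores = z %*% t(W), converged = converged,
                 iterations = iter),
            class = "ica_model")
}

#' Project a dataset into a fitted ICA component space
#'
#' Aligns the query genes onto the model's gene space by identifier (model
#' genes missing from the query are imputed as zero expression, with a
#' warning giving the count), centres on the model centre, applies the
#' whitening matrix and then the orthogonal rotation. Deterministic.
#'
#' @param model an [fit_ica()] result.
#' @param values genes x cells matrix of the query dataset.
#' @param min_gene_overlap minimum fraction of model genes that must be
#'   present in the query (default 0.5); below this the projection is
#'   refused as meaningless.
#' @return cells x k matrix of component scores.
#' @export
project_ica <- function(model, values, min_gene_overlap = 0.5) {
  present <- model$gene_ids %in% rownames(values)
  if (mean(present) < min_gene_overlap)
    stop(sprintf("only %.1f%% of model genes present in query (< %.0f%%)",
                 100 * mean(present), 100 * min_gene_overlap))
  if (!all(present))
    warning(sprintf("%d model gene(s) missing from query; imputed as 0",
                    sum(!present)))
  x <- matrix(0, ncol(values), length(model$gene_ids),
              dimnames = list(colnames(values), model$gene_ids))
  x[, present] <- t(as.matrix(values[model$gene_ids[present], , drop = FALSE]))
  sweep(x, 2, model$centre) %*% t(model$whitening) %*% t(model$rotation)
}

#' Transfer cell-type labels with a balanced multinomial classifier
#'
#' Trains multinomial logistic regression on up to `n_per_class` randomly
#' subsampled training cells per class (classes with fewer cells use all of
#' them, with a warning) and predicts class probabilities for the query
#' cells in the same component space.
#'
#' @param train_scores cells x k component-score matrix of the training set.
#' @param train_labels cell-type label per training cell (>= 2 classes).
#' @param query_scores cells x k matrix to classify.
#' @param n_per_class subsample size per class (default 500).
#' @param seed seed for the subsampling.
#' @return list(labels = predicted class per query cell,
#'   probabilities = query x class matrix, rows summing to 1).
#' @export
transfer_labels <- function(train_scores, train_labels, query_scores,
                            n_per_class = 500, seed = 1L) {
  train_labels <- as.character(train_labels)
  classes <- sort(unique(train_labels))
  if (length(classes) < 2) stop("need at least 2 training classes")
  stopifnot(nrow(train_scores) == length(train_labels),
            ncol(query_scores) == ncol(train_scores))
  set.seed(seed)
  small <- character()
  idx <- unlist(lapply(classes, function(cl) {
    i <- which(train_labels == cl)
    if (length(i) <= n_per_class) {
      if (length(i) < n_per_class) small <<- c(small, cl)
      i
    } else i[sample.int(length(i), n_per_class)]
  }))
  if (length(small))
    warning("classes with < n_per_class cells use all cells: ",
            paste(small, collapse = ", "))
  df <- data.frame(.label = factor(train_labels[idx], levels = classes),
                   train_scores[idx, , drop = FALSE])
  fit <- nnet::multinom(.label ~ ., df, trace = FALSE, maxit = 500,
                        MaxNWts = 1e5)
  qdf <- as.data.frame(query_scores)
  colnames(qdf) <- colnames(df)[-1]
  probs <- stats::predict(fit, qdf, type = "probs")
  if (length(classes) == 2)  # multinom returns P(class 2) as a vector
    probs <- cbind(1 - probs, probs)
  probs <- matrix(probs, nrow = nrow(qdf),
                  dimnames = list(rownames(query_scores), classes))
  list(labels = classes[max.col(probs, ties.method = "first")],
       probabilities = probs)
}
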