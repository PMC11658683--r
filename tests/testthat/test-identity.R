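test_that("AUC matches closed forms and the pairwise brute-force oracle", {
  expect_identical(compute_auc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1)
  expect_identical(compute_auc(c(2, 2), c(1, 0)), 0.5)
  expect_identical(compute_auc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_error(compute_auc(1:3, c(1, 1, 1)), "nonempty")

  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    values <- sample(0:5, n, replace = TRUE) + # heavy ties
      ifelse(runif(n) < 0.5, 0, runif(n))
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_lt(abs(compute_auc(values, labels) - oracle_auc(values, labels)),
              1e-12)
    if (!anyDuplicated(values))
      expect_lt(abs(compute_auc(values, labels) +
                      compute_auc(-values, labels) - 1), 1e-12)
  }
})

test_that("gene ranking recovers planted markers and handles degenerate genes", {
  cfg <- small_config(n_cells_per_type = 60, markers_per_type = 10,
                      n_background_genes = 150, seed = 29L)
  sim <- simulate_dataset(cfg)
  nrm <- normalize_counts(sim$counts)
  rk <- rank_genes(nrm$values, sim$cells, "Sertoli",
                   scope = list(genotype = c("XY_WT", "XY_Zdel")),
                   method = "rank")
  planted <- cfg$marker_table$gene_id[cfg$marker_table$cell_type == "Sertoli"]
  expect_gte(mean(planted %in% rk$gene_id[seq_len(2 * length(planted))]),
             0.9)
  expect_identical(rk$rank, seq_len(nrow(rk)))
  # discrimination strength is sorted
  expect_true(!is.unsorted(rev(abs(rk$auc - 0.5))))
  # markers of other types are depleted in Sertoli cells -> negative
  top_neg <- rk[rk$direction == "negative", ][1, "gene_id"]
  expect_false(top_neg %in% planted)
})

test_that("per-gene GLM scoring is equivalent to raw-expression AUC ranking", {
  cfg <- small_config(n_cells_per_type = 40, markers_per_type = 8,
                      n_background_genes = 80, seed = 31L)
  sim <- simulate_dataset(cfg)
  nrm <- normalize_counts(sim$counts)
  scope <- list(genotype = c("XY_WT", "XY_Zdel"))
  glm_rk <- rank_genes(nrm$values, sim$cells, "Sertoli", scope = scope,
                       method = "glm")
  raw_rk <- rank_genes(nrm$values, sim$cells, "Sertoli", scope = scope,
                       method = "rank")
  m <- merge(glm_rk[c("gene_id", "auc")], raw_rk[c("gene_id", "auc")],
             by = "gene_id")
  expect_lt(max(abs(m$auc.x - m$auc.y)), 1e-12)

  # a constant gene carries no information
  vals <- nrm$values
  vals["gene00001", ] <- 1
  rk2 <- rank_genes(vals, sim$cells, "Sertoli", scope = scope,
                    method = "glm")
  expect_equal(rk2$auc[rk2$gene_id == "gene00001"], 0.5)
  # last tier: ranked below every gene carrying any information
  informative_ranks <- rk2$rank[abs(rk2$auc - 0.5) > 1e-12]
  expect_gt(rk2$rank[rk2$gene_id == "gene00001"], max(informative_ranks))
})

test_that("stepwise selection finds informative genes and obeys its guards", {
  # 3 complementary informative genes: each marks a different third of the
  # target cells, so the model needs all three to separate the classes
  set.seed(51)
  n <- 120
  lab_type <- rep(c("Sertoli", "other"), each = n / 2)
  genes <- c(sprintf("inf%d", 1:3), sprintf("bg%03d", 1:80))
  vals <- matrix(rnorm(length(genes) * n, 1, 1), length(genes), n,
                 dimnames = list(genes, sprintf("c%03d", 1:n)))
  vals[1, 1:20] <- vals[1, 1:20] + 4
  vals[2, 21:40] <- vals[2, 21:40] + 4
  vals[3, 41:60] <- vals[3, 41:60] + 4
  vals <- pmax(vals, 0)
  cells <- data.frame(cell_id = colnames(vals), cell_type = lab_type)
  rk <- rank_genes(vals, cells, "Sertoli", min_cells = 0, method = "rank")
  mdl <- build_identity_model(vals, cells, rk, seed = 8)
  expect_true(all(sprintf("inf%d", 1:3) %in% mdl$selected_genes))
  expect_lte(length(mdl$selected_genes), 50)

  # accepted steps never decrease the running CV AUC
  acc <- mdl$trace[mdl$trace$accepted, "cv_auc"]
  expect_true(all(diff(acc) > 0))

  # an infinite tolerance accepts nothing and errors out
  expect_error(build_identity_model(vals, cells, rk, tol = Inf, seed = 8),
               "empty model")
  # too few cells per class to stratify
  tiny <- cells[c(1:3, 61:63), ]
  expect_error(
    build_identity_model(vals[, tiny$cell_id], tiny,
                         rank_genes(vals[, tiny$cell_id], tiny, "Sertoli",
                                    min_cells = 0, method = "rank"),
                         k_folds = 5, seed = 8),
    "fewer members than folds")
})

test_that("scoring is the logistic closed form, bounded, and separates the classes", {
  cfg <- small_config(n_cells_per_type = 60, markers_per_type = 10,
                      n_background_genes = 150, seed = 37L)
  sim <- simulate_dataset(cfg)
  nrm <- normalize_counts(sim$counts)
  rk_s <- rank_genes(nrm$values, sim$cells, "Sertoli",
                     scope = list(genotype = c("XY_WT", "XY_Zdel")),
                     method = "rank")
  rk_g <- rank_genes(nrm$values, sim$cells, "granulosa",
                     scope = list(genotype = "XX_WT"), method = "rank")
  ms <- build_identity_model(nrm$values, sim$cells, rk_s, seed = 8)
  mg <- build_identity_model(nrm$values, sim$cells, rk_g, seed = 8)
  sc <- score_cells(nrm$values, ms, mg)

  expect_true(all(sc$sci >= 0 & sc$sci <= 100))
  expect_true(all(sc$gci >= 0 & sc$gci <= 100))

  # an all-zero cell scores exactly 100 * logistic(intercept)
  zero <- nrm$values[, 1, drop = FALSE] * 0
  colnames(zero) <- "zero_cell"
  sc0 <- score_cells(zero, ms, mg)
  expect_equal(sc0$sci, 100 * plogis(ms$intercept))
  expect_equal(sc0$gci, 100 * plogis(mg$intercept))

  # training classes are separated; DP-truth cells sit in between
  tt <- sim$cells$true_type
  expect_gt(mean(sc$gci[tt == "granulosa"]), mean(sc$gci[tt == "Sertoli"]))
  expect_gt(mean(sc$sci[tt == "Sertoli"]), mean(sc$sci[tt == "granulosa"]))
  if (sum(tt == "DP") >= 5) {
    expect_gt(mean(sc$sci[tt == "DP"]), mean(sc$sci[tt == "granulosa"]))
    expect_lt(mean(sc$sci[tt == "DP"]), mean(sc$sci[tt == "Sertoli"]))
    expect_gt(mean(sc$gci[tt == "DP"]), mean(sc$gci[tt == "Sertoli"]))
    expect_lt(mean(sc$gci[tt == "DP"]), mean(sc$gci[tt == "granulosa"]))
  }

  # missing model genes are imputed as zero with a warning
  expect_warning(score_cells(nrm$values[-match(ms$selected_genes[1],
                                               rownames(nrm$values)), ],
                             ms, mg),
                 "missing")
})

test_that("swapping the positive and negative class mirrors the scores", {
  # overlapping tie-free classes: the label-swapped logistic MLE is the
  # exact negation, so scores reflect to 100 - s
  set.seed(61)
  n <- 200
  lab_type <- rep(c("Sertoli", "other"), each = n / 2)
  vals <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("gA", "gB"), sprintf("c%03d", 1:n)))
  vals[, lab_type == "Sertoli"] <- vals[, lab_type == "Sertoli"] + 1
  cells <- data.frame(cell_id = colnames(vals), cell_type = lab_type)
  rank_fwd <- rank_genes(vals, cells, "Sertoli", min_cells = 0,
                         method = "rank")
  rank_rev <- rank_genes(vals, cells, "other", min_cells = 0,
                         method = "rank")
  m_fwd <- build_identity_model(vals, cells, rank_fwd, tol = -Inf, seed = 8)
  m_rev <- build_identity_model(vals, cells, rank_rev, tol = -Inf, seed = 8)
  s_fwd <- score_cells(vals, m_fwd, m_fwd)$sci
  s_rev <- score_cells(vals, m_rev, m_rev)$sci
  expect_lt(max(abs(s_fwd - (100 - s_rev))), 1e-3)
})
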