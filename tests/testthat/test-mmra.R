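make_dbset <- function(pairs) {
  structure(list(pairs = pairs,
                 sources = split(pairs[, c("mirna_id", "gene_id")],
                                 pairs$source)),
            class = "target_database_set")
}

test_that("consensus targets require support from enough sources", {
  pairs <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2", "m2"),
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    source = c("A", "B", "A", "A", "C"),
    stringsAsFactors = FALSE)
  cons <- consensus_targets(make_dbset(pairs), 2L)
  expect_identical(cons$m1, "g1")   # g2 seen once only
  expect_identical(cons$m2, "g3")
  expect_error(consensus_targets(make_dbset(pairs), 4L), "min_sources")

  # randomized fixture against brute-force count-and-filter
  set.seed(8)
  for (i in 1:20) {
    rnd <- data.frame(
      mirna_id = sample(paste0("m", 1:5), 60, replace = TRUE),
      gene_id = sample(paste0("g", 1:15), 60, replace = TRUE),
      source = sample(c("A", "B", "C"), 60, replace = TRUE),
      stringsAsFactors = FALSE)
    cons <- consensus_targets(make_dbset(rnd), 2L)
    u <- unique(rnd[, 1:3])
    counts <- table(paste(u$mirna_id, u$gene_id))
    expected_pairs <- sort(names(counts)[counts >= 2])
    got_pairs <- sort(unlist(lapply(names(cons), function(m) {
      paste(m, cons[[m]])
    }), use.names = FALSE))
    expect_identical(got_pairs, expected_pairs)
  }
})

test_that("target enrichment p-values equal hypergeometric tail sums", {
  universe <- paste0("g", 1:10)
  sig <- structure(list(contrast = "c", up = paste0("g", 1:5),
                        down = character(0)), class = "signature")
  res <- target_enrichment("m", paste0("g", 1:2), sig, universe)
  # overlap 2 of 2 targets in a 5-gene signature over 10: C(5,2)/C(10,2)
  expect_equal(res$up$p_value, 10 / 45, tolerance = 1e-12)
  expect_identical(res$up$passed, res$up$p_value < 0.05)
  expect_equal(sum(res$up$table), length(universe))

  # empty targets: p = 1, not passed
  res0 <- target_enrichment("m", character(0), sig, universe)
  expect_identical(res0$up$p_value, 1)
  expect_false(res0$passed)
  # no overlap cannot enrich
  res_no <- target_enrichment("m", paste0("g", 6:7), sig, universe)
  expect_false(res_no$up$passed)
  expect_error(target_enrichment("m", "gX", sig, universe), "subset")
  expect_error(target_enrichment("m", character(0), sig, character(0)),
               "empty")

  # property: random tables match the brute-force oracle
  set.seed(13)
  for (i in 1:300) {
    N <- sample(10:60, 1)
    uni <- paste0("g", seq_len(N))
    s <- sample(uni, sample(0:N, 1))
    t <- sample(uni, sample(0:N, 1))
    sigr <- structure(list(contrast = "c", up = s, down = character(0)),
                      class = "signature")
    got <- target_enrichment("m", t, sigr, uni)$up$p_value
    want <- if (length(t) == 0) 1 else {
      bf_fisher_greater(length(intersect(t, s)), length(t), length(s), N)
    }
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the MI estimator tracks independence, identity and Gaussian MI", {
  set.seed(2)
  n <- 24
  x <- rnorm(n)
  expect_lt(abs(estimate_mi(x, sample(x))), 0.25)   # independence
  expect_equal(estimate_mi(x, x), estimate_mi(rev(x), rev(x)))
  # symmetric in its arguments
  y <- rnorm(n)
  expect_equal(estimate_mi(x, y), estimate_mi(y, x))
  # identity on n distinct values: plug-in part equals log(bins)
  b <- max(2, min(32, floor(sqrt(n))))
  expect_equal(estimate_mi(x, x, correct = FALSE), log(b), tolerance = 1e-12)
  expect_identical(estimate_mi(rep(1, n), rnorm(n)), 0)
  expect_error(estimate_mi(1:4, 1:4), "at least 8")
  expect_error(estimate_mi(1:10, 1:9), "equal length")
})

test_that("MI matches the analytic Gaussian value at n = 5000", {
  set.seed(17)
  n <- 5000
  for (rho in c(0, 0.5, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_lt(abs(estimate_mi(x, y) - (-0.5 * log(1 - rho^2))), 0.05)
  }
})

test_that("MI thresholds are monotone in the tail target and oracle-checked", {
  study <- generate_study(quick_config(seed = 41))
  g <- study$gene_matrix; m <- study$mirna_matrix
  expect_identical(mi_threshold(g, m, p_target = 1), 0)
  t2 <- mi_threshold(g, m, 1e-2, seed = 3)
  t4 <- mi_threshold(g, m, 1e-4, seed = 3)
  t7 <- mi_threshold(g, m, 1e-7, seed = 3)
  expect_lt(t2, t4)
  expect_lt(t4, t7)
  expect_error(mi_threshold(g, m, 1e-7, n_perm = 500L), "at least 1000")

  # extrapolated threshold at a reachable p agrees with direct permutation
  set.seed(4)
  n <- ncol(g)
  direct <- replicate(10000, {
    estimate_mi(g[sample(nrow(g), 1), ], m[sample(nrow(m), 1), sample(n)])
  })
  emp99 <- quantile(direct, 0.99)
  expect_lt(abs(t2 - emp99) / emp99, 0.10)
})

test_that("hub networks keep high-MI genes only and ignore row order", {
  study <- generate_study(quick_config(seed = 51, repression_strength = 0.9))
  hub <- study$truth$regulations$mirna_id[[1]]
  targets <- study$truth$regulations$gene_id[
    study$truth$regulations$mirna_id == hub]
  thr <- mi_threshold(study$gene_matrix, study$mirna_matrix, 1e-4, seed = 5)
  net <- build_network(hub, study$gene_matrix, study$mirna_matrix, thr)
  expect_true(all(net$edges$mi >= thr))
  # most planted targets are edges; the bulk of non-targets is excluded
  expect_gte(mean(targets %in% net$edges$gene_id), 0.5)
  non_targets <- setdiff(rownames(study$gene_matrix), targets)
  expect_gte(mean(!non_targets %in% net$edges$gene_id), 0.9)
  # permutation invariance over gene rows
  perm <- sample(nrow(study$gene_matrix))
  net2 <- build_network(hub, study$gene_matrix[perm, ],
                        study$mirna_matrix, thr)
  expect_identical(net$edges, net2$edges)
  # infinite threshold: empty network, enrichment not passed
  empty <- build_network(hub, study$gene_matrix, study$mirna_matrix, Inf)
  expect_identical(nrow(empty$edges), 0L)
  sig <- structure(list(contrast = "c", up = targets,
                        down = character(0)), class = "signature")
  expect_false(network_enrichment(empty, sig,
                                  rownames(study$gene_matrix))$passed)
})

test_that("stepwise regression is a local AIC optimum and matches the
           exhaustive oracle on small candidate sets", {
  set.seed(23)
  n <- 24
  # orthogonal single candidate -> intercept-only model
  y <- rnorm(n)
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "mA"))
  while (abs(cor(y, x[, 1])) > 0.05) x[, 1] <- rnorm(n)
  fit <- stepwise_regression(y, x)
  expect_length(fit$selected, 0)

  # perfect predictor recovered with its constructed slope
  x2 <- cbind(mA = rnorm(n))
  y2 <- 3 - 1.7 * x2[, "mA"]
  fit2 <- stepwise_regression(y2, x2)
  expect_identical(fit2$selected, "mA")
  expect_equal(unname(fit2$coefficients["mA"]), -1.7, tolerance = 1e-8)

  # zero-variance candidates dropped with a warning
  x3 <- cbind(mA = x2[, 1], mB = rep(1, n))
  expect_warning(stepwise_regression(y2, x3), "zero-variance")

  # exhaustive-subset oracle on <= 6 candidates
  aic_of <- function(y, X, sel) {
    M <- cbind(1, X[, sel, drop = FALSE])
    rss <- sum(.lm.fit(M, y)$residuals^2)
    length(y) * log(rss / length(y)) + 2 * ncol(M)
  }
  greedy_eq_global <- 0L
  for (i in 1:40) {
    p <- 6
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("m", letters[1:p])))
    beta <- ifelse(runif(p) < 0.4, rnorm(p, sd = 1), 0)
    yy <- drop(X %*% beta) + rnorm(n)
    fit <- stepwise_regression(yy, X)
    subsets <- lapply(0:(2^p - 1), function(mask) {
      colnames(X)[bitwAnd(mask, 2^(0:(p - 1))) > 0]
    })
    all_aic <- vapply(subsets, function(s) aic_of(yy, X, s), numeric(1))
    best <- min(all_aic)
    expect_gte(fit$aic, best - 1e-9)
    if (fit$aic <= best + 1e-9) greedy_eq_global <- greedy_eq_global + 1L
    # local optimality: no single add/remove improves the chosen model
    for (v in colnames(X)) {
      alt <- if (v %in% fit$selected) setdiff(fit$selected, v)
             else c(fit$selected, v)
      expect_gte(aic_of(yy, X, alt), fit$aic - 1e-9)
    }
  }
  # greedy matches the global optimum in the overwhelming majority of draws
  expect_gte(greedy_eq_global, 32L)

  # candidate truncation for identifiability
  Xbig <- matrix(rnorm(n * 30), n, 30,
                 dimnames = list(NULL, sprintf("m%02d", 1:30)))
  expect_message(fitb <- stepwise_regression(rnorm(n), Xbig), "truncating")
  expect_lte(length(fitb$candidates), n - 3L)
})

test_that("the four MMRA steps filter monotonically and recover planted
           regulators", {
  cfg <- quick_config(seed = 61)
  study <- generate_study(cfg)
  dbset <- generate_target_databases(study)
  res <- run_mmra(study, dbset, "HFepa_vs_reference", mi_p_target = 1e-4)
  expect_true(all(diff(unname(res$counts)) <= 0))
  # every surviving miRNA passed earlier steps: absent from the audit kills
  eliminated <- res$audit$mirna_id[!is.na(res$audit$eliminated_at)]
  expect_length(intersect(unique(res$pairs$mirna_id), eliminated), 0)
  # recovered pairs are dominated by planted regulations
  truth_key <- with(study$truth$regulations, paste(mirna_id, gene_id))
  got_key <- with(res$pairs, paste(mirna_id, gene_id))
  expect_gt(mean(got_key %in% truth_key), 0.5)

  # an empty consensus empties the pipeline without error
  cfg0 <- quick_config(seed = 61, db_overlap = 0, db_false_rate = 0)
  study0 <- generate_study(cfg0)
  db0 <- generate_target_databases(study0)
  res0 <- run_mmra(study0, db0, "HFepa_vs_reference", mi_p_target = 1e-4)
  expect_identical(nrow(res0$pairs), 0L)
  expect_identical(unname(res0$counts[["step2"]]), 0L)
})
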