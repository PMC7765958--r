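#' Consensus miRNA-target predictions across database sources
#'
#' A (miRNA, gene) pair is a consensus target when it is reported by at
#' least \code{min_sources} distinct sources.
#'
#' @param dbset a \code{target_database_set} (see
#'   \code{\link{generate_target_databases}}) or any list with a
#'   \code{pairs} data.frame holding \code{mirna_id}, \code{gene_id},
#'   \code{source}.
#' @param min_sources minimal number of supporting sources, default 2.
#' @return named list: miRNA id -> character vector of consensus target
#'   gene ids.
#' @export
consensus_targets <- function(dbset, min_sources = 2L) {
  pairs <- dbset$pairs
  stopifnot(all(c("mirna_id", "gene_id", "source") %in% names(pairs)))
  n_src <- if (!is.null(dbset$sources)) length(dbset$sources)
           else length(unique(pairs$source))
  if (min_sources > n_src) {
    stop("min_sources (", min_sources, ") exceeds the number of sources (",
         n_src, ")")
  }
  pairs <- unique(pairs[, c("mirna_id", "gene_id", "source")])
  key <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
  support <- table(key)
  keep <- names(support)[support >= min_sources]
  if (!length(keep)) return(setNames(list(), character(0)))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  df <- data.frame(mirna_id = vapply(parts, `[`, "", 1L),
                   gene_id = vapply(parts, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  lapply(split(df$gene_id, df$mirna_id), function(g) sort(unique(g)))
}

fisher_enrichment_result <- function(mirna, side, members, sig_side,
                                     universe, alpha = 0.05) {
  overlap <- length(intersect(members, sig_side))
  a <- overlap
  b <- length(members) - overlap
  c_ <- length(sig_side) - overlap
  d <- length(universe) - a - b - c_
  p <- if (length(members) == 0L) 1 else {
    fisher.test(matrix(c(a, b, c_, d), 2L, 2L),
                alternative = "greater")$p.value
  }
  list(mirna = mirna, signature_side = side,
       table = c(overlap = a, targets_not_sig = b,
                 sig_not_targets = c_, neither = d),
       p_value = p, passed = p < alpha)
}

#' Fisher enrichment of a miRNA's targets in an up/down signature
#'
#' One-sided (enrichment) Fisher exact test of the 2x2 table crossing
#' membership in the miRNA's target set with membership in each signature
#' side, over the measured-gene universe. The miRNA passes when either
#' side is enriched at \code{alpha}.
#'
#' @param mirna miRNA identifier (carried through to the result).
#' @param targets character vector of target gene ids (subset of universe).
#' @param signature a \code{signature} object.
#' @param universe character vector of all measured gene ids.
#' @param alpha significance threshold, default 0.05.
#' @return list with elements \code{up}, \code{down} (each a Fisher result
#'   with the 2x2 counts, p-value and pass flag) and \code{passed}.
#' @export
target_enrichment <- function(mirna, targets, signature, universe,
                              alpha = 0.05) {
  if (length(universe) == 0L) stop("empty gene universe")
  if (length(setdiff(targets, universe))) {
    stop("targets must be a subset of the universe")
  }
  up <- fisher_enrichment_result(mirna, "up", targets, signature$up,
                                 universe, alpha)
  down <- fisher_enrichment_result(mirna, "down", targets, signature$down,
                                   universe, alpha)
  list(up = up, down = down, passed = up$passed || down$passed)
}

mi_bins <- function(n) max(2L, min(32L, floor(sqrt(n))))

#' Mutual information between two sample vectors
#'
#' Rank-based equal-frequency binning with Miller-Madow bias correction:
#' both vectors are rank-transformed, cut into equal-count bins
#' (\code{max(2, min(32, floor(sqrt(n))))} by default), and the plug-in
#' mutual information of the joint histogram is corrected by
#' (Kxy - Kx - Ky + 1) / (2n), K* being occupied cell counts. The estimate
#' is symmetric and non-negative up to the bias correction; constant
#' vectors give 0 exactly.
#'
#' @param x,y numeric vectors of equal length (>= 8), finite values.
#' @param bins number of marginal bins; default as above.
#' @param correct apply the Miller-Madow correction (default TRUE).
#' @return mutual information in nats.
#' @export
estimate_mi <- function(x, y, bins = NULL, correct = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 8L) stop("need at least 8 paired samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (var(x) == 0 || var(y) == 0) return(0)
  if (is.null(bins)) bins <- mi_bins(n)
  bx <- ceiling(rank(x, ties.method = "first") / (n / bins))
  by <- ceiling(rank(y, ties.method = "first") / (n / bins))
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  pj <- joint / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- ent(px) + ent(py) - ent(pj)
  if (correct) {
    kxy <- sum(joint > 0); kx <- sum(px > 0); ky <- sum(py > 0)
    mi <- mi - (kxy - kx - ky + 1) / (2 * n)
  }
  mi
}

#' Mutual-information threshold for a target tail probability
#'
#' Builds a permutation null for the MI estimator by pairing randomly
#' chosen gene rows with sample-permuted miRNA rows, then fits an
#' exponential tail to the upper null quantiles (linear regression of log
#' tail probability on MI) and extrapolates to \code{p_target}. Direct
#' permutation cannot reach tail probabilities such as 1e-7 at n around
#' 24; the exponential extrapolation substitutes a fitted null, in the
#' spirit of information-theoretic network inference tools.
#'
#' @param gene_matrix,mirna_matrix log2 matrices sharing sample columns.
#' @param p_target desired tail probability (default 1e-7).
#' @param n_perm number of null draws, at least 1000.
#' @param tail_frac fraction of the largest null values used for the tail
#'   fit (default 0.1; at least 50 points required).
#' @param seed integer seed for the permutation null.
#' @return the MI threshold (nats) whose fitted tail probability equals
#'   \code{p_target}; 0 when \code{p_target >= 1}.
#' @export
mi_threshold <- function(gene_matrix, mirna_matrix, p_target = 1e-7,
                         n_perm = 2000L, tail_frac = 0.1, seed = 1L) {
  if (p_target >= 1) return(0)
  if (p_target <= 0) stop("p_target must lie in (0, 1]")
  if (n_perm < 1000L) stop("n_perm must be at least 1000 for a stable tail fit")
  k <- ceiling(tail_frac * n_perm)
  if (k < 50L) {
    stop("tail_frac * n_perm = ", k, " points is too few for the tail fit; ",
         "increase n_perm or tail_frac (need >= 50)")
  }
  n <- ncol(gene_matrix)
  stopifnot(ncol(mirna_matrix) == n)
  set.seed(seed)
  gi <- sample(nrow(gene_matrix), n_perm, replace = TRUE)
  mi_ <- sample(nrow(mirna_matrix), n_perm, replace = TRUE)
  null_mi <- vapply(seq_len(n_perm), function(i) {
    estimate_mi(gene_matrix[gi[i], ], mirna_matrix[mi_[i], sample(n)])
  }, numeric(1))
  tail_vals <- sort(null_mi, decreasing = TRUE)[seq_len(k)]
  ## empirical tail probability of the i-th largest value
  pp <- (seq_len(k) - 0.5) / n_perm
  fit <- lm(log(pp) ~ tail_vals)
  slope <- coef(fit)[[2L]]
  if (!is.finite(slope) || slope >= 0) {
    stop("tail fit failed (non-decreasing tail); increase n_perm")
  }
  thr <- (log(p_target) - coef(fit)[[1L]]) / slope
  max(thr, 0)
}

#' Build a miRNA-hub mutual-information network
#'
#' Scores every gene against one hub miRNA with \code{\link{estimate_mi}}
#' and keeps edges at or above \code{threshold_mi}. Only miRNA-gene edges
#' are considered; gene-gene mutual information is never computed, so the
#' miRNA is the only hub of the network and there are no triangles to
#' prune.
#'
#' @param hub_mirna miRNA id (row of \code{mirna_matrix}).
#' @param gene_matrix,mirna_matrix log2 matrices sharing sample columns.
#' @param threshold_mi minimal MI (nats) for an edge.
#' @return object of class \code{mi_network}: list(hub, edges =
#'   data.frame(gene_id, mi), threshold_mi).
#' @export
build_network <- function(hub_mirna, gene_matrix, mirna_matrix,
                          threshold_mi) {
  if (!hub_mirna %in% rownames(mirna_matrix)) {
    stop("hub miRNA ", hub_mirna, " not found in mirna_matrix")
  }
  hub <- mirna_matrix[hub_mirna, ]
  mi <- vapply(seq_len(nrow(gene_matrix)),
               function(i) estimate_mi(hub, gene_matrix[i, ]), numeric(1))
  names(mi) <- rownames(gene_matrix)
  keep <- mi >= threshold_mi
  edges <- data.frame(gene_id = rownames(gene_matrix)[keep],
                      mi = unname(mi[keep]), stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(hub = hub_mirna, edges = edges,
                 threshold_mi = threshold_mi),
            class = "mi_network")
}

#' Fisher enrichment of a hub network's genes in a signature
#'
#' Identical to \code{\link{target_enrichment}} with the network's gene
#' set in place of the predicted targets.
#'
#' @param network an \code{mi_network}.
#' @inheritParams target_enrichment
#' @return as \code{\link{target_enrichment}}.
#' @export
network_enrichment <- function(network, signature, universe, alpha = 0.05) {
  target_enrichment(network$hub, network$edges$gene_id, signature,
                    universe, alpha)
}

slr_aic <- function(y, X, selected) {
  n <- length(y)
  M <- cbind(1, X[, selected, drop = FALSE])
  fit <- .lm.fit(M, y)
  rss <- sum(fit$residuals^2)
  k <- ncol(M)
  list(aic = n * log(rss / n) + 2 * k, coef = fit$coefficients)
}

#' Stepwise-AIC linear regression of a gene on candidate miRNAs
#'
#' Bidirectional greedy search in ordinary least squares, starting from
#' the intercept-only model: at each step the single variable addition or
#' removal that most decreases AIC (n log(RSS/n) + 2k, k counting the
#' intercept) is applied; the search stops when no move decreases AIC.
#' Ties are broken deterministically by candidate id order. Zero-variance
#' candidates are dropped with a warning; when the candidate count reaches
#' n - 2 the candidates are pre-ranked by absolute correlation with the
#' response and truncated to n - 3 for OLS identifiability (reported via
#' a message).
#'
#' @param gene_vector numeric response (log2 expression across samples).
#' @param candidate_mirna_matrix numeric matrix, samples x candidate
#'   miRNAs, with column names.
#' @return object of class \code{slr_model}: list(candidates, selected,
#'   coefficients (named, selected only), intercept, aic).
#' @export
stepwise_regression <- function(gene_vector, candidate_mirna_matrix) {
  y <- as.numeric(gene_vector)
  X <- candidate_mirna_matrix
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L, dimnames = list(NULL, "x1"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y))
  n <- length(y)

  keep <- apply(X, 2L, var) > 0
  if (any(!keep)) {
    warning("dropping zero-variance candidate(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X <- X[, order(colnames(X)), drop = FALSE]
  if (ncol(X) >= n - 2L) {
    message("candidate count (", ncol(X), ") >= n - 2; truncating to the ",
            n - 3L, " candidates most correlated with the response")
    r <- abs(apply(X, 2L, cor, y = y))
    X <- X[, order(-r, colnames(X))[seq_len(n - 3L)], drop = FALSE]
    X <- X[, order(colnames(X)), drop = FALSE]
  }
  candidates <- colnames(X)

  selected <- character(0)
  current <- slr_aic(y, X, selected)
  repeat {
    moves <- c(setdiff(candidates, selected),  # additions
               selected)                       # removals
    if (!length(moves)) break
    ## evaluate all one-variable moves; candidate id order breaks ties
    trials <- lapply(moves, function(v) {
      sel <- if (v %in% selected) setdiff(selected, v) else c(selected, v)
      slr_aic(y, X, sel)
    })
    aics <- vapply(trials, `[[`, numeric(1), "aic")
    ord <- order(aics, moves)
    best <- ord[[1L]]
    if (aics[best] < current$aic - 1e-10) {
      v <- moves[best]
      selected <- if (v %in% selected) setdiff(selected, v)
                  else sort(c(selected, v))
      current <- trials[[best]]
    } else break
  }
  fit <- slr_aic(y, X, selected)
  coefs <- fit$coef
  structure(list(candidates = candidates,
                 selected = selected,
                 intercept = coefs[[1L]],
                 coefficients = if (length(selected))
                   setNames(coefs[-1L], selected) else setNames(numeric(0),
                                                                character(0)),
                 aic = fit$aic),
            class = "slr_model")
}

#' Run the four-step MicroRNA Master Regulator Analysis
#'
#' Progressive filtering of candidate miRNAs for one contrast:
#' \enumerate{
#'   \item differential expression of miRNAs (|log2fc| and raw-p criteria);
#'   \item Fisher enrichment of database-consensus targets in the up/down
#'     gene signature;
#'   \item mutual-information hub network around each surviving miRNA,
#'     tested for signature enrichment;
#'   \item per-gene stepwise-AIC regression; a (miRNA, gene) pair survives
#'     when the miRNA is selected in the gene's model.
#' }
#' MI is computed on all samples pooled across conditions; signature genes
#' and the measured-gene universe come from the gene matrix.
#'
#' @param study an \code{\link{expression_study}} (or a list with
#'   \code{gene_matrix}, \code{mirna_matrix}, \code{annotation}).
#' @param dbset a \code{target_database_set}.
#' @param contrast contrast string, e.g. \code{"HFepa_vs_reference"}.
#' @param mirna_fc_threshold,mirna_p_threshold step-1 criteria (0.25, 0.01).
#' @param signature_threshold adjusted-p cutoff for the gene signature.
#' @param fisher_alpha enrichment threshold for steps 2 and 3 (0.05).
#' @param mi_p_target MI tail probability defining the network threshold
#'   (default 1e-7).
#' @param mi_n_perm permutations for the MI null (default 2000).
#' @param min_sources database consensus requirement (default 2).
#' @param seed seed for the MI permutation null.
#' @param verbose log per-step candidate counts (default FALSE).
#' @return object of class \code{mmra_result}: list with \code{contrast},
#'   \code{pairs} (data.frame mirna_id, gene_id, coefficient,
#'   mirna_direction, gene_direction), \code{surviving} (miRNA -> gene
#'   vector), \code{audit} (per-candidate eliminating step), \code{counts}
#'   (candidates after each step), plus the intermediate signature and
#'   threshold.
#' @export
run_mmra <- function(study, dbset, contrast,
                     mirna_fc_threshold = 0.25,
                     mirna_p_threshold = 0.01,
                     signature_threshold = 0.05,
                     fisher_alpha = 0.05,
                     mi_p_target = 1e-7,
                     mi_n_perm = 2000L,
                     min_sources = 2L,
                     seed = 1L,
                     verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  universe <- rownames(study$gene_matrix)

  ## step 1: DE miRNAs
  mir_de <- mirna_differential_expression(
    study$mirna_matrix, study$annotation, contrast,
    fc_threshold = mirna_fc_threshold, p_threshold = mirna_p_threshold)
  step1 <- mir_de$feature_id[mir_de$direction != "ns"]
  mirna_dir <- setNames(mir_de$direction, mir_de$feature_id)
  say("step 1 (miRNA DE): ", length(step1), " candidates")

  ## gene signature for the contrast
  gene_de <- differential_expression(study$gene_matrix, study$annotation,
                                     contrast,
                                     adj_threshold = signature_threshold)
  signature <- build_signature(gene_de, signature_threshold)
  gene_dir <- setNames(gene_de$direction, gene_de$feature_id)

  audit <- data.frame(mirna_id = step1, eliminated_at = NA_character_,
                      stringsAsFactors = FALSE)
  mark <- function(audit, ids, step) {
    audit$eliminated_at[audit$mirna_id %in% ids &
                          is.na(audit$eliminated_at)] <- step
    audit
  }

  ## step 2: consensus-target enrichment
  consensus <- consensus_targets(dbset, min_sources)
  step2 <- character(0)
  for (m in step1) {
    targets <- intersect(consensus[[m]] %||% character(0), universe)
    res <- target_enrichment(m, targets, signature, universe, fisher_alpha)
    if (res$passed) step2 <- c(step2, m)
  }
  audit <- mark(audit, setdiff(step1, step2), "target_enrichment")
  say("step 2 (target enrichment): ", length(step2), " candidates")

  ## step 3: MI hub networks
  networks <- list()
  step3 <- character(0)
  if (length(step2)) {
    thr <- mi_threshold(study$gene_matrix, study$mirna_matrix,
                        p_target = mi_p_target, n_perm = mi_n_perm,
                        seed = seed)
    for (m in step2) {
      net <- build_network(m, study$gene_matrix, study$mirna_matrix, thr)
      res <- network_enrichment(net, signature, universe, fisher_alpha)
      if (res$passed) {
        step3 <- c(step3, m)
        networks[[m]] <- net
      }
    }
  } else thr <- NA_real_
  audit <- mark(audit, setdiff(step2, step3), "network_enrichment")
  say("step 3 (network enrichment): ", length(step3), " candidates")

  ## step 4: stepwise regression per signature gene
  pairs <- data.frame(mirna_id = character(0), gene_id = character(0),
                      coefficient = numeric(0), stringsAsFactors = FALSE)
  if (length(step3)) {
    sig_genes <- c(signature$up, signature$down)
    for (g in sig_genes) {
      cand <- step3[vapply(step3, function(m) {
        g %in% networks[[m]]$edges$gene_id ||
          g %in% (consensus[[m]] %||% character(0))
      }, logical(1))]
      if (!length(cand)) next
      model <- stepwise_regression(study$gene_matrix[g, ],
                                   t(study$mirna_matrix[cand, , drop = FALSE]))
      for (m in model$selected) {
        pairs <- rbind(pairs, data.frame(
          mirna_id = m, gene_id = g,
          coefficient = model$coefficients[[m]],
          stringsAsFactors = FALSE))
      }
    }
  }
  step4 <- unique(pairs$mirna_id)
  audit <- mark(audit, setdiff(step3, step4), "stepwise_regression")
  say("step 4 (stepwise regression): ", length(step4), " candidates")

  if (nrow(pairs)) {
    pairs$mirna_direction <- unname(mirna_dir[pairs$mirna_id])
    pairs$gene_direction <- unname(gene_dir[pairs$gene_id])
    pairs <- pairs[order(pairs$gene_id, pairs$mirna_id), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs$mirna_direction <- character(0)
    pairs$gene_direction <- character(0)
  }

  structure(list(contrast = contrast,
                 pairs = pairs,
                 surviving = lapply(split(pairs$gene_id, pairs$mirna_id),
                                    function(g) sort(unique(g))),
                 audit = audit,
                 counts = c(step1 = length(step1), step2 = length(step2),
                            step3 = length(step3), step4 = length(step4)),
                 signature = signature,
                 mi_threshold = thr),
            class = "mmra_result")
}

#' @export
print.mmra_result <- function(x, ...) {
  cat("MMRA result [", x$contrast, "]\n", sep = "")
  cat("  candidates per step:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  cat("  surviving pairs:", nrow(x$pairs), "\n")
  invisible(x)
}
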