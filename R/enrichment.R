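#' Rank genes by fold change after a raw-p filter
#'
#' Keeps genes with raw p below \code{raw_p_filter} (no FDR adjustment)
#' and sorts them by log2 fold change, descending, ties broken by gene id.
#'
#' @param de_records data.frame from \code{\link{differential_expression}}
#'   (one contrast).
#' @param raw_p_filter raw p-value cutoff, default 0.05.
#' @return character vector of gene ids, most upregulated first.
#' @export
rank_by_fc <- function(de_records, raw_p_filter = 0.05) {
  keep <- de_records[de_records$p_value < raw_p_filter, , drop = FALSE]
  keep$feature_id[order(-keep$log2fc, keep$feature_id)]
}

## one-sided survival function of the Kolmogorov statistic,
## Q(lambda) = 2 sum_k (-1)^(k-1) exp(-2 k^2 lambda^2)
ks_q <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov enrichment of a gene set in a ranked list
#'
#' Two-sample KS comparison of the rank positions of in-set versus
#' out-of-set genes. Direction is \code{"top"} when the in-set empirical
#' CDF leads (members accumulate among the most upregulated genes) and
#' \code{"bottom"} otherwise. The p-value uses the asymptotic Kolmogorov
#' distribution by default, or a label-permutation Monte Carlo estimate.
#' Sets with fewer than \code{min_size} members in the list are skipped
#' (returned with \code{skipped = TRUE} and a reason).
#'
#' @param ranked character vector from \code{\link{rank_by_fc}}.
#' @param gene_set character vector of member gene ids.
#' @param set_name label carried into the result.
#' @param method \code{"asymptotic"} or \code{"permutation"}.
#' @param n_perm permutations for the Monte Carlo p (default 2000).
#' @param min_size minimal in-list set size, default 3.
#' @return list with \code{set_name}, \code{D}, \code{direction},
#'   \code{p_value}, \code{n_in}, \code{n_out}, \code{skipped},
#'   \code{reason}.
#' @export
ks_enrichment <- function(ranked, gene_set, set_name = "set",
                          method = c("asymptotic", "permutation"),
                          n_perm = 2000L, min_size = 3L) {
  method <- match.arg(method)
  skip <- function(reason) list(set_name = set_name, D = NA_real_,
                                direction = NA_character_,
                                p_value = NA_real_, n_in = NA_integer_,
                                n_out = NA_integer_, skipped = TRUE,
                                reason = reason)
  n <- length(ranked)
  inset <- ranked %in% gene_set
  m <- sum(inset)
  if (m == 0L) return(skip("set disjoint from the ranked list"))
  if (m < min_size) return(skip("fewer than min_size members in the list"))
  if (m == n) return(skip("set covers the whole ranked list"))

  ks_d <- function(inset, n) {
    m <- sum(inset)
    f_in <- cumsum(inset) / m
    f_out <- cumsum(!inset) / (n - m)
    c(dplus = max(f_in - f_out), dminus = max(f_out - f_in))
  }
  d <- ks_d(inset, n)
  D <- max(d)
  direction <- if (d[["dplus"]] >= d[["dminus"]]) "top" else "bottom"
  ne <- sqrt(m * (n - m) / n)
  p <- switch(method,
    asymptotic = ks_q(ne * D),
    permutation = {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        max(ks_d(sample(inset), n)) >= D - 1e-12
      }, logical(1)))
      (1 + hits) / (n_perm + 1)
    })
  list(set_name = set_name, D = D, direction = direction, p_value = p,
       n_in = m, n_out = n - m, skipped = FALSE, reason = NA_character_)
}

#' Enrich a gene-set collection against a ranked list
#'
#' Applies \code{\link{ks_enrichment}} to every set and adjusts p-values
#' across sets (Benjamini-Yekutieli by default, as appropriate for the
#' dependent, overlapping sets of pathway collections).
#'
#' @param ranked ranked gene list.
#' @param collection named list of gene-id vectors.
#' @param adjust \code{"BY"} (default) or \code{"BH"}.
#' @param alpha significance cutoff on adjusted p, default 0.05.
#' @param ... passed to \code{\link{ks_enrichment}}.
#' @return data.frame with one row per set: set_name, n_in, D, direction,
#'   p_value, adj_p, significant, skipped, reason. Skipped sets carry NA
#'   statistics and do not enter the adjustment.
#' @export
enrich_collection <- function(ranked, collection, adjust = c("BY", "BH"),
                              alpha = 0.05, ...) {
  adjust <- match.arg(adjust)
  if (!length(collection)) {
    return(data.frame(set_name = character(0), n_in = integer(0),
                      D = numeric(0), direction = character(0),
                      p_value = numeric(0), adj_p = numeric(0),
                      significant = logical(0), skipped = logical(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  res <- lapply(names(collection), function(nm) {
    ks_enrichment(ranked, collection[[nm]], set_name = nm, ...)
  })
  df <- data.frame(
    set_name = vapply(res, `[[`, "", "set_name"),
    n_in = vapply(res, function(r) as.integer(r$n_in %||% NA), integer(1)),
    D = vapply(res, `[[`, numeric(1), "D"),
    direction = vapply(res, `[[`, "", "direction"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    skipped = vapply(res, `[[`, logical(1), "skipped"),
    reason = vapply(res, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  df$adj_p <- NA_real_
  tested <- !df$skipped
  df$adj_p[tested] <- adjust_pvalues(df$p_value[tested], adjust)
  df$significant <- !df$skipped & df$adj_p < alpha
  df[order(df$adj_p, df$set_name), c("set_name", "n_in", "D", "direction",
                                     "p_value", "adj_p", "significant",
                                     "skipped", "reason")]
}

#' Map per-contrast DE genes onto metabolic reactions with attributes
#'
#' Reactions catalyzed by a DE gene of the oleic-arm contrast only get
#' attribute 1, of the EPA-arm contrast only attribute 2, of both
#' contrasts attribute 3; the three attribute classes partition the hit
#' reactions. DE genes absent from the mapping are reported as unmapped.
#'
#' @param signatures named list of \code{signature} objects; names must
#'   include \code{HFoleic_vs_reference} and \code{HFepa_vs_reference}.
#' @param mapping list with \code{gene2reaction} (data.frame gene_id,
#'   reaction_id) and \code{reaction2pathway} (data.frame reaction_id,
#'   pathway).
#' @return list with \code{reactions} (data.frame reaction_id, attribute),
#'   and \code{unmapped} (named list of DE gene ids missing from the
#'   mapping, per contrast).
#' @export
map_to_reactions <- function(signatures, mapping) {
  g2r <- mapping$gene2reaction
  needed <- c("HFoleic_vs_reference", "HFepa_vs_reference")
  if (!all(needed %in% names(signatures))) {
    stop("signatures must be named with: ", paste(needed, collapse = ", "))
  }
  de_genes <- lapply(signatures[needed], function(s) c(s$up, s$down))
  hit <- lapply(de_genes, function(g) {
    sort(unique(g2r$reaction_id[g2r$gene_id %in% g]))
  })
  unmapped <- lapply(de_genes, function(g) sort(setdiff(g, g2r$gene_id)))
  both <- intersect(hit[[1L]], hit[[2L]])
  only1 <- setdiff(hit$HFoleic_vs_reference, both)
  only2 <- setdiff(hit$HFepa_vs_reference, both)
  reactions <- data.frame(
    reaction_id = c(only1, only2, both),
    attribute = rep(c(1L, 2L, 3L), c(length(only1), length(only2),
                                     length(both))),
    stringsAsFactors = FALSE)
  reactions <- reactions[order(reactions$reaction_id), , drop = FALSE]
  rownames(reactions) <- NULL
  list(reactions = reactions, unmapped = unmapped)
}

#' Fisher enrichment of metabolic pathways in an attributed reaction set
#'
#' One-tailed Fisher exact test per pathway on the 2x2 table crossing
#' pathway membership with membership in the selected reaction subset,
#' over the universe of all mapped reactions, followed by
#' Benjamini-Hochberg adjustment across pathways.
#'
#' @param attributed result of \code{\link{map_to_reactions}} (or a
#'   data.frame with reaction_id, attribute).
#' @param mapping as in \code{\link{map_to_reactions}}.
#' @param subset which attribute classes to test, a subset of
#'   \code{c(1, 2, 3)} (default all three: any hit reaction).
#' @return data.frame pathway, n_pathway, n_overlap, p_value, adj_p,
#'   ordered by adjusted p. Pathways with zero reactions are skipped.
#' @export
reaction_pathway_enrichment <- function(attributed, mapping,
                                        subset = c(1L, 2L, 3L)) {
  rx <- if (is.data.frame(attributed)) attributed else attributed$reactions
  r2p <- mapping$reaction2pathway
  universe <- unique(r2p$reaction_id)
  selected <- intersect(rx$reaction_id[rx$attribute %in% subset], universe)
  pathways <- split(r2p$reaction_id, r2p$pathway)
  pathways <- pathways[lengths(pathways) > 0L]
  rows <- lapply(names(pathways), function(pw) {
    members <- unique(pathways[[pw]])
    ov <- length(intersect(members, selected))
    a <- ov
    b <- length(selected) - ov
    c_ <- length(members) - ov
    d <- length(universe) - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2L, 2L),
                     alternative = "greater")$p.value
    data.frame(pathway = pw, n_pathway = length(members), n_overlap = ov,
               p_value = p, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$adj_p <- adjust_pvalues(df$p_value, "BH")
  df <- df[order(df$adj_p, df$pathway), , drop = FALSE]
  rownames(df) <- NULL
  df
}
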