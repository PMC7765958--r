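#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the same distribution: the value at rank
#' r in each column becomes the mean over columns of the r-th smallest
#' values. Ties within a column receive the mean of the pooled reference
#' values at the tied ranks. Feature and sample identifiers are preserved.
#'
#' @param matrix numeric matrix, features x samples, no missing values.
#' @return matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("quantile_normalize expects a numeric matrix")
  }
  if (anyNA(matrix)) stop("matrix contains missing values")
  if (ncol(matrix) == 1L) {
    warning("single-sample matrix: quantile normalization is the identity")
    return(matrix)
  }
  ref <- rowMeans(apply(matrix, 2L, sort))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    o <- order(x)
    # tied values share the mean of the reference values at the sorted
    # positions the tie group occupies
    out[o, j] <- ave(ref, match(x[o], x[o]), FUN = mean)
  }
  out
}

## Vectorized two-sample t-tests across the rows of two matrices.
## Returns log2fc (mean1 - mean2), t, df, p. Degenerate rows (zero pooled
## standard error) get p = 1 when the means agree and p = 0 otherwise;
## NaN p-values are mapped to 1, keeping downstream ranks defined.
row_t_test <- function(x1, x2, var_equal = FALSE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  lfc <- m1 - m2
  t <- lfc / se
  p <- 2 * pt(-abs(t), df)
  degenerate <- se == 0
  p[degenerate & lfc == 0] <- 1
  p[degenerate & lfc != 0] <- 0
  p[is.nan(p)] <- 1
  data.frame(log2fc = lfc, t = t, df = df, p_value = p)
}

#' Differential expression between two conditions of a study
#'
#' Per-feature two-sided two-sample t-tests on log2 values (Welch by
#' default, pooled-variance optionally), with Benjamini-Hochberg adjustment
#' across all features of the contrast. The log2 fold change is
#' mean(group1) - mean(group2), group1 being the first-named condition of
#' the contrast.
#'
#' @param matrix numeric log2 expression matrix, features x samples.
#' @param annotation data.frame with columns \code{sample_id},
#'   \code{condition}; sample_id must match the matrix columns.
#' @param contrast string \code{"<group1>_vs_<group2>"}.
#' @param method \code{"welch"} (default) or \code{"pooled"}.
#' @param adj_threshold adjusted-p cutoff used for the \code{direction}
#'   call (default 0.05).
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{contrast}, \code{log2fc}, \code{p_value}, \code{adj_p},
#'   \code{direction} (\code{up}/\code{down}/\code{ns}).
#' @export
differential_expression <- function(matrix, annotation, contrast,
                                    method = c("welch", "pooled"),
                                    adj_threshold = 0.05) {
  method <- match.arg(method)
  groups <- parse_contrast(contrast, unique(annotation$condition))
  idx <- function(cond) {
    ids <- annotation$sample_id[annotation$condition == cond]
    j <- match(ids, colnames(matrix))
    if (anyNA(j)) stop("annotation sample ids missing from matrix columns")
    j
  }
  j1 <- idx(groups$group1); j2 <- idx(groups$group2)
  if (length(j1) < 2L || length(j2) < 2L) {
    stop("need at least 2 samples per group in contrast ", contrast)
  }
  tt <- row_t_test(matrix[, j1, drop = FALSE], matrix[, j2, drop = FALSE],
                   var_equal = method == "pooled")
  adj <- adjust_pvalues(tt$p_value, "BH")
  direction <- rep("ns", nrow(tt))
  direction[adj < adj_threshold & tt$log2fc > 0] <- "up"
  direction[adj < adj_threshold & tt$log2fc < 0] <- "down"
  data.frame(feature_id = rownames(matrix),
             contrast = contrast,
             log2fc = tt$log2fc,
             p_value = tt$p_value,
             adj_p = adj,
             direction = direction,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Adjust p-values for multiple testing (step-up FDR)
#'
#' Benjamini-Hochberg, or Benjamini-Yekutieli for arbitrary dependence
#' (BH multiplied by the harmonic-number factor), both clipped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} or \code{"BY"}.
#' @return adjusted p-values, same length and order as \code{p}.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Build an up/down phenotype signature from DE records
#'
#' Up signature: log2fc > 0 and adjusted p below the threshold; down
#' signature: log2fc < 0 and adjusted p below the threshold.
#'
#' @param records data.frame from \code{\link{differential_expression}}
#'   (one contrast only).
#' @param threshold adjusted-p cutoff, default 0.05.
#' @return object of class \code{signature}: list(contrast, up, down).
#' @export
build_signature <- function(records, threshold = 0.05) {
  stopifnot(all(c("feature_id", "log2fc", "adj_p", "contrast") %in%
                  names(records)))
  if (length(unique(records$contrast)) > 1L) {
    stop("records must come from a single contrast")
  }
  sig <- records$adj_p < threshold
  structure(list(contrast = records$contrast[1] %||% NA_character_,
                 up = sort(records$feature_id[sig & records$log2fc > 0]),
                 down = sort(records$feature_id[sig & records$log2fc < 0])),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat("signature [", x$contrast, "]: ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

#' miRNA differential expression with fold-change and raw-p criteria
#'
#' Same test machinery as \code{\link{differential_expression}}, but the
#' DE call requires |log2fc| strictly greater than \code{fc_threshold} and
#' raw p strictly below \code{p_threshold} (defaults 0.25 and 0.01, the
#' raw-p criterion standing in for an FDR of about 0.05 at miRNome scale).
#'
#' @inheritParams differential_expression
#' @param fc_threshold threshold on |log2fc| (strict), default 0.25.
#' @param p_threshold threshold on raw p (strict), default 0.01.
#' @return data.frame as \code{\link{differential_expression}}, with
#'   \code{direction} based on the miRNA criteria.
#' @export
mirna_differential_expression <- function(matrix, annotation, contrast,
                                          method = c("welch", "pooled"),
                                          fc_threshold = 0.25,
                                          p_threshold = 0.01) {
  stopifnot(fc_threshold > 0, p_threshold > 0)
  rec <- differential_expression(matrix, annotation, contrast,
                                 method = method)
  de <- abs(rec$log2fc) > fc_threshold & rec$p_value < p_threshold
  rec$direction <- ifelse(de & rec$log2fc > 0, "up",
                          ifelse(de & rec$log2fc < 0, "down", "ns"))
  rec
}
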