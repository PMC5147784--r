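## Comparative layer: correlation matrices over condition profiles,
## hierarchical clustering, PCA, Jensen-Shannon divergence, and the
## label-dominance score that quantifies species- vs tissue-driven
## clustering.

#' Condition-by-condition correlation matrix
#'
#' Correlates the columns of a profile matrix (features x conditions)
#' using pairwise-complete rows per column pair. Spearman is Pearson on
#' ranks with average ranks for ties. Pairs with fewer than `min_n`
#' complete rows get NA with a warning.
#'
#' @param m numeric matrix, features in rows, conditions in columns.
#' @param method "spearman" (default) or "pearson".
#' @param min_n minimum complete rows per pair (default 3).
#' @return square symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m, method = c("spearman", "pearson"),
                               min_n = 3) {
  method <- match.arg(method)
  cc <- stats::cor(m, method = method, use = "pairwise.complete.obs")
  ok <- crossprod(!is.na(m)) >= min_n
  if (any(!ok)) {
    warning("some condition pairs have fewer than ", min_n,
            " complete rows; their correlations are NA")
    cc[!ok] <- NA_real_
  }
  diag(cc) <- 1
  cc
}

#' Hierarchical clustering of conditions
#'
#' Agglomerative clustering with complete linkage on the Euclidean
#' distances between the rows of the correlation matrix (the behaviour
#' of the standard heatmap clustering of a correlation matrix). The
#' merge order is deterministic; equal-height ties resolve to the
#' lowest column index.
#'
#' @param cmat complete correlation matrix (no NA cells).
#' @return an object of class `hclust`.
#' @export
hcluster <- function(cmat) {
  if (any(is.na(cmat))) {
    stop("correlation matrix has missing cells; recompute upstream with ",
         "pairwise-complete rows before clustering")
  }
  stats::hclust(stats::dist(cmat), method = "complete")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust` object.
#' @param path optional file path; when given, the string is written
#'   there.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' PCA of condition profiles
#'
#' Conditions are the observations and features the variables; rows
#' with any missing value are dropped (complete cases); variables are
#' centered, not scaled, and scores come from singular value
#' decomposition.
#'
#' @param m numeric matrix, features in rows, conditions in columns.
#' @return list: `scores` (conditions x PCs), `variance_fraction`
#'   (fraction of total variance per PC, summing to 1), `n_features`
#'   (complete-case rows used).
#' @export
profile_pca <- function(m) {
  keep <- stats::complete.cases(m)
  if (sum(keep) < 1L) stop("no complete-case rows for PCA")
  if (ncol(m) < 2L) stop("need at least 2 conditions")
  p <- stats::prcomp(t(m[keep, , drop = FALSE]), center = TRUE,
                     scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, variance_fraction = vf, n_features = sum(keep))
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence between two nonnegative profiles
#'
#' Profiles are normalized to probability vectors; JSD uses base-2
#' logarithms, so it is bounded in [0, 1].
#'
#' @param p,q nonnegative numeric vectors with positive sums.
#' @return JSD (not its square root).
#' @export
jsd <- function(p, q) {
  if (sum(p) <= 0 || sum(q) <= 0) stop("profiles must have positive sums")
  p <- p / sum(p); q <- q / sum(q)
  .entropy2((p + q) / 2) - (.entropy2(p) + .entropy2(q)) / 2
}

#' Jensen-Shannon distance matrix over conditions
#'
#' Square root of the base-2 Jensen-Shannon divergence between every
#' pair of columns; the square root is a metric bounded in [0, 1].
#' Rows with any missing value are dropped before normalization.
#'
#' @param m numeric matrix, features in rows, conditions in columns,
#'   nonnegative.
#' @return symmetric matrix of distances with zero diagonal.
#' @export
jsd_matrix <- function(m) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (any(m < 0)) stop("profiles must be nonnegative")
  if (any(colSums(m) <= 0)) stop("all-zero column in profile matrix")
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d <- sqrt(max(jsd(m[, i], m[, j]), 0))
        out[i, j] <- d
        out[j, i] <- d
      }
    }
  }
  out
}

#' Nearest-neighbor label dominance
#'
#' For each condition, finds the nearest neighbor (highest off-diagonal
#' correlation; ties resolve to the lowest column index) and reports the
#' fraction of conditions whose nearest neighbor shares the given
#' label. Quantifies whether clustering is dominated by species or by
#' tissue/context.
#'
#' @param cmat correlation matrix with labeled conditions as
#'   row/column names.
#' @param labels character vector: the label (species or context) of
#'   each condition, in column order.
#' @return fraction in [0, 1].
#' @export
label_dominance <- function(cmat, labels) {
  stopifnot(length(labels) == ncol(cmat))
  n <- ncol(cmat)
  share <- vapply(seq_len(n), function(i) {
    x <- cmat[i, ]
    x[i] <- -Inf
    nn <- which.max(x)  # lowest index on ties
    labels[nn] == labels[i]
  }, logical(1))
  mean(share)
}
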