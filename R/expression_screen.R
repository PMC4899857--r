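#' Read a gene-by-sample expression matrix
#'
#' Delimited text, first column gene identifiers, remaining columns sample
#' (e.g. cell-line) expression values. Rows with any missing value are
#' dropped with a warning, so downstream z-scoring sees complete data.
#'
#' @param path tab-separated file with a header row.
#' @return numeric matrix, rownames = genes, colnames = samples.
#' @export
read_expression_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  ok <- stats::complete.cases(m)
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with missing values dropped: ",
            paste(head(genes[!ok], 5), collapse = ", "))
    m <- m[ok, , drop = FALSE]
  }
  m
}

#' Row-wise z-score transform
#'
#' Standardizes each gene's expression across samples: subtract the row
#' mean and divide by the row sample standard deviation (ddof = 1), the
#' transform applied to cross-cell-line expression panels before
#' coexpression analysis. Constant rows have no defined z-score and are
#' dropped with a warning.
#'
#' @param m numeric matrix (genes x samples).
#' @return matrix with each surviving row at mean 0, sd 1.
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning(sum(const), " constant row(s) dropped: ",
            paste(head(rownames(m)[const], 5), collapse = ", "))
    m <- m[!const, , drop = FALSE]; mu <- mu[!const]; s <- s[!const]
  }
  (m - mu) / s
}

#' Rank candidates by coexpression with a replication gene set
#'
#' Scores each candidate gene by the mean Pearson correlation of its
#' (z-scored) expression profile with every gene in a replication-associated
#' reference set, and returns the candidates sorted by decreasing mean
#' correlation. Genes lost to constant-row filtering are reported.
#'
#' @param m numeric matrix (genes x samples), raw or z-scored; correlation
#'   is affine-invariant so either works.
#' @param candidates character vector of candidate gene names.
#' @param replication_set character vector of reference gene names
#'   (non-empty).
#' @param top_k number of top candidates to return (default all).
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return data.frame `gene`, `mean_correlation`, sorted descending.
#' @export
coexpression_rank <- function(m, candidates, replication_set,
                              top_k = length(candidates),
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!length(replication_set)) stop("empty replication gene set")
  z <- suppressWarnings(zscore_rows(m))
  missing <- setdiff(c(candidates, replication_set), rownames(z))
  if (length(missing))
    stop("gene(s) absent from matrix after filtering: ",
         paste(missing, collapse = ", "))
  refs <- t(z[replication_set, , drop = FALSE])
  score <- vapply(candidates, function(g) {
    mean(cor(z[g, ], refs, method = method))
  }, 0)
  out <- data.frame(gene = candidates, mean_correlation = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_correlation), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_k)
}
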