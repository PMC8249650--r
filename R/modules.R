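## Differential screening, weighted co-expression module detection with
## eigengenes, and hypergeometric pathway enrichment.

#' Wilcoxon rank-sum test (exact for small samples, ties allowed)
#'
#' For `n_a + n_b <= exact_limit` the two-sided p-value is computed by
#' exhaustive enumeration of all `choose(n, n_a)` group assignments of the
#' mid-ranks (so ties are handled exactly); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' The two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))` where `W` is
#' the rank sum of the first group.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_limit Largest `n_a + n_b` for which enumeration is used
#'   (default 12).
#' @return List with `statistic` (rank sum of `x`) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12L) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  na <- length(x); nb <- length(y); n <- na + nb
  r <- rank(c(x, y))
  w <- sum(r[seq_len(na)])
  if (n <= exact_limit) {
    sums <- utils::combn(n, na, function(i) sum(r[i]))
    ## guard against floating noise in midrank sums
    p_le <- mean(sums <= w + 1e-9)
    p_ge <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = w, p.value = 1))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p.value = p)
}

#' Rank-based differential feature screen
#'
#' Features pass when both the Wilcoxon rank-sum p-value is at or below
#' `p_threshold` and the absolute log2 fold change of the group means
#' (with a pseudocount of 1) is at least `lfc_threshold`.
#'
#' @param mat Numeric matrix, features x samples (non-negative values,
#'   e.g. RPKM).
#' @param groups Character/factor vector over samples defining exactly
#'   two groups.
#' @param p_threshold Wilcoxon p-value cutoff (default 0.05).
#' @param lfc_threshold Minimum `|log2((mean_a + 1) / (mean_b + 1))|`
#'   (default 1).
#' @return Data frame (`feature`, `p_value`, `log2_fc`) for passing
#'   features.
#' @export
differential_features <- function(mat, groups, p_threshold = 0.05,
                                  lfc_threshold = 1) {
  lv <- unique(as.character(groups))
  if (length(lv) != 2L)
    stop("`groups` must define exactly two groups", call. = FALSE)
  a <- which(groups == lv[1L]); b <- which(groups == lv[2L])
  p <- apply(mat, 1L, function(row)
    wilcoxon_rank_sum(row[a], row[b])$p.value)
  lfc <- log2((rowMeans(mat[, a, drop = FALSE]) + 1) /
                (rowMeans(mat[, b, drop = FALSE]) + 1))
  keep <- p <= p_threshold & abs(lfc) >= lfc_threshold
  data.frame(feature = rownames(mat)[keep], p_value = p[keep],
             log2_fc = lfc[keep], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Detect co-expression modules (weighted-correlation clustering)
#'
#' A deterministic, simplified form of weighted gene co-expression
#' network analysis: signed adjacency
#' `a_ij = ((1 + cor_ij) / 2)^power`, topological overlap dissimilarity,
#' average-linkage hierarchical clustering, and a static tree cut at
#' `cut_height`. Clusters smaller than `min_module_size` are relabelled
#' `"unassigned"`; surviving modules are named `"M1"`, `"M2"`, ... by
#' decreasing size. Values are log2(x + 1)-transformed before correlation
#' when `log_transform = TRUE` (use for RPKM input; simulated
#' already-symmetric matrices should pass `FALSE`).
#'
#' @param mat Numeric matrix, genes x samples (>= 4 samples). Constant
#'   gene rows are dropped with a warning before correlation.
#' @param power Soft-thresholding exponent (default 6).
#' @param min_module_size Smallest reported module (default 30).
#' @param cut_height Static cut height on the topological-overlap
#'   dissimilarity dendrogram (default 0.65).
#' @param log_transform Apply `log2(x + 1)` first (default `FALSE`).
#' @return Object of class `coexpression_modules`: list with `labels`
#'   (named character vector, `"M1"`... or `"unassigned"`), `sizes`,
#'   `eigengenes` (samples x modules matrix of unit-norm eigengenes),
#'   `variance_explained`, `dendrogram` (the `hclust`), and `params`.
#' @export
detect_modules <- function(mat, power = 6, min_module_size = 30L,
                           cut_height = 0.65, log_transform = FALSE) {
  if (ncol(mat) < 4L) stop("need >= 4 samples", call. = FALSE)
  if (nrow(mat) < min_module_size)
    stop("need at least `min_module_size` genes", call. = FALSE)
  if (log_transform) {
    if (any(mat < 0)) stop("negative values with log_transform", call. = FALSE)
    mat <- log2(mat + 1)
  }
  const <- apply(mat, 1L, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant gene row(s) removed before correlation",
            call. = FALSE)
    mat <- mat[!const, , drop = FALSE]
  }
  genes <- rownames(mat) %||% paste0("gene_", seq_len(nrow(mat)))

  adj <- ((1 + stats::cor(t(mat))) / 2)^power
  diag(adj) <- 0
  k <- rowSums(adj)
  shared <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (shared + adj) / denom
  diag(tom) <- 1
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  ## floating rounding can leave average-linkage heights microscopically
  ## non-monotone (e.g. at zero noise); cutree requires sorted heights
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  cl <- stats::cutree(hc, h = cut_height)

  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- rep("unassigned", length(cl))
  if (length(big)) {
    ord <- big[order(-as.integer(sizes[big]), as.integer(big))]
    for (i in seq_along(ord))
      labels[cl == as.integer(ord[i])] <- paste0("M", i)
  }
  names(labels) <- genes

  mods <- setdiff(sort(unique(labels)), "unassigned")
  eig <- NULL; varexp <- NULL
  if (length(mods)) {
    eig <- matrix(NA_real_, ncol(mat), length(mods),
                  dimnames = list(colnames(mat), mods))
    varexp <- stats::setNames(numeric(length(mods)), mods)
    for (m in mods) {
      me <- module_eigengene(mat[labels == m, , drop = FALSE])
      eig[, m] <- me$eigengene
      varexp[m] <- me$variance_explained
    }
  }
  structure(list(labels = labels,
                 sizes = table(labels), eigengenes = eig,
                 variance_explained = varexp, dendrogram = hc,
                 params = list(power = power,
                               min_module_size = min_module_size,
                               cut_height = cut_height)),
            class = "coexpression_modules")
}

#' @export
print.coexpression_modules <- function(x, ...) {
  n_mod <- sum(names(x$sizes) != "unassigned")
  cat(sprintf("Co-expression modules: %d module(s) over %d genes\n",
              n_mod, length(x$labels)))
  print(x$sizes)
  invisible(x)
}

#' Plot module eigengenes as per-sample bars
#'
#' @param x A `coexpression_modules` object.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @method plot coexpression_modules
#' @export
plot.coexpression_modules <- function(x, ...) {
  if (is.null(x$eigengenes)) {
    warning("no modules to plot", call. = FALSE)
    return(invisible(x))
  }
  mods <- colnames(x$eigengenes)
  old <- graphics::par(mfrow = c(length(mods), 1L),
                       mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in mods)
    graphics::barplot(x$eigengenes[, m], main = m,
                      ylab = "eigengene", las = 2, ...)
  invisible(x)
}

#' Module eigengene (first principal direction)
#'
#' The eigengene is the first right singular vector of the
#' gene-standardized module submatrix: one unit-norm value per sample,
#' sign-oriented so its correlation with the module's mean expression
#' profile is positive. The fraction of variance explained is also
#' reported.
#'
#' @param mat Numeric matrix: the module's genes x samples (>= 2 genes).
#' @return List with `eigengene` (named per-sample vector, unit norm)
#'   and `variance_explained`.
#' @export
module_eigengene <- function(mat) {
  if (nrow(mat) < 2L) stop("module must have >= 2 genes", call. = FALSE)
  sds <- apply(mat, 1L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("degenerate module: all gene rows constant",
                       call. = FALSE)
  x <- t(scale(t(mat[keep, , drop = FALSE])))
  sv <- svd(x)
  if (sv$d[1L] == 0) stop("degenerate (rank-0) module submatrix",
                          call. = FALSE)
  e <- sv$v[, 1L]
  profile <- colMeans(mat)
  if (stats::sd(profile) > 0 && stats::cor(e, profile) < 0) e <- -e
  names(e) <- colnames(mat)
  list(eigengene = e,
       variance_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Hypergeometric pathway over-representation test
#'
#' For each pathway, with `N` background genes, `K` of them in the
#' pathway, a module of `n` genes and an overlap of `k`, the p-value is
#' the exact upper tail `P(X >= k)` of the hypergeometric distribution,
#' computed by summation of point masses. P-values are
#' Benjamini-Hochberg-adjusted across pathways.
#'
#' @param module_genes Character vector of module gene ids (subset of
#'   `background`).
#' @param pathway_sets Named list of pathway gene-id vectors (subsets of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @return Data frame with `pathway`, `k`, `K`, `n`, `N`, `p_value`,
#'   `adjusted_p`, ordered by p-value.
#' @export
hypergeometric_enrichment <- function(module_genes, pathway_sets,
                                      background) {
  background <- unique(background)
  N <- length(background)
  if (!all(module_genes %in% background))
    stop("module genes must be contained in the background", call. = FALSE)
  n <- length(unique(module_genes))
  res <- lapply(names(pathway_sets), function(pw) {
    set <- unique(pathway_sets[[pw]])
    if (!all(set %in% background))
      stop("pathway `", pw, "` contains genes outside the background",
           call. = FALSE)
    K <- length(set)
    k <- length(intersect(module_genes, set))
    p <- sum(stats::dhyper(k:min(K, n), K, N - K, n))
    data.frame(pathway = pw, k = k, K = K, n = n, N = N,
               p_value = min(1, p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 the expected agreement of random
#' labelings.
#'
#' @param a,b Label vectors of equal length (any types coercible to
#'   factors).
#' @return A number `<= 1`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(length(a))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
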