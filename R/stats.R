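# Descriptive multivariate layer: per-feature one-way ANOVA with
# Tukey-Kramer letters, correlation-matrix PCA, and Ward clustering of
# class means.

#' One-way ANOVA with Tukey-Kramer letters for one feature
#'
#' Fits a one-way ANOVA of one descriptor against the class label, runs
#' Tukey's HSD post hoc test (the Tukey-Kramer form, valid for unequal
#' group sizes), and summarizes the pairwise results as a compact letter
#' display: classes sharing no letter differ at level `alpha`, classes
#' sharing a letter do not.
#'
#' @param table Labeled feature data.frame (needs `class_id` and the
#'   feature column).
#' @param feature Feature column name, e.g. `"AR"`.
#' @param alpha Significance level (default 0.05).
#' @param group Grouping column (default `"class_id"`).
#' @return Object of class `tukey_result`: `feature`, `F`, `p`,
#'   `group_letters` (named character vector), `pairwise` (data.frame with
#'   per-pair differences and adjusted p-values).
#' @export
anova_tukey <- function(table, feature, alpha = 0.05, group = "class_id") {
  stopifnot(feature %in% names(table), group %in% names(table))
  g <- factor(table[[group]])
  if (nlevels(g) < 2) stop("need at least 2 classes")
  counts <- base::table(g)
  if (any(counts < 2))
    stop("class with fewer than 2 rows: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  y <- table[[feature]]
  fit <- stats::aov(y ~ g)
  av <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, strsplit(rownames(hsd), "-", fixed = TRUE))
  pairwise <- data.frame(class_a = pairs[, 1], class_b = pairs[, 2],
                         diff = hsd[, "diff"], p_adj = hsd[, "p adj"],
                         row.names = NULL)
  letters <- letter_display(levels(g), pairwise, alpha)
  structure(list(feature = feature, F = av[["F value"]][1],
                 p = av[["Pr(>F)"]][1], group_letters = letters,
                 pairwise = pairwise, alpha = alpha),
            class = "tukey_result")
}

# compact letter display by insert-and-absorb
letter_display <- function(groups, pairwise, alpha) {
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  cols <- list(groups)  # each column = set of groups sharing a letter
  for (r in seq_len(nrow(sig))) {
    a <- sig$class_a[r]; b <- sig$class_b[r]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else new_cols <- c(new_cols, list(col))
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_cols[[i]] %in% new_cols[[j]]) &&
          !(all(new_cols[[j]] %in% new_cols[[i]]) && i < j))
        keep[i] <- FALSE
    }
    cols <- new_cols[keep]
  }
  out <- setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols))
    for (gname in cols[[ci]])
      out[gname] <- paste0(out[gname], letters[ci])
  out
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("%s: F = %.2f, p = %.3g (one-way ANOVA), Tukey-Kramer at alpha = %g\n",
              x$feature, x$F, x$p, x$alpha))
  print(x$group_letters)
  invisible(x)
}

#' Principal component analysis of a feature table
#'
#' Columns are centered and, by default, scaled to unit variance
#' (correlation-matrix PCA) so no descriptor dominates through its raw
#' scale; `standardize = FALSE` gives raw-covariance PCA.
#'
#' @param table Data.frame or matrix of feature columns only.
#' @param standardize Scale columns to unit variance (default TRUE).
#' @return Object of class `pca_result`: `explained` (percent variance per
#'   component, summing to 100), `loadings` (feature x component, orthonormal
#'   columns), `scores` (sample x component).
#' @export
pca_features <- function(table, standardize = TRUE) {
  X <- as.matrix(table)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need at least 2 rows and 2 features")
  if (standardize && any(apply(X, 2, sd) == 0))
    stop("constant column cannot be standardized")
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(explained = expl, loadings = pc$rotation, scores = pc$x,
                 standardized = standardize),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA (", if (x$standardized) "correlation" else "covariance",
      " matrix): explained % = ",
      paste(sprintf("%.1f", x$explained[seq_len(min(4, length(x$explained)))]),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering of class mean descriptor vectors
#'
#' Standardizes the class-mean matrix column-wise, computes Euclidean
#' distances and clusters agglomeratively (Ward linkage by default). Merge
#' heights are non-decreasing; for two classes the single merge height is
#' their Euclidean distance.
#'
#' @param class_means Class x feature matrix or data.frame (rownames =
#'   class labels).
#' @param linkage An `hclust` method (default `"ward.D2"`).
#' @param standardize Scale columns before clustering (default TRUE).
#' @return An `hclust` object (fields `merge`, `height`, `labels`).
#' @export
hcluster_classes <- function(class_means, linkage = "ward.D2",
                             standardize = TRUE) {
  X <- as.matrix(class_means)
  if (nrow(X) < 2) stop("need at least 2 classes")
  if (standardize) {
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1
    X <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  }
  stats::hclust(stats::dist(X), method = linkage)
}

#' Per-class mean vectors of the nine descriptors
#'
#' @param table Labeled feature data.frame.
#' @param group Grouping column (default `"class_id"`).
#' @return Class x feature matrix of means.
#' @export
class_mean_table <- function(table, group = "class_id") {
  feats <- intersect(FEATURE_NAMES, names(table))
  m <- do.call(rbind, lapply(split(table[feats], table[[group]]), colMeans))
  m
}

#' Write stats results (ANOVA letters, PCA, dendrogram) as CSV files
#'
#' @param tukeys List of `tukey_result`s (one per feature).
#' @param pca A `pca_result` (or NULL).
#' @param hc An `hclust` (or NULL).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_stats_results <- function(tukeys, pca = NULL, hc = NULL, dir = ".") {
  paths <- character(0)
  if (length(tukeys)) {
    anova_df <- do.call(rbind, lapply(tukeys, function(t)
      data.frame(feature = t$feature, F = t$F, p = t$p)))
    p1 <- file.path(dir, "anova.csv"); write.csv(anova_df, p1, row.names = FALSE)
    letters_df <- do.call(rbind, lapply(tukeys, function(t)
      data.frame(feature = t$feature, class = names(t$group_letters),
                 letters = unname(t$group_letters))))
    p2 <- file.path(dir, "tukey_letters.csv"); write.csv(letters_df, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  if (!is.null(pca)) {
    p3 <- file.path(dir, "pca_explained.csv")
    write.csv(data.frame(component = seq_along(pca$explained),
                         explained_pct = pca$explained), p3, row.names = FALSE)
    p4 <- file.path(dir, "pca_loadings.csv")
    write.csv(data.frame(feature = rownames(pca$loadings), pca$loadings),
              p4, row.names = FALSE)
    paths <- c(paths, p3, p4)
  }
  if (!is.null(hc)) {
    p5 <- file.path(dir, "dendrogram_merges.csv")
    write.csv(data.frame(step = seq_along(hc$height),
                         left = hc$merge[, 1], right = hc$merge[, 2],
                         height = hc$height), p5, row.names = FALSE)
    paths <- c(paths, p5)
  }
  invisible(paths)
}
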