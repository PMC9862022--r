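#' Welch unequal-variance t test
#'
#' Two-sided Welch t with Welch-Satterthwaite degrees of freedom. If both
#' groups have zero variance and equal means the statistic is defined as 0
#' with p = 1; any other zero-variance situation is handled with a small
#' variance floor and a warning.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_floor Variance floor used when a group is constant.
#' @return A list with `t`, `df`, `p`.
#' @examples
#' welch_t(c(0, 1, 2), c(3, 4, 5))
#' @export
welch_t <- function(a, b, var_floor = 1e-12) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    warning("both groups constant with different means; applying variance floor")
    va <- vb <- var_floor
  } else if (va == 0 || vb == 0) {
    warning("one group constant; applying variance floor")
    va <- max(va, var_floor)
    vb <- max(vb, var_floor)
  }
  ws <- welch_stat(mean(a), va, length(a), mean(b), vb, length(b))
  ws
}

# core Welch computation from moments; vectorized
welch_stat <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Welch t test from summary statistics
#'
#' The same Welch formulas as [welch_t()], evaluated from group means,
#' standard deviations and sizes — as needed to reproduce a demographic
#' table's t test from its printed summaries.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A list with `t`, `df`, `p`.
#' @examples
#' t_from_summary(54.3, 11.7, 200, 63.7, 14.5, 101)
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  welch_stat(mean1, sd1^2, n1, mean2, sd2^2, n2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values, clipped at 1, returned in the
#' input order. Thin wrapper over `stats::p.adjust(method = "BH")` that
#' validates the input range.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (q-values), same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression between two sample groups
#'
#' For every gene, a Welch t test between the two groups on `log2(x + 1)`
#' values (or raw values with `scale = "linear"`), a fold change, a
#' Benjamini-Hochberg adjustment across all tested genes, and a volcano
#' classification: `over` if the fold change is at least `fc_high` and
#' `q < alpha`, `under` if at most `fc_low` and `q < alpha`, otherwise `ns`.
#' Genes constant across both groups get `t = 0, p = 1, ns`.
#'
#' The default fold-change estimator is geometric:
#' `log2fc = mean(log2(x + 1))_B - mean(log2(x + 1))_A`, the usual log2FC
#' of t-test expression pipelines, which is robust to the heavy right tail
#' of expression data. `fc_method = "linear"` instead uses the ratio of
#' linear-scale group means `(mean_B + eps) / (mean_A + eps)`; that
#' estimator has high sampling variance on log-normal data at moderate group
#' sizes.
#'
#' @param expression Expression tibble (`gene` column + sample columns).
#' @param clinical Clinical tibble with `sample` and `group`.
#' @param group_a Reference group label (e.g. `"Normal"`).
#' @param group_b Comparison group label (e.g. `"PP"`); fold changes are
#'   B over A.
#' @param scale Test scale: `"log2"` (default, variance-stabilised) or
#'   `"linear"`.
#' @param fc_method Fold-change estimator: `"geometric"` (default) or
#'   `"linear"` (ratio of linear means).
#' @param fc_low,fc_high Linear fold-change thresholds for `under`/`over`.
#' @param alpha Adjusted-p threshold.
#' @param eps Pseudocount for the linear fold-change ratio.
#' @return A tibble `gene`, `t`, `df`, `p`, `q`, `log2fc`, `class` with
#'   attribute `contrast`.
#' @seealso [select_group_specific()], [plot_volcano()]
#' @export
differential_expression <- function(expression, clinical, group_a, group_b,
                                    scale = c("log2", "linear"),
                                    fc_method = c("geometric", "linear"),
                                    fc_low = 0.5, fc_high = 2, alpha = 0.05,
                                    eps = 1e-3) {
  scale <- match.arg(scale)
  fc_method <- match.arg(fc_method)
  sa <- intersect(expr_samples(expression),
                  clinical$sample[clinical$group == group_a])
  sb <- intersect(expr_samples(expression),
                  clinical$sample[clinical$group == group_b])
  if (length(sa) < 2 || length(sb) < 2) {
    stop("need at least 2 samples per group; got ",
         length(sa), " [", group_a, "] and ", length(sb), " [", group_b, "]")
  }
  ma <- as.matrix(expression[sa])
  mb <- as.matrix(expression[sb])
  ta <- if (scale == "log2") log2(ma + 1) else ma
  tb <- if (scale == "log2") log2(mb + 1) else mb

  n1 <- ncol(ta); n2 <- ncol(tb)
  m1 <- rowMeans(ta); m2 <- rowMeans(tb)
  v1 <- rowSums((ta - m1)^2) / (n1 - 1)
  v2 <- rowSums((tb - m2)^2) / (n2 - 1)
  const <- v1 == 0 & v2 == 0
  # variance floor keeps the vectorized formulas defined; constant genes are
  # overwritten below
  ws <- welch_stat(m2, pmax(v2, 1e-12), n2, m1, pmax(v1, 1e-12), n1)
  t <- ws$t; df <- ws$df; p <- ws$p
  t[const & m1 == m2] <- 0
  p[const & m1 == m2] <- 1
  fc <- if (fc_method == "geometric") {
    2^(rowMeans(log2(mb + 1)) - rowMeans(log2(ma + 1)))
  } else {
    (rowMeans(mb) + eps) / (rowMeans(ma) + eps)
  }
  q <- bh_adjust(p)
  res <- tibble::tibble(
    gene = expression$gene,
    t = unname(t), df = unname(df), p = unname(p), q = unname(q),
    log2fc = unname(log2(fc)),
    class = dplyr::case_when(
      const & m1 == m2 ~ "ns",
      fc >= fc_high & q < alpha ~ "over",
      fc <= fc_low & q < alpha ~ "under",
      .default = "ns"
    )
  )
  attr(res, "contrast") <- c(a = group_a, b = group_b)
  res
}

#' Select genes differentially expressed in one prognosis group only
#'
#' Set algebra over two differential-expression tables sharing a gene
#' universe (each tumour group against normal tissue): genes over- or
#' under-expressed in PP but not in GP, in GP but not in PP, and in both.
#'
#' @param de_pp DE table for PP vs Normal (from
#'   [differential_expression()]).
#' @param de_gp DE table for GP vs Normal, over the same genes.
#' @return An object of class `gene_set_selection`: a named list of character
#'   vectors `pp_only_over`, `pp_only_under`, `gp_only_over`,
#'   `gp_only_under`, `shared_over`, `shared_under`.
#' @export
select_group_specific <- function(de_pp, de_gp) {
  if (!setequal(de_pp$gene, de_gp$gene) || nrow(de_pp) != nrow(de_gp)) {
    stop("DE tables cover different gene universes")
  }
  sets <- function(de, cls) de$gene[de$class == cls]
  pp_over <- sets(de_pp, "over"); pp_under <- sets(de_pp, "under")
  gp_over <- sets(de_gp, "over"); gp_under <- sets(de_gp, "under")
  structure(
    list(
      pp_only_over = setdiff(pp_over, gp_over),
      pp_only_under = setdiff(pp_under, gp_under),
      gp_only_over = setdiff(gp_over, pp_over),
      gp_only_under = setdiff(gp_under, pp_under),
      shared_over = intersect(pp_over, gp_over),
      shared_under = intersect(pp_under, gp_under)
    ),
    class = "gene_set_selection"
  )
}

#' @export
print.gene_set_selection <- function(x, ...) {
  cat("<gene_set_selection>\n")
  for (nm in names(x)) cat("  ", nm, ": ", length(x[[nm]]), " genes\n", sep = "")
  invisible(x)
}

#' Two-component principal component analysis of samples
#'
#' Projects samples onto the top two principal directions of the
#' `log2(x + 1)` expression of a gene set, after per-gene centring and (by
#' default) unit-variance scaling. The sign of each component is fixed so
#' that the largest-magnitude gene loading is positive.
#'
#' @param expression Expression tibble.
#' @param genes Genes to use; default all. Constant genes are dropped.
#' @param clinical Optional clinical tibble with `sample`, `group`; adds a
#'   `group` column to the scores.
#' @param standardize Scale genes to unit variance before the SVD.
#' @return An object of class `pca2`: list with `scores` (tibble `sample`,
#'   `PC1`, `PC2`, optional `group`), `var_explained` (length 2),
#'   `loadings`, and `rank_deficient` flag.
#' @export
pca2 <- function(expression, genes = NULL, clinical = NULL,
                 standardize = TRUE) {
  genes <- genes %||% expression$gene
  miss <- setdiff(genes, expression$gene)
  if (length(miss) > 0) {
    stop("gene(s) not in expression table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  samples <- expr_samples(expression)
  if (length(genes) < 2 || length(samples) < 3) {
    stop("pca2() needs >= 2 genes and >= 3 samples")
  }
  x <- log2(t(as.matrix(expression[match(genes, expression$gene), samples])) + 1)
  colnames(x) <- genes
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  x <- scale(x[, keep, drop = FALSE], center = TRUE,
             scale = if (standardize) sds[keep] else FALSE)
  sv <- svd(x)
  d2 <- sv$d^2
  rank_deficient <- sum(d2 > d2[1] * 1e-12) < 2
  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2, 2)
  loadings <- sv$v[, 1:2, drop = FALSE]
  # deterministic sign: largest-|loading| gene positive per component
  for (j in 1:2) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  sc <- tibble::tibble(sample = samples, PC1 = scores[, 1], PC2 = scores[, 2])
  if (!is.null(clinical)) {
    sc <- dplyr::left_join(sc, dplyr::select(clinical, "sample", "group"),
                           by = "sample")
  }
  structure(
    list(scores = sc,
         var_explained = d2[1:2] / sum(d2),
         loadings = tibble::tibble(gene = colnames(x),
                                   PC1 = loadings[, 1], PC2 = loadings[, 2]),
         rank_deficient = rank_deficient),
    class = "pca2"
  )
}

#' @export
print.pca2 <- function(x, ...) {
  cat("<pca2> ", nrow(x$scores), " samples; variance explained ",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " / "),
      if (x$rank_deficient) " (rank deficient)" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy PCA scores
#' @param x A `pca2` object.
#' @param ... Unused.
#' @return The per-sample score tibble.
#' @export
tidy.pca2 <- function(x, ...) x$scores

#' @export
autoplot.pca2 <- function(object, ...) {
  aes <- if ("group" %in% names(object$scores)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(object$scores, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    )
}

#' Volcano plot of a differential-expression table
#'
#' @param de Tibble from [differential_expression()].
#' @param label_top Number of most significant genes to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, label_top = 0) {
  p <- ggplot2::ggplot(de, ggplot2::aes(.data$log2fc, -log10(.data$q),
                                        colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(over = "#d73027", under = "#4575b4", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p")
  if (label_top > 0) {
    lab <- de |> dplyr::filter(.data$class != "ns") |>
      dplyr::slice_min(.data$q, n = label_top, with_ties = FALSE)
    p <- p + ggplot2::geom_text(
      data = lab, mapping = ggplot2::aes(label = .data$gene),
      size = 2.5, vjust = -0.6, show.legend = FALSE
    )
  }
  p
}
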