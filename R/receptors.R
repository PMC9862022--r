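#' Determine receptor positivity thresholds by Gaussian deconvolution
#'
#' For each receptor gene (by default *ESR1* for ER, *PGR* for PR and *ERBB2*
#' for HER2), fits a two-component Gaussian mixture to the log10-transformed
#' expression of tumour samples and takes the density intersection between the
#' negative and positive components as the positivity threshold.
#'
#' Mixtures are fitted on tumour samples only (normal tissue is excluded)
#' unless `include_normals = TRUE`; normal tissue would otherwise inflate the
#' low component. Zeros are admitted through a `log10(x + eps)` transform.
#'
#' @param expression Expression table: a tibble with a `gene` column and one
#'   numeric column per sample (see [read_expression()]).
#' @param clinical Clinical table with `sample` and `group` columns (from
#'   [classify_prognosis()] or [simulate_cohort()]); used to restrict fitting
#'   to tumour samples. May be `NULL`, in which case all columns are used.
#' @param genes Character vector of receptor gene symbols.
#' @param include_normals Also use normal-tissue samples when fitting.
#' @param eps Pseudocount added before the log10 transform.
#' @param ... Passed on to [fit_gmm1d()].
#'
#' @return A tibble with one row per receptor gene: `gene`, `threshold`
#'   (log10 scale), `in_interval` and a `fit` list-column of `gmm_fit`
#'   objects.
#' @seealso [call_receptors()], [subtype_calls()]
#' @export
receptor_thresholds <- function(expression, clinical = NULL,
                                genes = c("ESR1", "PGR", "ERBB2"),
                                include_normals = FALSE, eps = 1e-3, ...) {
  missing_genes <- setdiff(genes, expression$gene)
  if (length(missing_genes) > 0) {
    stop("receptor gene(s) not in expression table: ",
         paste(missing_genes, collapse = ", "))
  }
  samples <- expr_samples(expression)
  if (!is.null(clinical) && !include_normals) {
    tumor <- clinical$sample[clinical$group %in% c("GP", "PP")]
    samples <- intersect(samples, tumor)
  }
  purrr::map_dfr(genes, function(g) {
    vals <- log10(as.numeric(expression[expression$gene == g, samples]) + eps)
    fit <- fit_gmm1d(vals, k = 2, ...)
    thr <- gaussian_intersection(fit)
    tibble::tibble(
      gene = g,
      threshold = as.numeric(thr),
      in_interval = attr(thr, "in_interval"),
      fit = list(fit)
    )
  })
}

#' Call per-sample receptor status against fitted thresholds
#'
#' A sample is positive for a receptor iff its log10 expression strictly
#' exceeds the threshold; a value exactly at the threshold is negative.
#'
#' @param expression Expression table (tibble with `gene` column).
#' @param thresholds Tibble from [receptor_thresholds()] (columns `gene`,
#'   `threshold`), or a named numeric vector of log10 thresholds.
#' @param samples Samples to call; defaults to every sample column.
#' @param eps Pseudocount matching the one used for threshold fitting.
#'
#' @return A tibble with `sample` and one logical column per receptor gene
#'   (`TRUE` = positive).
#' @export
call_receptors <- function(expression, thresholds, samples = NULL, eps = 1e-3) {
  if (is.numeric(thresholds)) {
    thresholds <- tibble::tibble(gene = names(thresholds),
                                 threshold = unname(thresholds))
  }
  missing_genes <- setdiff(thresholds$gene, expression$gene)
  if (length(missing_genes) > 0) {
    stop("receptor gene(s) not in expression table: ",
         paste(missing_genes, collapse = ", "))
  }
  samples <- samples %||% expr_samples(expression)
  out <- tibble::tibble(sample = samples)
  for (i in seq_len(nrow(thresholds))) {
    g <- thresholds$gene[i]
    vals <- log10(as.numeric(expression[expression$gene == g, samples]) + eps)
    out[[g]] <- vals > thresholds$threshold[i]
  }
  out
}

#' Assign a surrogate intrinsic subtype from ER/PR/HER2 status
#'
#' Implements the clinical surrogate rules: Luminal A is (ER+ and/or PR+) and
#' HER2-; Luminal B is (ER+ and/or PR+) and HER2+; HER2-enriched is ER-, PR-
#' and HER2+; Triple Negative is ER-, PR- and HER2-. Vectorised; a total
#' function of the three statuses.
#'
#' @param er,pr,her2 Logical vectors (`TRUE` = positive).
#' @return A character vector with levels `"Luminal A"`, `"Luminal B"`,
#'   `"HER2 enriched"`, `"Triple Negative"`.
#' @examples
#' assign_subtype(TRUE, FALSE, FALSE)   # Luminal A
#' assign_subtype(FALSE, TRUE, TRUE)    # Luminal B
#' assign_subtype(FALSE, FALSE, FALSE)  # Triple Negative
#' @export
assign_subtype <- function(er, pr, her2) {
  stopifnot(is.logical(er), is.logical(pr), is.logical(her2))
  hormone <- er | pr
  dplyr::case_when(
    hormone & !her2 ~ "Luminal A",
    hormone & her2 ~ "Luminal B",
    !hormone & her2 ~ "HER2 enriched",
    .default = "Triple Negative"
  )
}

#' Receptor status and subtype for every tumour sample
#'
#' Convenience wrapper: calls receptors against thresholds and maps the three
#' statuses to the surrogate intrinsic subtype.
#'
#' @inheritParams call_receptors
#' @param er_gene,pr_gene,her2_gene Symbols of the genes standing in for the
#'   three receptors in `thresholds`.
#' @return A tibble `sample`, `er`, `pr`, `her2` (logical), `subtype`.
#' @export
subtype_calls <- function(expression, thresholds, samples = NULL, eps = 1e-3,
                          er_gene = "ESR1", pr_gene = "PGR",
                          her2_gene = "ERBB2") {
  calls <- call_receptors(expression, thresholds, samples = samples, eps = eps)
  tibble::tibble(
    sample = calls$sample,
    er = calls[[er_gene]],
    pr = calls[[pr_gene]],
    her2 = calls[[her2_gene]],
    subtype = assign_subtype(calls[[er_gene]], calls[[pr_gene]],
                             calls[[her2_gene]])
  )
}

#' Cross-tabulate positivity for a pair of receptors
#'
#' Percentages of samples in each of the four status combinations for a pair
#' of receptors, as reported alongside receptor scatterplots.
#'
#' @param calls Tibble from [call_receptors()] or [subtype_calls()].
#' @param a,b Names of two logical status columns in `calls`.
#' @return A tibble with `a_status`, `b_status`, `n`, `percent` (of all
#'   samples in `calls`).
#' @export
receptor_crosstab <- function(calls, a, b) {
  stopifnot(a %in% names(calls), b %in% names(calls))
  tab <- calls |>
    dplyr::count(a_status = .data[[a]], b_status = .data[[b]], name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n))
  tidyr::complete(tab,
                  a_status = c(FALSE, TRUE), b_status = c(FALSE, TRUE),
                  fill = list(n = 0L, percent = 0)) |>
    dplyr::arrange(dplyr::desc(.data$a_status), dplyr::desc(.data$b_status))
}
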