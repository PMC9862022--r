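#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the probability-mass two-sided rule: the
#' p-value sums the probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. Computed via
#' `stats::fisher.test()`, which implements exactly this definition. A zero
#' margin makes every table equally (un)informative: p = 1 with a warning.
#'
#' @param tbl A 2x2 integer matrix of counts, rows = groups, columns =
#'   in-category / not. Alternatively pass the four counts `a, b, c, d`
#'   (row-wise) as separate arguments.
#' @param a,b,c,d Row-wise cell counts, used when `tbl` is missing.
#' @return A list with `p`, `odds_ratio` (conditional MLE), and the table.
#' @examples
#' fisher_exact(a = 0, b = 200, c = 12, d = 89)$p   # < 0.0001
#' fisher_exact(a = 49, b = 151, c = 9, d = 92)$p   # ~ 0.001
#' @export
fisher_exact <- function(tbl = NULL, a = NULL, b = NULL, c = NULL, d = NULL) {
  if (is.null(tbl)) tbl <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  storage.mode(tbl) <- "integer"
  stopifnot(identical(dim(tbl), c(2L, 2L)), all(tbl >= 0))
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    warning("zero margin; Fisher exact test is degenerate, p = 1")
    return(list(p = 1, odds_ratio = NA_real_, table = tbl))
  }
  ft <- stats::fisher.test(tbl)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tbl)
}

#' Demographic table with group-comparison statistics
#'
#' Builds the GP-vs-PP comparison of a clinical demographics table: a Welch
#' t test for age from per-group summaries, and a two-sided Fisher exact test
#' for each categorical level (stage, subtype, race), each level tested as
#' in-category vs not within tumour samples.
#'
#' @param clinical Clinical tibble with `group` (`GP`/`PP`), `age` and any of
#'   the columns named in `categories`.
#' @param categories Categorical clinical columns to tabulate.
#' @return A tibble: `variable`, `level`, `n_gp`, `n_pp`, `test`, `p`.
#' @export
table1_stats <- function(clinical,
                         categories = intersect(c("stage", "subtype", "race"),
                                                names(clinical))) {
  tum <- dplyr::filter(clinical, .data$group %in% c("GP", "PP"))
  gp <- dplyr::filter(tum, .data$group == "GP")
  pp <- dplyr::filter(tum, .data$group == "PP")
  rows <- list()
  if ("age" %in% names(tum)) {
    tt <- t_from_summary(mean(gp$age), stats::sd(gp$age), nrow(gp),
                         mean(pp$age), stats::sd(pp$age), nrow(pp))
    rows[[1]] <- tibble::tibble(variable = "age", level = "mean",
                                n_gp = nrow(gp), n_pp = nrow(pp),
                                test = "welch_t", p = tt$p)
  }
  cat_rows <- purrr::map_dfr(categories, function(v) {
    purrr::map_dfr(sort(unique(tum[[v]])), function(lv) {
      a <- sum(gp[[v]] == lv); b <- nrow(gp) - a
      cc <- sum(pp[[v]] == lv); d <- nrow(pp) - cc
      tibble::tibble(variable = v, level = as.character(lv),
                     n_gp = a, n_pp = cc, test = "fisher",
                     p = fisher_exact(a = a, b = b, c = cc, d = d)$p)
    })
  })
  dplyr::bind_rows(rows, cat_rows)
}

#' Logistic regression for independent clinical prognosis factors
#'
#' Binomial logistic regression of poor prognosis (PP = 1) versus good
#' prognosis (GP = 0) on dichotomised clinical factors: age above the cohort
#' median, late stage (III-IV vs I-II), and any further predictors supplied.
#' Maximum likelihood via `stats::glm`; Wald standard errors, odds ratios and
#' 95% confidence intervals. Complete or quasi-complete separation is
#' flagged when a coefficient's magnitude exceeds 10 on the log-odds scale.
#'
#' @param clinical Clinical tibble with `group` (`GP`/`PP`), `age`, `stage`
#'   and the columns named in `extra`.
#' @param extra Further categorical predictor columns (e.g. `"race"`).
#' @param late_stages Stage labels counted as late; anything whose first
#'   roman numeral matches III or IV by default.
#' @return An object of class `logistic_fit`: a tibble `term`, `estimate`
#'   (log-odds), `std_error`, `odds_ratio`, `conf_low`, `conf_high`,
#'   `p.value`, with attributes `converged`, `separation`, `n`,
#'   `age_median`.
#' @export
logistic_prognosis <- function(clinical, extra = character(),
                               late_stages = c("III", "IIIA", "IIIB", "IIIC",
                                               "IV")) {
  tum <- dplyr::filter(clinical, .data$group %in% c("GP", "PP"))
  if (sum(tum$group == "PP") < 10) {
    stop("fewer than 10 poor-prognosis events; regression unreliable")
  }
  age_median <- stats::median(tum$age)
  df <- tibble::tibble(
    y = as.integer(tum$group == "PP"),
    age_over_median = as.integer(tum$age > age_median),
    late_stage = as.integer(tum$stage %in% late_stages)
  )
  for (v in extra) df[[v]] <- factor(tum[[v]])
  keep <- purrr::map_lgl(df, ~ length(unique(.x)) > 1)
  if (!keep[["y"]]) stop("outcome is constant")
  dropped <- setdiff(names(df)[!keep], "y")
  if (length(dropped) > 0) {
    warning("dropping constant predictor(s): ", paste(dropped, collapse = ", "))
  }
  df <- df[keep]
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  sm <- summary(fit)$coefficients
  separation <- any(abs(sm[, "Estimate"]) > 10)
  if (separation) {
    warning("possible separation: a coefficient exceeds 10 on the log-odds ",
            "scale; interpret with caution")
  }
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = est,
    std_error = se,
    odds_ratio = exp(est),
    conf_low = exp(est - 1.96 * se),
    conf_high = exp(est + 1.96 * se),
    p.value = unname(sm[, "Pr(>|z|)"])
  )
  structure(out, class = c("logistic_fit", class(out)),
            converged = fit$converged, separation = separation,
            n = nrow(df), age_median = age_median)
}

#' Tidy a prognosis logistic fit
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return The coefficient tibble (already tidy).
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), converged = attr(x, "converged"),
                 separation = attr(x, "separation"),
                 age_median = attr(x, "age_median"))
}

#' One-way ANOVA with Tukey post-test for one cell type
#'
#' Compares a cell-type fraction across the Normal / GP / PP groups by
#' one-way ANOVA, with Tukey honest-significant-difference pairwise p-values
#' from the studentized-range distribution (via `stats::aov` +
#' `stats::TukeyHSD`).
#'
#' @param fractions Tibble of per-sample cell fractions with a `sample`
#'   column and one column per cell type.
#' @param clinical Clinical tibble with `sample`, `group`.
#' @param cell_type Name of the fraction column to test.
#' @return A list with `f`, `p_anova` and `tukey` (tibble `comparison`,
#'   `diff`, `conf_low`, `conf_high`, `p_adj`).
#' @export
anova_tukey <- function(fractions, clinical, cell_type) {
  stopifnot(cell_type %in% names(fractions))
  df <- dplyr::inner_join(
    dplyr::select(fractions, "sample", value = dplyr::all_of(cell_type)),
    dplyr::select(clinical, "sample", "group"),
    by = "sample"
  ) |>
    dplyr::filter(.data$group %in% c("Normal", "GP", "PP"))
  counts <- table(df$group)
  if (any(counts < 2) || length(counts) < 2) {
    stop("need at least 2 samples in each of at least 2 groups")
  }
  if (all(tapply(df$value, df$group, stats::var) == 0)) {
    stop("zero within-group variance; ANOVA undefined")
  }
  df$group <- factor(df$group)
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(
    f = an[["F value"]][1],
    p_anova = an[["Pr(>F)"]][1],
    tukey = tibble::tibble(
      comparison = rownames(tk),
      diff = tk[, "diff"], conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  )
}

#' Compare all cell-type fractions across prognosis groups
#'
#' Runs [anova_tukey()] for every fraction column and collects the ANOVA and
#' pairwise results in one tibble.
#'
#' @inheritParams anova_tukey
#' @param cell_types Columns to test; default every non-`sample` column.
#' @return A tibble: `cell_type`, `f`, `p_anova`, then one row per Tukey
#'   pairwise comparison (`comparison`, `diff`, `p_adj`) nested long.
#' @export
cell_fraction_compare <- function(fractions, clinical,
                                  cell_types = setdiff(names(fractions),
                                                       "sample")) {
  purrr::map_dfr(cell_types, function(ct) {
    res <- anova_tukey(fractions, clinical, ct)
    res$tukey |>
      dplyr::mutate(cell_type = ct, f = res$f, p_anova = res$p_anova,
                    .before = 1)
  })
}

#' Pearson correlation with t-approximation p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, non-constant.
#' @return A list with `r` and `p` (two-sided).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
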