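#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric survival-curve estimate under right censoring. At each
#' distinct event time `t` with `d` deaths among `n` at risk, the survival
#' probability multiplies by `(1 - d/n)`. Ties between deaths and censorings
#' at the same time are resolved deaths-first (censored subjects leave the
#' risk set after the time point).
#'
#' @param times Non-negative follow-up times (years).
#' @param events Logical (or 0/1): `TRUE` if the subject died at `times`,
#'   `FALSE` if censored.
#' @return An object of class `km_curve`: a tibble with one row per distinct
#'   observed time — `time`, `n_risk`, `n_event`, `n_censor`, `surv` — plus
#'   attribute `n` (subjects at time 0). `surv` starts at 1 (implicitly, at
#'   time 0) and is non-increasing.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' survival_at(km, 2.5)  # 2/3
#' @export
km_estimate <- function(times, events) {
  events <- as.logical(events)
  stopifnot(length(times) == length(events), all(times >= 0), !anyNA(times),
            !anyNA(events))
  if (length(times) == 0) stop("km_estimate(): empty input")
  tab <- tibble::tibble(time = times, event = events) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(n_event = sum(.data$event),
                     n_censor = sum(!.data$event)) |>
    dplyr::arrange(.data$time)
  n <- length(times)
  at_risk <- n - c(0, cumsum(tab$n_event + tab$n_censor))[seq_len(nrow(tab))]
  surv <- cumprod(1 - tab$n_event / at_risk)
  out <- tibble::tibble(
    time = tab$time, n_risk = at_risk, n_event = tab$n_event,
    n_censor = tab$n_censor, surv = surv
  )
  structure(out, class = c("km_curve", class(out)), n = n)
}

#' Survival probability at a time point
#'
#' Right-continuous step-function value of a Kaplan-Meier curve: at an event
#' time the post-jump value applies. Beyond the last observed time the last
#' value is carried forward and flagged through the `extrapolated`
#' attribute.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Time (years), `t >= 0`.
#' @return Survival fraction in `[0, 1]` with attribute `extrapolated`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(t >= 0)
  idx <- findInterval(t, curve$time)
  s <- if (idx == 0) 1 else curve$surv[idx]
  attr(s, "extrapolated") <- t > max(curve$time)
  s
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank chi-square: at each distinct event time the
#' observed events in group A are compared with the expectation under the
#' hypergeometric distribution given the risk sets, and the squared summed
#' difference is scaled by the summed hypergeometric variance. p comes from
#' the chi-square distribution with 1 degree of freedom. If no events occur
#' in either group the test is degenerate: `chi2 = 0, p = 1`, flagged.
#'
#' @param times_a,events_a Follow-up times and event indicators, group A.
#' @param times_b,events_b Same for group B.
#' @return An object of class `logrank_test`: list with `chi2`, `df = 1`,
#'   `p`, `observed` and `expected` (length-2, groups A and B), `degenerate`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  events_a <- as.logical(events_a); events_b <- as.logical(events_b)
  stopifnot(length(times_a) >= 1, length(times_b) >= 1)
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c(1L, 2L), c(length(times_a), length(times_b)))
  ev_times <- sort(unique(time[event]))
  if (length(ev_times) == 0) {
    return(structure(list(chi2 = 0, df = 1L, p = 1,
                          observed = c(0, 0), expected = c(0, 0),
                          degenerate = TRUE),
                     class = "logrank_test"))
  }
  o1 <- e1 <- v <- 0
  obs <- c(0, 0)
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & grp == 1L)
    obs <- obs + c(d1, d - d1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  total <- sum(obs)
  expected <- c(e1, total - e1)
  if (v <= 0) {
    return(structure(list(chi2 = 0, df = 1L, p = 1,
                          observed = obs, expected = expected,
                          degenerate = TRUE),
                     class = "logrank_test"))
  }
  chi2 <- (o1 - e1)^2 / v
  structure(
    list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
         observed = obs, expected = expected, degenerate = FALSE),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("<logrank_test> chi2 = ", format(x$chi2, digits = 5),
      ", df = 1, p = ", format(x$p, digits = 4),
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

#' Glance at a log-rank test
#' @param x A `logrank_test`.
#' @param ... Unused.
#' @return One-row tibble `chi2`, `df`, `p.value`, `degenerate`.
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p.value = x$p,
                 degenerate = x$degenerate)
}

#' Split patients into expression tertiles
#'
#' Rank-based split into lowest / centre / highest thirds, with group sizes
#' as equal as possible. When `n` is not divisible by 3 the extra slots go to
#' the extreme groups, lowest first (`n = 10` gives sizes 4/3/3;
#' `n = 11` gives 4/3/4). Ties are broken by stable input order, so the split
#' is deterministic; a warning is emitted when tied values span a boundary.
#'
#' @param values Numeric vector (one value per patient), length >= 3.
#' @return A factor with levels `low`, `mid`, `high` in input order.
#' @export
tertile_stratify <- function(values) {
  n <- length(values)
  if (n < 3) stop("tertile_stratify() needs at least 3 values")
  base <- n %/% 3
  extra <- n %% 3
  sizes <- c(low = base + (extra >= 1), mid = base, high = base + (extra == 2))
  ord <- order(values)  # stable: ties keep input order
  labels <- rep(c("low", "mid", "high"), times = sizes)
  out <- character(n)
  out[ord] <- labels
  # tied values spanning a boundary?
  sorted <- values[ord]
  b1 <- sizes[["low"]]; b2 <- sizes[["low"]] + sizes[["mid"]]
  if (sorted[b1] == sorted[b1 + 1] || sorted[b2] == sorted[min(b2 + 1, n)]) {
    warning("tied values span a tertile boundary; split by stable rank order")
  }
  factor(out, levels = c("low", "mid", "high"))
}

#' Genome-wide tertile survival screen
#'
#' For each gene, tumour patients are stratified into expression tertiles;
#' the highest and lowest thirds are compared by a log-rank test and their
#' five-year survival fractions are read off Kaplan-Meier curves. This is
#' the screen applied to prognosis-group-specific genes and to immune
#' checkpoint gene lists. No multiple-testing correction is applied to the
#' ranking by default, matching common practice of reporting raw log-rank p
#' for screens; a BH-adjusted column `q` is included for reference.
#'
#' @param expression Expression tibble.
#' @param clinical Clinical tibble with `sample`, `group`, `vital_status`,
#'   `time_years`; only tumour samples (groups GP/PP) are used.
#' @param genes Genes to screen; absent genes are skipped with a warning.
#' @param at_years Time at which tertile survival fractions are read.
#' @return A tibble sorted by `p`: `gene`, `n_low`, `n_high`, `chi2`, `p`,
#'   `s5_low`, `s5_high`, `q`.
#' @export
gene_survival_screen <- function(expression, clinical, genes,
                                 at_years = 5) {
  tum <- clinical |>
    dplyr::filter(.data$group %in% c("GP", "PP"),
                  !is.na(.data$vital_status), !is.na(.data$time_years))
  samples <- intersect(expr_samples(expression), tum$sample)
  tum <- tum[match(samples, tum$sample), ]
  if (length(samples) < 6) stop("too few tumour samples with survival data")
  miss <- setdiff(genes, expression$gene)
  if (length(miss) > 0) {
    warning("skipping ", length(miss), " gene(s) absent from the matrix: ",
            paste(utils::head(miss, 5), collapse = ", "))
    genes <- intersect(genes, expression$gene)
  }
  times <- tum$time_years
  events <- tum$vital_status == "dead"
  mat <- as.matrix(expression[match(genes, expression$gene), samples])
  rows <- purrr::map_dfr(seq_along(genes), function(i) {
    tert <- suppressWarnings(tertile_stratify(mat[i, ]))
    lo <- tert == "low"; hi <- tert == "high"
    lr <- logrank(times[hi], events[hi], times[lo], events[lo])
    tibble::tibble(
      gene = genes[i],
      n_low = sum(lo), n_high = sum(hi),
      chi2 = lr$chi2, p = lr$p,
      s5_low = as.numeric(survival_at(km_estimate(times[lo], events[lo]), at_years)),
      s5_high = as.numeric(survival_at(km_estimate(times[hi], events[hi]), at_years))
    )
  })
  rows$q <- bh_adjust(rows$p)
  dplyr::arrange(rows, .data$p)
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_curve`, or a named list of them (one step line per
#'   element).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  plot_km(list(all = object))
}

#' @rdname autoplot.km_curve
#' @param curves Named list of `km_curve` objects.
#' @export
plot_km <- function(curves) {
  df <- purrr::imap_dfr(curves, function(cv, nm) {
    tibble::tibble(group = nm,
                   time = c(0, cv$time),
                   surv = c(1, cv$surv))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "survival fraction")
}
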