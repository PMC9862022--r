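test_that("fisher_exact equals brute-force enumeration for all small tables", {
  # every 2x2 table with total N <= 60 in steps that keep runtime sane:
  # exhaustive over margins up to 12, randomized larger tables up to N = 60
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    expect_equal(fisher_exact(a = a, b = b, c = cc, d = d)$p,
                 fisher_oracle(a, b, cc, d), tolerance = 1e-7)
  }
  tabs <- withr::with_seed(5, purrr::map(1:200, function(i) {
    n <- sample(4:60, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], n - cuts[3])
  }))
  for (tb in tabs) {
    if (tb[1] + tb[2] == 0 || tb[3] + tb[4] == 0 ||
        tb[1] + tb[3] == 0 || tb[2] + tb[4] == 0) next
    expect_equal(fisher_exact(a = tb[1], b = tb[2], c = tb[3], d = tb[4])$p,
                 fisher_oracle(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-7)
  }
})

test_that("fisher_exact degenerate and symmetric cases", {
  expect_warning(res <- fisher_exact(a = 0, b = 0, c = 3, d = 4), "margin")
  expect_equal(res$p, 1)
  expect_equal(fisher_exact(a = 5, b = 5, c = 5, d = 5)$p, 1)
  # swapping rows together with columns leaves p unchanged
  p1 <- fisher_exact(a = 7, b = 2, c = 3, d = 11)$p
  p2 <- fisher_exact(a = 11, b = 3, c = 2, d = 7)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("demographic table statistics assemble per level", {
  co <- simulate_cohort(small_config(seed = 12))
  tb <- table1_stats(co$clinical, categories = c("stage", "race"))
  expect_true("age" %in% tb$variable)
  expect_true(all(tb$p >= 0 & tb$p <= 1))
  # counts per level add up to the group sizes
  gp_n <- sum(co$clinical$group == "GP")
  race_rows <- dplyr::filter(tb, .data$variable == "race")
  expect_equal(sum(race_rows$n_gp), gp_n)
})

test_that("single binary predictor logistic OR equals the cross-product ratio", {
  # construct a cohort with known 2x2: exposed/unexposed x PP/GP
  a <- 30; b <- 20; cc <- 15; d <- 35  # exposed-PP, exposed-GP, unexp-PP, unexp-GP
  clin <- tibble::tibble(
    sample = paste0("s", 1:(a + b + cc + d)),
    group = c(rep("PP", a), rep("GP", b), rep("PP", cc), rep("GP", d)),
    age = c(rep(70, a + b), rep(40, cc + d)),  # age flag == exposure
    stage = "IIA"
  )
  fit <- suppressWarnings(logistic_prognosis(clin))
  or <- fit$odds_ratio[fit$term == "age_over_median"]
  expect_equal(or, (a * d) / (b * cc), tolerance = 1e-6)
  expect_true(all(fit$conf_low <= fit$odds_ratio & fit$odds_ratio <= fit$conf_high))
})

test_that("null logistic simulation covers zero in its confidence intervals", {
  cover <- purrr::map_lgl(1:20, function(seed) {
    clin <- withr::with_seed(seed, tibble::tibble(
      sample = paste0("s", 1:300),
      group = sample(c("GP", "PP"), 300, replace = TRUE, prob = c(2 / 3, 1 / 3)),
      age = round(runif(300, 30, 85)),
      stage = sample(c("IIA", "IIIA"), 300, replace = TRUE)
    ))
    fit <- logistic_prognosis(clin)
    rows <- fit$term != "(Intercept)"
    all(fit$conf_low[rows] <= 1 & fit$conf_high[rows] >= 1)
  })
  expect_gte(mean(cover), 0.8)  # ~95% joint coverage per factor
})

test_that("two-group ANOVA reduces to the squared pooled t", {
  withr::with_seed(44, {
    frac <- tibble::tibble(sample = paste0("s", 1:40),
                           Tcells = c(rnorm(20, 0.2, 0.05),
                                      rnorm(20, 0.25, 0.05)))
  })
  clin <- tibble::tibble(sample = paste0("s", 1:40),
                         group = rep(c("GP", "PP"), each = 20))
  res <- anova_tukey(frac, clin, "Tcells")
  tt <- t.test(Tcells ~ rep(c("GP", "PP"), each = 20), data = frac,
               var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_anova, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey flags only the group with a planted shift", {
  hits <- purrr::map_dfr(1:5, function(seed) {
    withr::with_seed(seed, {
      frac <- tibble::tibble(
        sample = paste0("s", 1:150),
        M1 = c(rnorm(50, 0.2, 0.05), rnorm(50, 0.2, 0.05),
               rnorm(50, 0.15, 0.05))  # PP shifted by 1 SD
      )
    })
    clin <- tibble::tibble(sample = paste0("s", 1:150),
                           group = rep(c("Normal", "GP", "PP"), each = 50))
    tk <- anova_tukey(frac, clin, "M1")$tukey
    tibble::tibble(
      pp_gp = tk$p_adj[tk$comparison == "PP-GP"] < 0.05,
      pp_n = tk$p_adj[tk$comparison == "PP-Normal"] < 0.05,
      gp_n = tk$p_adj[tk$comparison == "Normal-GP"] < 0.05
    )
  })
  expect_gte(mean(hits$pp_gp), 0.9)
  expect_gte(mean(hits$pp_n), 0.9)
  expect_lte(mean(hits$gp_n), 0.2)
})

test_that("ANOVA p-values are calibrated under the null", {
  rej <- purrr::map_lgl(1:200, function(seed) {
    withr::with_seed(seed, {
      frac <- tibble::tibble(sample = paste0("s", 1:60),
                             ct = rnorm(60, 0.2, 0.05))
    })
    clin <- tibble::tibble(sample = paste0("s", 1:60),
                           group = rep(c("Normal", "GP", "PP"), each = 20))
    anova_tukey(frac, clin, "ct")$p_anova < 0.05
  })
  expect_lt(mean(rej), 0.1)
  expect_gt(mean(rej), 0.005)
})

test_that("cell_fraction_compare collects every cell type", {
  withr::with_seed(2, {
    frac <- tibble::tibble(sample = paste0("s", 1:60),
                           A = runif(60), B = runif(60))
  })
  clin <- tibble::tibble(sample = paste0("s", 1:60),
                         group = rep(c("Normal", "GP", "PP"), each = 20))
  out <- cell_fraction_compare(frac, clin)
  expect_setequal(unique(out$cell_type), c("A", "B"))
  expect_equal(nrow(out), 6)  # 2 cell types x 3 pairwise comparisons
})

test_that("pearson matches the closed-form correlation", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.4, 0.3)
  y <- c(0.8, 2.9, 2.5, 5.1, 5.0, 1.1)
  res <- pearson(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 6)), "constant")
})
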