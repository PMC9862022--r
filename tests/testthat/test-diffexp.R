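test_that("welch_t matches the hand formula and stats::t.test", {
  a <- c(0, 1, 2); b <- c(3, 4, 5)
  res <- welch_t(a, b)
  # direct formula evaluation
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  tt <- t.test(a, b)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("welch_t is antisymmetric and null on identical groups", {
  a <- withr::with_seed(1, rnorm(20)); b <- withr::with_seed(2, rnorm(25, 1))
  r1 <- welch_t(a, b); r2 <- welch_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  r3 <- welch_t(a, a)
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  # identical constant groups
  expect_equal(welch_t(rep(2, 5), rep(2, 7)), list(t = 0, df = 10, p = 1))
})

test_that("t_from_summary reproduces the age comparison and raw-data Welch", {
  res <- t_from_summary(54.3, 11.7, 200, 63.7, 14.5, 101)
  expect_lt(res$p, 0.0001)
  # agrees with welch_t on data constructed to have these exact moments
  make <- function(m, s, n) {
    x <- withr::with_seed(n, rnorm(n))
    m + s * (x - mean(x)) / sd(x)
  }
  a <- make(54.3, 11.7, 200); b <- make(63.7, 14.5, 101)
  raw <- welch_t(a, b)
  expect_equal(res$t, raw$t, tolerance = 1e-10)
  expect_equal(res$p, raw$p, tolerance = 1e-10)
  expect_equal(t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(t_from_summary(1, 0, 10, 2, 1, 10))
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # 1000 random vectors against an independent implementation
  withr::with_seed(123, {
    for (i in 1:1000) {
      p <- runif(sample(1:30, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_oracle(p))
      expect_true(all(sort(q) >= sort(p)))
      expect_true(all(q <= 1))
    }
  })
})

test_that("volcano classification follows the FC and q thresholds", {
  # three planted genes around the thresholds plus stable nulls
  n <- 40
  mk <- function(mu_a, mu_b, sd = 0.05) {
    withr::with_seed(7, c(rnorm(n, mu_a, sd), rnorm(n, mu_b, sd)))
  }
  vals <- rbind(
    mk(100, 100),      # FC = 1, ns however small p
    mk(100, 405),      # FC ~ 4, over
    mk(100, 24.9),     # FC ~ 0.25, under
    mk(50, 50.2)       # null filler
  )
  expr <- tibble::as_tibble(cbind(
    tibble::tibble(gene = c("flat", "up", "down", "null")),
    as.data.frame(vals)
  ))
  names(expr) <- c("gene", paste0("s", 1:(2 * n)))
  clin <- tibble::tibble(sample = paste0("s", 1:(2 * n)),
                         group = rep(c("Normal", "PP"), each = n))
  de <- differential_expression(expr, clin, "Normal", "PP")
  expect_equal(de$class[de$gene == "flat"], "ns")   # FC 1 despite tiny q
  expect_equal(de$class[de$gene == "up"], "over")
  expect_equal(de$class[de$gene == "down"], "under")
  expect_true(all(de$q >= de$p))
})

test_that("constant genes get t = 0, p = 1, ns", {
  expr <- tibble::tibble(gene = c("const", "varying"),
                         s1 = c(5, 1), s2 = c(5, 2), s3 = c(5, 3),
                         s4 = c(5, 9), s5 = c(5, 8), s6 = c(5, 7))
  clin <- tibble::tibble(sample = paste0("s", 1:6),
                         group = rep(c("Normal", "PP"), each = 3))
  de <- differential_expression(expr, clin, "Normal", "PP")
  expect_equal(de$t[de$gene == "const"], 0)
  expect_equal(de$p[de$gene == "const"], 1)
  expect_equal(de$class[de$gene == "const"], "ns")
})

test_that("group-specific selection is set algebra over the two contrasts", {
  mk_de <- function(over, under, universe) {
    tibble::tibble(gene = universe, t = 0, df = 1, p = 1, q = 1, log2fc = 0,
                   class = dplyr::case_when(universe %in% over ~ "over",
                                            universe %in% under ~ "under",
                                            .default = "ns"))
  }
  uni <- letters[1:6]
  de_pp <- mk_de(c("a", "b", "c"), "d", uni)
  de_gp <- mk_de("b", character(), uni)
  sel <- select_group_specific(de_pp, de_gp)
  expect_setequal(sel$pp_only_over, c("a", "c"))
  expect_equal(sel$shared_over, "b")
  expect_equal(sel$pp_only_under, "d")
  expect_equal(sel$gp_only_over, character(0))
  # identity: identical inputs leave all *_only sets empty
  sel2 <- select_group_specific(de_pp, de_pp)
  expect_equal(length(sel2$pp_only_over), 0)
  expect_equal(length(sel2$gp_only_under), 0)
  # partition invariant: only + shared reconstruct the per-group sets
  expect_setequal(c(sel$pp_only_over, sel$shared_over), c("a", "b", "c"))
  expect_setequal(c(sel$gp_only_over, sel$shared_over), "b")
  # mismatched universes error
  expect_error(select_group_specific(de_pp, mk_de("b", character(), letters[1:5])),
               "universe")
})

test_that("pca2 matches a covariance eigendecomposition oracle", {
  withr::with_seed(21, {
    vals <- matrix(rexp(10 * 20, 0.1), nrow = 10)
  })
  expr <- tibble::as_tibble(cbind(tibble::tibble(gene = paste0("g", 1:10)),
                                  as.data.frame(vals)))
  names(expr) <- c("gene", paste0("s", 1:20))
  res <- pca2(expr, standardize = FALSE)
  # oracle: eigendecomposition of the sample covariance of centred log2 data
  x <- scale(t(log2(vals + 1)), center = TRUE, scale = FALSE)
  ev <- eigen(cov(x))
  expect_equal(res$var_explained, ev$values[1:2] / sum(ev$values),
               tolerance = 1e-8)
  sc_oracle <- x %*% ev$vectors[, 1:2]
  # compare up to sign
  for (j in 1:2) {
    s <- sign(sum(res$scores[[j + 1]] * sc_oracle[, j]))
    expect_equal(res$scores[[j + 1]], s * sc_oracle[, j], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("collinear samples put 100% of variance on PC1", {
  base <- 1:8
  expr <- tibble::tibble(gene = c("g1", "g2"),
                         !!!stats::setNames(purrr::map(base, ~ c(2^.x - 1, 2^(2 * .x) - 1)),
                                            paste0("s", base)))
  res <- pca2(expr, standardize = FALSE)
  expect_equal(res$var_explained[1], 1, tolerance = 1e-12)
  expect_true(res$rank_deficient || res$var_explained[2] < 1e-12)
})

test_that("tumour and normal samples separate in PCA of planted genes", {
  co <- simulate_cohort(small_config(seed = 4))
  genes <- unlist(co$truth$de_sets, use.names = FALSE)
  res <- pca2(co$expression, genes = genes, clinical = co$clinical)
  sc <- dplyr::filter(res$scores, .data$group %in% c("Normal", "GP", "PP"))
  normal <- sc$group == "Normal"
  centroid_dist <- sqrt(sum((colMeans(sc[normal, c("PC1", "PC2")]) -
                               colMeans(sc[!normal, c("PC1", "PC2")]))^2))
  spread <- mean(c(sd(sc$PC1[normal]), sd(sc$PC1[!normal])))
  expect_gt(centroid_dist, spread)
})
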