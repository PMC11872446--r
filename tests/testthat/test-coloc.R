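test_that("labf_from_beta_se evaluates the ABF formula and its limits", {
  # beta = 0, se = 1, w = 0.0225: labf = 0.5 * log(1 - 0.0225/1.0225)
  expect_equal(labf_from_beta_se(0, 1, 0.0225),
               0.5 * log(1 - 0.0225 / 1.0225))
  # w -> 0: labf -> 0 for any finite z
  expect_equal(labf_from_beta_se(3, 0.5, 1e-12), 0, tolerance = 1e-8)
  expect_error(labf_from_beta_se(1, 0, 0.0225), "se")
  expect_error(labf_from_beta_se(1, 1, -1), "w")
})

test_that("labf matches numerical integration of the normal-prior Bayes factor", {
  cases <- list(c(0.5, 0.05, 0.0225), c(0, 1, 0.0225), c(-0.2, 0.1, 0.04),
                c(0.05, 0.02, 0.0225))
  for (cs in cases) {
    expect_equal(labf_from_beta_se(cs[1], cs[2], cs[3]),
                 oracle_labf_quadrature(cs[1], cs[2], cs[3]),
                 tolerance = 1e-8)
  }
})

test_that("labf is strictly increasing in |z| for fixed se and w", {
  z <- seq(0, 10, by = 0.5)
  labf <- labf_from_beta_se(z * 0.1, 0.1, 0.0225)
  expect_true(all(diff(labf) > 0))
})

test_that("the p-value route agrees with the beta-se route when V is consistent", {
  maf <- 0.25; n <- 10000; w <- 0.0225
  v <- 1 / (2 * n * maf * (1 - maf))
  se <- sqrt(v)
  z <- qnorm(1e-8 / 2, lower.tail = FALSE)
  expect_equal(labf_from_p(1e-8, maf, n, "quantitative", w = w),
               labf_from_beta_se(z * se, se, w), tolerance = 1e-10)

  # p = 1 gives z = 0
  expect_equal(labf_from_p(1, maf, n, "quantitative", w = w),
               0.5 * log(1 - w / (w + v)))

  # case-control variance includes the case-fraction term
  s <- 0.3
  v_cc <- v / (s * (1 - s))
  expect_equal(labf_from_p(0.01, maf, n, "case-control",
                           case_fraction = s, w = w),
               labf_from_beta_se(qnorm(0.005, lower.tail = FALSE) *
                                   sqrt(v_cc), sqrt(v_cc), w),
               tolerance = 1e-10)
})

test_that("sub-clip p-values are clipped at 1e-300 with a warning", {
  expect_warning(l <- labf_from_p(1e-320, 0.25, 1000), "clipped")
  expect_equal(l, suppressWarnings(labf_from_p(1e-300, 0.25, 1000)))
})

test_that("single-SNP posteriors match direct arithmetic and drop H3", {
  res <- coloc_posteriors(0, 0, coloc_priors())
  # weights (1, 1e-4, 1e-4, 0, 1e-5): PP0 = 1/1.00021
  expect_equal(res$pp0, 1 / 1.00021, tolerance = 1e-12)
  expect_equal(res$pp3, 0)
  expect_equal(res$pp1, 1e-4 / 1.00021, tolerance = 1e-12)
  expect_equal(res$pp4, 1e-5 / 1.00021, tolerance = 1e-12)
})

test_that("posteriors match the explicit configuration-enumeration oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    l1 <- rnorm(n, 0, 4)
    l2 <- rnorm(n, 0, 4)
    pri <- coloc_priors()
    res <- coloc_posteriors(l1, l2, pri)
    expect_equal(c(res$pp0, res$pp1, res$pp2, res$pp3, res$pp4),
                 oracle_coloc_posteriors(l1, l2, pri$p1, pri$p2, pri$p12),
                 tolerance = 1e-10)
  }
})

test_that("swapping traits with equal p1, p2 swaps PP1 and PP2 only", {
  set.seed(5)
  l1 <- rnorm(5, 1, 2); l2 <- rnorm(5, -1, 2)
  a <- coloc_posteriors(l1, l2)
  b <- coloc_posteriors(l2, l1)
  expect_equal(a$pp1, b$pp2)
  expect_equal(a$pp2, b$pp1)
  expect_equal(a$pp0, b$pp0)
  expect_equal(a$pp3, b$pp3)
  expect_equal(a$pp4, b$pp4)
})

test_that("posteriors are permutation invariant in SNP order", {
  set.seed(6)
  l1 <- rnorm(10, 0, 3); l2 <- rnorm(10, 0, 3)
  perm <- sample(10)
  a <- coloc_posteriors(l1, l2)
  b <- coloc_posteriors(l1[perm], l2[perm])
  for (f in c("pp0", "pp1", "pp2", "pp3", "pp4"))
    expect_equal(a[[f]], b[[f]])
})

test_that("PP4 is non-decreasing in the shared prior p12", {
  set.seed(8)
  l1 <- rnorm(20, 0, 3); l2 <- rnorm(20, 0, 3)
  p12_grid <- 10^seq(-8, log10(1e-4), length.out = 20)
  pp4 <- vapply(p12_grid, function(p12)
    coloc_posteriors(l1, l2, coloc_priors(p12 = p12))$pp4, numeric(1))
  expect_true(all(diff(pp4) >= 0))
})

test_that("interpretation bands and PP4/PP3 qualifiers follow the decision rules", {
  fake <- function(pp4, pp3) {
    structure(list(pp4 = pp4, pp3 = pp3,
                   pp4_pp3 = if (pp3 == 0) Inf else pp4 / pp3),
              class = "coloc_result")
  }
  expect_match(interpret_coloc(fake(0.968, 0.001)),
               "^single shared causal variant")
  expect_match(interpret_coloc(fake(0.874, 0.05)),
               "^likely single shared causal variant")
  expect_match(interpret_coloc(fake(0.5, 0.3)), "^limited evidence")
  expect_match(interpret_coloc(fake(0.040, 0.9)),
               "^no colocalization support")
  # qualifiers
  expect_match(interpret_coloc(fake(0.9, 0.15)), "further support")  # ratio 6
  expect_match(interpret_coloc(fake(0.8, 0.2)), "likely colocalization")
  expect_false(grepl("\\(", interpret_coloc(fake(0.5, 0.4))))  # ratio 1.25
  # band boundaries: 0.300 and 0.700 belong to "limited evidence"
  expect_match(interpret_coloc(fake(0.300, 0.1)), "^limited evidence")
  expect_match(interpret_coloc(fake(0.700, 0.1)), "^limited evidence")
})

test_that("coloc_region recovers H4, H0 and H3 scenarios end to end", {
  panel <- simulate_panel(panel_spec(n_individuals = 500, n_snps = 80,
                                     seed = 31))
  w <- locus_window(panel$variants$chrom[40], panel$variants$pos[40],
                    500000)
  run <- function(hyp, c1, c2, seed) {
    sc <- simulate_scenario(panel, scenario_spec(
      hypothesis = hyp, causal1 = c1, causal2 = c2,
      n1 = 8000, n2 = 4000, seed = seed))
    suppressMessages(coloc_region(sc$trait1, sc$trait2, w,
                                  route = "p-maf-n"))
  }
  h4 <- run("H4", 40L, 40L, 1)
  expect_gt(h4$pp4, 0.9)
  h0 <- run("H0", 40L, 40L, 2)
  expect_gt(h0$pp0, 0.5)
  h3 <- run("H3", 5L, 75L, 3)
  expect_gt(h3$pp3, 0.5)
  expect_lt(h3$pp4, 0.3)
  h1 <- run("H1", 40L, 40L, 4)
  expect_gt(h1$pp1, 0.5)
})

test_that("coloc_region signals an empty overlap instead of crashing", {
  a <- sumstat_table(make_sumstat_df("1", c(100, 200), p = c(0.1, 0.2)))
  b <- sumstat_table(make_sumstat_df("2", c(100, 200), p = c(0.1, 0.2)))
  expect_message(res <- coloc_region(a, b, locus_window("1", 150)),
                 "no shared variants")
  expect_null(res)
})
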