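test_that("panel simulation is deterministic and hits target frequencies", {
  spec <- panel_spec(n_individuals = 1000, n_snps = 100, seed = 77)
  p1 <- simulate_panel(spec)
  p2 <- simulate_panel(spec)
  expect_identical(p1$dosages, p2$dosages)

  # empirical allele frequency tracks the target on average
  emp <- colMeans(p1$dosages) / 2
  target <- attr(p1, "target_freqs")
  expect_lt(mean(abs(emp - target)), 0.03)
})

test_that("ld_rho controls adjacent-SNP LD and its decay with distance", {
  p0 <- simulate_panel(panel_spec(n_individuals = 1000, n_snps = 100,
                                  ld_rho = 0, seed = 78))
  adj0 <- vapply(1:99, function(j)
    suppressWarnings(cor(p0$dosages[, j], p0$dosages[, j + 1])^2),
    numeric(1))
  expect_lt(mean(adj0, na.rm = TRUE), 0.02)

  p95 <- simulate_panel(panel_spec(n_individuals = 1000, n_snps = 100,
                                   ld_rho = 0.95, seed = 79))
  adj95 <- vapply(1:99, function(j)
    cor(p95$dosages[, j], p95$dosages[, j + 1])^2, numeric(1))
  far95 <- vapply(1:50, function(j)
    cor(p95$dosages[, j], p95$dosages[, j + 50])^2, numeric(1))
  expect_gt(mean(adj95), mean(far95) + 0.2)  # monotone decay, large gap
})

test_that("null GWAS p-values are uniform and causal SNPs are powered", {
  panel <- simulate_panel(panel_spec(n_individuals = 500, n_snps = 300,
                                     ld_rho = 0, seed = 80))
  null_stats <- simulate_gwas(panel, n = 2000, seed = 81)
  expect_gt(ks.test(null_stats$p, "punif")$p.value, 0.01)

  # one causal SNP explaining 2% of variance at n = 20,000 is genome-wide
  # significant (expected chi-square ~ 400)
  freqs <- attr(panel, "target_freqs")
  beta <- sqrt(0.02 / (2 * freqs[150] * (1 - freqs[150])))
  for (s in 1:3) {
    g <- simulate_gwas(panel, 150L, beta, n = 20000, seed = 81 + s)
    expect_lt(g$p[g$rsid == "snp0150"], 5e-8)
  }
})

test_that("estimated effect signs match the generating sign", {
  panel <- simulate_panel(panel_spec(n_individuals = 500, n_snps = 50,
                                     ld_rho = 0.5, seed = 82))
  freqs <- attr(panel, "target_freqs")
  beta <- sqrt(0.05 / (2 * freqs[25] * (1 - freqs[25])))
  g <- simulate_gwas(panel, 25L, beta, n = 5000, seed = 83)
  expect_gt(g$beta[g$rsid == "snp0025"], 0)
  g_neg <- simulate_gwas(panel, 25L, -beta, n = 5000, seed = 84)
  expect_lt(g_neg$beta[g_neg$rsid == "snp0025"], 0)
})

test_that("case-control simulation yields calibrated nulls and its target prevalence", {
  panel <- simulate_panel(panel_spec(n_individuals = 500, n_snps = 200,
                                     ld_rho = 0, seed = 85))
  cc <- simulate_gwas(panel, n = 4000, trait_type = "case-control",
                      case_fraction = 0.3, seed = 86)
  expect_equal(attr(cc, "trait_type"), "case-control")
  expect_gt(ks.test(cc$p, "punif")$p.value, 0.01)
})

test_that("scenario simulation enforces the H3 low-LD precondition", {
  panel <- simulate_panel(panel_spec(n_individuals = 500, n_snps = 100,
                                     ld_rho = 0.95, seed = 87))
  # adjacent SNPs are in strong LD: H3 there must be refused
  expect_error(simulate_scenario(panel, scenario_spec(
    hypothesis = "H3", causal1 = 50L, causal2 = 51L, seed = 1)),
    "low-LD")
  # far-apart SNPs are fine and the truth is recorded
  sc <- simulate_scenario(panel, scenario_spec(
    hypothesis = "H3", causal1 = 5L, causal2 = 95L,
    n1 = 2000, n2 = 2000, seed = 1))
  expect_lt(ld_r2(panel, 5, 95)$r2, 0.01)
  expect_equal(sc$truth$hypothesis, "H3")
  expect_s3_class(sc$trait1, "sumstat_table")

  expect_error(scenario_spec(hypothesis = "H4", causal1 = 1L, causal2 = 2L),
               "shared causal")
})

test_that("null SNPs in LD with a causal SNP inherit signal proportional to r2", {
  panel <- simulate_panel(panel_spec(n_individuals = 1000, n_snps = 60,
                                     ld_rho = 0.95, seed = 88))
  freqs <- attr(panel, "target_freqs")
  beta <- sqrt(0.05 / (2 * freqs[30] * (1 - freqs[30])))
  g <- simulate_gwas(panel, 30L, beta, n = 10000, seed = 89)
  z2 <- qnorm(g$p / 2, lower.tail = FALSE)^2
  r2_to_causal <- vapply(seq_len(60), function(j)
    if (j == 30) 1 else ld_r2(panel, 30, j)$r2, numeric(1))
  near <- which(r2_to_causal > 0.5 & seq_len(60) != 30)
  far <- which(r2_to_causal < 0.05)
  expect_gt(mean(z2[near]), 10 * mean(z2[far]))
})

test_that("single-cell simulation is deterministic with planted truth recorded", {
  spec <- sc_sim_spec(n_donors_per_condition = 2,
                      cell_types = list(A = c(5L, 10L)), n_genes = 50,
                      de_genes = setNames(c(1, -1), c(3, 7)), seed = 90)
  m1 <- simulate_sc_counts(spec)
  m2 <- simulate_sc_counts(spec)
  expect_identical(m1$counts, m2$counts)
  truth <- attr(m1, "truth")
  expect_equal(truth$de_idx, c(3L, 7L))
  expect_equal(truth$log2fc[c(3, 7)], c(1, -1))
  expect_equal(sort(unique(m1$cell_meta$condition)),
               c("control", "disease"))
  expect_true(all(m1$counts >= 0))
})

test_that("planted fold changes shift pseudobulk means in the right direction", {
  spec <- sc_sim_spec(n_donors_per_condition = 4,
                      cell_types = list(A = c(30L, 40L)), n_genes = 100,
                      de_genes = setNames(2, 1), seed = 91)
  m <- simulate_sc_counts(spec)
  pb <- pseudobulk(m)   # 100-gene cells sit below the 500-count filter
  norm <- sweep(pb$counts, 1, size_factors(pb$counts), "/")
  dis <- pb$group_meta$condition == "disease"
  obs_l2fc <- log2(mean(norm[dis, 1]) / mean(norm[!dis, 1]))
  expect_gt(obs_l2fc, 1)
})
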