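make_cells <- function(counts, donor, type, cond) {
  cell_counts(counts,
              data.frame(barcode = paste0("c", seq_len(nrow(counts))),
                         donor_id = donor, cell_type = type,
                         condition = cond, stringsAsFactors = FALSE))
}

test_that("cell and cluster filters apply their boundaries inclusively", {
  # 12 cells typeA (all >= 500), 10 typeB with 2 below 500 -> 8 left, drop;
  # 9 typeC -> below 10, drop
  counts <- rbind(matrix(50, 12, 10),   # totals 500
                  matrix(50, 10, 10),
                  matrix(50, 9, 10))
  counts[13, ] <- 49                    # total 490
  counts[14, ] <- 49
  m <- make_cells(counts, "D1",
                  rep(c("A", "B", "C"), c(12, 10, 9)),
                  "control")
  expect_message(f <- filter_cells_clusters(m), "below 500")
  expect_equal(unique(f$cell_meta$cell_type), "A")
  expect_equal(nrow(f$counts), 12)

  # boundary: a 500-count cell and a 10-cell cluster survive
  counts2 <- matrix(50, 10, 10)
  m2 <- make_cells(counts2, "D1", "A", "disease")
  f2 <- filter_cells_clusters(m2)
  expect_equal(nrow(f2$counts), 10)

  # idempotent
  f3 <- filter_cells_clusters(f)
  expect_equal(f3$cell_meta, f$cell_meta)
  expect_equal(as.matrix(f3$counts), as.matrix(f$counts))
})

test_that("cell-type proportions sum to one per donor and match hand counts", {
  counts <- matrix(100, 100, 5)
  m <- make_cells(counts,
                  rep(c("D1", "D2"), c(50, 50)),
                  c(rep("A", 50), rep("A", 30), rep("B", 20)),
                  rep(c("control", "disease"), c(50, 50)))
  pr <- celltype_proportions(m)
  expect_equal(pr$fraction[pr$donor_id == "D1"], 1.0)
  d2 <- pr[pr$donor_id == "D2", ]
  expect_equal(d2$fraction[d2$cell_type == "A"], 0.6)
  expect_equal(d2$fraction[d2$cell_type == "B"], 0.4)
  sums <- tapply(pr$fraction, pr$donor_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("pseudobulk sums cells within donor x cell type and conserves counts", {
  counts <- rbind(c(1, 2, 0), c(0, 3, 5), c(7, 0, 1))
  m <- make_cells(counts, c("D1", "D1", "D2"), c("A", "A", "A"),
                  c("disease", "disease", "control"))
  pb <- pseudobulk(m)
  expect_equal(unname(pb$counts["D1||A", ]), c(1, 5, 5))
  expect_equal(unname(pb$counts["D2||A", ]), c(7, 0, 1))  # single cell
  expect_equal(pb$group_meta$n_cells, c(2L, 1L))
  expect_equal(colSums(pb$counts), colSums(counts),
               ignore_attr = TRUE)

  set.seed(30)
  big <- matrix(rpois(200 * 20, 5), 200, 20)
  mb <- make_cells(big, rep(paste0("D", 1:4), each = 50),
                   rep(rep(c("A", "B"), each = 25), 4),
                   rep(c("disease", "control"), each = 100))
  pbb <- pseudobulk(mb)
  expect_equal(colSums(pbb$counts), colSums(big), ignore_attr = TRUE)
})

test_that("size factors follow median-of-ratios", {
  # identical samples: all factors 1
  eq <- matrix(5, 3, 8)
  expect_equal(size_factors(eq), rep(1, 3))

  # exact doubling: factors in ratio 1:2
  a <- matrix(rpois(20, 20) + 1, 1, 20)
  two <- rbind(a, 2 * a)
  sf <- size_factors(two)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)

  # 4x7 fixture vs direct transcription of the definition
  set.seed(31)
  x <- matrix(rpois(28, 30) + 1, 4, 7)
  expect_equal(size_factors(x), oracle_size_factors(x), tolerance = 1e-12)

  # fallback path warns when no gene is expressed everywhere: 10 samples,
  # each gene zero in exactly one sample (so nonzero in 90%)
  y <- matrix(rpois(50, 10) + 1, 10, 5)
  y[cbind(1:5, 1:5)] <- 0
  expect_warning(sfy <- size_factors(y), "90")
  expect_true(all(is.finite(sfy) & sfy > 0))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(32)
  x <- matrix(rnbinom(12 * 50, mu = 40, size = 5) + 1, nrow = 50)  # gene x sample
  ours <- size_factors(t(x))
  ref <- DESeq2::estimateSizeFactorsForMatrix(x)
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("bulk_normalize filters on max count and divides by size factors", {
  counts <- rbind(g1 = c(4, 3, 2),      # max 4 -> removed
                  g2 = c(5, 1, 0),      # max 5 -> kept
                  g3 = c(100, 100, 100),
                  g4 = c(50, 60, 70),
                  g5 = c(30, 40, 50))   # 3 all-nonzero reference genes
  expect_message(norm <- bulk_normalize(counts), "removed")
  expect_false("g1" %in% rownames(norm))
  expect_true("g2" %in% rownames(norm))

  # identical samples: normalization is the identity
  same <- matrix(10, 5, 4)
  expect_equal(unname(bulk_normalize(same)), unname(same))

  # matches division by hand-computed factors
  kept <- counts[2:5, ]
  sf <- oracle_size_factors(t(kept))
  expect_equal(unname(norm), unname(sweep(kept, 2, sf, "/")),
               tolerance = 1e-12)
})

test_that("nb_wald_de skips under-replicated cell types and maps stars", {
  set.seed(33)
  counts <- matrix(rnbinom(30 * 40, mu = 20, size = 10), 30, 40)
  m <- make_cells(counts,
                  rep(c("D1", "D2", "D3"), each = 10),
                  rep("A", 30),
                  rep(c("disease", "control", "control"), each = 10))
  pb <- pseudobulk(m)
  expect_message(de <- nb_wald_de(pb), "skipped")
  expect_equal(nrow(de), 0)

  expect_equal(de_stars(c(0.2, 0.04, 0.0005, 5e-5, NA)),
               c("", "*", "**", "***", ""))
})

test_that("nb_wald_de detects a large planted effect and not null genes", {
  set.seed(34)
  n_donor <- 6
  donors <- paste0("D", 1:(2 * n_donor))
  cond <- rep(c("disease", "control"), each = n_donor)
  # pseudobulk-level counts built directly: gene 1 has a 4-fold effect
  mu <- matrix(100, 2 * n_donor, 20)
  mu[cond == "disease", 1] <- 400
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), nrow(mu))
  cells <- make_cells(counts, donors, "A", cond)
  pb <- pseudobulk(cells)
  de <- nb_wald_de(pb)
  expect_equal(nrow(de), 20)
  expect_lt(de$p_adj[1], 0.05)
  expect_equal(de$log2fc[1], 2, tolerance = 0.5)
  expect_true(all(de$p_adj >= de$p, na.rm = TRUE))
})

test_that("single-cell counts round-trip through MatrixMarket files", {
  set.seed(35)
  counts <- matrix(rpois(8 * 12, 3), 8, 12)
  m <- make_cells(counts, rep(c("D1", "D2"), each = 4), "A",
                  rep(c("disease", "control"), each = 4))
  dir <- withr::local_tempdir()
  write_sc_counts(m, dir)
  m2 <- read_sc_counts(file.path(dir, "counts.mtx"),
                       file.path(dir, "genes.txt"),
                       file.path(dir, "barcodes.txt"),
                       file.path(dir, "cell_meta.tsv"))
  expect_equal(unname(as.matrix(m2$counts)), unname(counts))
  expect_equal(m2$cell_meta$donor_id, m$cell_meta$donor_id)
  expect_equal(m2$gene_ids, m$gene_ids)
})
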