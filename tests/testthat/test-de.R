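# Differential expression: FPKM arithmetic, the expression filter,
# dispersion recovery, and the NB likelihood-ratio test.

test_that("FPKM follows the direct formula and its scale behavior", {
  meta <- two_group_meta(n = 1)
  counts <- matrix(c(100L, 999900L, 100L, 999900L), nrow = 2,
                   dimnames = list(c("g1", "g2"), meta$sample_id))
  cm <- count_matrix(counts, meta)
  genes <- gene_table(data.frame(chromosome = "1", start = c(0, 1e4),
                                 end = c(5e3, 2e4), gene_id = c("g1", "g2"),
                                 exonic_length = c(1000, 99990)))
  f <- compute_fpkm(cm, genes)
  # count 100, length 1000 bp, library 1e6 -> FPKM 100
  expect_equal(f["g1", 1], 100)
  expect_equal(f["g1", ], f["g1", c(2, 1)], ignore_attr = TRUE)
  # zero count -> zero FPKM
  counts0 <- counts; counts0["g1", 1] <- 0L
  f0 <- compute_fpkm(count_matrix(counts0, meta), genes)
  expect_equal(f0["g1", 1], 0)
  # doubling every count in a sample leaves its FPKM unchanged
  counts2 <- counts; counts2[, 1] <- counts2[, 1] * 2L
  f2 <- compute_fpkm(count_matrix(counts2, meta), genes)
  expect_equal(f2[, 1], f[, 1])
})

test_that("expression filter uses strict FPKM > 1 in >= 3 of 6 samples", {
  meta <- two_group_meta(n = 3)
  fpkm <- rbind(pass = c(1.5, 1.2, 1.1, 0, 0, 0),
                boundary = rep(1, 6),
                zero = rep(0, 6))
  colnames(fpkm) <- meta$sample_id
  ct <- contrast_spec("c", "musXdom", "mus", "DIP")
  keep <- filter_expressed(fpkm, meta, scope = "cell_type", contrast = ct)
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE))
  expect_error(filter_expressed(fpkm, meta, scope = "cell_type"),
               "requires a contrast")
})

test_that("dispersion estimation recovers Poisson and NB truth", {
  meta <- two_group_meta()
  # Poisson data: common dispersion collapses toward zero
  set.seed(21)
  mu <- 300 * rlnorm(2000, -0.5, 1)
  pois <- sapply(1:6, function(j) rpois(2000, mu))
  dimnames(pois) <- list(sprintf("g%04d", 1:2000), meta$sample_id)
  dp <- estimate_dispersions(count_matrix(pois, meta))
  expect_lte(dp$common, 0.05)
  # NB truth phi = 0.25 recovered within [0.15, 0.35] (10-seed average)
  commons <- vapply(1:10, function(s) {
    cm <- null_nb_matrix(2000, phi = 0.25, seed = 100 + s)
    estimate_dispersions(cm)$common
  }, 0)
  expect_gte(mean(commons), 0.15)
  expect_lte(mean(commons), 0.35)
  # infinite prior weight pins tagwise at common
  cm <- null_nb_matrix(500, phi = 0.1, seed = 5)
  dinf <- estimate_dispersions(cm, prior_weight = 1e9)
  expect_true(all(abs(dinf$tagwise - dinf$common) < 1e-6))
  expect_equal(dinf$bcv, sqrt(dinf$common))
})

test_that("identical groups give logfc 0 and p 1; BH matches by hand", {
  meta <- two_group_meta()
  counts <- matrix(rep(c(50L, 200L), 6), nrow = 2, byrow = FALSE,
                   dimnames = list(c("g1", "g2"), meta$sample_id))
  cm <- count_matrix(counts, meta)
  genes <- flat_annotation(c("g1", "g2"))
  de <- test_de(cm, genes, contrast_spec("c", "musXdom", "mus", "DIP"),
                fixed_dispersions(c("g1", "g2"), 0.05))
  expect_equal(de$logfc, c(0, 0))
  expect_equal(de$p_raw, c(1, 1))
  # hand-applied step-up: (.01,.02,.03,.04) with m = 4 -> all .04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("LRT agrees with a brute-force likelihood maximizer", {
  set.seed(77)
  cm <- null_nb_matrix(400, phi = 0.08, seed = 42)
  genes <- flat_annotation(rownames(cm$counts))
  disp <- estimate_dispersions(cm)
  de <- test_de(cm, genes, contrast_spec("c", "musXdom", "mus", "DIP"), disp)
  lib <- colSums(cm$counts)
  pick <- sample(nrow(cm$counts), 20)
  for (g in pick) {
    phi <- disp$tagwise[g]
    y_a <- cm$counts[g, 1:3]; y_b <- cm$counts[g, 4:6]
    ll_alt <- nb_maxll_oracle(y_a, lib[1:3], phi) +
      nb_maxll_oracle(y_b, lib[4:6], phi)
    ll_null <- nb_maxll_oracle(c(y_a, y_b), lib, phi)
    stat_oracle <- max(2 * (ll_alt - ll_null), 0)
    stat_pkg <- qchisq(de$p_raw[g], df = 1, lower.tail = FALSE)
    expect_lt(abs(stat_pkg - stat_oracle), 1e-3)
  }
  # the LRT statistic is never negative (alternative nests the null)
  expect_true(all(qchisq(de$p_raw, 1, lower.tail = FALSE) >= -1e-12))
})

test_that("null p-values are uniform under group-label permutation", {
  cm <- null_nb_matrix(2000, phi = 0.03, seed = 9)
  # permuted group labels: samples 1,2,4 vs 3,5,6
  meta <- cm$samples
  meta$cross <- c("musXdom", "musXdom", "mus", "musXdom", "mus", "mus")
  meta$replicate <- stats::ave(seq_len(6), meta$cross, FUN = seq_along)
  cmp <- count_matrix(cm$counts, meta)
  genes <- flat_annotation(rownames(cm$counts))
  de <- test_de(cmp, genes, contrast_spec("c", "musXdom", "mus", "DIP"),
                estimate_dispersions(cmp))
  ks <- suppressWarnings(ks.test(de$p_raw, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted X disruption is recovered at the stated operating point", {
  # defaults; sensitivity and FDR on the planted X truth, 3-seed average
  sens <- c(); fdr <- c()
  for (s in 1:3) {
    sim <- simulate_expression(expression_sim_config(seed = s))
    disp <- estimate_dispersions(sim$counts)
    for (ctr in list(c("musXdom", "mus", "DIP"), c("musXdom", "mus", "RS"))) {
      de <- test_de(sim$counts, sim$genes,
                    contrast_spec("x", ctr[1], ctr[2], ctr[3]), disp)
      tr <- sim$truth[sim$truth$hybrid == ctr[1] &
                        sim$truth$cell_type == ctr[3], ]
      dis <- tr$gene_id[tr$is_disrupted]
      x_ids <- sim$genes$gene_id[sim$genes$is_x]
      called_x <- intersect(de$gene_id[de$is_de], x_ids)
      sens <- c(sens, mean(dis %in% called_x))
      fdr <- c(fdr, if (length(called_x)) mean(!called_x %in% dis) else 0)
    }
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdr), 0.10)
})

test_that("DE results respect their own invariants", {
  sim <- simulate_expression(expression_sim_config(n_genes = 600, seed = 2))
  de <- test_de(sim$counts, sim$genes,
                contrast_spec("c", "musXdom", "mus", "DIP"))
  ok <- !is.na(de$p_adj)
  expect_true(all(de$p_adj[ok] >= de$p_raw[ok]))
  expect_true(all(de$is_de == (de$expressed_in_cell_type &
                                 !is.na(de$p_adj) & de$p_adj < 0.05)))
  expect_true(all(!de$is_de[!de$expressed_in_cell_type]))
})
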