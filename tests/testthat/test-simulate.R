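# Generators: determinism, planted structure, and closure properties.

test_that("expression simulator is a pure function of config + seed", {
  a <- simulate_expression(expression_sim_config(n_genes = 200, seed = 1))
  b <- simulate_expression(expression_sim_config(n_genes = 200, seed = 1))
  c <- simulate_expression(expression_sim_config(n_genes = 200, seed = 2))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("null configuration plants nothing and silences fertile DIP X", {
  cfg <- expression_sim_config(
    disrupt_frac_dip = c(musXdom = 0, domXmus = 0),
    disrupt_frac_rs = c(musXdom = 0, domXmus = 0), seed = 4)
  sim <- simulate_expression(cfg)
  expect_equal(sum(sim$truth$is_disrupted), 0)
  # mean X : autosome count ratio in fertile DIP ~ msci_silencing
  sm <- sim$counts$samples
  dip_fertile <- sm$sample_id[sm$cell_type == "DIP" &
                                sm$cross %in% c("dom", "mus")]
  is_x <- sim$genes$is_x[match(rownames(sim$counts$counts),
                               sim$genes$gene_id)]
  sub <- sim$counts$counts[, dip_fertile]
  ratio <- mean(sub[is_x, ]) / mean(sub[!is_x, ])
  # 3 SE over genes: lognormal(sdlog 1) means give SE/mean ~ 1.31/sqrt(150)
  expect_gt(ratio / cfg$msci_silencing, 1 - 3 * 0.11)
  expect_lt(ratio / cfg$msci_silencing, 1 + 3 * 0.11)
})

test_that("msci_silencing = 1 leaves fertile DIP X indistinguishable", {
  cfg <- expression_sim_config(
    msci_silencing = 1,
    disrupt_frac_dip = c(musXdom = 0, domXmus = 0),
    disrupt_frac_rs = c(musXdom = 0, domXmus = 0), seed = 11)
  sim <- simulate_expression(cfg)
  sm <- sim$counts$samples
  dip_fertile <- sm$sample_id[sm$cell_type == "DIP" & sm$cross == "dom"]
  is_x <- sim$genes$is_x[match(rownames(sim$counts$counts),
                               sim$genes$gene_id)]
  lx <- log1p(rowMeans(sim$counts$counts[is_x, dip_fertile]))
  la <- log1p(rowMeans(sim$counts$counts[!is_x, dip_fertile]))
  expect_gt(t.test(lx, la)$p.value, 0.01)
})

test_that("amplicon planting respects identity and capacity", {
  # identity 1 plants the query verbatim
  cfg1 <- amplicon_sim_config(backbone_length = 30000, gene_length = 600,
                              ref_copies = 1, true_copies = 1,
                              copy_identity = 1, seed = 2)
  g1 <- simulate_amplicon_genome(cfg1)
  iv <- g1$truth$intervals
  cp <- iv[iv$role == "copy", ]
  expect_identical(substr(g1$genome[["sim1"]], cp$start + 1, cp$end),
                   g1$query)
  # at 99% identity each planted copy differs at ~1% of positions
  cfg2 <- amplicon_sim_config(ref_copies = 3, gene_length = 2000,
                              copy_identity = 0.99, seed = 3)
  g2 <- simulate_amplicon_genome(cfg2)
  ivc <- g2$truth$intervals
  for (i in which(ivc$role == "copy")) {
    planted <- substr(g2$genome[["sim1"]], ivc$start[i] + 1, ivc$end[i])
    mism <- sum(charToRaw(planted) != charToRaw(g2$query))
    # binomial 2000 x 0.01: mean 20, 3 SD ~ 13.3
    expect_gt(mism, 20 - 3 * sqrt(2000 * 0.01 * 0.99))
    expect_lt(mism, 20 + 3 * sqrt(2000 * 0.01 * 0.99))
  }
  expect_error(simulate_amplicon_genome(
    amplicon_sim_config(backbone_length = 2500, gene_length = 600,
                        ref_copies = 3, true_copies = 3)),
    "too small")
})

test_that("simulated depth matches the collapsed-copy Poisson model", {
  cfg <- amplicon_sim_config(ref_copies = 4, true_copies = 40,
                             haploid_mean_depth = 10, seed = 6)
  g <- simulate_amplicon_genome(cfg)
  tr <- simulate_depth(g$truth)
  expect_true(all(tr$intervals$depth >= 0))
  expect_true(all(tr$intervals$depth == round(tr$intervals$depth)))
  iv <- g$truth$intervals
  cp <- iv[iv$role == "copy", ]
  m <- track_region_mean(tr, cp$chromosome, cp$start, cp$end)
  # Poisson mean (N/R)*(c/2) = 100; 3 SE over 2000 bases ~ 0.67
  expect_true(all(abs(m - 100) < 3 * sqrt(100 / 2000)))
  # balanced N = R case sits at the haploid depth
  cfgb <- amplicon_sim_config(ref_copies = 3, true_copies = 3, seed = 8)
  gb <- simulate_amplicon_genome(cfgb)
  trb <- simulate_depth(gb$truth)
  ivb <- gb$truth$intervals[gb$truth$intervals$role == "copy", ]
  mb <- track_region_mean(trb, ivb$chromosome, ivb$start, ivb$end)
  expect_true(all(abs(mb - 10) < 3 * sqrt(10 / 2000)))
})

test_that("phenotype simulator closes the multinomial and orders effects", {
  ph <- simulate_phenotypes(n_per_cross = 6, seed = 1)
  expect_true(all(rowSums(ph[, paste0("n_cat", 1:4)]) == 100))
  # degenerate multinomial (all category 1) pins the index at 3
  cfg <- default_phenotype_config()
  for (nm in names(cfg)) cfg[[nm]]$morph_probs <- c(1, 0, 0, 0)
  ph3 <- simulate_phenotypes(n_per_cross = 3, config = cfg, seed = 2)
  expect_true(all(morphology_index(ph3[, paste0("n_cat", 1:4)]) == 3))
  # configured hybrid testes-weight deficit shows in the medians
  hits <- 0
  for (s in 1:200) {
    p <- simulate_phenotypes(n_per_cross = 6, seed = s)
    med <- tapply(p$testes_mg_g, p$cross, median)
    if (max(med[c("musXdom", "domXmus")]) < min(med[c("dom", "mus")]))
      hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("zinc-finger generator plants recoverable triplets", {
  sim <- simulate_zf_protein(5, c("RER", "QKT", "ASD", "WMN"), seed = 3)
  expect_gte(nchar(sim$protein), 5 * 28)
  n_motifs <- length(gregexpr("C.{2}C.{12}H.{3}H", sim$protein)[[1]])
  expect_equal(n_motifs, 5)
  arr <- extract_zf_triplets(sim$protein)
  expect_equal(arr$fingers$triplet, c("RER", "QKT", "ASD", "WMN"))
  expect_error(simulate_zf_protein(4, c("RER", "QKT")), "need 3 triplets")
})
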