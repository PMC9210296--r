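# Paralog discovery, informative sites, and the two depth estimators.
# Fixtures are compact (30 kb backbone, 600 bp gene) so the exhaustive
# oracles stay cheap; parameter-recovery at study scale lives in the
# acceptance suite.

small_cfg <- function(ref_copies = 3, true_copies = 6, seed = 1, ...) {
  amplicon_sim_config(backbone_length = 30000, gene_length = 600,
                      ref_copies = ref_copies, true_copies = true_copies,
                      seed = seed, ...)
}

test_that("paralog search finds exact, mutated and reverse-complement hits", {
  g <- simulate_amplicon_genome(small_cfg(ref_copies = 1, copy_identity = 1,
                                          seed = 2))
  ps <- find_paralogs(g$query, g$genome)
  iv <- g$truth$intervals
  cp <- iv[iv$role == "copy", ]
  expect_equal(nrow(ps$intervals), 1)
  expect_equal(ps$intervals$start, cp$start)
  expect_equal(ps$intervals$end, cp$end)
  expect_equal(ps$intervals$identity, 1)

  # 3 copies at 99% and one decoy at 92%: exactly 3 intervals
  g3 <- simulate_amplicon_genome(small_cfg(seed = 3))
  ps3 <- find_paralogs(g3$query, g3$genome)
  expect_equal(nrow(ps3$intervals), 3)
  dec <- g3$truth$intervals[g3$truth$intervals$role == "decoy", ]
  expect_false(any(ps3$intervals$start < dec$end &
                     dec$start < ps3$intervals$end))

  # reverse-complemented planted copy is still found
  rc_genome <- g$genome
  rc_genome[["sim1"]] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rc_genome[["sim1"]])))
  ps_rc <- find_paralogs(g$query, rc_genome)
  expect_equal(nrow(ps_rc$intervals), 1)
  expect_equal(ps_rc$intervals$strand, "-")
  expect_error(find_paralogs(substr(g$query, 1, 150), g$genome), ">= 200 bp")
})

test_that("region-coverage estimator follows the halved-background formula", {
  # hand example: three regions at mean depth 30, background 20 -> 9.0
  iv <- data.frame(chromosome = "c",
                   start = c(0, 2000, 4000), end = c(1000, 3000, 5000),
                   strand = "+", identity = 1)
  ps <- structure(list(family = "fam", intervals = iv, query_length = 1000),
                  class = "paralog_set")
  bgiv <- data.frame(chromosome = "c",
                     start = c(1000, 3000, 5000), end = c(2000, 4000, 50000),
                     depth = 20)
  cpiv <- data.frame(chromosome = "c", start = iv$start, end = iv$end,
                     depth = 30)
  tr <- coverage_track(rbind(bgiv, cpiv))
  est <- cn_from_region_coverage(ps, tr)
  expect_equal(est$estimate, 9)
  # a single region at half the background mean is one copy
  one <- structure(list(family = "fam", intervals = iv[1, ],
                        query_length = 1000), class = "paralog_set")
  cp1 <- data.frame(chromosome = "c", start = 0, end = 1000, depth = 10)
  tr1 <- coverage_track(rbind(bgiv, cp1))
  expect_equal(cn_from_region_coverage(one, tr1)$estimate, 1)
  # estimator is exactly linear in depth (noiseless doubling)
  cp2 <- cpiv; cp2$depth <- 60
  tr2 <- coverage_track(rbind(bgiv, cp2))
  expect_equal(cn_from_region_coverage(ps, tr2)$estimate, 18,
               tolerance = 1e-9)
})

test_that("informative sites: unique query, planted multiplicity, mismatches", {
  # unique query: m = 1 and every kmer retained
  g <- simulate_amplicon_genome(small_cfg(ref_copies = 1, copy_identity = 1,
                                          seed = 4))
  si <- build_informative_sites(g$query, g$genome)
  expect_equal(si$m, 1)
  expect_equal(si$n_kmers, nchar(g$query) - 101 + 1)
  expect_true(all(si$sites$mismatches == 0))

  # 3 identical planted copies: m = 3, each kmer lists 3 locations
  g3 <- simulate_amplicon_genome(small_cfg(ref_copies = 3, copy_identity = 1,
                                           seed = 5))
  si3 <- build_informative_sites(g3$query, g3$genome)
  expect_equal(si3$m, 3)
  expect_true(all(table(si3$sites$kmer_index) == 3))

  # mutated second copy: its locations enter the <= 2-mismatch list but
  # not the exact-match counts, so m stays 1 and every retained kmer
  # lists the exact copy (0 mismatches) plus the mutated one (1-2)
  set.seed(6)
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  query <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  mut <- query
  for (pos in seq(50, 590, by = 90))  # every 101-mer spans 1-2 of these
    substr(mut, pos, pos) <- flip(substr(mut, pos, pos))
  backbone <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  genome <- c(sim1 = paste0(substr(backbone, 1, 2000), query,
                            substr(backbone, 2001, 6000), mut,
                            substr(backbone, 6001, 10000)))
  si1 <- build_informative_sites(query, genome)
  expect_equal(si1$m, 1)
  expect_equal(si1$n_kmers, 500)
  per_kmer <- table(si1$sites$kmer_index)
  expect_true(all(per_kmer == 2))
  expect_true(all(si1$sites$mismatches[si1$sites$mismatches > 0] <= 2))
  expect_gt(sum(si1$sites$mismatches > 0), 0)
})

test_that("mismatch scan agrees with brute-force Hamming comparison", {
  g <- simulate_amplicon_genome(small_cfg(seed = 7))
  si <- build_informative_sites(g$query, g$genome)
  gen <- g$genome[["sim1"]]
  qk <- substring(g$query, 1:(600 - 100), 101:600)
  for (r in sample(nrow(si$sites), min(50, nrow(si$sites)))) {
    s <- si$sites[r, ]
    w <- substr(gen, s$start + 1, s$start + 101)
    if (s$strand == "-")
      w <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
    mm <- sum(charToRaw(w) != charToRaw(qk[s$kmer_index]))
    expect_identical(mm, as.integer(s$mismatches))
  }
})

test_that("site estimator recovers balanced and collapsed configurations", {
  # N = R: estimate ~ R at haploid depth
  g <- simulate_amplicon_genome(small_cfg(ref_copies = 3, true_copies = 3,
                                          seed = 8))
  tr <- simulate_depth(g$truth)
  si <- build_informative_sites(g$query, g$genome)
  est <- cn_from_informative_sites(si, tr, g$genome)
  expect_lt(abs(est$estimate - 3), 0.45)
  # GC correction on an unbiased simulation moves the estimate < 2%
  est_nogc <- cn_from_informative_sites(si, tr, g$genome, gc_correct = FALSE)
  expect_lt(abs(est$estimate - est_nogc$estimate) / est_nogc$estimate, 0.02)
  # noiseless linearity: doubling planted copy depth doubles both
  # estimators exactly
  cp <- g$truth$intervals[g$truth$intervals$role == "copy", ]
  flat_track <- function(copy_depth) {
    L <- nchar(g$genome[["sim1"]])
    # flat depth-20 backbone with the copy intervals carved out
    pieces <- list()
    last <- 0
    for (i in seq_len(nrow(cp))) {
      if (cp$start[i] > last)
        pieces[[length(pieces) + 1]] <- data.frame(
          chromosome = "sim1", start = last, end = cp$start[i], depth = 20)
      pieces[[length(pieces) + 1]] <- data.frame(
        chromosome = "sim1", start = cp$start[i], end = cp$end[i],
        depth = copy_depth)
      last <- cp$end[i]
    }
    pieces[[length(pieces) + 1]] <- data.frame(
      chromosome = "sim1", start = last, end = L, depth = 20)
    coverage_track(do.call(rbind, pieces))
  }
  t1 <- flat_track(100); t2 <- flat_track(200)
  e1 <- cn_from_informative_sites(si, t1, g$genome, gc_correct = FALSE)
  e2 <- cn_from_informative_sites(si, t2, g$genome, gc_correct = FALSE)
  expect_equal(e2$estimate / e1$estimate, 2, tolerance = 1e-9)
  ps <- find_paralogs(g$query, g$genome)
  r1 <- cn_from_region_coverage(ps, t1)
  r2 <- cn_from_region_coverage(ps, t2)
  expect_equal(r2$estimate / r1$estimate, 2, tolerance = 1e-9)
})

test_that("family ratio reproduces the published worked examples", {
  # printed family copy numbers -> printed ratios at 2 significant digits
  expect_equal(compute_family_ratio(130, 100), 1.3)
  expect_equal(compute_family_ratio(215, 35), 6.1)
  expect_equal(compute_family_ratio(130, 35), 3.7)
  # this ratio is printed at three significant digits (exact value 2.15)
  expect_equal(compute_family_ratio(215, 100, digits = 3), 2.15)
  expect_equal(compute_family_ratio(50, 25, 25), 1)
  expect_error(compute_family_ratio(10, 0, 0), "zero denominator")
  # accepts estimate objects
  e <- structure(list(family = "f", method = "region_coverage",
                      estimate = 130, n_regions_or_sites = 1,
                      genome_mean_depth = 20),
                 class = "copy_number_estimate")
  expect_equal(compute_family_ratio(e, 100), 1.3)
})
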