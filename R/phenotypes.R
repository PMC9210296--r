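# Sperm phenotype summaries: weighted morphology index, per-cross trait
# medians with bootstrap standard errors, and Wilcoxon rank-sum
# comparisons of hybrids against parents with BH FDR correction.

#' Weighted sperm-morphology index
#'
#' Category weights 1 -> 3 (normal, long apical hook), 2 -> 2 (slightly
#' abnormal, shortened hook), 3 -> 1 (abnormal, short hook, rounded),
#' 4 -> 0 (severely abnormal, amorphous), so the index runs from 3 (all
#' normal) down to 0 (all severely abnormal):
#' `(3 n1 + 2 n2 + 1 n3 + 0 n4) / total`.
#'
#' @param counts length-4 vector, or a matrix/data.frame with four
#'   columns (categories 1..4, one row per animal).
#' @return numeric index (per animal when given a matrix).
#' @export
morphology_index <- function(counts) {
  m <- if (is.null(dim(counts))) matrix(as.numeric(counts), nrow = 1)
  else as.matrix(counts)
  if (ncol(m) != 4) .stopf("expected 4 morphology categories, got %d", ncol(m))
  if (any(m < 0)) .stopf("negative category count")
  tot <- rowSums(m)
  if (any(tot == 0)) .stopf("animal with zero scored sperm")
  as.numeric(m %*% c(3, 2, 1, 0) / tot)
}

#' @keywords internal
.boot_se_median <- function(x, n_boot, seed) {
  .with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(x, length(x), replace = TRUE)), 0)
    stats::sd(reps)
  })
}

#' Summarize reproductive traits and test hybrids against parents
#'
#' For every trait, reports the per-cross median with a seeded bootstrap
#' standard error, and for every hybrid x parent pair a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction). If
#' the phenotype table carries the four morphology-category counts, a
#' `morphology_index` trait is derived first. P-values are BH-adjusted
#' across all trait x pair tests of the run; a comparison is flagged
#' `lower` when the hybrid median is below the parent's and
#' `p_adj < alpha`.
#'
#' @param phenotypes data.frame from [simulate_phenotypes()] or a file
#'   with the same schema (`cross` column plus numeric trait columns and
#'   optionally `n_cat1..n_cat4`).
#' @param traits character vector of trait column names; defaults to the
#'   standard five.
#' @param hybrids,parents cross labels treated as hybrids / parents.
#' @param n_boot bootstrap resamples for the median SE.
#' @param alpha significance threshold on adjusted p-values.
#' @param seed RNG seed for the bootstrap.
#' @return list with `summaries` (cross x trait medians and SEs) and
#'   `tests` (pairwise Wilcoxon results with `p_adj` and `lower` flags).
#' @export
summarize_and_test <- function(phenotypes, traits = NULL,
                               hybrids = c("musXdom", "domXmus"),
                               parents = c("dom", "mus"),
                               n_boot = 1000, alpha = 0.05, seed = 1) {
  ph <- as.data.frame(phenotypes)
  if (all(paste0("n_cat", 1:4) %in% names(ph)) &&
      !"morphology_index" %in% names(ph))
    ph$morphology_index <- morphology_index(ph[, paste0("n_cat", 1:4)])
  if (is.null(traits)) {
    std <- c("testes_mg_g", "sv_mg_g", "motility", "sperm_count_m",
             "morphology_index")
    traits <- intersect(std, names(ph))
  }
  if (!length(traits)) .stopf("no trait columns found")
  crosses <- unique(ph$cross)

  summaries <- do.call(rbind, lapply(crosses, function(cr) {
    do.call(rbind, lapply(traits, function(tr) {
      x <- ph[[tr]][ph$cross == cr]
      x <- x[!is.na(x)]
      data.frame(cross = cr, trait = tr, n = length(x),
                 median = stats::median(x),
                 se_median = .boot_se_median(x, n_boot,
                                             seed + match(tr, traits)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summaries) <- NULL

  tests <- list()
  for (h in intersect(hybrids, crosses)) {
    for (p in intersect(parents, crosses)) {
      for (tr in traits) {
        xh <- ph[[tr]][ph$cross == h]; xh <- xh[!is.na(xh)]
        xp <- ph[[tr]][ph$cross == p]; xp <- xp[!is.na(xp)]
        if (length(xh) < 3 || length(xp) < 3)
          .stopf("need >= 3 animals per group for testing (%s vs %s)", h, p)
        if (length(unique(c(xh, xp))) == 1) {
          .warnf("trait %s constant in %s vs %s; p set to 1", tr, h, p)
          w <- NA_real_; pv <- 1
        } else {
          wt <- suppressWarnings(
            stats::wilcox.test(xh, xp, exact = FALSE, correct = TRUE))
          w <- unname(wt$statistic); pv <- wt$p.value
        }
        tests[[length(tests) + 1]] <- data.frame(
          hybrid = h, parent = p, trait = tr, statistic = w, p_raw = pv,
          hybrid_median = stats::median(xh), parent_median = stats::median(xp),
          stringsAsFactors = FALSE)
      }
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_adj <- bh_adjust(tests$p_raw)
  tests$lower <- tests$hybrid_median < tests$parent_median &
    !is.na(tests$p_adj) & tests$p_adj < alpha
  list(summaries = summaries, tests = tests)
}
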