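# Sliding gene-window scan for local clusters of directionally
# misexpressed genes, flagged against the 99th quantile of a Poisson
# model of the genome-wide direction rate.

#' Poisson quantile threshold
#'
#' Smallest integer k such that `P(Poisson(lambda) <= k) >= quantile`.
#' A window is flagged when its direction count strictly exceeds this
#' threshold ("falls outside" the quantile).
#'
#' @param lambda Poisson mean.
#' @param quantile cumulative probability (default 0.99).
#' @return integer threshold.
#' @export
poisson_threshold <- function(lambda, quantile = 0.99) {
  if (lambda < 0) .stopf("lambda must be >= 0")
  as.integer(stats::qpois(quantile, lambda))
}

#' Sliding gene-window enrichment scan
#'
#' Orders expressed genes by chromosomal position (`order_index`), slides
#' a window of `W` consecutive genes advancing by `step` within each
#' chromosome (windows never span chromosomes; a final partial window is
#' dropped), and counts genes whose log fold change is positive (up) or
#' negative (down). The expected count per window for direction d is
#' `lambda_d = (count of direction-d genes / expressed genes) * W`,
#' estimated over the scanned gene universe (or per chromosome with
#' `per_chromosome_rates`). Windows whose count strictly exceeds the
#' Poisson 99th-quantile threshold are flagged.
#'
#' @param de a `de_result` from [test_de()].
#' @param genes a [gene_table()].
#' @param W window size in genes.
#' @param step stride in genes.
#' @param autosomes_only scan autosomes only (default), as the X is
#'   analyzed chromosome-wide instead.
#' @param quantile flagging quantile.
#' @param per_chromosome_rates estimate lambda per chromosome instead of
#'   genome-wide.
#' @return data.frame with one row per window: gene span (order indices
#'   and coordinates), `n_up`, `n_down`, `lambda_*`, `threshold_*`,
#'   `flagged_*`.
#' @export
scan_gene_windows <- function(de, genes, W = 250, step = 25,
                              autosomes_only = TRUE, quantile = 0.99,
                              per_chromosome_rates = FALSE) {
  if (W < 2) .stopf("window size must be >= 2")
  if (step < 1) .stopf("step must be >= 1")
  idx <- match(de$gene_id, genes$gene_id)
  if (anyNA(idx))
    .stopf("gene %s absent from annotation", de$gene_id[is.na(idx)][1])
  d <- data.frame(gene_id = de$gene_id,
                  chromosome = genes$chromosome[idx],
                  order_index = genes$order_index[idx],
                  start = genes$start[idx], end = genes$end[idx],
                  logfc = de$logfc,
                  expressed = de$expressed_in_cell_type,
                  is_x = genes$is_x[idx])
  d <- d[d$expressed, , drop = FALSE]
  if (autosomes_only) d <- d[!d$is_x, , drop = FALSE]
  d <- d[order(d$order_index), , drop = FALSE]
  n_tot <- nrow(d)
  if (n_tot == 0) .stopf("no expressed genes to scan")
  rate_up_g <- sum(d$logfc > 0) / n_tot
  rate_dn_g <- sum(d$logfc < 0) / n_tot

  res <- list()
  for (chr in unique(d$chromosome)) {
    sub <- d[d$chromosome == chr, , drop = FALSE]
    n <- nrow(sub)
    if (n < W) {
      .warnf("chromosome %s has %d expressed genes (< window %d); skipped",
             chr, n, W)
      next
    }
    if (per_chromosome_rates) {
      rate_up <- sum(sub$logfc > 0) / n
      rate_dn <- sum(sub$logfc < 0) / n
    } else {
      rate_up <- rate_up_g; rate_dn <- rate_dn_g
    }
    lam_up <- rate_up * W; lam_dn <- rate_dn * W
    thr_up <- poisson_threshold(lam_up, quantile)
    thr_dn <- poisson_threshold(lam_dn, quantile)
    starts <- seq(1, n - W + 1, by = step)
    up_cum <- cumsum(sub$logfc > 0)
    dn_cum <- cumsum(sub$logfc < 0)
    n_up <- up_cum[starts + W - 1] - c(0, up_cum)[starts]
    n_dn <- dn_cum[starts + W - 1] - c(0, dn_cum)[starts]
    res[[chr]] <- data.frame(
      chromosome = chr, window_index = seq_along(starts),
      first_order_index = sub$order_index[starts],
      last_order_index = sub$order_index[starts + W - 1],
      span_start = sub$start[starts], span_end = sub$end[starts + W - 1],
      n_genes = W, n_up = n_up, n_down = n_dn,
      lambda_up = lam_up, lambda_down = lam_dn,
      threshold_up = thr_up, threshold_down = thr_dn,
      flagged_up = n_up > thr_up, flagged_down = n_dn > thr_dn,
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(chromosome = character(0), window_index = integer(0),
                      first_order_index = integer(0),
                      last_order_index = integer(0),
                      span_start = numeric(0), span_end = numeric(0),
                      n_genes = integer(0), n_up = integer(0),
                      n_down = integer(0), lambda_up = numeric(0),
                      lambda_down = numeric(0), threshold_up = integer(0),
                      threshold_down = integer(0), flagged_up = logical(0),
                      flagged_down = logical(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
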