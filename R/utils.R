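# Shared helpers: multiple-testing adjustment and coverage-track arithmetic.

#' Benjamini-Hochberg adjustment
#'
#' Single shared FDR implementation used by every module that reports
#' adjusted p-values (differential expression, asymmetry tests, phenotype
#' comparisons). Thin wrapper over [stats::p.adjust()] so the procedure has
#' one source of truth across the package.
#'
#' @param p numeric vector of raw p-values; `NA`s are kept in place.
#' @return numeric vector of BH-adjusted p-values, same length as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' @keywords internal
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.CROSSES <- c("dom", "mus", "musXdom", "domXmus")
.CELL_TYPES <- c("LZ", "DIP", "RS")

# ---- coverage-track arithmetic ------------------------------------------

# Per-chromosome cumulative-sum index over a sorted, non-overlapping track.
# Enables O(log n) depth sums over arbitrary [start, end) regions.
#' @keywords internal
.track_index <- function(track) {
  iv <- track$intervals
  lapply(split(iv, iv$chromosome), function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    list(start = sub$start, end = sub$end, depth = sub$depth,
         # cumulative depth-sum up to the END of each interval
         cum = cumsum((sub$end - sub$start) * sub$depth))
  })
}

# Cumulative per-base depth from the chromosome origin up to position x
# (0-based, exclusive), via the cumulative index.
#' @keywords internal
.cum_depth_at <- function(idx, x) {
  i <- findInterval(x, idx$start)  # last interval with start <= x
  out <- numeric(length(x))
  has <- i >= 1
  ii <- i[has]
  full <- ifelse(ii > 1, idx$cum[pmax(ii - 1, 1)], 0)
  full[ii <= 1] <- 0
  inside <- pmin(pmax(x[has] - idx$start[ii], 0),
                 idx$end[ii] - idx$start[ii]) * idx$depth[ii]
  out[has] <- full + inside
  out
}

#' Mean depth over genomic regions
#'
#' Length-weighted mean depth of a coverage track over each query region.
#' Bases of a region not covered by any track interval count as depth zero.
#'
#' @param track a `coverage_track` (see [read_coverage_bedgraph()]).
#' @param chromosome,start,end vectors describing 0-based half-open regions.
#' @return numeric vector of mean depths.
#' @export
track_region_mean <- function(track, chromosome, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  if (any(end <= start)) .stopf("region with end <= start")
  by_chr <- .track_index(track)
  out <- numeric(length(start))
  chromosome <- as.character(chromosome)
  for (chr in unique(chromosome)) {
    idx <- by_chr[[chr]]
    sel <- chromosome == chr
    if (is.null(idx)) { out[sel] <- 0; next }
    out[sel] <- (.cum_depth_at(idx, end[sel]) -
                   .cum_depth_at(idx, start[sel])) / (end[sel] - start[sel])
  }
  out
}

# Background depth over the track after masking out `mask` (a data.frame
# with chromosome/start/end; intervals may overlap, they are merged per
# chromosome first). Robust to residual high-copy contamination the mask
# misses: the length-weighted mean is restricted to intervals whose depth
# lies within 50% of the length-weighted median depth, so collapsed-
# amplicon pile-ups cannot inflate the background even when the mask is
# incomplete. On a homogeneous track this equals the plain mean to within
# the (negligible) mass outside the +/-50% band.
#' @keywords internal
.track_background_mean <- function(track, mask = NULL) {
  iv <- track$intervals
  w <- iv$end - iv$start
  if (!is.null(mask) && nrow(mask) > 0) {
    for (chr in unique(mask$chromosome)) {
      m <- .merge_intervals(mask[mask$chromosome == chr, , drop = FALSE])
      midx <- list(start = m$start, end = m$end,
                   depth = rep(1, nrow(m)),
                   cum = cumsum(m$end - m$start))
      sel <- iv$chromosome == chr
      ov <- .cum_depth_at(midx, iv$end[sel]) -
        .cum_depth_at(midx, iv$start[sel])
      w[sel] <- pmax(w[sel] - ov, 0)
    }
  }
  keep <- w > 0
  if (!any(keep)) .stopf("mask covers the whole track")
  d <- iv$depth[keep]; w <- w[keep]
  o <- order(d)
  med <- d[o][which(cumsum(w[o]) >= sum(w) / 2)[1]]
  band <- d >= 0.5 * med & d <= 1.5 * med
  if (!any(band)) .stopf("no background intervals near the median depth")
  sum(w[band] * d[band]) / sum(w[band])
}

# Merge overlapping/adjacent intervals (single chromosome).
#' @keywords internal
.merge_intervals <- function(df) {
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) <= 1) return(df)
  out_s <- df$start[1]; out_e <- df$end[1]
  res_s <- c(); res_e <- c()
  for (i in 2:nrow(df)) {
    if (df$start[i] <= out_e) {
      out_e <- max(out_e, df$end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- df$start[i]; out_e <- df$end[i]
    }
  }
  res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
  data.frame(chromosome = df$chromosome[1], start = res_s, end = res_e)
}

# Write a data.frame as a canonical TSV: header line, tab-delimited, LF,
# floats at 6 significant digits.
#' @keywords internal
.write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
      df2[[j]] <- signif(df2[[j]], 6)
    }
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
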