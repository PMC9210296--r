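# X-versus-autosome misexpression asymmetry: per contrast and cell type,
# classify expressed genes by direction of the log fold change, compare
# the X and autosomal up/down proportions with Pearson's chi-square, and
# count DE-gene overlap between contrasts.

#' Tally direction of expression change on X and autosomes
#'
#' Over the genes expressed in the contrast's cell type, a gene counts as
#' up when `logfc > 0` and down when `logfc < 0`; genes with `logfc == 0`
#' have no direction and are excluded from both tallies. DE subsets use
#' the `is_de` call.
#'
#' @param de a `de_result` from [test_de()].
#' @param genes a [gene_table()].
#' @return data.frame with one row per chromosome class (`X`,
#'   `autosome`): `n_up`, `n_down`, `n_de_up`, `n_de_down`, `n_expressed`.
#' @export
classify_direction <- function(de, genes) {
  idx <- match(de$gene_id, genes$gene_id)
  if (anyNA(idx))
    .stopf("gene %s absent from annotation", de$gene_id[is.na(idx)][1])
  ct <- attr(de, "contrast")
  de <- de[de$expressed_in_cell_type, , drop = FALSE]
  is_x <- genes$is_x[match(de$gene_id, genes$gene_id)]
  tally <- function(sel) {
    d <- de[sel, , drop = FALSE]
    data.frame(n_up = sum(d$logfc > 0), n_down = sum(d$logfc < 0),
               n_de_up = sum(d$is_de & d$logfc > 0),
               n_de_down = sum(d$is_de & d$logfc < 0),
               n_expressed = nrow(d))
  }
  out <- rbind(cbind(chromosome_class = "X", tally(is_x)),
               cbind(chromosome_class = "autosome", tally(!is_x)))
  if (!is.null(ct)) {
    out$contrast <- ct$name
    out$cell_type <- ct$cell_type
  }
  out
}

# Textbook Pearson chi-square on a 2x2 table, no continuity correction.
#' @keywords internal
.pearson_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

#' Test X-vs-autosome asymmetry of misexpression direction
#'
#' Pearson's chi-square (1 df, no continuity correction by default) on the
#' 2x2 table of up/down counts for X versus autosomes, over all expressed
#' genes (`scope = "all_expressed"`) or DE genes only
#' (`scope = "de_only"`). When any marginal total is zero the test is
#' undefined and flagged rather than computed. Raw p-values are returned;
#' apply [adjust_asymmetry_panel()] across the full panel of tests of a
#' run for the FDR-corrected values.
#'
#' @param direction data.frame from [classify_direction()].
#' @param scope `"all_expressed"` or `"de_only"`.
#' @param correct apply the Yates continuity correction (off by default).
#' @return one-row data.frame: `chi2`, `df`, `p_raw`, `defined`, plus the
#'   contrast columns when present.
#' @export
xa_asymmetry_test <- function(direction, scope = c("all_expressed", "de_only"),
                              correct = FALSE) {
  scope <- match.arg(scope)
  x <- direction[direction$chromosome_class == "X", ]
  a <- direction[direction$chromosome_class == "autosome", ]
  if (nrow(x) != 1 || nrow(a) != 1)
    .stopf("direction table must have one X and one autosome row")
  tab <- if (scope == "de_only")
    rbind(c(x$n_de_up, x$n_de_down), c(a$n_de_up, a$n_de_down))
  else rbind(c(x$n_up, x$n_down), c(a$n_up, a$n_down))
  defined <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  if (defined) {
    if (correct) {
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      chi2 <- sum((abs(tab - e) - 0.5)^2 / e)
    } else chi2 <- .pearson_chi2(tab)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_; p <- NA_real_
  }
  out <- data.frame(scope = scope, chi2 = chi2, df = 1L, p_raw = p,
                    defined = defined)
  for (col in c("contrast", "cell_type"))
    if (col %in% names(direction)) out[[col]] <- direction[[col]][1]
  out
}

#' FDR-adjust a panel of asymmetry tests
#'
#' BH adjustment across every test emitted in one run (all contrasts x
#' cell types x scopes), matching an FDR correction applied across the
#' whole reported panel. Undefined tests keep `NA`.
#'
#' @param tests data.frame of rows from [xa_asymmetry_test()].
#' @return the same data.frame with a `p_adj` column.
#' @export
adjust_asymmetry_panel <- function(tests) {
  tests$p_adj <- bh_adjust(tests$p_raw)
  tests
}

#' Count DE-gene overlap between two contrasts
#'
#' @param de_a,de_b `de_result` tables over the same annotation.
#' @param genes a [gene_table()].
#' @param x_only restrict to X-linked genes.
#' @return list with `n_a`, `n_b`, `n_shared`.
#' @export
contrast_overlap <- function(de_a, de_b, genes, x_only = TRUE) {
  pick <- function(de) {
    ids <- de$gene_id[de$is_de]
    if (x_only) ids[genes$is_x[match(ids, genes$gene_id)]] else ids
  }
  a <- pick(de_a); b <- pick(de_b)
  list(n_a = length(a), n_b = length(b),
       n_shared = length(intersect(a, b)))
}
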