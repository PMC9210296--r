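# Ampliconic gene-family copy number from relative sequencing depth.
# Two estimators: (1) region coverage -- sum of per-paralog-region mean
# depths over half the background depth; (2) informative sites -- kmer-
# derived locations where depth is summed per kmer, optionally GC-
# corrected. Paralog discovery and kmer mapping use an internal exact-
# match index (seed + ungapped extension, pigeonhole mismatch scan), so
# results are deterministic functions of the sequences.

#' @keywords internal
.genome_as_character <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    out <- as.character(ss)
    names(out) <- sub("\\s.*", "", names(ss))
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) .stopf("genome sequences must be named")
    return(toupper(genome))
  }
  .stopf("genome must be a FASTA path, named character vector, or DNAStringSet")
}

#' @keywords internal
.query_as_character <- function(query) {
  if (inherits(query, "DNAStringSet")) return(as.character(query)[1])
  if (inherits(query, "DNAString")) return(as.character(query))
  if (is.character(query) && length(query) == 1 && file.exists(query))
    return(as.character(Biostrings::readDNAStringSet(query))[1])
  toupper(as.character(query)[1])
}

#' @keywords internal
.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Number of matching characters between equal-length strings.
#' @keywords internal
.n_match <- function(a, b) sum(charToRaw(a) == charToRaw(b))

# All substrings of width k starting at every position.
#' @keywords internal
.kmers <- function(s, k) {
  n <- nchar(s) - k + 1
  if (n < 1) .stopf("sequence shorter than k = %d", k)
  substring(s, 1:n, k:(k + n - 1))
}

# ---- paralog discovery ---------------------------------------------------

#' Find near-identical paralogs of a query gene in a genome
#'
#' Seeds with exact `seed_k`-mers of the query (internal dictionary
#' match), extends each seeded locus by ungapped alignment over the full
#' query span, and keeps loci with sequence identity at least
#' `min_identity` and aligned length at least `min_cov` of the query.
#' Both strands are searched; overlapping hits are merged keeping the
#' higher identity; at most `max_hits` loci are returned.
#'
#' @param query query gene sequence (character, `DNAString`, or FASTA
#'   path; length >= 200 bp).
#' @param genome genome (FASTA path, named character vector, or
#'   `DNAStringSet`).
#' @param family gene-family label carried in the result.
#' @param min_identity identity threshold (default 0.97).
#' @param max_hits cap on returned loci.
#' @param seed_k exact seed length.
#' @param min_cov minimum aligned fraction of the query.
#' @return object of class `paralog_set`: list with `family`, `intervals`
#'   (data.frame: chromosome, start, end [0-based half-open], strand,
#'   identity) and `query_length`.
#' @export
find_paralogs <- function(query, genome, family = "family",
                          min_identity = 0.97, max_hits = 1000,
                          seed_k = 31, min_cov = 0.9) {
  q <- .query_as_character(query)
  lq <- nchar(q)
  if (lq < 200) .stopf("query must be >= 200 bp (got %d)", lq)
  if (lq < seed_k) .stopf("query shorter than seed length %d", seed_k)
  gen <- .genome_as_character(genome)
  qk <- .kmers(q, seed_k)
  pd <- Biostrings::PDict(qk)

  hits <- list()
  for (chr in names(gen)) {
    subj_fwd <- gen[[chr]]
    L <- nchar(subj_fwd)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") subj_fwd else .revcomp(subj_fwd)
      ml <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj))
      st <- Biostrings::startIndex(ml)
      cand <- integer(0)
      for (i in seq_along(st)) {
        if (!is.null(st[[i]]) && length(st[[i]]))
          cand <- c(cand, st[[i]] - (i - 1L))
      }
      cand <- unique(cand)
      for (p in cand) {
        a1 <- max(p, 1L); a2 <- min(p + lq - 1L, L)
        aligned <- a2 - a1 + 1L
        if (aligned < min_cov * lq) next
        qs <- substr(q, a1 - p + 1L, a2 - p + 1L)
        gs <- substr(subj, a1, a2)
        ident <- .n_match(qs, gs) / aligned
        if (ident < min_identity) next
        # forward-strand 0-based half-open coordinates
        if (strand == "+") {
          s0 <- a1 - 1L; e0 <- a2
        } else {
          s0 <- L - a2; e0 <- L - a1 + 1L
        }
        hits[[length(hits) + 1]] <-
          data.frame(chromosome = chr, start = s0, end = e0,
                     strand = strand, identity = ident,
                     stringsAsFactors = FALSE)
      }
    }
  }
  iv <- if (length(hits)) do.call(rbind, hits)
  else data.frame(chromosome = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  identity = numeric(0))
  # merge overlaps keeping the higher-identity locus
  if (nrow(iv) > 1) {
    iv <- iv[order(-iv$identity, iv$chromosome, iv$start), , drop = FALSE]
    keep <- logical(nrow(iv))
    for (i in seq_len(nrow(iv))) {
      acc <- iv[keep & iv$chromosome == iv$chromosome[i], , drop = FALSE]
      ov <- nrow(acc) && any(acc$start < iv$end[i] & iv$start[i] < acc$end)
      keep[i] <- !ov
    }
    iv <- iv[keep, , drop = FALSE]
  }
  iv <- iv[order(iv$chromosome, iv$start), , drop = FALSE]
  if (nrow(iv) > max_hits) iv <- iv[seq_len(max_hits), , drop = FALSE]
  rownames(iv) <- NULL
  structure(list(family = family, intervals = iv, query_length = lq),
            class = "paralog_set")
}

#' @export
print.paralog_set <- function(x, ...) {
  cat(sprintf("paralog_set '%s': %d interval(s), query %d bp\n",
              x$family, nrow(x$intervals), x$query_length))
  invisible(x)
}

# ---- copy-number estimate container -------------------------------------

#' @keywords internal
.cn_estimate <- function(family, method, estimate, n, genome_mean) {
  structure(list(family = family, method = method, estimate = estimate,
                 n_regions_or_sites = n, genome_mean_depth = genome_mean),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("%s copy number (%s): %.2f  [%d %s, background depth %.2f]\n",
              x$family, x$method, x$estimate, x$n_regions_or_sites,
              if (x$method == "region_coverage") "regions" else "sites",
              x$genome_mean_depth))
  invisible(x)
}

# ---- region-coverage estimator ------------------------------------------

#' Copy number from summed paralog-region coverage
#'
#' Sums the mean depth of each paralog region and divides by half the
#' background depth (half because the bulk of the genome is diploid while
#' the sex chromosomes carrying these families are haploid in males), so
#' a single haploid-depth region contributes 1 copy. By default the
#' background is the length-weighted mean depth over the track excluding
#' the paralog regions themselves; on a whole-genome track this is
#' indistinguishable from the plain genome-wide mean, but it keeps the
#' estimator unbiased on compact targeted tracks where the amplicon is a
#' non-negligible fraction of the sequence.
#'
#' @param paralogs a [find_paralogs()] result.
#' @param depth a [coverage_track()].
#' @param background `"non_paralog"` (default) or `"genome_mean"` (use
#'   the track's genome-wide mean verbatim).
#' @return a `copy_number_estimate`.
#' @export
cn_from_region_coverage <- function(paralogs, depth,
                                    background = c("non_paralog",
                                                   "genome_mean")) {
  stopifnot(inherits(paralogs, "paralog_set"),
            inherits(depth, "coverage_track"))
  background <- match.arg(background)
  iv <- paralogs$intervals
  if (nrow(iv) == 0) .stopf("paralog set is empty")
  bg <- if (background == "genome_mean") depth$genome_mean
  else .track_background_mean(depth, iv[, c("chromosome", "start", "end")])
  if (bg <= 0) .stopf("background depth is zero")
  means <- track_region_mean(depth, iv$chromosome, iv$start, iv$end)
  .cn_estimate(paralogs$family, "region_coverage",
               sum(means) / (bg / 2), nrow(iv), bg)
}

# ---- informative sites ---------------------------------------------------

#' Derive informative sites from query kmers
#'
#' Extracts every kmer of length `k` from the query, counts its exact-
#' match locations in the genome (both strands, counts capped at
#' `map_cap`), and takes the modal nonzero count m (smallest value on
#' ties) as the reference multiplicity of the family. Kmers mapping
#' exactly m times are retained; for those, every genome location
#' matching with at most `max_mismatch` mismatches is enumerated (exact
#' chunk seeding by pigeonhole, then full-window verification). The
#' retained kmer windows are the informative sites used by
#' [cn_from_informative_sites()].
#'
#' @param query query gene sequence (>= `k` bp).
#' @param genome genome (FASTA path, named character vector, or
#'   `DNAStringSet`).
#' @param family gene-family label.
#' @param k kmer length (default 101).
#' @param map_cap cap on exact-match counts per kmer.
#' @param max_mismatch mismatch allowance for site enumeration.
#' @return object of class `informative_site_set`: list with `family`,
#'   `k`, `m` (modal multiplicity), `n_kmers` (retained kmers),
#'   `exact_counts` (per query kmer), and `sites` (data.frame:
#'   kmer_index, chromosome, start [0-based, forward coords], strand,
#'   mismatches).
#' @export
build_informative_sites <- function(query, genome, family = "family",
                                    k = 101, map_cap = 500,
                                    max_mismatch = 2) {
  q <- .query_as_character(query)
  if (nchar(q) < k) .stopf("query (%d bp) shorter than k = %d", nchar(q), k)
  gen <- .genome_as_character(genome)
  qk <- .kmers(q, k)
  n_kmer <- length(qk)
  pd <- Biostrings::PDict(qk)
  counts <- integer(n_kmer)
  for (chr in names(gen)) {
    counts <- counts +
      Biostrings::countPDict(pd, Biostrings::DNAString(gen[[chr]])) +
      Biostrings::countPDict(pd, Biostrings::DNAString(.revcomp(gen[[chr]])))
  }
  capped <- pmin(counts, map_cap)
  mapped <- capped[capped >= 1 & counts <= map_cap]
  if (!length(mapped)) {
    if (all(counts > map_cap))
      .stopf("all kmers exceed the mapping cap (%d); family too repetitive",
             map_cap)
    .stopf("no query kmer has an exact match in the genome")
  }
  tab <- table(mapped)
  m <- as.integer(names(tab)[tab == max(tab)])
  m <- min(m)  # smallest multiplicity on ties
  retained <- which(counts == m)

  # pigeonhole enumeration of <= max_mismatch locations for retained kmers
  n_chunks <- max_mismatch + 1L
  cw <- k %/% n_chunks
  sites <- list()
  for (chr in names(gen)) {
    subj_fwd <- gen[[chr]]
    L <- nchar(subj_fwd)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") subj_fwd else .revcomp(subj_fwd)
      subj_ds <- Biostrings::DNAString(subj)
      cand <- list()
      for (j in seq_len(n_chunks)) {
        off <- (j - 1L) * cw
        chunks <- substring(qk[retained], off + 1L, off + cw)
        pc <- Biostrings::PDict(chunks)
        ml <- Biostrings::matchPDict(pc, subj_ds)
        st <- Biostrings::startIndex(ml)
        for (i in seq_along(st)) {
          if (is.null(st[[i]]) || !length(st[[i]])) next
          cand[[length(cand) + 1]] <-
            cbind(ki = retained[i], p = st[[i]] - off)
        }
      }
      if (!length(cand)) next
      cm <- unique(do.call(rbind, cand))
      cm <- cm[cm[, "p"] >= 1 & cm[, "p"] + k - 1 <= L, , drop = FALSE]
      if (!nrow(cm)) next
      mism <- integer(nrow(cm))
      okay <- logical(nrow(cm))
      for (r in seq_len(nrow(cm))) {
        w <- substr(subj, cm[r, "p"], cm[r, "p"] + k - 1L)
        mm <- k - .n_match(w, qk[cm[r, "ki"]])
        mism[r] <- mm
        okay[r] <- mm <= max_mismatch
      }
      cm <- cm[okay, , drop = FALSE]
      if (!nrow(cm)) next
      mism <- mism[okay]
      p1 <- cm[, "p"]
      start0 <- if (strand == "+") p1 - 1L else L - (p1 - 1L + k)
      sites[[length(sites) + 1]] <- data.frame(
        kmer_index = cm[, "ki"], chromosome = chr, start = start0,
        strand = strand, mismatches = mism, stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites)
  else data.frame(kmer_index = integer(0), chromosome = character(0),
                  start = integer(0), strand = character(0),
                  mismatches = integer(0))
  rownames(sites) <- NULL
  structure(list(family = family, k = k, m = m,
                 n_kmers = length(retained), exact_counts = counts,
                 retained = retained, sites = sites),
            class = "informative_site_set")
}

#' @export
print.informative_site_set <- function(x, ...) {
  cat(sprintf(
    "informative_site_set '%s': m = %d, %d retained kmers, %d site(s)\n",
    x$family, x$m, x$n_kmers, nrow(x$sites)))
  invisible(x)
}

#' Copy number from informative-site relative depth
#'
#' For every retained kmer, the relative depth at each of its genome
#' locations is the mean depth over the k-bp window divided by half the
#' background depth (optionally corrected for GC content); the kmer's
#' contribution is the sum over its locations, and the estimate is the
#' mean contribution over retained kmers. GC correction bins k-bp windows
#' by GC fraction in `gc_bin`-wide bins and divides each window's
#' relative depth by its bin's median relative depth (normalized to the
#' global median so the correction removes GC trend without rescaling),
#' estimated from `n_gc_windows` windows sampled uniformly from the
#' genome.
#'
#' @param sites a [build_informative_sites()] result.
#' @param depth a [coverage_track()].
#' @param genome the genome the sites were derived from (needed for GC
#'   content; may be `NULL` when `gc_correct = FALSE`).
#' @param gc_correct apply the GC correction (default TRUE).
#' @param gc_bin GC-fraction bin width (default 0.02).
#' @param n_gc_windows genome windows sampled for the bin medians.
#' @param seed RNG seed for the window sampling.
#' @param background `"non_paralog"` (exclude site windows from the
#'   background mean; default) or `"genome_mean"`.
#' @return a `copy_number_estimate`.
#' @export
cn_from_informative_sites <- function(sites, depth, genome = NULL,
                                      gc_correct = TRUE, gc_bin = 0.02,
                                      n_gc_windows = 1000, seed = 1,
                                      background = c("non_paralog",
                                                     "genome_mean")) {
  stopifnot(inherits(sites, "informative_site_set"),
            inherits(depth, "coverage_track"))
  background <- match.arg(background)
  ss <- sites$sites
  if (nrow(ss) == 0) .stopf("informative site set is empty")
  k <- sites$k
  win <- data.frame(chromosome = ss$chromosome, start = ss$start,
                    end = ss$start + k)
  bg <- if (background == "genome_mean") depth$genome_mean
  else .track_background_mean(depth, win)
  if (bg <= 0) .stopf("background depth is zero")
  rel <- track_region_mean(depth, win$chromosome, win$start, win$end) /
    (bg / 2)

  if (gc_correct) {
    if (is.null(genome)) .stopf("gc_correct = TRUE requires the genome")
    gen <- .genome_as_character(genome)
    gc_frac <- function(seqs) {
      v <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                       letters = "GC", as.prob = TRUE)
      as.numeric(v)
    }
    # control windows are sampled from copy-neutral sequence: windows
    # overlapping the informative-site mask would contaminate the bin
    # medians with the amplicon's own elevated depth
    mask_by_chr <- lapply(split(win, win$chromosome), .merge_intervals)
    samp <- .with_seed(seed, {
      chr_len <- nchar(gen)
      got <- list(); need <- n_gc_windows
      for (tries in 1:20) {
        if (need <= 0) break
        chrs <- sample(names(gen), 2 * need, replace = TRUE,
                       prob = chr_len / sum(chr_len))
        st <- vapply(chrs, function(ch)
          sample.int(nchar(gen[[ch]]) - k + 1L, 1L), 1L)
        cand <- data.frame(chromosome = chrs, start = st - 1L,
                           end = st - 1L + k, stringsAsFactors = FALSE)
        ok <- vapply(seq_len(nrow(cand)), function(i) {
          mk <- mask_by_chr[[cand$chromosome[i]]]
          is.null(mk) || !any(mk$start < cand$end[i] & cand$start[i] < mk$end)
        }, TRUE)
        cand <- cand[ok, , drop = FALSE]
        if (nrow(cand)) {
          got[[length(got) + 1]] <- utils::head(cand, need)
          need <- need - min(nrow(cand), need)
        }
      }
      if (need > 0) .stopf("could not sample copy-neutral control windows")
      do.call(rbind, got)
    })
    samp_rel <- track_region_mean(depth, samp$chromosome, samp$start,
                                  samp$end) / (bg / 2)
    samp_gc <- gc_frac(substring(gen[samp$chromosome], samp$start + 1,
                                 samp$end))
    site_gc <- gc_frac(substring(gen[win$chromosome], win$start + 1,
                                 win$end))
    bin_of <- function(g) floor(g / gc_bin)
    overall <- stats::median(samp_rel)
    if (overall <= 0) .stopf("sampled genome windows have zero depth")
    # relative correction: each bin's median depth against the global
    # median, so the correction removes GC trend without rescaling copies
    med <- tapply(samp_rel, bin_of(samp_gc), stats::median) / overall
    fac <- med[as.character(bin_of(site_gc))]
    fac[is.na(fac) | fac <= 0] <- 1
    rel <- rel / as.numeric(fac)
  }

  contrib <- tapply(rel, ss$kmer_index, sum)
  .cn_estimate(sites$family, "informative_sites",
               mean(contrib), nrow(ss), bg)
}

# ---- family ratio --------------------------------------------------------

#' Sly/Slx copy-number family ratio
#'
#' Ratio of the Y-linked family's copy number to the sum of the two
#' X-linked families' copy numbers, `sly / (slx + slxl1)`, rounded to
#' `digits` significant digits. Accepts `copy_number_estimate` objects or
#' plain numbers.
#'
#' @param sly,slx,slxl1 copy-number estimates (objects or numerics);
#'   `slxl1` may be 0 when the family total is already in `slx`.
#' @param digits significant digits of the reported ratio.
#' @return the rounded ratio.
#' @export
compute_family_ratio <- function(sly, slx, slxl1 = 0, digits = 2) {
  val <- function(x) if (inherits(x, "copy_number_estimate")) x$estimate
  else as.numeric(x)
  num <- val(sly); den <- val(slx) + val(slxl1)
  if (num < 0 || den < 0) .stopf("copy numbers must be >= 0")
  if (den == 0) .stopf("zero denominator: slx + slxl1 must be > 0")
  signif(num / den, digits)
}
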