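# C2H2 zinc-finger detection and Prdm9-style allele typing. Fingers are
# located with the C2H2 consensus pattern C-x(2,4)-C-x(12)-H-x(3,5)-H
# (fixed 12-residue inter-C/H spacer; tandem PRDM9 fingers are regular
# 28-residue repeats). The DNA-contacting recognition-helix residues at
# positions -1, 3 and 6 sit at offsets H1-7, H1-4 and H1-1 from the first
# zinc-coordinating histidine.

.ZF_PATTERN <- "C(.{2,4})C(.{12})H(.{3,5})H"

#' Extract recognition-helix triplets from a zinc-finger protein
#'
#' Scans the protein left to right for non-overlapping C2H2 motifs and,
#' per finger, reports the residues at recognition-helix positions -1, 3
#' and 6 (offsets H1-7, H1-4, H1-1 from the first histidine). The first
#' finger -- nonvariant in PRDM9 arrays -- is dropped by default.
#'
#' @param protein protein sequence (character, `AAString`, or FASTA path).
#' @param exclude_first drop the first detected finger (default TRUE).
#' @param protein_id identifier carried in the result.
#' @return object of class `zf_array`: list with `protein_id` and
#'   `fingers` (data.frame: start, end [1-based residue positions],
#'   triplet). Empty (with a warning) when no motif matches.
#' @export
extract_zf_triplets <- function(protein, exclude_first = TRUE,
                                protein_id = "protein") {
  p <- if (is.character(protein) && length(protein) == 1 &&
           file.exists(protein)) {
    as.character(Biostrings::readAAStringSet(protein))[1]
  } else if (inherits(protein, "AAString") ||
             inherits(protein, "AAStringSet")) {
    as.character(protein)[1]
  } else toupper(as.character(protein)[1])
  # 21 = minimal span of the C2H2 motif (C-x2-C-x12-H-x3-H)
  if (nchar(p) < 21) .stopf("protein shorter than one C2H2 motif (21 residues)")

  m <- gregexpr(.ZF_PATTERN, p, perl = TRUE)[[1]]
  empty <- data.frame(start = integer(0), end = integer(0),
                      triplet = character(0))
  if (m[1] == -1) {
    .warnf("no C2H2 motif found in %s", protein_id)
    return(structure(list(protein_id = protein_id, fingers = empty),
                     class = "zf_array"))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # H1 = the histidine closing the 12-residue spacer = end of capture
  # group 2 (the x12) + 1, taken from the engine's own parse
  cs2 <- attr(m, "capture.start")[, 2]
  h1s <- cs2 + 12L
  fingers <- do.call(rbind, lapply(seq_along(starts), function(i) {
    h1 <- h1s[i]
    data.frame(start = starts[i], end = starts[i] + lens[i] - 1L,
               triplet = paste0(substr(p, h1 - 7, h1 - 7),
                                substr(p, h1 - 4, h1 - 4),
                                substr(p, h1 - 1, h1 - 1)),
               stringsAsFactors = FALSE)
  }))
  if (exclude_first && nrow(fingers) >= 1)
    fingers <- fingers[-1, , drop = FALSE]
  rownames(fingers) <- NULL
  structure(list(protein_id = protein_id, fingers = fingers),
            class = "zf_array")
}

#' @export
print.zf_array <- function(x, ...) {
  cat(sprintf("zf_array '%s': %d finger(s): %s\n", x$protein_id,
              nrow(x$fingers), paste(x$fingers$triplet, collapse = "-")))
  invisible(x)
}

#' Read an allele signature table
#'
#' TSV with columns `allele` and `signature` (comma-separated -1/3/6
#' triplets, one per finger).
#'
#' @param path TSV path.
#' @return named list of character vectors (triplet signatures).
#' @export
read_allele_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("allele", "signature") %in% names(df)))
    .stopf("allele table needs 'allele' and 'signature' columns")
  if (anyDuplicated(df$allele))
    .stopf("duplicate allele name: %s", df$allele[duplicated(df$allele)][1])
  sig <- strsplit(df$signature, ",", fixed = TRUE)
  sig <- lapply(sig, trimws)
  names(sig) <- df$allele
  sig
}

#' Match a zinc-finger signature against known alleles
#'
#' An exact triplet-signature match returns the allele name; otherwise
#' the call is `"novel"` and the per-finger Hamming distance to the
#' nearest known allele(s) is reported (signatures of unequal length add
#' the length difference to the distance). Ties for nearest are all
#' reported, not broken.
#'
#' @param array a `zf_array` from [extract_zf_triplets()].
#' @param table named list of triplet signatures (see
#'   [read_allele_table()]).
#' @return list with `allele` (name or `"novel"`), `distance` (0 for an
#'   exact match), and `nearest` (character vector).
#' @export
match_allele <- function(array, table) {
  stopifnot(inherits(array, "zf_array"))
  if (!length(table)) .stopf("allele table is empty")
  sig <- array$fingers$triplet
  if (!length(sig)) .stopf("empty signature; no fingers detected")
  dist_to <- vapply(table, function(ref) {
    n <- min(length(sig), length(ref))
    sum(sig[seq_len(n)] != ref[seq_len(n)]) +
      abs(length(sig) - length(ref))
  }, 0)
  if (any(dist_to == 0)) {
    hit <- names(dist_to)[dist_to == 0][1]
    return(list(allele = hit, distance = 0, nearest = hit))
  }
  dmin <- min(dist_to)
  list(allele = "novel", distance = dmin,
       nearest = names(dist_to)[dist_to == dmin])
}
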