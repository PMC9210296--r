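# Synthetic-data generators. Each generator is a pure function of its
# config + seed: the RNG state is saved, seeded locally, and restored, so
# generators neither depend on nor disturb global RNG state.

#' @keywords internal
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# ---- expression ----------------------------------------------------------

#' Configuration for the expression simulator
#'
#' Defaults emulate a stage-resolved testis RNA-seq design: four crosses
#' (two parental strains, two reciprocal F1 hybrids), three FACS-enriched
#' cell types (leptotene/zygotene LZ, diplotene DIP, round spermatid RS),
#' three replicates. Counts are negative binomial with variance
#' `mu + dispersion * mu^2`; the default dispersion is 0.1748^2 (a
#' biological coefficient of variation of 0.1748). In diplotene of the
#' fertile parental crosses, X-linked gene means are multiplied by
#' `msci_silencing`, emulating meiotic sex chromosome inactivation; in the
#' hybrids, a configurable fraction of X genes escape (DIP) or are
#' de-repressed (RS) with log2 fold change `disrupt_logfc` relative to the
#' parent sharing their X chromosome.
#'
#' @param n_genes number of genes.
#' @param frac_x fraction of genes on the X chromosome.
#' @param replicates biological replicates per cross x cell type.
#' @param baseline_mean average baseline expression in counts.
#' @param dispersion NB dispersion phi (variance mu + phi mu^2).
#' @param msci_silencing multiplier on X-gene means in DIP (both parental
#'   crosses and non-disrupted hybrid genes).
#' @param disrupt_frac_dip,disrupt_frac_rs named vectors (names `musXdom`,
#'   `domXmus`): fraction of X genes disrupted per hybrid in DIP / RS.
#' @param disrupt_logfc log2 fold change of planted disruptions.
#' @param n_autosomes number of autosomes in the toy genome.
#' @param seed integer RNG seed.
#' @return a validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 3000, frac_x = 0.05,
                                  replicates = 3, baseline_mean = 500,
                                  dispersion = 0.1748^2,
                                  msci_silencing = 0.02,
                                  disrupt_frac_dip = c(musXdom = 0.5, domXmus = 0.3),
                                  disrupt_frac_rs = c(musXdom = 0.5, domXmus = 0),
                                  disrupt_logfc = 2,
                                  n_autosomes = 5, seed = 1) {
  stopifnot(n_genes > 0, frac_x > 0, frac_x < 1, replicates >= 1,
            baseline_mean > 0, dispersion > 0,
            msci_silencing >= 0, msci_silencing <= 1)
  for (h in c("musXdom", "domXmus")) {
    if (is.na(disrupt_frac_dip[h]) || is.na(disrupt_frac_rs[h]))
      .stopf("disrupt fractions must be named vectors with entries for %s", h)
  }
  if (any(c(disrupt_frac_dip, disrupt_frac_rs) < 0) ||
      any(c(disrupt_frac_dip, disrupt_frac_rs) > 1))
    .stopf("disrupt fractions must lie in [0, 1]")
  structure(as.list(environment()), class = "expression_sim_config")
}

#' Simulate a stage-resolved hybrid expression study
#'
#' Generates a toy gene annotation, a count matrix over
#' 4 crosses x 3 cell types x `replicates` samples, and a truth table of
#' every planted effect. Gene exonic lengths are log-uniform in
#' [500, 5000] bp so FPKM filtering is non-trivial; per-gene cell-type
#' offsets make samples cluster by cell type.
#'
#' @param cfg an [expression_sim_config()].
#' @return list with elements `genes` ([gene_table()]), `counts`
#'   ([count_matrix()]) and `truth` (data.frame: hybrid, gene_id,
#'   cell_type, true_logfc, is_disrupted).
#' @export
simulate_expression <- function(cfg = expression_sim_config()) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_genes
    n_x <- max(1L, round(cfg$frac_x * n))
    n_a <- n - n_x
    chrom <- c(rep(as.character(seq_len(cfg$n_autosomes)),
                   length.out = n_a), rep("X", n_x))
    ids <- sprintf("gene%05d", seq_len(n))
    # positions: genes laid out in 10 kb steps per chromosome
    rank_in_chr <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    start <- (rank_in_chr - 1) * 10000
    genes <- gene_table(data.frame(
      chromosome = chrom, start = start, end = start + 5000,
      gene_id = ids,
      exonic_length = round(exp(stats::runif(n, log(500), log(5000)))),
      stringsAsFactors = FALSE))

    # per-gene baseline (log-normal spread) and per-gene cell-type offsets
    base_mu <- cfg$baseline_mean * stats::rlnorm(n, meanlog = -0.5, sdlog = 1)
    ct_off <- matrix(stats::rlnorm(n * 3, meanlog = 0, sdlog = 0.5),
                     nrow = n, dimnames = list(ids, .CELL_TYPES))
    names(base_mu) <- ids

    is_x <- genes$is_x[match(ids, genes$gene_id)]
    x_ids <- ids[is_x]

    # planted disruptions per hybrid and stage
    pick <- function(frac) {
      k <- round(frac * length(x_ids))
      if (k == 0) character(0) else sample(x_ids, k)
    }
    disrupted <- list(
      musXdom = list(DIP = pick(cfg$disrupt_frac_dip["musXdom"]),
                     RS = pick(cfg$disrupt_frac_rs["musXdom"])),
      domXmus = list(DIP = pick(cfg$disrupt_frac_dip["domXmus"]),
                     RS = pick(cfg$disrupt_frac_rs["domXmus"])))

    mean_for <- function(cross, ct) {
      mu <- base_mu * ct_off[, ct]
      if (ct == "DIP") mu[is_x] <- mu[is_x] * cfg$msci_silencing
      if (cross %in% c("musXdom", "domXmus")) {
        d <- disrupted[[cross]][[ct]]
        if (length(d)) mu[d] <- mu[d] * 2^cfg$disrupt_logfc
      }
      mu
    }

    samples <- expand.grid(replicate = seq_len(cfg$replicates),
                           cell_type = .CELL_TYPES, cross = .CROSSES,
                           stringsAsFactors = FALSE)
    samples <- samples[, c("cross", "cell_type", "replicate")]
    samples$sample_id <- sprintf("%s_%s_%d", samples$cross,
                                 samples$cell_type, samples$replicate)
    samples <- samples[, c("sample_id", "cross", "cell_type", "replicate")]

    counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                     dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- mean_for(samples$cross[j], samples$cell_type[j])
      counts[, j] <- stats::rnbinom(n, size = 1 / cfg$dispersion, mu = mu)
    }

    truth <- do.call(rbind, lapply(c("musXdom", "domXmus"), function(h) {
      do.call(rbind, lapply(.CELL_TYPES, function(ct) {
        d <- disrupted[[h]][[ct]]
        data.frame(hybrid = h, gene_id = ids, cell_type = ct,
                   true_logfc = ifelse(ids %in% d, cfg$disrupt_logfc, 0),
                   is_disrupted = ids %in% d, stringsAsFactors = FALSE)
      }))
    }))

    list(genes = genes, counts = count_matrix(counts, samples),
         truth = truth, config = cfg)
  })
}

# ---- amplicon genome + depth --------------------------------------------

#' Configuration for the ampliconic-genome simulator
#'
#' Builds a toy genome containing `ref_copies` near-identical planted
#' copies of a query gene (each at per-base identity `copy_identity`) and
#' one decoy copy at `decoy_identity`, below the 97% paralog-identity
#' threshold, so the paralog filter is exercised on both sides. Depth
#' simulation treats the backbone as diploid and the planted paralog
#' intervals as carrying the reads of all `true_copies` sample copies
#' spread over the `ref_copies` reference locations.
#'
#' @param backbone_length toy genome length (bp).
#' @param gene_length query gene length (bp).
#' @param ref_copies number of reference paralog copies R.
#' @param true_copies sample copy number N (drives simulated depth).
#' @param copy_identity per-base identity of planted copies to the query.
#' @param decoy_identity identity of the decoy copy (must be < 0.97).
#' @param haploid_mean_depth haploid mean sequencing depth c/2.
#' @param seed integer RNG seed.
#' @export
amplicon_sim_config <- function(backbone_length = 200000, gene_length = 2000,
                                ref_copies = 4, true_copies = 40,
                                copy_identity = 0.99, decoy_identity = 0.92,
                                haploid_mean_depth = 10, seed = 1) {
  stopifnot(backbone_length > 0, gene_length > 0, ref_copies >= 1,
            true_copies >= 1, copy_identity > 0, copy_identity <= 1,
            decoy_identity > 0, decoy_identity < 1, haploid_mean_depth > 0)
  if (!(copy_identity >= 0.97 && decoy_identity < 0.97))
    .stopf("copy_identity must be >= 0.97 and decoy_identity < 0.97")
  structure(as.list(environment()), class = "amplicon_sim_config")
}

#' @keywords internal
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
.mutate_dna <- function(seq, identity) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) > identity)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

#' Simulate a genome with a planted ampliconic gene family
#'
#' @param cfg an [amplicon_sim_config()].
#' @return list with `genome` (named character, one chromosome `sim1`),
#'   `query` (character, the family query sequence), and `truth` (list:
#'   `intervals` data.frame with 0-based half-open planted coordinates and
#'   roles `copy`/`decoy`, `ref_copies`, `true_copies`, `config`).
#' @export
simulate_amplicon_genome <- function(cfg = amplicon_sim_config()) {
  stopifnot(inherits(cfg, "amplicon_sim_config"))
  .with_seed(cfg$seed, {
    n_slots <- cfg$ref_copies + 1  # planted copies + decoy
    slot <- cfg$backbone_length %/% n_slots
    if (slot < cfg$gene_length + 200)
      .stopf("backbone too small to plant %d non-overlapping copies",
             n_slots)
    backbone <- .random_dna(cfg$backbone_length)
    query <- .random_dna(cfg$gene_length)
    roles <- c(rep("copy", cfg$ref_copies), "decoy")
    # decoy position shuffled among the slots
    roles <- sample(roles)
    starts <- integer(n_slots)
    genome <- backbone
    for (i in seq_len(n_slots)) {
      off <- sample.int(slot - cfg$gene_length - 100, 1) + 50
      s <- (i - 1) * slot + off  # 0-based start
      starts[i] <- s
      ident <- if (roles[i] == "copy") cfg$copy_identity else cfg$decoy_identity
      planted <- if (ident >= 1) query else .mutate_dna(query, ident)
      substr(genome, s + 1, s + cfg$gene_length) <- planted
    }
    truth <- list(
      intervals = data.frame(chromosome = "sim1", start = starts,
                             end = starts + cfg$gene_length, role = roles,
                             stringsAsFactors = FALSE),
      ref_copies = cfg$ref_copies, true_copies = cfg$true_copies,
      config = cfg)
    list(genome = c(sim1 = genome), query = query, truth = truth)
  })
}

#' Simulate per-base sequencing depth over a planted amplicon genome
#'
#' Backbone and decoy bases draw depth from Poisson(2 * haploid depth)
#' (diploid genome); bases inside planted paralog intervals draw from
#' Poisson((N/R) * haploid depth), emulating reads from all N sample
#' copies collapsing onto the R reference locations.
#'
#' @param truth the `truth` element from [simulate_amplicon_genome()].
#' @param cfg the matching [amplicon_sim_config()]; defaults to the config
#'   recorded in `truth`.
#' @param seed RNG seed; defaults to `cfg$seed + 1` so genome and depth
#'   use distinct streams.
#' @return a [coverage_track()] (run-length encoded per-base depth).
#' @export
simulate_depth <- function(truth, cfg = truth$config, seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "amplicon_sim_config"))
  .with_seed(seed, {
    L <- cfg$backbone_length
    rate <- rep(2 * cfg$haploid_mean_depth, L)
    iv <- truth$intervals
    for (i in which(iv$role == "copy")) {
      idx <- (iv$start[i] + 1):iv$end[i]
      rate[idx] <- (cfg$true_copies / cfg$ref_copies) * cfg$haploid_mean_depth
    }
    depth <- stats::rpois(L, rate)
    r <- rle(depth)
    ends <- cumsum(r$lengths)
    coverage_track(data.frame(
      chromosome = "sim1", start = ends - r$lengths, end = ends,
      depth = r$values, stringsAsFactors = FALSE))
  })
}

# ---- phenotypes ----------------------------------------------------------

#' Default per-cross phenotype simulation settings
#'
#' Trait means/SDs and sperm-morphology multinomials emulating a
#' reciprocal-cross sterility study: parental crosses with normal sperm,
#' hybrids with reduced testis weight, low sperm counts and abnormal
#' morphology (more severe in the musXdom direction).
#'
#' @return named list (per cross) of trait parameter lists.
#' @export
default_phenotype_config <- function() {
  list(
    dom = list(testes = c(11.3, 0.8), sv = c(5.2, 0.7),
               motility = c(0.82, 0.08), sperm = c(14.8, 4),
               morph_probs = c(0.99, 0.01, 0, 0)),
    mus = list(testes = c(9.5, 1.4), sv = c(5.6, 1.2),
               motility = c(0.87, 0.08), sperm = c(17.8, 5),
               morph_probs = c(0.995, 0.005, 0, 0)),
    domXmus = list(testes = c(6.3, 0.7), sv = c(5.7, 1.1),
                   motility = c(0.83, 0.1), sperm = c(4.2, 1.7),
                   morph_probs = c(0.10, 0.25, 0.49, 0.16)),
    musXdom = list(testes = c(6.5, 0.8), sv = c(5.4, 0.6),
                   motility = c(0.65, 0.15), sperm = c(5.8, 2.7),
                   morph_probs = c(0.02, 0.10, 0.40, 0.48))
  )
}

#' Simulate a per-animal reproductive phenotype table
#'
#' Traits: relative testis weight (mg/g), relative seminal-vesicle weight
#' (mg/g), proportion of motile sperm, total sperm count (millions), and
#' `n_scored` sperm classified into four head-morphology categories
#' (1 normal long apical hook ... 4 severely abnormal amorphous) by a
#' per-cross multinomial.
#'
#' @param n_per_cross animals per cross.
#' @param config per-cross parameters, see [default_phenotype_config()].
#' @param n_scored sperm scored per animal (study design: 100).
#' @param seed integer RNG seed.
#' @return data.frame with one row per animal.
#' @export
simulate_phenotypes <- function(n_per_cross = 6,
                                config = default_phenotype_config(),
                                n_scored = 100, seed = 1) {
  .with_seed(seed, {
    rows <- lapply(names(config), function(cr) {
      p <- config[[cr]]
      morph <- t(stats::rmultinom(n_per_cross, n_scored, p$morph_probs))
      data.frame(
        animal_id = sprintf("%s_%02d", cr, seq_len(n_per_cross)),
        cross = cr,
        testes_mg_g = pmax(0.1, stats::rnorm(n_per_cross, p$testes[1], p$testes[2])),
        sv_mg_g = pmax(0.1, stats::rnorm(n_per_cross, p$sv[1], p$sv[2])),
        motility = pmin(1, pmax(0, stats::rnorm(n_per_cross, p$motility[1],
                                                p$motility[2]))),
        sperm_count_m = pmax(0, stats::rnorm(n_per_cross, p$sperm[1], p$sperm[2])),
        n_cat1 = morph[, 1], n_cat2 = morph[, 2],
        n_cat3 = morph[, 3], n_cat4 = morph[, 4],
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# ---- zinc-finger arrays --------------------------------------------------

# residues used as spacer filler: no C or H, so no spurious C2H2 motifs
.ZF_FILLER <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N", "P",
                "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a tandem C2H2 zinc-finger protein
#'
#' Builds a protein of `n_fingers` tandem 28-residue C2H2 repeats of the
#' form C-x2-C-x12-H-x3-H-x7. The first finger is fixed (the nonvariant
#' finger); fingers 2..n carry the requested residues at the
#' DNA-contacting recognition-helix positions -1, 3 and 6.
#'
#' @param n_fingers number of fingers (>= 2).
#' @param triplets character vector of 3-letter strings, one per finger
#'   after the first (length `n_fingers - 1`).
#' @param seed integer RNG seed (spacer residues).
#' @return list with `protein` (character) and `truth` (list: `triplets`,
#'   `n_fingers`).
#' @export
simulate_zf_protein <- function(n_fingers, triplets, seed = 1) {
  if (n_fingers < 2) .stopf("n_fingers must be >= 2")
  if (length(triplets) != n_fingers - 1)
    .stopf("need %d triplets for %d fingers, got %d",
           n_fingers - 1, n_fingers, length(triplets))
  if (any(nchar(triplets) != 3)) .stopf("each triplet must be 3 residues")
  .with_seed(seed, {
    make_finger <- function(triplet) {
      x <- sample(.ZF_FILLER, 28, replace = TRUE)
      x[c(1, 4)] <- "C"
      x[c(17, 21)] <- "H"
      if (!is.null(triplet)) {
        t3 <- strsplit(triplet, "")[[1]]
        x[c(10, 13, 16)] <- t3  # H1-7, H1-4, H1-1 = helix -1/3/6
      }
      paste(x, collapse = "")
    }
    first <- "CPECGKAFSRSDELTRHQRTHTGEKPYV"  # fixed nonvariant finger
    body <- vapply(triplets, make_finger, "")
    leader <- paste(sample(.ZF_FILLER, 10, replace = TRUE), collapse = "")
    protein <- paste0(leader, first, paste(body, collapse = ""))
    list(protein = protein,
         truth = list(triplets = triplets, n_fingers = n_fingers))
  })
}
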