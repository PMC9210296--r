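# End-to-end synthetic study: simulate -> differential expression ->
# asymmetry -> window scan -> copy number -> phenotypes, with every stage
# written to disk as TSV plus a JSON run summary, so each stage is
# independently re-runnable.

#' Default configuration for the full synthetic study
#'
#' @param seed master seed; stage seeds are derived by small offsets.
#' @param expression an [expression_sim_config()].
#' @param sly_amplicon,slx_amplicon [amplicon_sim_config()]s for a
#'   Y-linked-family analog and an X-linked-family analog; defaults plant
#'   a relative deficit of the Y family (ratio below parity), emulating a
#'   Sly-deficient hybrid genotype.
#' @param n_per_cross animals per cross in the phenotype table.
#' @param window_size,window_step gene-window scan parameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       expression = expression_sim_config(seed = seed),
                       sly_amplicon = amplicon_sim_config(
                         ref_copies = 4, true_copies = 26, seed = seed + 100),
                       slx_amplicon = amplicon_sim_config(
                         ref_copies = 4, true_copies = 20, seed = seed + 200),
                       n_per_cross = 6, window_size = 250,
                       window_step = 25) {
  structure(list(seed = seed, expression = expression,
                 sly_amplicon = sly_amplicon, slx_amplicon = slx_amplicon,
                 n_per_cross = n_per_cross, window_size = window_size,
                 window_step = window_step), class = "run_config")
}

#' Run the full synthetic study
#'
#' Executes every stage of the pipeline on generated data and writes a
#' run report: direction/asymmetry tables for each contrast and cell
#' type, DE-gene overlap between the hybrid contrasts, flagged gene
#' windows, copy-number estimates with the family ratio, phenotype
#' summaries, and the planted truth, plus a JSON summary of parameters
#' and seeds. A fixed config yields byte-identical reports.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with all stage results.
#' @export
run_full_synthetic <- function(cfg = run_config(), out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(out_dir, name)

  # -- expression + DE ----
  sim <- simulate_expression(cfg$expression)
  write_count_table(sim$counts, fp("counts.tsv"), fp("samples.tsv"))
  write_gene_annotation(sim$genes, fp("genes.tsv"))
  .write_tsv(sim$truth, fp("expression_truth.tsv"))
  disp <- estimate_dispersions(sim$counts)
  contrasts <- canonical_contrasts()
  de <- lapply(contrasts, function(ct)
    test_de(sim$counts, sim$genes, ct, dispersions = disp))

  # -- asymmetry panel ----
  directions <- do.call(rbind, lapply(de, classify_direction,
                                      genes = sim$genes))
  tests <- do.call(rbind, unlist(lapply(de, function(d) {
    dir <- classify_direction(d, sim$genes)
    list(xa_asymmetry_test(dir, "all_expressed"),
         xa_asymmetry_test(dir, "de_only"))
  }), recursive = FALSE))
  tests <- adjust_asymmetry_panel(tests)
  .write_tsv(directions, fp("direction_summary.tsv"))
  .write_tsv(tests, fp("asymmetry_tests.tsv"))

  # -- DE-gene overlap between the two hybrid-vs-parent contrasts ----
  overlaps <- do.call(rbind, lapply(.CELL_TYPES, function(ct) {
    ov <- contrast_overlap(de[[paste0("musXdom_vs_mus_", ct)]],
                           de[[paste0("domXmus_vs_dom_", ct)]],
                           sim$genes, x_only = TRUE)
    data.frame(cell_type = ct, n_musXdom = ov$n_a, n_domXmus = ov$n_b,
               n_shared = ov$n_shared)
  }))
  .write_tsv(overlaps, fp("de_overlap.tsv"))

  # -- window scan on the hybrid-vs-hybrid round-spermatid contrast ----
  windows <- withCallingHandlers(
    scan_gene_windows(de[["musXdom_vs_domXmus_RS"]], sim$genes,
                      W = cfg$window_size, step = cfg$window_step),
    warning = function(w) invokeRestart("muffleWarning"))
  .write_tsv(windows, fp("window_scan.tsv"))

  # -- copy number ----
  cn_one <- function(acfg, fam) {
    g <- simulate_amplicon_genome(acfg)
    dp <- simulate_depth(g$truth)
    par <- find_paralogs(g$query, g$genome, family = fam)
    sites <- build_informative_sites(g$query, g$genome, family = fam)
    list(region = cn_from_region_coverage(par, dp),
         sites = cn_from_informative_sites(sites, dp, g$genome,
                                           seed = acfg$seed + 1),
         truth = g$truth)
  }
  sly <- cn_one(cfg$sly_amplicon, "slyLike")
  slx <- cn_one(cfg$slx_amplicon, "slxLike")
  cn_tab <- do.call(rbind, lapply(list(sly$region, sly$sites, slx$region,
                                       slx$sites), function(e)
    data.frame(family = e$family, method = e$method, estimate = e$estimate,
               n = e$n_regions_or_sites,
               background_depth = e$genome_mean_depth)))
  cn_tab$true_copies <- rep(c(cfg$sly_amplicon$true_copies,
                              cfg$slx_amplicon$true_copies), each = 2)
  .write_tsv(cn_tab, fp("copy_number.tsv"))
  ratio <- compute_family_ratio(sly$region, slx$region)

  # -- phenotypes ----
  ph <- simulate_phenotypes(cfg$n_per_cross, seed = cfg$seed + 300)
  .write_tsv(ph, fp("phenotypes.tsv"))
  ph_res <- summarize_and_test(ph, seed = cfg$seed + 301)
  .write_tsv(ph_res$summaries, fp("phenotype_summaries.tsv"))
  .write_tsv(ph_res$tests, fp("phenotype_tests.tsv"))

  summary <- list(
    seed = cfg$seed,
    n_genes = cfg$expression$n_genes,
    contrasts = names(contrasts),
    bcv = disp$bcv,
    family_ratio_region = ratio,
    family_ratio_sites = compute_family_ratio(sly$sites, slx$sites),
    n_flagged_windows = sum(windows$flagged_up | windows$flagged_down),
    n_phenotype_tests = nrow(ph_res$tests))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             fp("run_summary.json"))

  invisible(list(sim = sim, dispersions = disp, de = de,
                 directions = directions, asymmetry = tests,
                 overlaps = overlaps, windows = windows,
                 copy_number = cn_tab, family_ratio = ratio,
                 phenotypes = ph_res))
}
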