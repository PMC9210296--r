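# Shared fixture builders. Everything is generated in code; no binary or
# stored data.

# Minimal sample metadata for a two-group (cross x cell type) design.
two_group_meta <- function(cross_a = "musXdom", cross_b = "mus",
                           cell_type = "DIP", n = 3) {
  data.frame(
    sample_id = c(sprintf("%s_%d", cross_a, 1:n),
                  sprintf("%s_%d", cross_b, 1:n)),
    cross = rep(c(cross_a, cross_b), each = n),
    cell_type = cell_type,
    replicate = rep(1:n, 2),
    stringsAsFactors = FALSE)
}

# NB count matrix for a null two-group design with given per-gene means.
null_nb_matrix <- function(n_genes, phi = 0.03, mean_scale = 500,
                           meta = two_group_meta(), seed = 1) {
  set.seed(seed)
  mu <- mean_scale * rlnorm(n_genes, -0.5, 1)
  counts <- sapply(seq_len(nrow(meta)), function(j)
    rnbinom(n_genes, size = 1 / phi, mu = mu))
  rownames(counts) <- sprintf("g%05d", seq_len(n_genes))
  colnames(counts) <- meta$sample_id
  count_matrix(counts, meta)
}

# One-chromosome annotation covering the genes of a count matrix.
flat_annotation <- function(gene_ids, chromosome = "1",
                            exonic_length = 1500) {
  n <- length(gene_ids)
  gene_table(data.frame(
    chromosome = chromosome, start = seq(0, by = 1e4, length.out = n),
    end = seq(0, by = 1e4, length.out = n) + 5000,
    gene_id = gene_ids, exonic_length = exonic_length,
    stringsAsFactors = FALSE))
}

# A de_result-like table built directly from direction labels, for the
# window scan and asymmetry operations (logfc sign is all they use).
de_from_directions <- function(gene_ids, direction, expressed = TRUE,
                               is_de = FALSE) {
  res <- data.frame(gene_id = gene_ids,
                    logfc = direction,
                    p_raw = 0.5, p_adj = 0.5,
                    expressed_in_cell_type = expressed,
                    is_de = is_de, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

# Dispersion object with known fixed phi (oracle-style input to test_de).
fixed_dispersions <- function(gene_ids, phi) {
  structure(list(common = phi,
                 tagwise = stats::setNames(rep(phi, length(gene_ids)),
                                           gene_ids),
                 bcv = sqrt(phi)),
            class = "dispersion_estimates")
}

# NB log-likelihood for one gene / one group with offsets, used by the
# brute-force optimizer oracle.
nb_loglik_oracle <- function(y, sizes, phi, log_q) {
  mu <- exp(log_q) * sizes
  sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# Brute-force maximized NB log-likelihood via 1-D golden-section search
# (stats::optimize), independent of the package's IRLS fitting path.
nb_maxll_oracle <- function(y, sizes, phi) {
  f <- function(lq) -nb_loglik_oracle(y, sizes, phi, lq)
  q0 <- log((sum(y) + 0.5) / sum(sizes))
  stats::optimize(f, interval = c(q0 - 8, q0 + 8), tol = 1e-10)$objective * -1
}
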