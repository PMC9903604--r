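# Shared fixture builders: everything is generated in code at test time.

# expr_matrix with explicit per-group columns; `groups` is a data.frame with
# genotype, dap, replicate; `values` a matrix with one column per row of it.
make_expr <- function(values, genotype, dap, replicate, unit = "fpkm") {
  samples <- data.frame(
    sample_id = sprintf("%s_dap%d_r%d", genotype, dap, replicate),
    genotype = genotype, dap = dap, replicate = replicate,
    stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  expression_matrix(values, samples, unit = unit)
}

# small triad at a single DAP: 3 genotypes x n_reps replicates
make_triad_expr <- function(values, n_reps = 3, dap = 3, unit = "fpkm") {
  g <- rep(c("M", "H", "P"), each = n_reps)
  make_expr(values, g, rep(dap, length(g)), rep(seq_len(n_reps), 3),
            unit = unit)
}

small_sim_spec <- function(n_genes = 500, ...) {
  args <- list(n_genes = n_genes, daps = 3L, library_size = 2e6, seed = 42L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(triad_sim_spec, args)
}

# three deg_tables with prescribed calls for a hand-built classification
make_deg_trio <- function(calls_mp, calls_mh, calls_ph,
                          mu_M = NULL, mu_H = NULL, mu_P = NULL) {
  n <- length(calls_mp)
  ids <- sprintf("g%03d", seq_len(n))
  if (is.null(mu_M)) mu_M <- rep(10, n)
  if (is.null(mu_H)) mu_H <- rep(10, n)
  if (is.null(mu_P)) mu_P <- rep(10, n)
  mk <- function(calls, a, b, mean_a, mean_b) {
    structure(data.frame(gene_id = ids, mean_a = mean_a, mean_b = mean_b,
                         log2fc = 0, p_raw = 0.5, p_adj = 0.5, call = calls,
                         stringsAsFactors = FALSE),
              class = c("deg_table", "data.frame"),
              contrast = c(a = a, b = b), dap = 3L)
  }
  # orientation: M_vs_P (up = P > M), M_vs_H (up = H > M), P_vs_H (up = H > P)
  list(mp = mk(calls_mp, "M", "P", mu_M, mu_P),
       mh = mk(calls_mh, "M", "H", mu_M, mu_H),
       ph = mk(calls_ph, "P", "H", mu_P, mu_H))
}

# symbol triple -> deg-table call triple under the orientations above
# s_mp "M>P" means P vs M is DOWN in the M_vs_P table, etc.
sym_to_calls <- function(s_mp, s_mh, s_ph) {
  list(mp = c("M>P" = "down", "M<P" = "up", ns = "ns")[s_mp],
       mh = c("H>M" = "up", "H<M" = "down", ns = "ns")[s_mh],
       ph = c("H>P" = "up", "H<P" = "down", ns = "ns")[s_ph])
}

ref_path <- function(name) system.file("extdata", name,
                                       package = "triadexpress")
read_ref <- function(name) utils::read.table(ref_path(name), sep = "\t",
                                             header = TRUE,
                                             stringsAsFactors = FALSE)
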