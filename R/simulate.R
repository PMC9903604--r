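#' The 13 triad expression-pattern classes
#'
#' Canonical table of the thirteen hybrid-parent expression patterns, their
#' five-way category (additive, ELD_M, ELD_P, transgressive up/down), the
#' signed-call triple that defines each pattern, and the high-/mid-/
#' low-parent summary level. Signs are relative to
#' `s_mp` (+1 = M > P), `s_mh` (+1 = H > M) and `s_ph` (+1 = H > P);
#' 0 = not significant.
#'
#' Classes are ordered: transgressive up x3 (by parental direction),
#' transgressive down x3, ELD_M x2, ELD_P x2, additive-intermediate x2,
#' additive-conserved x1.
#'
#' @return data.frame with columns `class_id`, `class_label`, `category`,
#'   `s_mp`, `s_mh`, `s_ph`, `parent_level`.
#' @export
triad_class_table <- function() {
  data.frame(
    class_id = 1:13,
    class_label = c("trans_up_M_gt_P", "trans_up_M_eq_P", "trans_up_M_lt_P",
                    "trans_down_M_gt_P", "trans_down_M_eq_P", "trans_down_M_lt_P",
                    "ELD_M_high", "ELD_M_low", "ELD_P_high", "ELD_P_low",
                    "additive_M_gt_P", "additive_M_lt_P", "additive_conserved"),
    category = c(rep("transgressive_up", 3), rep("transgressive_down", 3),
                 "ELD_M", "ELD_M", "ELD_P", "ELD_P",
                 "additive", "additive", "additive"),
    s_mp = c(1L, 0L, -1L,  1L, 0L, -1L,  1L, -1L, -1L, 1L,  1L, -1L, 0L),
    s_mh = c(1L, 1L, 1L,  -1L, -1L, -1L,  0L, 0L, 1L, -1L,  -1L, 1L, 0L),
    s_ph = c(1L, 1L, 1L,  -1L, -1L, -1L,  1L, -1L, 0L, 0L,  1L, -1L, 0L),
    parent_level = c(rep("high_parent", 3), rep("low_parent", 3),
                     "high_parent", "low_parent", "high_parent", "low_parent",
                     rep("mid_parent", 3)),
    stringsAsFactors = FALSE
  )
}

#' Default class mixture for the simulator
#'
#' Class weights emulating the composition observed in a maize seed-coat
#' hybrid-parent triad at an early time point: ~85% additive (mostly
#' parentally conserved), ~13% expression-level dominance, <0.5%
#' transgressive.
#'
#' @return named numeric vector of weights over the 13 class labels
#'   (normalised to sum to 1).
#' @export
default_class_proportions <- function() {
  w <- c(trans_up_M_gt_P = 15, trans_up_M_eq_P = 3, trans_up_M_lt_P = 4,
         trans_down_M_gt_P = 70, trans_down_M_eq_P = 12, trans_down_M_lt_P = 0,
         ELD_M_high = 622, ELD_M_low = 790,
         ELD_P_high = 1385, ELD_P_low = 529,
         additive_M_gt_P = 1075, additive_M_lt_P = 1594,
         additive_conserved = 17045)
  w / sum(w)
}

#' Simulation specification for a hybrid-parent triad experiment
#'
#' Collects every knob of the synthetic triad generator. Defaults emulate
#' the bulk RNA-seq design of a maize seed-coat heterosis survey: three
#' genotypes (maternal M, hybrid H, paternal P) x six time points
#' (2-4 and 8-10 days after pollination) x three biological replicates,
#' ~23,000 expressed genes, negative-binomial counts over log-normal
#' baseline expression.
#'
#' @param n_genes number of genes.
#' @param daps integer vector of time points (each simulated independently).
#' @param n_reps biological replicates per genotype per time point.
#' @param class_proportions named nonnegative weights over the 13 class
#'   labels of [triad_class_table()]; renormalised internally.
#' @param baseline_log_mean,baseline_log_sd meanlog / sdlog of the
#'   log-normal baseline expression distribution (expression units).
#' @param effect_log2 log2 separation between "different" genotype means
#'   (>= 0).
#' @param dispersion NB dispersion: `Var = mu + dispersion * mu^2`
#'   (0 = Poisson).
#' @param library_size expected total counts per sample.
#' @param library_jitter half-width of a uniform per-sample library-size
#'   factor (e.g. 0.1 for +-10%); 0 = uniform libraries.
#' @param gene_length_range bp interval for simulated transcript lengths.
#' @param seed integer RNG seed.
#' @return an object of class `"triad_sim_spec"` (a validated list).
#' @export
triad_sim_spec <- function(n_genes = 23000, daps = c(2:4, 8:10), n_reps = 3,
                           class_proportions = default_class_proportions(),
                           baseline_log_mean = 3, baseline_log_sd = 1.5,
                           effect_log2 = 2, dispersion = 0.08,
                           library_size = 2e7, library_jitter = 0,
                           gene_length_range = c(500, 5000), seed = 1L) {
  if (!is_count(n_genes)) stopf("'n_genes' must be a nonnegative integer")
  if (!is_count(n_reps, min = 1)) stopf("'n_reps' must be >= 1")
  if (effect_log2 < 0) stopf("'effect_log2' must be >= 0")
  if (dispersion < 0) stopf("'dispersion' must be >= 0")
  if (library_size <= 0) stopf("'library_size' must be positive")
  if (library_jitter < 0 || library_jitter >= 1)
    stopf("'library_jitter' must be in [0, 1)")
  labels <- triad_class_table()$class_label
  miss <- setdiff(labels, names(class_proportions))
  if (length(miss))
    stopf("class_proportions misses label(s): %s", paste(miss, collapse = ", "))
  unknown <- setdiff(names(class_proportions), labels)
  if (length(unknown))
    stopf("unknown class label(s): %s", paste(unknown, collapse = ", "))
  w <- class_proportions[labels]
  if (any(w < 0) || sum(w) <= 0)
    stopf("class_proportions must be nonnegative with positive sum")
  if (length(gene_length_range) != 2L || any(gene_length_range <= 0) ||
      diff(gene_length_range) < 0)
    stopf("'gene_length_range' must be an increasing positive bp interval")
  structure(list(n_genes = as.integer(n_genes), daps = as.integer(daps),
                 n_reps = as.integer(n_reps),
                 class_proportions = w / sum(w),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 effect_log2 = effect_log2, dispersion = dispersion,
                 library_size = library_size, library_jitter = library_jitter,
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "triad_sim_spec")
}

#' Idealised genotype means for one expression-pattern class
#'
#' Realises the defining relations of a class around a baseline expression
#' level: "different" parents sit `effect_log2` log2 units apart,
#' symmetric about the baseline; additive hybrids sit exactly at the
#' arithmetic mid-parent `(M + P) / 2`; ELD hybrids equal the matched
#' parent; transgressive hybrids sit `effect_log2` log2 units above the
#' higher (below the lower) parent.
#'
#' @param baseline positive expression level(s); vectorised.
#' @param class_label one of the 13 labels of [triad_class_table()].
#' @param effect_log2 nonnegative log2 separation.
#' @return a list with numeric vectors `mu_M`, `mu_H`, `mu_P`.
#' @examples
#' assign_class_means(100, "additive_M_gt_P", 2) # M 200, P 50, H 125
#' @export
assign_class_means <- function(baseline, class_label, effect_log2) {
  if (any(baseline <= 0)) stopf("'baseline' must be positive")
  if (effect_log2 < 0) stopf("'effect_log2' must be >= 0")
  tab <- triad_class_table()
  i <- match(class_label, tab$class_label)
  if (is.na(i)) stopf("unknown class label '%s'", class_label)
  hi <- baseline * 2^(effect_log2 / 2)
  lo <- baseline * 2^(-effect_log2 / 2)
  mu_M <- switch(as.character(tab$s_mp[i]),
                 "1" = hi, "-1" = lo, "0" = baseline)
  mu_P <- switch(as.character(tab$s_mp[i]),
                 "1" = lo, "-1" = hi, "0" = baseline)
  mu_H <- switch(tab$category[i],
                 additive = (mu_M + mu_P) / 2,
                 ELD_M = mu_M,
                 ELD_P = mu_P,
                 transgressive_up = pmax(mu_M, mu_P) * 2^effect_log2,
                 transgressive_down = pmin(mu_M, mu_P) * 2^(-effect_log2))
  list(mu_M = mu_M, mu_H = mu_H, mu_P = mu_P)
}

#' Simulate a hybrid-parent triad count experiment with known truth
#'
#' For each gene: draw a class from the mixture, a baseline from the
#' log-normal, set the three genotype means via [assign_class_means()],
#' scale expected counts (proportional to mean x transcript length) so each
#' sample's expected total equals `library_size`, and draw NB counts for
#' every replicate at every time point. Time points are independent; a
#' gene's class and means are shared across time points. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [triad_sim_spec()].
#' @return an object of class `"triad_sim"`: list with `counts`
#'   (an `expr_matrix` of counts), `truth` (data.frame: gene_id,
#'   class_label, category, mu_M, mu_H, mu_P, gene_length_bp),
#'   `gene_lengths` (named vector) and `spec`.
#' @export
simulate_triad_counts <- function(spec) {
  stopifnot(inherits(spec, "triad_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  tab <- triad_class_table()
  samples <- expand.grid(replicate = seq_len(spec$n_reps),
                         genotype = c("M", "H", "P"), dap = spec$daps,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "dap", "replicate")]
  samples$sample_id <- sprintf("%s_dap%d_r%d", samples$genotype,
                               samples$dap, samples$replicate)
  ns <- nrow(samples)
  if (n == 0L) {
    counts <- matrix(numeric(0), nrow = 0, ncol = ns,
                     dimnames = list(NULL, samples$sample_id))
    truth <- data.frame(gene_id = character(0), class_label = character(0),
                        category = character(0), mu_M = numeric(0),
                        mu_H = numeric(0), mu_P = numeric(0),
                        gene_length_bp = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(counts = expression_matrix(counts, samples, "counts"),
                          truth = truth, gene_lengths = numeric(0),
                          spec = spec), class = "triad_sim"))
  }
  gene_id <- sprintf("g%05d", seq_len(n))
  labels <- if (spec$effect_log2 == 0) {
    rep("additive_conserved", n)
  } else {
    sample(tab$class_label, n, replace = TRUE, prob = spec$class_proportions)
  }
  baseline <- stats::rlnorm(n, spec$baseline_log_mean, spec$baseline_log_sd)
  len <- floor(stats::runif(n, spec$gene_length_range[1L],
                            spec$gene_length_range[2L] + 1))
  mu <- matrix(0, n, 3, dimnames = list(gene_id, c("M", "H", "P")))
  for (lb in unique(labels)) {
    i <- which(labels == lb)
    m <- assign_class_means(baseline[i], lb, spec$effect_log2)
    mu[i, "M"] <- m$mu_M; mu[i, "H"] <- m$mu_H; mu[i, "P"] <- m$mu_P
  }
  jitter <- if (spec$library_jitter > 0)
    stats::runif(ns, 1 - spec$library_jitter, 1 + spec$library_jitter)
  else rep(1, ns)
  counts <- matrix(0, n, ns, dimnames = list(gene_id, samples$sample_id))
  expected <- sweep(mu, 1L, len, "*")                  # counts ~ mu * length
  scale_g <- spec$library_size / colSums(expected)     # per-genotype scale
  for (s in seq_len(ns)) {
    g <- samples$genotype[s]
    mu_s <- expected[, g] * scale_g[[g]] * jitter[s]
    counts[, s] <- if (spec$dispersion == 0) stats::rpois(n, mu_s)
                   else stats::rnbinom(n, mu = mu_s, size = 1 / spec$dispersion)
  }
  truth <- data.frame(gene_id = gene_id, class_label = labels,
                      category = tab$category[match(labels, tab$class_label)],
                      mu_M = mu[, "M"], mu_H = mu[, "H"], mu_P = mu[, "P"],
                      gene_length_bp = len, stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(counts = expression_matrix(counts, samples, "counts"),
                 truth = truth,
                 gene_lengths = stats::setNames(len, gene_id),
                 spec = spec),
            class = "triad_sim")
}

#' @export
print.triad_sim <- function(x, ...) {
  cat(sprintf("triad_sim: %d genes x %d samples (seed %d)\n",
              nrow(x$counts$values), ncol(x$counts$values), x$spec$seed))
  if (nrow(x$truth)) print(round_half_up(100 * prop.table(
    table(category = x$truth$category)), 2))
  invisible(x)
}

#' Write a simulated triad experiment as plain-text TSVs
#'
#' Writes `counts.tsv`, `samples.tsv`, `truth.tsv` and `gene_lengths.tsv`
#' into `dir`, in the formats read back by [read_expression_matrix()] and
#' [utils::read.table()].
#'
#' @param sim a `"triad_sim"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_triad_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "triad_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$counts, file.path(dir, "counts.tsv"),
                          file.path(dir, "samples.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(sim$gene_lengths),
                                length_bp = unname(sim$gene_lengths)),
                     file.path(dir, "gene_lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate phenotype trajectories for the triad
#'
#' Per-genotype logistic growth curves `K / (1 + exp(-r (t - t0)))` with
#' additive Gaussian noise truncated at zero, emulating seed-coat area
#' expansion over early seed development. Default parameters give the
#' hybrid a late-DAP asymptote above the mid-parent value.
#'
#' @param params named list (`M`, `H`, `P`) of lists with `K` (asymptote,
#'   trait units), `r` (rate, 1/day) and `t0` (inflection, DAP).
#' @param daps integer time grid (default 0:15).
#' @param n_reps replicate measurements per genotype per DAP.
#' @param noise_sd Gaussian measurement/biological noise sd (>= 0).
#' @param trait trait name recorded on the output.
#' @param seed integer RNG seed.
#' @return data.frame (`genotype`, `dap`, `replicate`, `value`) with a
#'   `trait` attribute.
#' @export
simulate_phenotype_series <- function(params = list(
                                        M = list(K = 90, r = 0.55, t0 = 6),
                                        H = list(K = 92, r = 0.60, t0 = 6),
                                        P = list(K = 70, r = 0.55, t0 = 7)),
                                      daps = 0:15, n_reps = 6, noise_sd = 3,
                                      trait = "seed_coat_area_mm2",
                                      seed = 1L) {
  if (is.unsorted(daps, strictly = TRUE)) stopf("'daps' must be increasing")
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  miss <- setdiff(c("M", "H", "P"), names(params))
  if (length(miss)) stopf("params misses genotype(s): %s",
                          paste(miss, collapse = ", "))
  set.seed(seed)
  out <- do.call(rbind, lapply(c("M", "H", "P"), function(g) {
    p <- params[[g]]
    curve <- p$K / (1 + exp(-p$r * (daps - p$t0)))
    do.call(rbind, lapply(seq_along(daps), function(i) {
      v <- pmax(0, curve[i] + stats::rnorm(n_reps, 0, noise_sd))
      data.frame(genotype = g, dap = daps[i], replicate = seq_len(n_reps),
                 value = v, stringsAsFactors = FALSE)
    }))
  }))
  attr(out, "trait") <- trait
  out
}
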