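#' Mid-parent value
#'
#' The additive expectation for a hybrid trait or expression level: the
#' arithmetic mean of the two parental values. Vectorised.
#'
#' @param m_value,p_value maternal and paternal values.
#' @return `(m_value + p_value) / 2`.
#' @examples
#' mid_parent_value(138, 319) # 228.5 cells per 0.1 mm^2
#' @export
mid_parent_value <- function(m_value, p_value) (m_value + p_value) / 2

#' Relative growth rate of a phenotype series
#'
#' Day-over-day proportional increase of the per-DAP trait mean:
#' `RGR(t) = (x_t - x_(t-1)) / x_(t-1)` (method `"ratio"`, the default), or
#' the classical log-difference `log(x_t / x_(t-1))` (method `"log"`).
#' Undefined where the previous mean is zero (returned as `NA`).
#'
#' @param series data.frame with columns `genotype`, `dap`, `value`
#'   (replicate rows), e.g. from [simulate_phenotype_series()].
#' @param genotype optional single genotype to restrict to.
#' @param method `"ratio"` or `"log"`.
#' @return data.frame (`genotype`, `dap`, `rgr`), one row per step, `dap`
#'   labelling the later day of each step.
#' @export
relative_growth_rate <- function(series, genotype = NULL,
                                 method = c("ratio", "log")) {
  method <- match.arg(method)
  if (!is.null(genotype)) series <- series[series$genotype %in% genotype, ]
  out <- do.call(rbind, lapply(split(series, series$genotype), function(s) {
    mu <- tapply(s$value, s$dap, mean)
    dap <- as.integer(names(mu))
    o <- order(dap)
    mu <- as.numeric(mu[o]); dap <- dap[o]
    if (length(mu) < 2L) stopf("need >= 2 time points per genotype")
    prev <- mu[-length(mu)]
    cur <- mu[-1L]
    rgr <- switch(method,
                  ratio = ifelse(prev == 0, NA_real_, (cur - prev) / prev),
                  log = ifelse(prev == 0 | cur == 0, NA_real_,
                               log(cur / prev)))
    data.frame(genotype = s$genotype[1L], dap = dap[-1L], rgr = rgr,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Test a hybrid sample against the mid-parent value
#'
#' Forms a pseudo-MPV sample `{(m_i + p_j) / 2}` from parent replicate
#' pairs (all pairs, or a seeded random subset when the grid exceeds
#' `max_pairs`) and applies a two-sided Welch t-test of the hybrid values
#' against it. The pair means are sorted before any subsampling so the
#' result is invariant to swapping the two parents.
#'
#' @param h_values hybrid replicate values (>= 2).
#' @param m_values,p_values parental replicate values (>= 2 each).
#' @param max_pairs cap on the pseudo-MPV sample size (default 200).
#' @param seed seed for the pair subsample.
#' @return two-sided p-value (degenerate-variance rule as in
#'   [gene_test()]).
#' @export
mpv_significance <- function(h_values, m_values, p_values, max_pairs = 200,
                             seed = 1L) {
  if (length(h_values) < 2L || length(m_values) < 2L || length(p_values) < 2L)
    stopf("need >= 2 replicate values per genotype")
  pairs <- sort(as.numeric(outer(m_values, p_values, "+") / 2))
  if (length(pairs) > max_pairs) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    pairs <- pairs[sample.int(length(pairs), max_pairs)]
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  .t_p(mean(h_values), mean(pairs),
       stats::var(h_values), stats::var(pairs),
       length(h_values), length(pairs), var_equal = FALSE)
}

#' Seed-coat cell density per 0.1 mm^2
#'
#' @param cell_count number of cells counted.
#' @param area_mm2 area of the counting window in mm^2 (> 0).
#' @return cells per 0.1 mm^2: `cell_count / (area_mm2 / 0.1)`.
#' @examples
#' cell_density(319, 0.1) # 319
#' @export
cell_density <- function(cell_count, area_mm2) {
  if (any(area_mm2 <= 0)) stopf("'area_mm2' must be positive")
  cell_count / (area_mm2 / 0.1)
}

#' Relative expression by the Livak 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; per (gene, genotype,
#' DAP) group, `ddCt = mean dCt(group) - mean dCt(calibrator group)`;
#' relative expression `2^-ddCt`. Averaging is on dCt before differencing
#' (the standard Livak ordering), so the calibrator group itself reports
#' exactly 1.
#'
#' @param ct data.frame with columns `gene_id`, `genotype`, `dap`,
#'   `replicate`, `ct_target`, `ct_reference` (positive finite cycles).
#' @param calibrator list or named vector with `genotype` and (if several
#'   time points are present) `dap`, naming the calibrator group.
#' @return data.frame (`gene_id`, `genotype`, `dap`, `n`, `mean_dct`,
#'   `ddct`, `rel_expr`).
#' @export
ddct_relative_expression <- function(ct, calibrator) {
  req <- c("gene_id", "genotype", "dap", "replicate", "ct_target",
           "ct_reference")
  miss <- setdiff(req, names(ct))
  if (length(miss)) stopf("Ct table misses column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)) ||
      any(ct$ct_target <= 0) || any(ct$ct_reference <= 0))
    stopf("Ct values must be positive and finite")
  cal_g <- calibrator[["genotype"]]
  cal_d <- calibrator[["dap"]]
  if (is.null(cal_d)) {
    if (length(unique(ct$dap)) > 1L)
      stopf("several time points present; calibrator needs a 'dap'")
    cal_d <- unique(ct$dap)
  }
  ct$dct <- ct$ct_target - ct$ct_reference
  agg <- stats::aggregate(dct ~ gene_id + genotype + dap, data = ct,
                          FUN = mean)
  nrep <- stats::aggregate(dct ~ gene_id + genotype + dap, data = ct,
                           FUN = length)
  agg$n <- nrep$dct
  out <- do.call(rbind, lapply(split(agg, agg$gene_id), function(g) {
    cal <- g$dct[g$genotype == cal_g & g$dap == cal_d]
    if (length(cal) != 1L)
      stopf("calibrator group missing for gene '%s'", g$gene_id[1L])
    data.frame(gene_id = g$gene_id, genotype = g$genotype, dap = g$dap,
               n = g$n, mean_dct = g$dct, ddct = g$dct - cal,
               rel_expr = 2^-(g$dct - cal), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
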