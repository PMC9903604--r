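# Vectorised two-sided two-sample t-test p-values from group summaries.
# var_equal = TRUE pools the variance (Student t, df = na + nb - 2);
# var_equal = FALSE uses the Welch-Satterthwaite approximation. At the
# n = 3 replication typical of triad RNA-seq designs the Welch df
# approximation is markedly conservative (type I ~ 0.035 at nominal 0.05
# even under normality), so pooling is the default throughout the package.
# Degenerate-variance rule: when both groups have zero variance the test is
# undecidable by t statistics; equal means give p = 1, unequal means p = 0.
.t_p <- function(ma, mb, va, vb, na, nb, var_equal = TRUE) {
  p <- rep(NA_real_, length(ma))
  deg <- va + vb == 0
  p[deg] <- ifelse(ma[deg] == mb[deg], 1, 0)
  ok <- !deg
  if (any(ok)) {
    if (var_equal) {
      pool <- ((na - 1) * va[ok] + (nb - 1) * vb[ok]) / (na + nb - 2)
      se2 <- pool * (1 / na + 1 / nb)
      df <- na + nb - 2
    } else {
      se2 <- va[ok] / na + vb[ok] / nb
      df <- se2^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
    }
    tt <- (mb[ok] - ma[ok]) / sqrt(se2)
    p[ok] <- 2 * stats::pt(-abs(tt), df)
  }
  p
}

# row means and variances of a matrix
.row_mv <- function(m) {
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (ncol(m) - 1)
  list(mean = mu, var = v)
}

#' Per-gene two-group expression test
#'
#' Two-sided two-sample t-test on `log2(x + 1)`-transformed replicate
#' values -- the replicate-level, distribution-light test behind every
#' pairwise contrast in this package. By default the variance is pooled
#' (Student t): at the 3-replicate design typical of triad experiments the
#' Welch-Satterthwaite degrees of freedom are badly conservative (type I
#' error ~0.035 at nominal 0.05 even for normal data), while the pooled
#' test is calibrated; `var_equal = FALSE` gives the Welch form. When both
#' groups are constant the test is degenerate: equal constants give
#' `p = 1`, unequal constants `p = 0`.
#'
#' @param values_a,values_b numeric replicate vectors (>= 2 values each).
#' @param log2_transform test on `log2(x + 1)` (default) or raw values.
#' @param var_equal pool the two group variances (default `TRUE`).
#' @return two-sided p-value.
#' @export
gene_test <- function(values_a, values_b, log2_transform = TRUE,
                      var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("need at least two values per group")
  if (log2_transform) {
    values_a <- log2(values_a + 1)
    values_b <- log2(values_b + 1)
  }
  .t_p(mean(values_a), mean(values_b),
       stats::var(values_a), stats::var(values_b),
       length(values_a), length(values_b), var_equal = var_equal)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up BH adjustment with cumulative-minimum enforcement;
#' output order matches input order.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stopf("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Apply the fold-change / FDR call rule to a DEG table
#'
#' `up` when `log2fc >= log2(fc_threshold)` and `p_adj < alpha` (direction
#' is b relative to a); `down` when `log2fc <= -log2(fc_threshold)` and
#' `p_adj < alpha`; otherwise `ns`. The fold-change bound is inclusive, the
#' significance bound strict.
#'
#' @param deg a `deg_table` (or any data.frame with `log2fc` and `p_adj`).
#' @param fc_threshold fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return `deg` with its `call` column (re)populated.
#' @export
call_degs <- function(deg, fc_threshold = 2, alpha = 0.05) {
  lfc <- log2(fc_threshold)
  deg$call <- ifelse(deg$p_adj < alpha & deg$log2fc >= lfc, "up",
                     ifelse(deg$p_adj < alpha & deg$log2fc <= -lfc,
                            "down", "ns"))
  deg
}

#' Pairwise differential expression between two genotypes at one time point
#'
#' For every gene: replicate means in each group, fold change on the means
#' with a pseudo-count (`log2fc = log2((mean_b + pseudo) / (mean_a +
#' pseudo))`), a two-sample t p-value on `log2(x + 1)` replicate values
#' (pooled variance by default, see [gene_test()]), BH adjustment across
#' genes, and the fold-change/FDR call.
#'
#' @param x an `expr_matrix` (typically FPKM).
#' @param a,b genotypes to contrast (direction of calls is `b` relative to
#'   `a`).
#' @param dap time point at which to contrast.
#' @param fc_threshold,alpha call thresholds, see [call_degs()].
#' @param pseudo pseudo-count added to both means in the fold change.
#' @param genes optional gene universe (character vector) to restrict to.
#' @param var_equal pool the group variances in the t-test (default `TRUE`).
#' @return a data.frame of class `"deg_table"` with columns `gene_id`,
#'   `mean_a`, `mean_b`, `log2fc`, `p_raw`, `p_adj`, `call`, and attributes
#'   `contrast` (named c(a =, b =)), `dap`, `fc_threshold`, `alpha`.
#' @export
deg_test <- function(x, a, b, dap, fc_threshold = 2, alpha = 0.05,
                     pseudo = 1, genes = NULL, var_equal = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (a == b) stopf("'a' and 'b' must differ")
  ja <- which(x$samples$genotype == a & x$samples$dap == dap)
  jb <- which(x$samples$genotype == b & x$samples$dap == dap)
  if (length(ja) < 2L || length(jb) < 2L)
    stopf("need >= 2 replicates per genotype at DAP %s", dap)
  va <- x$values[, ja, drop = FALSE]
  vb <- x$values[, jb, drop = FALSE]
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(x$values))
    if (length(miss)) stopf("%d requested gene(s) absent from the matrix",
                            length(miss))
    va <- va[genes, , drop = FALSE]
    vb <- vb[genes, , drop = FALSE]
  }
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  la <- .row_mv(log2(va + 1))
  lb <- .row_mv(log2(vb + 1))
  p_raw <- .t_p(la$mean, lb$mean, la$var, lb$var, ncol(va), ncol(vb),
                var_equal = var_equal)
  deg <- data.frame(gene_id = rownames(va), mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2((mean_b + pseudo) / (mean_a + pseudo)),
                    p_raw = p_raw, p_adj = bh_fdr(p_raw),
                    stringsAsFactors = FALSE, row.names = NULL)
  deg <- call_degs(deg, fc_threshold = fc_threshold, alpha = alpha)
  structure(deg, class = c("deg_table", "data.frame"),
            contrast = c(a = a, b = b), dap = dap,
            fc_threshold = fc_threshold, alpha = alpha)
}

#' Up/down summary of a DEG table
#'
#' @param deg a `deg_table` with calls populated.
#' @return list with `n_up`, `n_down`, `n_total_deg` and 2-decimal
#'   percentages `pct_up`, `pct_down` of the DEG total (`NA` when there are
#'   no DEGs).
#' @export
updown_summary <- function(deg) {
  n_up <- sum(deg$call == "up")
  n_down <- sum(deg$call == "down")
  total <- n_up + n_down
  list(n_up = n_up, n_down = n_down, n_total_deg = total,
       pct_up = pct(n_up, total), pct_down = pct(n_down, total))
}

#' Write / read a DEG table as TSV
#'
#' The contrast and time point are carried in a `# contrast:` comment line
#' above the header so stages remain independently runnable.
#'
#' @param deg a `deg_table`.
#' @param path TSV path.
#' @return `deg` (write) or the re-read `deg_table` (read).
#' @export
write_deg_table <- function(deg, path) {
  ct <- attr(deg, "contrast")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contrast: %s_vs_%s, dap=%s", ct[["a"]], ct[["b"]],
                     attr(deg, "dap")), con)
  utils::write.table(deg, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(deg)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("# contrast: (\\w+)_vs_(\\w+), dap=(\\d+)", header))[[1]]
  if (length(m) != 4L) stopf("'%s' lacks a '# contrast:' header line", path)
  deg <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           stringsAsFactors = FALSE)
  structure(deg, class = c("deg_table", "data.frame"),
            contrast = c(a = m[2L], b = m[3L]), dap = as.integer(m[4L]))
}
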