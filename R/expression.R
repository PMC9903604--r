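#' Gene x sample expression container
#'
#' A light container pairing a nonnegative numeric gene x sample matrix
#' (counts or FPKM) with its sample sheet. All downstream operations
#' (normalisation, differential testing, classification) consume this class.
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids). All values must be finite
#'   and `>= 0`.
#' @param samples data.frame with columns `sample_id`, `genotype` (one of
#'   `"M"`, `"H"`, `"P"`), `dap` (integer days after pollination) and
#'   `replicate` (integer), one row per column of `values`.
#' @param unit `"counts"` or `"fpkm"`; recorded, not checked.
#' @return an object of class `"expr_matrix"`: a list with elements
#'   `values`, `samples`, `unit`.
#' @export
expression_matrix <- function(values, samples, unit = c("counts", "fpkm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- sprintf("g%05d", seq_len(nrow(values)))
  gid <- rownames(values)
  dup <- gid[duplicated(gid)]
  if (length(dup))
    stopf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stopf("expression values must be finite and non-missing")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stopf("negative value at gene '%s', sample '%s'",
          rownames(values)[bad[1L]], colnames(values)[bad[2L]])
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "dap", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stopf("sample sheet misses column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample id(s) in sample sheet")
  if (is.null(colnames(values)) && nrow(samples) == ncol(values))
    colnames(values) <- samples$sample_id
  if (!setequal(colnames(values), samples$sample_id) ||
      ncol(values) != nrow(samples))
    stopf("sample sheet does not cover the matrix columns exactly")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$genotype %in% c("M", "H", "P")))
    stopf("genotype must be one of 'M', 'H', 'P'")
  if (anyNA(samples$dap) || any(samples$dap != floor(samples$dap)))
    stopf("'dap' must be integer")
  samples$dap <- as.integer(samples$dap)
  samples$replicate <- as.integer(samples$replicate)
  structure(list(values = values, samples = samples, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat(sprintf("genotypes: %s | DAP: %s | replicates per group: %s\n",
              paste(sort(unique(x$samples$genotype)), collapse = "/"),
              paste(sort(unique(x$samples$dap)), collapse = ","),
              paste(range(table(interaction(x$samples$genotype,
                                            x$samples$dap, drop = TRUE))),
                    collapse = "-")))
  invisible(x)
}

# internal: separator from file extension
.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix and its sample sheet
#'
#' @param path TSV/CSV with a header line; first column gene ids, remaining
#'   columns one per sample.
#' @param sample_sheet_path TSV/CSV with columns `sample_id`, `genotype`,
#'   `dap`, `replicate` covering every matrix column.
#' @param unit unit of the stored values (`"counts"` or `"fpkm"`).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sample_sheet_path,
                                   unit = c("counts", "fpkm")) {
  tab <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  gid <- as.character(tab[[1L]])
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stopf("duplicate gene id(s) in '%s': %s", path, paste(dup, collapse = ", "))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gid
  sheet <- utils::read.table(sample_sheet_path, sep = .sep_for(sample_sheet_path),
                             header = TRUE, stringsAsFactors = FALSE)
  missing_samples <- setdiff(colnames(values), sheet$sample_id)
  if (length(missing_samples))
    stopf("sample(s) missing from sheet: %s",
          paste(missing_samples, collapse = ", "))
  sheet <- sheet[sheet$sample_id %in% colnames(values), , drop = FALSE]
  expression_matrix(values, sheet, unit = match.arg(unit))
}

#' Write an expression matrix (and optionally its sample sheet) as TSV
#'
#' @param x an `expr_matrix`.
#' @param path output TSV path for the matrix (gene_id + one column per sample).
#' @param sample_sheet_path optional output TSV path for the sample sheet.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sample_sheet_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path))
    utils::write.table(x$samples, sample_sheet_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' FPKM normalisation
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length_bp[g] * total_counts[s])`.
#'
#' @param x an `expr_matrix` of counts.
#' @param gene_lengths named numeric vector (or two-column data.frame
#'   `gene_id`, `length_bp`) of transcript lengths in bp; must cover every
#'   gene and be positive.
#' @return an `expr_matrix` with `unit = "fpkm"`.
#' @export
fpkm <- function(x, gene_lengths) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.data.frame(gene_lengths))
    gene_lengths <- stats::setNames(gene_lengths[[2L]],
                                    as.character(gene_lengths[[1L]]))
  miss <- setdiff(rownames(x$values), names(gene_lengths))
  if (length(miss))
    stopf("missing gene length for: %s",
          paste(utils::head(miss, 5L), collapse = ", "))
  len <- gene_lengths[rownames(x$values)]
  if (any(len <= 0)) stopf("gene lengths must be positive")
  totals <- colSums(x$values)
  if (any(totals <= 0))
    stopf("zero total counts in sample(s): %s",
          paste(colnames(x$values)[totals <= 0], collapse = ", "))
  vals <- sweep(x$values * 1e9 / len, 2L, totals, "/")
  expression_matrix(vals, x$samples, unit = "fpkm")
}

# internal: list of column indices per (genotype, dap) group
.group_cols <- function(x) {
  key <- paste(x$samples$genotype, x$samples$dap, sep = "_dap")
  split(seq_len(ncol(x$values)), key)
}

#' Average replicates within each (genotype, DAP) group
#'
#' Arithmetic per-gene mean over the biological replicates of each group,
#' the expression level taken forward for expressed-gene calling and fold
#' changes.
#'
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` with one column per (genotype, DAP) group and
#'   `replicate = NA` in the collapsed sample sheet.
#' @export
mean_replicates <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  grp <- .group_cols(x)
  vals <- vapply(grp, function(j) rowMeans(x$values[, j, drop = FALSE]),
                 numeric(nrow(x$values)))
  if (nrow(x$values) == 1L) vals <- matrix(vals, nrow = 1L,
                                           dimnames = list(rownames(x$values),
                                                           names(grp)))
  meta <- do.call(rbind, lapply(names(grp), function(k) {
    s <- x$samples[grp[[k]][1L], ]
    data.frame(sample_id = k, genotype = s$genotype, dap = s$dap,
               replicate = NA_integer_, stringsAsFactors = FALSE)
  }))
  expression_matrix(vals[, meta$sample_id, drop = FALSE], meta, unit = x$unit)
}

#' Between-replicate squared correlation
#'
#' For every (genotype, DAP) group, the mean squared Pearson correlation
#' over all replicate pairs, plus the grand mean over groups -- the quality
#' statistic summarised as "average R^2" in triad RNA-seq surveys.
#' By default correlations are computed on `log2(x + 1)` values, the
#' community norm (raw-scale correlation is dominated by a handful of high
#' expressors); set `log2_transform = FALSE` for raw values.
#'
#' A replicate pair in which either column is constant has an undefined
#' correlation; such pairs are excluded with a warning.
#'
#' @param x an `expr_matrix` with at least two genes and two replicates per
#'   group.
#' @param log2_transform compute on `log2(x + 1)` (default) or raw values.
#' @return list with `per_group` (data.frame: genotype, dap, n_pairs,
#'   mean_r2) and `grand_mean`.
#' @export
replicate_r2 <- function(x, log2_transform = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (nrow(x$values) < 2L) stopf("need at least two genes")
  v <- if (log2_transform) log2(x$values + 1) else x$values
  grp <- .group_cols(x)
  dropped <- 0L
  rows <- lapply(names(grp), function(k) {
    j <- grp[[k]]
    if (length(j) < 2L) stopf("group '%s' has fewer than 2 replicates", k)
    pairs <- utils::combn(j, 2L)
    r2 <- apply(pairs, 2L, function(p) {
      a <- v[, p[1L]]; b <- v[, p[2L]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)^2
    })
    dropped <<- dropped + sum(is.na(r2))
    s <- x$samples[j[1L], ]
    data.frame(genotype = s$genotype, dap = s$dap,
               n_pairs = sum(!is.na(r2)), mean_r2 = mean(r2, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  if (dropped > 0L)
    warning(sprintf("%d replicate pair(s) with zero variance excluded from R^2",
                    dropped), call. = FALSE)
  per_group <- do.call(rbind, rows)
  list(per_group = per_group, grand_mean = mean(per_group$mean_r2, na.rm = TRUE))
}

#' Expressed-gene calling
#'
#' A gene is called expressed in a (genotype, DAP) group when its
#' replicate-mean expression is at or above `threshold` (default 1 FPKM).
#'
#' @param x an `expr_matrix` (typically FPKM).
#' @param genotype `"M"`, `"H"` or `"P"`.
#' @param dap integer time point; `NULL` returns the union over all DAPs of
#'   the genotype (its "total expressed" set).
#' @param threshold expression cut-off on the replicate mean.
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(x, genotype, dap = NULL, threshold = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  daps <- if (is.null(dap)) sort(unique(x$samples$dap[x$samples$genotype == genotype])) else dap
  if (!length(daps)) stopf("no samples for genotype '%s'", genotype)
  out <- character(0)
  for (d in daps) {
    j <- which(x$samples$genotype == genotype & x$samples$dap == d)
    if (!length(j)) stopf("no samples for genotype '%s' at DAP %s", genotype, d)
    m <- rowMeans(x$values[, j, drop = FALSE])
    out <- union(out, rownames(x$values)[m >= threshold])
  }
  out
}

#' Exact multi-set overlap (Venn) accounting
#'
#' Decomposes two or more labelled gene sets into their exact Venn regions
#' and reports the core intersection and its share of each set and of the
#' union.
#'
#' @param sets named list (>= 2 elements) of character vectors.
#' @return an object of class `"gene_set_overlap"`: list with `labels`,
#'   `set_sizes`, `region_counts` (named by membership pattern, e.g.
#'   `"A&C"`), `core_count`, `union_size`, `per_set_core_pct`
#'   (100 * core / |set|), and `core_pct_of_union` (100 * core / |union|),
#'   percentages rounded to two decimals.
#' @export
overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) stopf("need at least two sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  universe <- unique(unlist(sets, use.names = FALSE))
  mem <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) mem <- matrix(mem, nrow = 1L,
                                            dimnames = list(NULL, names(sets)))
  key <- apply(mem, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  region_counts <- table(key)
  core_key <- paste(names(sets), collapse = "&")
  core <- if (core_key %in% names(region_counts))
    as.integer(region_counts[[core_key]]) else 0L
  set_sizes <- vapply(sets, function(s) length(unique(s)), integer(1))
  structure(list(
    labels = names(sets),
    set_sizes = set_sizes,
    region_counts = stats::setNames(as.integer(region_counts),
                                    names(region_counts)),
    core_count = core,
    union_size = length(universe),
    per_set_core_pct = pct(core, set_sizes),
    core_pct_of_union = pct(core, length(universe))
  ), class = "gene_set_overlap")
}

#' @export
print.gene_set_overlap <- function(x, ...) {
  cat(sprintf("overlap of %d sets (union %d genes)\n",
              length(x$labels), x$union_size))
  cat(sprintf("core intersection: %d (%.2f%% of union)\n",
              x$core_count, x$core_pct_of_union))
  df <- data.frame(set = x$labels, size = x$set_sizes,
                   core_pct = x$per_set_core_pct)
  print(df, row.names = FALSE)
  invisible(x)
}
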