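#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()].
#' Either a simulation block is enabled (the default) or paths to a count
#' matrix, sample sheet and gene-length table are supplied.
#'
#' @param simulate logical; generate the input triad with
#'   [simulate_triad_counts()].
#' @param sim_spec a [triad_sim_spec()] (used when `simulate = TRUE`).
#' @param matrix_path,sample_sheet_path,gene_lengths_path input TSVs (used
#'   when `simulate = FALSE`).
#' @param phenotype_path optional phenotype TSV (`genotype`, `dap`,
#'   `replicate`, `value`); when `NULL` and `simulate = TRUE` a synthetic
#'   series is generated.
#' @param expressed_threshold FPKM cut-off for expressed-gene calling.
#' @param fc_threshold,alpha DEG call thresholds.
#' @param focal_daps time points at which the triad is classified.
#' @param seed seed for the phenotype simulation and any subsampling.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = TRUE, sim_spec = triad_sim_spec(),
                            matrix_path = NULL, sample_sheet_path = NULL,
                            gene_lengths_path = NULL, phenotype_path = NULL,
                            expressed_threshold = 1, fc_threshold = 2,
                            alpha = 0.05, focal_daps = c(3L, 8L),
                            seed = 1L) {
  if (expressed_threshold < 0) stopf("'expressed_threshold' must be >= 0")
  if (fc_threshold <= 0) stopf("'fc_threshold' must be positive")
  if (alpha <= 0 || alpha >= 1) stopf("'alpha' must be in (0, 1)")
  if (!simulate &&
      (is.null(matrix_path) || is.null(sample_sheet_path) ||
       is.null(gene_lengths_path)))
    stopf("simulation disabled but matrix/sample sheet/gene lengths not all given")
  structure(list(simulate = simulate, sim_spec = sim_spec,
                 matrix_path = matrix_path,
                 sample_sheet_path = sample_sheet_path,
                 gene_lengths_path = gene_lengths_path,
                 phenotype_path = phenotype_path,
                 expressed_threshold = expressed_threshold,
                 fc_threshold = fc_threshold, alpha = alpha,
                 focal_daps = as.integer(focal_daps),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; keys under
#' `sim_spec:` mirror [triad_sim_spec()].
#'
#' @param path YAML path.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 only scientific-notates "1.0e+6"; rescue "1.0e6"-style scalars
  fix_num <- function(x) {
    if (is.list(x)) return(lapply(x, fix_num))
    if (is.character(x) && length(x) &&
        all(grepl("^-?[0-9.]+e-?\\+?[0-9]+$", x))) return(as.numeric(x))
    x
  }
  y <- fix_num(y)
  spec_args <- y$sim_spec
  y$sim_spec <- NULL
  sim_spec <- if (is.null(spec_args)) triad_sim_spec()
              else do.call(triad_sim_spec, spec_args)
  do.call(pipeline_config, c(y, list(sim_spec = sim_spec)))
}

# internal: abort with the failing stage's name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the end-to-end triad expression pipeline
#'
#' Orchestrates the full analysis: obtain counts (simulated or read from
#' disk), FPKM-normalise, score replicate agreement, call expressed genes
#' and their multi-time-point overlap per genotype, run the three pairwise
#' contrasts and the 13-class classification at each focal time point,
#' summarise (category layout, parent-level layout, up/down table), and
#' compute phenotype heterosis statistics (MPV series, relative growth
#' rates, hybrid-vs-MPV test at the last DAP). Deterministic given the
#' configuration (including its seeds).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every table is written as
#'   TSV along with a `run_log.txt` recording seed, thresholds and package
#'   version.
#' @return an object of class `"triad_report"`: list with `sim` (or
#'   `NULL`), `fpkm`, `replicate_r2`, `expressed` (per-genotype per-DAP
#'   sets), `overlap` (per genotype), `deg` (nested list
#'   `[[dap]][[contrast]]`), `updown`, `patterns` (per focal DAP),
#'   `table1`, `parent_level`, `phenotype` (list: series, mpv, rgr,
#'   mpv_test), `recovery` (when simulated), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$simulate) {
    sim <- .stage("simulate", simulate_triad_counts(config$sim_spec))
    counts <- sim$counts
    gene_lengths <- sim$gene_lengths
  } else {
    sim <- NULL
    counts <- .stage("read", read_expression_matrix(config$matrix_path,
                                                    config$sample_sheet_path))
    gl <- .stage("read", utils::read.table(config$gene_lengths_path,
                                           header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE))
    gene_lengths <- stats::setNames(gl[[2L]], as.character(gl[[1L]]))
  }
  bad <- setdiff(config$focal_daps, counts$samples$dap)
  if (length(bad))
    stopf("pipeline stage 'validate' failed: focal DAP(s) %s absent from design",
          paste(bad, collapse = ", "))
  fk <- .stage("fpkm", fpkm(counts, gene_lengths))
  r2 <- .stage("replicate_r2", replicate_r2(fk))
  daps <- sort(unique(fk$samples$dap))
  expressed <- lapply(stats::setNames(c("M", "H", "P"), c("M", "H", "P")),
                      function(g) {
    sets <- lapply(stats::setNames(daps, paste0("dap", daps)), function(d)
      expressed_genes(fk, g, d, config$expressed_threshold))
    sets
  })
  ov <- if (length(daps) >= 2L)
    lapply(expressed, overlap)
  else NULL
  deg <- list(); updown <- list(); patterns <- list()
  for (d in config$focal_daps) {
    key <- paste0("dap", d)
    universe <- .stage("universe", Reduce(intersect, lapply(
      c("M", "H", "P"), function(g)
        expressed_genes(fk, g, d, config$expressed_threshold))))
    dd <- .stage("deg", list(
      M_vs_P = deg_test(fk, "M", "P", d, config$fc_threshold, config$alpha,
                        genes = universe),
      M_vs_H = deg_test(fk, "M", "H", d, config$fc_threshold, config$alpha,
                        genes = universe),
      P_vs_H = deg_test(fk, "P", "H", d, config$fc_threshold, config$alpha,
                        genes = universe)))
    deg[[key]] <- dd
    updown[[key]] <- lapply(dd, updown_summary)
    patterns[[key]] <- .stage("classify",
                              classify_triad(dd$M_vs_P, dd$M_vs_H, dd$P_vs_H))
  }
  table1 <- .stage("summarise",
                   render_table1(lapply(patterns, class_summary)))
  parent_level <- lapply(patterns, parent_level_summary)
  pheno_series <- if (!is.null(config$phenotype_path)) {
    .stage("phenotype", utils::read.table(config$phenotype_path,
                                          header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE))
  } else if (config$simulate) {
    simulate_phenotype_series(seed = config$seed)
  } else NULL
  phenotype <- NULL
  if (!is.null(pheno_series)) {
    phenotype <- .stage("phenotype", {
      mu <- stats::aggregate(value ~ genotype + dap, pheno_series, mean)
      wide <- stats::reshape(mu, idvar = "dap", timevar = "genotype",
                             direction = "wide")
      names(wide) <- sub("^value\\.", "", names(wide))
      wide$MPV <- mid_parent_value(wide$M, wide$P)
      last_dap <- max(pheno_series$dap)
      at_last <- function(g) pheno_series$value[
        pheno_series$genotype == g & pheno_series$dap == last_dap]
      list(series = pheno_series,
           mpv = wide[order(wide$dap), c("dap", "M", "H", "P", "MPV")],
           rgr = relative_growth_rate(pheno_series),
           mpv_test = data.frame(
             dap = last_dap,
             p_value = mpv_significance(at_last("H"), at_last("M"),
                                        at_last("P"), seed = config$seed)))
    })
  }
  recovery <- if (config$simulate && length(patterns)) {
    lapply(patterns, function(tp)
      class_recovery(sim$truth[sim$truth$gene_id %in% tp$gene_id, ], tp))
  } else NULL
  report <- structure(list(sim = sim, fpkm = fk, replicate_r2 = r2,
                           expressed = expressed, overlap = ov, deg = deg,
                           updown = updown, patterns = patterns,
                           table1 = table1, parent_level = parent_level,
                           phenotype = phenotype, recovery = recovery,
                           config = config),
                      class = "triad_report")
  if (!is.null(out_dir)) .stage("write", write_report(report, out_dir))
  report
}

#' Lay out category summaries in the published table format
#'
#' One row per time point; columns are the additive sum, the two dominance
#' categories, the two transgressive categories, the classified total, and
#' the matching 2-decimal proportions of all classified genes.
#'
#' @param summaries named list (one element per DAP, e.g. `dap3`) of
#'   [class_summary()] outputs.
#' @return data.frame with count and `pct_*` columns; empty input gives an
#'   empty data.frame.
#' @export
render_table1 <- function(summaries) {
  if (!length(summaries)) return(data.frame())
  rows <- lapply(names(summaries), function(k) {
    s <- summaries[[k]]
    n <- stats::setNames(s$category$n, s$category$category)
    p <- stats::setNames(s$category$pct, s$category$category)
    data.frame(dap = k,
               additive = n[["additive"]], ELD_M = n[["ELD_M"]],
               ELD_P = n[["ELD_P"]],
               transgressive_up = n[["transgressive_up"]],
               transgressive_down = n[["transgressive_down"]],
               total = s$n_total,
               pct_additive = p[["additive"]], pct_ELD_M = p[["ELD_M"]],
               pct_ELD_P = p[["ELD_P"]],
               pct_transgressive_up = p[["transgressive_up"]],
               pct_transgressive_down = p[["transgressive_down"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a pipeline report bundle as TSVs
#'
#' @param report a `"triad_report"` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (key in names(report$deg)) {
    for (ct in names(report$deg[[key]]))
      write_deg_table(report$deg[[key]][[ct]],
                      file.path(out_dir, sprintf("deg_%s_%s.tsv", ct, key)))
    write_triad_patterns(report$patterns[[key]],
                         file.path(out_dir,
                                   sprintf("classification_%s.tsv", key)))
    wt(report$parent_level[[key]], sprintf("parent_level_%s.tsv", key))
  }
  wt(report$table1, "table1_summary.tsv")
  ud <- do.call(rbind, lapply(names(report$updown), function(k)
    do.call(rbind, lapply(names(report$updown[[k]]), function(ct) {
      u <- report$updown[[k]][[ct]]
      data.frame(dap = k, contrast = ct, n_up = u$n_up, n_down = u$n_down,
                 n_total_deg = u$n_total_deg, pct_up = u$pct_up,
                 pct_down = u$pct_down, stringsAsFactors = FALSE)
    }))))
  wt(ud, "updown_summary.tsv")
  wt(report$replicate_r2$per_group, "replicate_r2.tsv")
  if (!is.null(report$overlap)) {
    for (g in names(report$overlap)) {
      o <- report$overlap[[g]]
      wt(data.frame(region = names(o$region_counts),
                    n = unname(o$region_counts), stringsAsFactors = FALSE),
         sprintf("overlap_regions_%s.tsv", g))
    }
    wt(data.frame(genotype = names(report$overlap),
                  total_expressed = vapply(report$overlap,
                                           function(o) o$union_size,
                                           integer(1)),
                  core = vapply(report$overlap, function(o) o$core_count,
                                integer(1)),
                  core_pct = vapply(report$overlap,
                                    function(o) o$core_pct_of_union,
                                    numeric(1)),
                  stringsAsFactors = FALSE),
         "overlap_summary.tsv")
  }
  if (!is.null(report$phenotype)) {
    wt(report$phenotype$mpv, "phenotype_mpv.tsv")
    wt(report$phenotype$rgr, "phenotype_rgr.tsv")
    wt(report$phenotype$mpv_test, "phenotype_mpv_test.tsv")
  }
  cfg <- report$config
  log_lines <- c(
    sprintf("triadexpress %s",
            as.character(utils::packageVersion("triadexpress"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("sim_seed: %s",
            if (cfg$simulate) cfg$sim_spec$seed else "NA (real data)"),
    sprintf("expressed_threshold: %g", cfg$expressed_threshold),
    sprintf("fc_threshold: %g", cfg$fc_threshold),
    sprintf("alpha: %g", cfg$alpha),
    sprintf("focal_daps: %s", paste(cfg$focal_daps, collapse = ",")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.triad_report <- function(x, ...) {
  cat("triad_report\n")
  cat(sprintf("  input: %s\n",
              if (x$config$simulate)
                sprintf("simulated (%d genes, seed %d)",
                        nrow(x$fpkm$values), x$config$sim_spec$seed)
              else x$config$matrix_path))
  cat(sprintf("  replicate R^2 (grand mean): %.3f\n",
              x$replicate_r2$grand_mean))
  if (nrow(x$table1)) {
    cat("  classification:\n")
    print(x$table1[, c("dap", "additive", "ELD_M", "ELD_P",
                       "transgressive_up", "transgressive_down", "total",
                       "pct_additive")], row.names = FALSE)
  }
  invisible(x)
}
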