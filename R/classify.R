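# internal: map user-facing call symbols to signs
.sym_to_sign <- function(x, pos, neg, arg) {
  s <- rep(NA_integer_, length(x))
  s[x == pos] <- 1L
  s[x == neg] <- -1L
  s[x == "ns"] <- 0L
  if (anyNA(s))
    stopf("malformed %s call symbol(s): %s", arg,
          paste(unique(x[is.na(s)]), collapse = ", "))
  s
}

# internal: vectorised classification from signed calls (+ means for the
# distance fallback). Clean patterns (one signed triple per class) are looked
# up in triad_class_table(); the 14 remaining combinations are conflicting --
# no named pattern describes them -- and fall back to the category whose
# idealised reference (mid-parent for additive, matched parent for dominance)
# is nearest to mu_H, ties resolved towards additive.
.classify_signs <- function(s_mp, s_mh, s_ph, mu_M, mu_H, mu_P) {
  tab <- triad_class_table()
  key <- paste(s_mp, s_mh, s_ph)
  id <- tab$class_id[match(key, paste(tab$s_mp, tab$s_mh, tab$s_ph))]
  fb <- which(is.na(id))
  if (length(fb)) {
    d_add <- abs(mu_H[fb] - (mu_M[fb] + mu_P[fb]) / 2)
    d_m <- abs(mu_H[fb] - mu_M[fb])
    d_p <- abs(mu_H[fb] - mu_P[fb])
    cat_fb <- ifelse(d_add <= pmin(d_m, d_p) | d_m == d_p, "additive",
                     ifelse(d_m < d_p, "ELD_M", "ELD_P"))
    dir_fb <- ifelse(s_mp[fb] != 0L, s_mp[fb], sign(mu_M[fb] - mu_P[fb]))
    id[fb] <- ifelse(cat_fb == "additive",
                     ifelse(s_mp[fb] == 1L, 11L,
                            ifelse(s_mp[fb] == -1L, 12L, 13L)),
              ifelse(cat_fb == "ELD_M",
                     ifelse(dir_fb >= 0, 7L, 8L),
                     ifelse(dir_fb <= 0, 9L, 10L)))
  }
  id
}

#' Classify one gene's triad expression pattern
#'
#' Assigns one of the 13 expression-pattern classes from the three signed
#' pairwise calls of a gene (M vs P, H vs M, H vs P). Thirteen of the 27
#' possible call combinations are the named patterns themselves
#' (see [triad_class_table()]); the remaining combinations are internally
#' conflicting and are resolved by the distance fallback: the category
#' whose idealised reference (mid-parent for additive, matched parent for
#' dominance) lies nearest `mu_H`, ties going to additive.
#'
#' @param s_mp `"M>P"`, `"M<P"` or `"ns"`.
#' @param s_mh `"H>M"`, `"H<M"` or `"ns"`.
#' @param s_ph `"H>P"`, `"H<P"` or `"ns"`.
#' @param mu_M,mu_H,mu_P replicate-mean expression levels (used only by the
#'   fallback).
#' @return list with `class_id`, `class_label`, `category`.
#' @examples
#' classify_gene("M>P", "ns", "H>P", 10, 10, 2) # ELD_M
#' @export
classify_gene <- function(s_mp, s_mh, s_ph, mu_M = NA_real_, mu_H = NA_real_,
                          mu_P = NA_real_) {
  id <- .classify_signs(.sym_to_sign(s_mp, "M>P", "M<P", "s_mp"),
                        .sym_to_sign(s_mh, "H>M", "H<M", "s_mh"),
                        .sym_to_sign(s_ph, "H>P", "H<P", "s_ph"),
                        mu_M, mu_H, mu_P)
  tab <- triad_class_table()
  list(class_id = id, class_label = tab$class_label[id],
       category = tab$category[id])
}

# internal: signed call for genotype g1 relative to g2 from a deg_table
.signed_call <- function(deg, g1, g2) {
  ct <- attr(deg, "contrast")
  if (!setequal(ct, c(g1, g2)))
    stopf("deg table contrasts %s vs %s, expected %s/%s",
          ct[["a"]], ct[["b"]], g1, g2)
  s <- ifelse(deg$call == "up", 1L, ifelse(deg$call == "down", -1L, 0L))
  if (ct[["b"]] == g1) s else -s   # 'up' means b > a
}

# internal: replicate mean of genotype g from a deg_table
.mean_of <- function(deg, g) {
  ct <- attr(deg, "contrast")
  if (ct[["a"]] == g) deg$mean_a else deg$mean_b
}

#' Classify every gene of a triad from its three pairwise DEG tables
#'
#' The central classification step: combines the M-vs-P, M-vs-H and P-vs-H
#' contrasts of one time point into a per-gene 13-class pattern call, its
#' 5-way category and its high-/mid-/low-parent level. The three tables may
#' have either orientation (the stored contrast attribute disambiguates)
#' but must share one gene universe.
#'
#' @param deg_mp `deg_table` contrasting M and P.
#' @param deg_mh `deg_table` contrasting M and H.
#' @param deg_ph `deg_table` contrasting P and H.
#' @return a data.frame of class `"triad_patterns"`: `gene_id`, `s_mp`,
#'   `s_mh`, `s_ph` (call symbols), `class_id`, `class_label`, `category`,
#'   `parent_level`, `mu_M`, `mu_H`, `mu_P`.
#' @export
classify_triad <- function(deg_mp, deg_mh, deg_ph) {
  ids <- deg_mp$gene_id
  for (other in list(deg_mh, deg_ph)) {
    sd_n <- length(setdiff(ids, other$gene_id)) +
      length(setdiff(other$gene_id, ids))
    if (sd_n > 0)
      stopf("gene universes differ between contrasts (symmetric difference: %d genes)",
            sd_n)
  }
  ct_mh <- attr(deg_mh, "contrast")
  ct_ph <- attr(deg_ph, "contrast")
  deg_mh <- deg_mh[match(ids, deg_mh$gene_id), ]
  deg_ph <- deg_ph[match(ids, deg_ph$gene_id), ]
  attr(deg_mh, "contrast") <- ct_mh
  attr(deg_ph, "contrast") <- ct_ph
  s_mp <- .signed_call(deg_mp, "M", "P")
  s_mh <- .signed_call(deg_mh, "H", "M")
  s_ph <- .signed_call(deg_ph, "H", "P")
  mu_M <- .mean_of(deg_mp, "M")
  mu_H <- .mean_of(deg_mh, "H")
  mu_P <- .mean_of(deg_ph, "P")
  id <- .classify_signs(s_mp, s_mh, s_ph, mu_M, mu_H, mu_P)
  tab <- triad_class_table()
  out <- data.frame(
    gene_id = ids,
    s_mp = c("M<P", "ns", "M>P")[s_mp + 2L],
    s_mh = c("H<M", "ns", "H>M")[s_mh + 2L],
    s_ph = c("H<P", "ns", "H>P")[s_ph + 2L],
    class_id = id,
    class_label = tab$class_label[id],
    category = tab$category[id],
    parent_level = tab$parent_level[id],
    mu_M = mu_M, mu_H = mu_H, mu_P = mu_P,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("triad_patterns", "data.frame"),
            dap = attr(deg_mp, "dap"))
}

#' Category and class composition of a classified triad
#'
#' @param table a `triad_patterns` table (nonempty).
#' @return list with `n_total`, `category` (data.frame: category, n, pct)
#'   and `class` (data.frame: class_id, class_label, category, n, pct);
#'   percentages of all classified genes, two decimals.
#' @export
class_summary <- function(table) {
  if (nrow(table) == 0L) stopf("empty classification table")
  tab <- triad_class_table()
  n_total <- nrow(table)
  cls_n <- vapply(tab$class_id, function(i) sum(table$class_id == i),
                  integer(1))
  cats <- c("additive", "ELD_M", "ELD_P", "transgressive_up",
            "transgressive_down")
  cat_n <- vapply(cats, function(cc) sum(table$category == cc), integer(1))
  list(n_total = n_total,
       category = data.frame(category = cats, n = unname(cat_n),
                             pct = pct(unname(cat_n), n_total),
                             stringsAsFactors = FALSE),
       class = data.frame(class_id = tab$class_id,
                          class_label = tab$class_label,
                          category = tab$category, n = cls_n,
                          pct = pct(cls_n, n_total),
                          stringsAsFactors = FALSE))
}

#' High-/mid-/low-parent summary
#'
#' Collapses the 13 classes into the three parent-level categories:
#' mid-parent (all additive classes), high-parent (transgressive up plus
#' dominance classes matching the higher-expressed parent) and low-parent
#' (transgressive down plus dominance classes matching the lower parent).
#'
#' @param table a `triad_patterns` table.
#' @return data.frame (`parent_level`, `n`, `pct`).
#' @export
parent_level_summary <- function(table) {
  lv <- c("high_parent", "mid_parent", "low_parent")
  n <- vapply(lv, function(l) sum(table$parent_level == l), integer(1))
  data.frame(parent_level = lv, n = unname(n),
             pct = pct(unname(n), nrow(table)), stringsAsFactors = FALSE)
}

#' Score classification recovery against simulation truth
#'
#' @param truth truth data.frame from [simulate_triad_counts()] (columns
#'   `gene_id`, `category`).
#' @param predicted a `triad_patterns` table over the same gene universe.
#' @return list with `confusion` (5x5 matrix, truth rows x predicted
#'   columns), `accuracy` and per-category `sensitivity`.
#' @export
class_recovery <- function(truth, predicted) {
  sd_n <- length(setdiff(truth$gene_id, predicted$gene_id)) +
    length(setdiff(predicted$gene_id, truth$gene_id))
  if (sd_n > 0)
    stopf("gene universes differ (symmetric difference: %d genes)", sd_n)
  cats <- c("additive", "ELD_M", "ELD_P", "transgressive_up",
            "transgressive_down")
  pred <- predicted$category[match(truth$gene_id, predicted$gene_id)]
  confusion <- table(truth = factor(truth$category, cats),
                     predicted = factor(pred, cats))
  confusion <- unclass(confusion)
  acc <- sum(diag(confusion)) / sum(confusion)
  sens <- diag(confusion) / rowSums(confusion)
  list(confusion = confusion, accuracy = acc, sensitivity = sens)
}

#' @export
print.triad_patterns <- function(x, ...) {
  cat(sprintf("triad_patterns: %d genes classified%s\n", nrow(x),
              if (!is.null(attr(x, "dap")))
                sprintf(" (DAP %s)", attr(x, "dap")) else ""))
  if (nrow(x)) {
    cs <- class_summary(x)
    print(cs$category, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.triad_patterns <- function(object, ...) {
  out <- list(class_summary = class_summary(object),
              parent_level = parent_level_summary(object),
              dap = attr(object, "dap"))
  class(out) <- "summary.triad_patterns"
  out
}

#' @export
print.summary.triad_patterns <- function(x, ...) {
  cat(sprintf("Triad expression-pattern summary%s (%d genes)\n",
              if (!is.null(x$dap)) sprintf(", DAP %s", x$dap) else "",
              x$class_summary$n_total))
  cat("\nCategories:\n")
  print(x$class_summary$category, row.names = FALSE)
  cat("\nClasses:\n")
  print(x$class_summary$class, row.names = FALSE)
  cat("\nParent level:\n")
  print(x$parent_level, row.names = FALSE)
  invisible(x)
}

#' @export
plot.triad_patterns <- function(x, ...) {
  cs <- class_summary(x)
  graphics::barplot(stats::setNames(cs$category$n, cs$category$category),
                    las = 2, ylab = "genes",
                    main = "Triad expression-pattern categories", ...)
  invisible(x)
}

#' Write a classification table as TSV
#'
#' @param table a `triad_patterns` table.
#' @param path TSV path.
#' @export
write_triad_patterns <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}
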