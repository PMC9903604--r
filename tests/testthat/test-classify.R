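syms_mp <- c("M>P", "ns", "M<P")
syms_mh <- c("H>M", "ns", "H<M")
syms_ph <- c("H>P", "ns", "H<P")

test_that("classify_gene reproduces the named worked patterns", {
  expect_equal(classify_gene("M>P", "ns", "H>P")$category, "ELD_M")
  expect_equal(classify_gene("ns", "ns", "ns")$class_label,
               "additive_conserved")
  expect_equal(classify_gene("ns", "H>M", "H>P")$category, "transgressive_up")
  expect_error(classify_gene("M>>P", "ns", "ns"), "malformed")
})

test_that("all 27 call combinations match the independent rule oracle", {
  mean_cfgs <- list(c(M = 200, H = 125, P = 50), c(M = 50, H = 125, P = 200),
                    c(M = 10, H = 9, P = 30), c(M = 30, H = 31, P = 10),
                    c(M = 80, H = 80, P = 80), c(M = 5, H = 100, P = 40))
  for (cfg in mean_cfgs) {
    for (a in syms_mp) for (b in syms_mh) for (cc in syms_ph) {
      got <- classify_gene(a, b, cc, cfg[["M"]], cfg[["H"]], cfg[["P"]])
      want <- oracle_classify(a, b, cc, cfg[["M"]], cfg[["H"]], cfg[["P"]])
      expect_identical(got$class_label, want,
                       info = sprintf("%s | %s | %s @ M=%g H=%g P=%g",
                                      a, b, cc, cfg[["M"]], cfg[["H"]],
                                      cfg[["P"]]))
    }
  }
})

test_that("every gene gets exactly one class and categories partition", {
  set.seed(41)
  n <- 400
  trio <- make_deg_trio(sample(c("up", "down", "ns"), n, TRUE),
                        sample(c("up", "down", "ns"), n, TRUE),
                        sample(c("up", "down", "ns"), n, TRUE),
                        mu_M = rexp(n, 0.05), mu_H = rexp(n, 0.05),
                        mu_P = rexp(n, 0.05))
  tp <- classify_triad(trio$mp, trio$mh, trio$ph)
  expect_equal(nrow(tp), n)
  expect_true(all(tp$class_id %in% 1:13))
  cs <- class_summary(tp)
  expect_equal(sum(cs$category$n), n)
  expect_equal(sum(cs$class$n), n)
  expect_lt(abs(sum(cs$category$pct) - 100), 0.03)
})

test_that("swapping the M and P inputs maps ELD_M and ELD_P onto each other", {
  set.seed(43)
  for (rep in 1:5) {
    n <- 200
    calls_mp <- sample(c("up", "down", "ns"), n, TRUE)
    calls_mh <- sample(c("up", "down", "ns"), n, TRUE)
    calls_ph <- sample(c("up", "down", "ns"), n, TRUE)
    mu_M <- rexp(n, 0.05); mu_H <- rexp(n, 0.05); mu_P <- rexp(n, 0.05)
    trio <- make_deg_trio(calls_mp, calls_mh, calls_ph, mu_M, mu_H, mu_P)
    tp <- classify_triad(trio$mp, trio$mh, trio$ph)
    # swap roles: M<->P flips the M~P call and exchanges the H contrasts
    flip <- c(up = "down", down = "up", ns = "ns")
    swapped <- make_deg_trio(unname(flip[calls_mp]), calls_ph, calls_mh,
                             mu_M = mu_P, mu_H = mu_H, mu_P = mu_M)
    tp2 <- classify_triad(swapped$mp, swapped$mh, swapped$ph)
    map <- c(additive = "additive", ELD_M = "ELD_P", ELD_P = "ELD_M",
             transgressive_up = "transgressive_up",
             transgressive_down = "transgressive_down")
    expect_identical(tp2$category, unname(map[tp$category]))
    # category totals are consistent under the swap
    expect_equal(sum(tp2$category == "ELD_P"), sum(tp$category == "ELD_M"))
    expect_equal(sum(tp2$category == "additive"),
                 sum(tp$category == "additive"))
  }
})

test_that("classify_triad validates universes and is order-equivariant", {
  trio <- make_deg_trio(c("ns", "up", "down"), c("ns", "ns", "ns"),
                        c("ns", "up", "down"))
  short <- trio$mh[-1, ]
  attr(short, "contrast") <- attr(trio$mh, "contrast")
  expect_error(classify_triad(trio$mp, short, trio$ph),
               "symmetric difference: 1")
  tp <- classify_triad(trio$mp, trio$mh, trio$ph)
  perm <- c(3, 1, 2)
  trio_p <- lapply(trio, function(d) {
    dp <- d[perm, ]
    attr(dp, "contrast") <- attr(d, "contrast")
    class(dp) <- class(d)
    dp
  })
  tp2 <- classify_triad(trio_p$mp, trio_p$mh, trio_p$ph)
  expect_identical(tp2$class_id, tp$class_id[perm])
  expect_identical(tp2$gene_id, tp$gene_id[perm])
})

test_that("class_summary reproduces the published category arithmetic", {
  ref <- read_ref("table1_reference_counts.tsv")
  for (d in c(3, 8)) {
    r <- ref[ref$dap == d, ]
    fake <- structure(data.frame(
      gene_id = sprintf("g%06d", seq_len(sum(r$n))),
      class_id = rep(match(r$class_label, triad_class_table()$class_label),
                     r$n),
      class_label = rep(r$class_label, r$n),
      category = rep(r$category, r$n),
      parent_level = rep(triad_class_table()$parent_level[
        match(r$class_label, triad_class_table()$class_label)], r$n),
      stringsAsFactors = FALSE), class = c("triad_patterns", "data.frame"))
    cs <- class_summary(fake)
    addv <- cs$category$pct[cs$category$category == "additive"]
    expect_equal(addv, if (d == 3) 85.18 else 86.45)
    if (d == 3) {
      expect_equal(cs$category$pct[cs$category$category == "ELD_M"], 6.10)
      expect_equal(cs$category$pct[cs$category$category == "ELD_P"], 8.27)
      expect_equal(cs$category$pct[cs$category$category == "transgressive_up"],
                   0.10)
      expect_equal(cs$category$pct[cs$category$category == "transgressive_down"],
                   0.35)
    }
  }
  # single-gene table: that class is 100%
  one <- structure(data.frame(gene_id = "g1", class_id = 13L,
                              class_label = "additive_conserved",
                              category = "additive",
                              parent_level = "mid_parent",
                              stringsAsFactors = FALSE),
                   class = c("triad_patterns", "data.frame"))
  expect_equal(class_summary(one)$class$pct[13], 100.00)
})

test_that("parent levels follow the class definitions", {
  tab <- triad_class_table()
  # all-additive table maps entirely to mid-parent
  add <- structure(data.frame(gene_id = c("a", "b"),
                              class_id = c(11L, 13L),
                              class_label = tab$class_label[c(11, 13)],
                              category = "additive",
                              parent_level = tab$parent_level[c(11, 13)],
                              stringsAsFactors = FALSE),
                   class = c("triad_patterns", "data.frame"))
  pl <- parent_level_summary(add)
  expect_equal(pl$n[pl$parent_level == "mid_parent"], 2L)
  # ELD_M matching the higher parent is a high-parent pattern
  expect_identical(tab$parent_level[tab$class_label == "ELD_M_high"],
                   "high_parent")
  # random table vs brute-force per-gene mapping
  set.seed(47)
  ids <- sample(1:13, 300, TRUE)
  rnd <- structure(data.frame(gene_id = sprintf("g%03d", 1:300),
                              class_id = ids,
                              class_label = tab$class_label[ids],
                              category = tab$category[ids],
                              parent_level = tab$parent_level[ids],
                              stringsAsFactors = FALSE),
                   class = c("triad_patterns", "data.frame"))
  pl <- parent_level_summary(rnd)
  brute <- table(tab$parent_level[ids])
  for (lv in names(brute))
    expect_equal(pl$n[pl$parent_level == lv], unname(unclass(brute[lv])))
})

test_that("class_recovery scores a confusion matrix correctly", {
  tab <- triad_class_table()
  ids <- c(7L, 9L, 13L, 1L, 4L)
  truth <- data.frame(gene_id = letters[1:5],
                      category = tab$category[ids],
                      stringsAsFactors = FALSE)
  pred <- structure(data.frame(gene_id = letters[1:5],
                               category = tab$category[ids],
                               stringsAsFactors = FALSE),
                    class = c("triad_patterns", "data.frame"))
  r <- class_recovery(truth, pred)
  expect_equal(r$accuracy, 1.0)
  expect_true(all(diag(r$confusion) == rowSums(r$confusion)))
  # all-one-category prediction: accuracy equals that category's truth share
  pred2 <- pred
  pred2$category <- "additive"
  r2 <- class_recovery(truth, pred2)
  expect_equal(r2$accuracy, mean(truth$category == "additive"))
  expect_error(class_recovery(truth[-1, ], pred), "symmetric difference")
})
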