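test_that("expression categories: threshold then rank tertiles", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     x = c(0, 1, 10, 100), stringsAsFactors = FALSE)
  cat <- categorize_expression(expr, "x", none_threshold = 0.5)
  expect_equal(as.character(cat[c("g1", "g2", "g3", "g4")]),
               c("none", "low", "medium", "high"))
  all_none <- categorize_expression(
    data.frame(gene_id = c("a", "b"), x = c(0.1, 0.2)), "x")
  expect_true(all(all_none == "none"))
  expect_error(categorize_expression(expr, "missing"), "not in expression")
  expect_error(categorize_expression(expr[0, ], "x"), "empty")
})

test_that("tertile sizes differ by at most one on 10007 genes", {
  set.seed(51)
  n <- 10007
  expr <- data.frame(gene_id = sprintf("g%05d", 1:n),
                     x = stats::rlnorm(n, 1, 1) + 1)
  cat <- categorize_expression(expr, "x", none_threshold = 1)
  sizes <- table(cat)[c("low", "medium", "high")]
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), sum(expr$x >= 1))
})

test_that("categories are order-invariant and monotone in RPKM", {
  set.seed(52)
  n <- 200
  expr <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     x = round(stats::rlnorm(n, 1, 1), 3))
  cat <- categorize_expression(expr, "x")
  perm <- expr[sample(n), ]
  cat_p <- categorize_expression(perm, "x")
  expect_equal(as.character(cat_p[expr$gene_id]),
               as.character(cat[expr$gene_id]))
  ## raising one gene's RPKM never lowers its category
  i <- sample(n, 1)
  expr2 <- expr
  expr2$x[i] <- expr2$x[i] * 10
  cat2 <- categorize_expression(expr2, "x")
  expect_gte(as.integer(cat2[expr$gene_id[i]]),
             as.integer(cat[expr$gene_id[i]]))
})

unit_track <- function(lens, hot = NULL) {
  cov <- lapply(lens, function(L) S4Vectors::Rle(0, L))
  if (!is.null(hot))
    cov[[hot$scaffold]][(hot$start + 1):hot$end] <- hot$value
  ecdreg:::new_coverage_track(cov)
}

test_that("metaprofile is strand-oriented around the TSS", {
  lens <- c(s1 = 10000L)
  gp <- make_genes("gp", "s1", 5000, 6000, "+")
  gm <- make_genes("gm", "s1", 5000, 6000, "-")
  cats <- stats::setNames(
    factor("high", levels = c("none", "low", "medium", "high")), "gp")
  ## coverage 1 on [TSS, TSS+50) of the + gene
  trk <- unit_track(lens, list(scaffold = "s1", start = 5000, end = 5050,
                               value = 1))
  mp <- tss_metaprofile(trk, gp, cats, flank = 200, bin = 50)
  expect_equal(mp$centers, c(-175, -125, -75, -25, 25, 75, 125, 175))
  expect_equal(unname(mp$profile["high", ]), c(0, 0, 0, 0, 1, 0, 0, 0))
  ## same oriented pattern for a - gene: TSS at 5999, downstream is 5950..5999
  cats2 <- stats::setNames(cats, "gm")
  trk2 <- unit_track(lens, list(scaffold = "s1", start = 5950, end = 6000,
                                value = 1))
  mp2 <- tss_metaprofile(trk2, gm, cats2, flank = 200, bin = 50)
  expect_equal(unname(mp2$profile["high", ]), c(0, 0, 0, 0, 1, 0, 0, 0))
})

test_that("metaprofile of a constant track is constant, truncation tolerated", {
  lens <- c(s1 = 3000L)
  gm <- make_genes(c("g1", "g2"), "s1", c(100, 2000), c(900, 2900),
                   c("+", "-"))
  cats <- stats::setNames(
    factor(c("low", "high"), levels = c("none", "low", "medium", "high")),
    c("g1", "g2"))
  trk <- ecdreg:::new_coverage_track(list(s1 = S4Vectors::Rle(3, 3000)))
  mp <- tss_metaprofile(trk, gm, cats, flank = 2000, bin = 50)
  expect_true(all(abs(mp$profile - 3) < 1e-12, na.rm = TRUE))
  expect_equal(sort(names(mp$n_genes)), c("high", "low"))
  expect_error(tss_metaprofile(trk, gm, cats, flank = 2001, bin = 50),
               "divisible")
})

test_that("class means: log2 transform, dedup, and the all-genes identity", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"), x = c(3, 1, 0),
                     stringsAsFactors = FALSE)
  r <- expression_by_element_class(list(one = "g1"), expr, "x")
  expect_equal(r$mean_log2_expr, 2.0)  # log2(3+1)
  ## duplicates collapse
  r2 <- expression_by_element_class(list(dup = c("g1", "g1", "g2")),
                                    expr, "x")
  expect_equal(r2$n_genes, 2L)
  expect_equal(r2$mean_log2_expr, mean(log2(c(4, 2))))
  ## all-genes class equals the global mean
  r3 <- expression_by_element_class(list(all_genes = expr$gene_id),
                                    expr, "x")
  expect_equal(r3$mean_log2_expr, mean(log2(expr$x + 1)))
  ## unknown genes counted as dropped; empty class warns
  r4 <- expression_by_element_class(list(mix = c("g1", "gX")), expr, "x")
  expect_equal(r4$n_dropped, 1L)
  expect_warning(
    r5 <- expression_by_element_class(list(bad = "gZ"), expr, "x"),
    "no genes")
  expect_true(is.na(r5$mean_log2_expr))
})

test_that("activity-coupled expression separates element classes", {
  ## active-element target genes are drawn with a 4x RPKM scale, so their
  ## mean log-expression should exceed both the inactive-element targets'
  ## and the all-genes mean
  ds <- simulate_dataset(small_cfg(seed = 77, make_sequence = FALSE,
                                   make_coverage = FALSE))
  el <- call_elements(ds$peaks$H3K4me1$control, ds$peaks$H3K4me3$control,
                      ds$peaks$H3K27ac$control, ds$genes)
  cls <- element_target_classes(el, ds$expression)
  r <- expression_by_element_class(cls, ds$expression, "control")
  m <- stats::setNames(r$mean_log2_expr, r$class)
  expect_gt(m[["active_DRE"]], m[["inactive_DRE"]])
  expect_gt(m[["active_DRE"]], m[["all_genes"]])
})
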