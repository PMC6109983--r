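# One gene with TSS at 10000 on a comfortable scaffold, used by the
# definitional cases below.
one_gene <- make_genes("g1", "s1", 10000, 14000, "+")

test_that("element definitions: distal H3K4me1 is a DRE, proximal is dropped", {
  me1 <- peak_frame("s1", c(14600, 10500), c(15400, 11100),
                    c("distal", "proximal"), 5, c(400L, 300L))
  ## summits: 15000 (5 kb from TSS) and 10800 (800 bp)
  me3 <- peak_frame(character(), integer(), integer(), character(),
                    numeric(), integer())
  ac <- peak_frame("s1", 14900, 15500, "ac1", 3, 300L)
  el <- call_elements(me1, me3, ac, one_gene)
  expect_equal(nrow(el), 1L)
  expect_equal(el$kind, "DRE")
  expect_equal(el$name, "distal")
  expect_true(el$active)
  expect_equal(el$nearest_gene, "g1")
  expect_equal(el$tss_distance, 5000)
})

test_that("promoters come only from H3K4me3 within 1.5 kb of a TSS", {
  me3 <- peak_frame("s1", c(9500, 20000), c(10300, 20800),
                    c("prox", "far"), 5, c(400L, 400L))
  empty <- peak_frame(character(), integer(), integer(), character(),
                      numeric(), integer())
  el <- call_elements(empty, me3, empty, one_gene)
  expect_equal(el$name, "prox")       # distal H3K4me3 is not an element
  expect_equal(el$kind, "promoter")
  expect_false(el$active)
  expect_error(call_elements(empty, me3, empty,
                             make_genes(character(), character(), integer(),
                                        integer(), character())),
               "empty gene set")
})

test_that("no peak is both promoter and DRE, and calls ignore input order", {
  set.seed(31)
  ds <- simulate_dataset(small_cfg(seed = 9, make_sequence = FALSE,
                                   make_coverage = FALSE))
  me1 <- ds$peaks$H3K4me1$treated
  me3 <- ds$peaks$H3K4me3$treated
  ac <- ds$peaks$H3K27ac$treated
  el <- call_elements(me1, me3, ac, ds$genes)
  expect_equal(anyDuplicated(el$name), 0L)
  expect_true(all(abs(el$tss_distance[el$kind == "DRE"]) > 1500,
                  na.rm = TRUE))
  expect_true(all(abs(el$tss_distance[el$kind == "promoter"]) <= 1500))
  shuf <- function(x) x[sample(nrow(x)), ]
  el2 <- call_elements(shuf(me1), shuf(me3), shuf(ac), ds$genes)
  srt <- function(x) {
    x <- x[order(x$name), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(srt(el2), srt(el))
})

test_that("activity is monotone in the H3K27ac peak set", {
  set.seed(32)
  ds <- simulate_dataset(small_cfg(seed = 10, make_sequence = FALSE,
                                   make_coverage = FALSE))
  ac <- ds$peaks$H3K27ac$control
  half <- ac[sample(nrow(ac), nrow(ac) %/% 2L), ]
  el_half <- call_elements(ds$peaks$H3K4me1$control,
                           ds$peaks$H3K4me3$control, half, ds$genes)
  el_full <- call_elements(ds$peaks$H3K4me1$control,
                           ds$peaks$H3K4me3$control, ac, ds$genes)
  m <- match(el_half$name, el_full$name)
  expect_true(all(el_full$active[m] >= el_half$active))
})

test_that("TSS co-occurrence counts match a per-TSS brute force", {
  set.seed(33)
  n <- 15
  gm <- make_genes(sprintf("g%02d", 1:n), "s1",
                   s <- sort(sample(seq(3000, 80000, by = 700), n)),
                   s + 600L, sample(c("+", "-"), n, replace = TRUE))
  me1 <- rand_peaks(30, scaffolds = "s1", max_pos = 85000)
  me3 <- rand_peaks(30, scaffolds = "s1", max_pos = 85000)
  ac <- rand_peaks(30, scaffolds = "s1", max_pos = 85000)
  got <- cooccurrence_at_tss(me1, me3, ac, gm)
  tssv <- ifelse(gm$genes$strand == "+", gm$genes$start, gm$genes$end - 1L)
  win <- data.frame(scaffold = "s1", start = pmax(tssv - 1500L, 0L),
                    end = tssv + 1500L)
  h3 <- bf_overlap_any(win, me3); h1 <- bf_overlap_any(win, me1)
  ha <- bf_overlap_any(win, ac)
  want <- c(sum(h3 & ha), sum(h1 & ha), sum(h3 & !ha), sum(h1 & !ha))
  expect_equal(got$count, want)
  expect_equal(got$denominator, rep(n, 4))
  ## no peaks at all: zero counts
  empty <- me1[0, ]
  z <- cooccurrence_at_tss(empty, empty, empty, gm)
  expect_true(all(z$count == 0))
})

test_that("intergenic co-occurrence restricts to intergenic summits", {
  set.seed(34)
  gm <- make_genes("g1", "s1", 30000, 34000, "+")
  part <- build_partition(gm, c(s1 = 100000L))
  ## one intergenic me1 peak overlapping ac, one genic me1 peak
  me1 <- peak_frame("s1", c(60000, 31000), c(60800, 31800),
                    c("inter", "genic"), 2, c(400L, 400L))
  me3 <- peak_frame(character(), integer(), integer(), character(),
                    numeric(), integer())
  ac <- peak_frame("s1", 60400, 61000, "ac", 2, 300L)
  got <- cooccurrence_intergenic(me1, me3, ac, part)
  expect_equal(got$count[got$category == "me1_and_ac"], 1L)
  expect_equal(got$denominator[got$category == "me1_and_ac"], 1L)
  expect_equal(got$count[got$category == "me3_and_ac"], 0L)
  ## all-genic peak set: all counts zero
  got2 <- cooccurrence_intergenic(me1[2, ], me3, ac, part)
  expect_true(all(got2$count == 0))
})

test_that("distance histogram bins |distance| with the default kb edges", {
  el <- data.frame(kind = "DRE", tss_distance = c(7000, -7000, 2000,
                                                  120000, NA))
  h <- tss_distance_histogram(el)
  expect_equal(h$count[h$bin == "[5,10)kb"], 2L)
  expect_equal(h$count[h$bin == "[1.5,5)kb"], 1L)
  expect_equal(h$count[h$bin == ">=100kb"], 1L)
  expect_equal(sum(h$count), 4L)  # one DRE lacks a nearest gene
  expect_error(tss_distance_histogram(el, edges_kb = c(5, 1.5)),
               "increasing")
  none <- tss_distance_histogram(el[0, ])
  expect_true(all(none$count == 0L))
})

test_that("distances drawn from a known mixture reproduce its proportions", {
  set.seed(35)
  n <- 5000
  mix <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  d <- c(runif(n, 1500, 5000), runif(n, 5000, 10000),
         runif(n, 10000, 20000))[(mix - 1) * n + seq_len(n)]
  el <- data.frame(kind = "DRE", tss_distance = d)
  h <- tss_distance_histogram(el)
  frac <- h$count / n
  expect_lt(abs(frac[h$bin == "[1.5,5)kb"] - 0.5), 0.03)
  expect_lt(abs(frac[h$bin == "[5,10)kb"] - 0.3), 0.03)
  expect_lt(abs(frac[h$bin == "[10,20)kb"] - 0.2), 0.03)
})
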