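iv <- function(scaffold, start, end) {
  data.frame(scaffold = scaffold, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

test_that("half-open overlap semantics: shared base required, abutment excluded", {
  expect_true(intervals_overlap(iv("s1", 0, 100), iv("s1", 50, 150)))
  expect_false(intervals_overlap(iv("s1", 0, 100), iv("s1", 100, 200)))
  expect_false(intervals_overlap(iv("s1", 0, 100), iv("s2", 0, 100)))
})

test_that("overlap tests are symmetric and match all-pairs brute force", {
  set.seed(21)
  for (rep in 1:5) {
    a <- rand_intervals(60)
    b <- rand_intervals(80)
    expect_equal(overlap_any(a, b), bf_overlap_any(a, b))
    ## symmetry of the pairwise predicate
    i <- sample(60, 20); j <- sample(80, 20)
    expect_equal(intervals_overlap(a[i, ], b[j, ]),
                 intervals_overlap(b[j, ], a[i, ]))
  }
})

test_that("overlap_fraction handles identity, disjoint and empty sets", {
  a <- rand_intervals(30)
  expect_equal(overlap_fraction(a, a)$fraction, 1.0)
  far <- iv("s9", 1, 10)
  expect_equal(overlap_fraction(a, far)$count, 0L)
  expect_true(is.na(overlap_fraction(a[0, ], a)$fraction))
})

test_that("single-gene partition follows the documented windows and priority", {
  gm <- make_genes("g1", "s1", 5000, 8000, "+")
  part <- build_partition(gm, c(s1 = 20000L))
  lab_at <- function(pos) {
    p <- peak_frame("s1", pos, pos + 2L, "x", 1, 0L)
    assign_peak_region(p, part)
  }
  expect_equal(lab_at(4500), "promoter-TSS")   # inside [4000, 5200)
  expect_equal(lab_at(7900), "exon")           # exon beats TTS window
  expect_equal(lab_at(8500), "TTS")            # [8000, 9000) after exon priority
  expect_equal(lab_at(15000), "intergenic")
  seg <- part[part$scaffold == "s1", ]
  expect_equal(sum(seg$end - seg$start), 20000L)  # total tiling
})

test_that("empty gene set partitions everything as intergenic", {
  gm <- make_genes(character(), character(), integer(), integer(), character())
  part <- build_partition(gm, c(s1 = 5000L))
  expect_equal(nrow(part), 1L)
  expect_equal(part$label, "intergenic")
  p <- peak_frame("s1", 100, 200, "x", 1, NA_integer_)
  expect_equal(assign_peak_region(p, part), "intergenic")
})

test_that("partition labels match per-base brute force on random gene layouts", {
  set.seed(22)
  for (rep in 1:8) {
    L <- 15000L
    n <- sample(2:4, 1)
    start <- sort(sample(seq(1500L, L - 4000L, by = 500L), n))
    width <- sample(800:2000, n, replace = TRUE)
    gm <- make_genes(sprintf("g%d", 1:n), "s1", start,
                     pmin(start + width, L - 1200L),
                     sample(c("+", "-"), n, replace = TRUE))
    ## carve a two-exon structure into the first gene
    g1 <- gm$genes[1, ]
    mid <- (g1$start + g1$end) %/% 2L
    gm$exons <- rbind(
      data.frame(gene_id = g1$gene_id, scaffold = "s1",
                 start = g1$start, end = mid - 100L),
      data.frame(gene_id = g1$gene_id, scaffold = "s1",
                 start = mid + 100L, end = g1$end),
      gm$genes[-1, c("gene_id", "scaffold", "start", "end")]
    )
    part <- build_partition(gm, c(s1 = L))
    expect_equal(sum(part$end - part$start), L)
    pos <- sample(0:(L - 1L), 120)
    got <- part$label[findInterval(pos, part$start)]
    want <- vapply(pos, function(p) bf_partition_label("s1", p, gm),
                   character(1))
    expect_equal(got, want)
  }
})

test_that("partition rejects genes beyond the scaffold end", {
  gm <- make_genes("g1", "s1", 100, 900, "+")
  expect_error(build_partition(gm, c(s1 = 500L)), "beyond scaffold end")
})

test_that("summit beyond the scaffold is an error in region assignment", {
  gm <- make_genes("g1", "s1", 5000, 8000, "+")
  part <- build_partition(gm, c(s1 = 10000L))
  p <- peak_frame("s1", 9990, 10020, "x", 1, 25L)  # summit at 10015
  expect_error(assign_peak_region(p, part), "beyond scaffold")
  p2 <- peak_frame("s9", 10, 20, "x", 1, 0L)
  expect_error(assign_peak_region(p2, part), "absent from partition")
})

test_that("nearest TSS: signed distance, tie-break, and cross-scaffold absence", {
  gm <- make_genes(c("gB", "gA"), "s1", c(900, 1200), c(1000, 1300),
                   c("+", "+"))
  r <- distance_to_nearest_tss(data.frame(scaffold = "s1", pos = 1000), gm)
  expect_equal(r$gene_id, "gB")
  expect_equal(r$distance, 100)
  ## equidistant: lexicographically smaller gene id wins
  gm2 <- make_genes(c("gZ", "gA"), "s1", c(900, 1100), c(1000, 1200),
                    c("+", "+"))
  r2 <- distance_to_nearest_tss(data.frame(scaffold = "s1", pos = 1000), gm2)
  expect_equal(r2$gene_id, "gA")
  expect_equal(r2$distance, -100)
  ## gene-free scaffold: absent result
  r3 <- distance_to_nearest_tss(data.frame(scaffold = "s7", pos = 1000), gm)
  expect_true(is.na(r3$gene_id) && is.na(r3$distance))
})

test_that("nearest TSS agrees with exhaustive search and ignores gene order", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    gm <- make_genes(sprintf("g%03d", sample(900, n)),
                     sample(c("s1", "s2"), n, replace = TRUE),
                     s <- sample.int(50000, n),
                     s + sample(500:2000, n, replace = TRUE),
                     sample(c("+", "-"), n, replace = TRUE))
    pts <- data.frame(scaffold = sample(c("s1", "s2"), 40, replace = TRUE),
                      pos = sample.int(52000, 40))
    got <- distance_to_nearest_tss(pts, gm)
    for (i in seq_len(nrow(pts))) {
      want <- bf_nearest_tss(pts$scaffold[i], pts$pos[i], gm)
      expect_identical(got$gene_id[i], want$gene_id)
      expect_identical(as.integer(got$distance[i]),
                       as.integer(want$distance))
    }
    ## permutation invariance
    perm <- sample(n)
    gm_p <- make_genes(gm$genes$gene_id[perm], gm$genes$scaffold[perm],
                       gm$genes$start[perm], gm$genes$end[perm],
                       gm$genes$strand[perm])
    expect_equal(distance_to_nearest_tss(pts, gm_p), got)
  }
})
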