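const_track <- function(value, lens, library_size = 1e6) {
  cov <- lapply(lens, function(L) S4Vectors::Rle(value, L))
  ecdreg:::new_coverage_track(cov, library_size)
}

test_that("union regions merge overlapping peaks but not half-open abutment", {
  a <- peak_frame("s1", 0, 100, "a", 1, 50L)
  b <- peak_frame("s1", 50, 150, "b", 1, 50L)
  r <- union_regions(a, b)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0L, 150L))
  c_ <- peak_frame("s1", 100, 200, "c", 1, 50L)
  r2 <- union_regions(a, c_)
  expect_equal(nrow(r2), 2L)
})

test_that("union regions equal brute-force connected components", {
  set.seed(41)
  for (rep in 1:6) {
    pc <- rand_peaks(40, max_pos = 4000)
    pt <- rand_peaks(40, max_pos = 4000)
    got <- union_regions(pc, pt)
    want <- bf_union_components(rbind(pc[, 1:3], pt[, 1:3]))
    want <- want[order(want$scaffold, want$start), ]
    rownames(want) <- NULL
    expect_equal(got[, c("scaffold", "start", "end")], want)
  }
})

test_that("region signal is the library-scaled per-base mean", {
  lens <- c(s1 = 1000L)
  trk <- const_track(2.0, lens)
  reg <- data.frame(scaffold = "s1", start = 100L, end = 300L)
  expect_equal(region_signal(reg, trk), 2.0)  # identity scaling at 1e6
  expect_equal(region_signal(reg, const_track(0, lens)), 0)
  ## library scaling
  trk2 <- const_track(2.0, lens, library_size = 2e6)
  expect_equal(region_signal(reg, trk2), 1.0)
  expect_error(region_signal(data.frame(scaffold = "s1", start = 900L,
                                        end = 1100L), trk),
               "outside track bounds")
})

test_that("region signal matches direct per-base arithmetic on random tracks", {
  set.seed(42)
  v <- stats::rpois(2000, 4)
  trk <- ecdreg:::new_coverage_track(list(s1 = S4Vectors::Rle(v)))
  for (rep in 1:20) {
    s <- sample(0:1900, 1); e <- s + sample(1:100, 1)
    reg <- data.frame(scaffold = "s1", start = s, end = e)
    expect_equal(region_signal(reg, trk), sum(v[(s + 1):e]) / (e - s))
  }
})

test_that("twofold classification thresholds and pseudocount behave as stated", {
  lens <- c(s1 = 1000L)
  reg <- data.frame(scaffold = "s1", start = 0L, end = 1000L)
  d <- classify_dynamics(reg, const_track(1, lens), const_track(3, lens),
                         pseudocount = 0)
  expect_equal(d$fold_change, 3.0)
  expect_equal(d$klass, "increased")
  d2 <- classify_dynamics(reg, const_track(2, lens), const_track(2, lens))
  expect_equal(d2$klass, "stable")
  ## exactly twofold: stable under the strict rule, increased under >= rule
  d3 <- classify_dynamics(reg, const_track(1, lens), const_track(2, lens),
                          pseudocount = 0)
  expect_equal(d3$klass, "stable")
  d4 <- classify_dynamics(reg, const_track(1, lens), const_track(2, lens),
                          pseudocount = 0, boundary = "inclusive")
  expect_equal(d4$klass, "increased")
  expect_error(classify_dynamics(reg, const_track(1, lens),
                                 const_track(1, lens), pseudocount = -1),
               "non-negative")
})

test_that("classification is anti-symmetric and scale-invariant", {
  set.seed(43)
  lens <- c(s1 = 3000L)
  vc <- stats::rpois(3000, 3); vt <- stats::rpois(3000, 3)
  tc <- ecdreg:::new_coverage_track(list(s1 = S4Vectors::Rle(vc)))
  tt <- ecdreg:::new_coverage_track(list(s1 = S4Vectors::Rle(vt)))
  reg <- data.frame(scaffold = "s1",
                    start = seq(0L, 2800L, by = 100L))
  reg$end <- reg$start + 100L
  fwd <- classify_dynamics(reg, tc, tt)
  rev_ <- classify_dynamics(reg, tt, tc)
  map <- c(increased = "decreased", decreased = "increased",
           stable = "stable")
  expect_equal(rev_$klass, unname(map[fwd$klass]))
  ## multiplying coverage and library size by the same constant fixes folds
  k <- 7
  tck <- ecdreg:::new_coverage_track(list(s1 = S4Vectors::Rle(vc * k)),
                                     library_size = 1e6 * k)
  ttk <- ecdreg:::new_coverage_track(list(s1 = S4Vectors::Rle(vt * k)),
                                     library_size = 1e6 * k)
  expect_equal(classify_dynamics(reg, tck, ttk)$fold_change,
               fwd$fold_change)
})

test_that("presence calls partition each condition and match brute force", {
  set.seed(44)
  pc <- rand_peaks(50, max_pos = 5000)
  pt <- rand_peaks(50, max_pos = 5000)
  pres <- presence_calls(pc, pt)
  expect_equal(sum(pres$condition == "control"), 50L)
  expect_equal(sum(pres$condition == "treated"), 50L)
  want_c <- ifelse(bf_overlap_any(pc, pt), "both", "control_only")
  expect_equal(pres$presence[pres$condition == "control"], want_c)
  ## identity and disjoint edge cases
  same <- presence_calls(pc, pc)
  expect_true(all(same$presence == "both"))
  far <- pc; far$scaffold <- "s9"
  disj <- presence_calls(pc, far)
  expect_true(all(disj$presence != "both"))
})

test_that("DRE acetylation dynamics use the at-least-twofold boundary", {
  lens <- c(s1 = 10000L)
  dres <- data.frame(scaffold = "s1", start = 1000L, end = 2000L,
                     name = "d1", kind = "DRE", nearest_gene = "g1",
                     tss_distance = 5000L, stringsAsFactors = FALSE)
  d <- dre_h3k27ac_dynamics(dres, const_track(1, lens),
                            const_track(5, lens), pseudocount = 0)
  expect_equal(d$klass, "increased")
  z <- dre_h3k27ac_dynamics(dres, const_track(0, lens),
                            const_track(0, lens), pseudocount = 0.1)
  expect_equal(z$fold_change, 1.0)
  expect_equal(z$klass, "stable")
})
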