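test_that("window counting bins variants on the fixed 100-kb grid", {
  v <- variants("Chr1", c(50L, 150000L, 150001L), "A", "G", "hom", 50L)
  tr <- window_counts(v, c(Chr1 = 200000L))
  expect_equal(tr$windows$count, c(1L, 2L))
  expect_false(any(tr$windows$partial))
  # trailing partial window is recorded but flagged
  tr2 <- window_counts(variants(), c(Chr1 = 250000L))
  expect_equal(tr2$windows$count, c(0L, 0L, 0L))
  expect_equal(tr2$windows$partial, c(FALSE, FALSE, TRUE))
  expect_error(window_counts(variants("ChrX", 1L, "A", "G", "hom", 1L),
                             c(Chr1 = 1000L)), "unknown")
})

test_that("window counts equal brute-force binning on random variants", {
  withr::local_seed(31)
  lens <- c(Chr01 = 1000000L, Chr02 = 700001L)
  v <- random_variants(10000, max_pos = 700001L)
  tr <- window_counts(v, lens)
  w <- tr$windows
  brute <- vapply(seq_len(nrow(w)), function(i)
    sum(v$chrom == w$chrom[i] & v$pos >= w$start[i] & v$pos <= w$end[i]), 0L)
  expect_equal(w$count, brute)
  expect_equal(sum(w$count), nrow(v))
})

test_that("five-number summary uses linear interpolation over complete windows", {
  mk <- function(counts, partial = rep(FALSE, length(counts))) {
    structure(list(window_bp = 100000L,
                   windows = data.frame(chrom = "Chr1",
                                        start = seq_along(counts), end = seq_along(counts),
                                        count = counts, partial = partial)),
              class = "density_track")
  }
  expect_equal(five_number(mk(1:9)),
               list(min = 1, q1 = 3, median = 5, q3 = 7, max = 9))
  expect_equal(five_number(mk(rep(4, 4))),
               list(min = 4, q1 = 4, median = 4, q3 = 4, max = 4))
  withr::local_seed(32)
  x <- sample(0:500, 1000, replace = TRUE)
  fn <- five_number(mk(x))
  expect_equal(unlist(fn, use.names = FALSE),
               oracle_quantile7(x, c(0, 0.25, 0.5, 0.75, 1)))
  expect_error(five_number(mk(c(1, 2), partial = c(TRUE, TRUE))), "complete")
})

test_that("region calling flags Tukey-fence outliers and degenerate cases", {
  mk <- function(counts) {
    n <- length(counts)
    structure(list(window_bp = 100000L,
                   windows = data.frame(chrom = "Chr1",
                                        start = (seq_len(n) - 1L) * 100000L + 1L,
                                        end = seq_len(n) * 100000L,
                                        count = counts, partial = FALSE)),
              class = "density_track")
  }
  calls <- call_regions(mk(c(1, 1, 1, 1, 100)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$label, "rich")
  expect_equal(calls$count, 100)
  expect_equal(nrow(call_regions(mk(rep(7, 10)))), 0L)  # IQR = 0, no outliers
  # every call satisfies its fence by construction
  withr::local_seed(33)
  counts <- c(rpois(60, 100), 500, 2)
  calls2 <- call_regions(mk(counts))
  q <- oracle_quantile7(counts, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  expect_true(all(calls2$count[calls2$label == "rich"] > q[2] + 1.5 * iqr))
  expect_true(all(calls2$count[calls2$label == "poor"] < q[1] - 1.5 * iqr))
})

test_that("region calls are scale-equivariant and monotone in the count", {
  mk <- function(counts) {
    n <- length(counts)
    structure(list(window_bp = 100000L,
                   windows = data.frame(chrom = "Chr1",
                                        start = (seq_len(n) - 1L) * 100000L + 1L,
                                        end = seq_len(n) * 100000L,
                                        count = counts, partial = FALSE)),
              class = "density_track")
  }
  withr::local_seed(34)
  counts <- c(rpois(50, 80), 400, 1)
  t1 <- mk(counts); t2 <- mk(counts * 2)
  expect_equal(unlist(five_number(t2)), 2 * unlist(five_number(t1)))
  c1 <- call_regions(t1); c2 <- call_regions(t2)
  expect_equal(c1[, c("chrom", "start", "end", "label")],
               c2[, c("chrom", "start", "end", "label")])
  # raising a called rich window keeps it rich
  counts3 <- counts; counts3[51] <- counts3[51] + 1000
  c3 <- call_regions(mk(counts3))
  expect_true(t1$windows$start[51] %in% c1$start[c1$label == "rich"])
  expect_true(t1$windows$start[51] %in% c3$start[c3$label == "rich"])
})

test_that("planted rich and poor windows are recovered exactly", {
  genome_lens <- c(Chr01 = 2000000L, Chr02 = 2000000L)
  rich <- data.frame(chrom = c("Chr01", "Chr02"), start = c(300001L, 1100001L))
  poor <- data.frame(chrom = "Chr01", start = 1500001L)
  genome <- simulate_genome(genome_lens, seed = 35)
  sv <- simulate_variants(genome, n_snps = 7000L, n_indels = 1000L,
                          cds_indel_frac = 0, rich_tiles = rich,
                          poor_tiles = poor, seed = 35)
  calls <- call_regions(window_counts(sv$variants, genome_lens))
  got_rich <- calls[calls$label == "rich", c("chrom", "start")]
  got_poor <- calls[calls$label == "poor", c("chrom", "start")]
  expect_equal(got_rich, rich[order(rich$chrom, rich$start), ], ignore_attr = TRUE)
  expect_equal(got_poor, poor, ignore_attr = TRUE)
})

test_that("shared regions are the set intersection across samples", {
  tile <- function(chrom, start)
    data.frame(chrom = chrom, start = start, end = start + 99999L,
               label = "rich", count = 1L)
  a <- rbind(tile("Chr10", 2900001L), tile("Chr01", 1L))
  b <- rbind(tile("Chr10", 2900001L), tile("Chr02", 1L))
  c_ <- tile("Chr10", 2900001L)
  sh <- shared_regions(list(a = a, b = b, c = c_), "rich")
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$name, "Chr10:2.9-3.0")
  # a sample lacking the tile excludes it
  expect_equal(nrow(shared_regions(list(a = a, d = tile("Chr05", 1L)), "rich")), 0L)
  # random label sets match the plain set-intersection oracle
  withr::local_seed(36)
  grid <- (0:49) * 100000L + 1L
  sets <- lapply(1:3, function(i) {
    s <- sample(grid, 20)
    do.call(rbind, lapply(s, function(p) tile("Chr01", p)))
  })
  names(sets) <- c("s1", "s2", "s3")
  sh2 <- shared_regions(sets, "rich")
  expect_equal(sort(sh2$start),
               sort(Reduce(intersect, lapply(sets, `[[`, "start"))))
  # mismatched grids are rejected
  bad <- data.frame(chrom = "Chr01", start = 1L, end = 50000L,
                    label = "rich", count = 1L)
  expect_error(shared_regions(list(a = a, bad = bad), "rich"), "grid")
})
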