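test_that("regular-enhancer filter applies the strict >5 kb gap rule", {
  genes <- data.frame(chrom = "chr1", start = 0, end = 10000)
  pk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  expect_equal(nrow(filter_regular_enhancers(pk(20000, 21000), genes)), 1)  # gap 10 kb
  expect_equal(nrow(filter_regular_enhancers(pk(5000, 6000), genes)), 0)    # genic
  expect_equal(nrow(filter_regular_enhancers(pk(15000, 16000), genes)), 0)  # gap exactly 5 kb
  expect_equal(nrow(filter_regular_enhancers(pk(15001, 16000), genes)), 1)  # gap 5001
  expect_equal(nrow(filter_regular_enhancers(pk(10000, 11000), genes)), 0)  # bookended
  # chromosome without genes retains its peaks; empty gene list retains all
  pk2 <- data.frame(chrom = "chr2", start = 0, end = 100)
  expect_equal(nrow(filter_regular_enhancers(pk2, genes)), 1)
  expect_equal(nrow(filter_regular_enhancers(pk2, genes[0, ])), 1)
})

test_that("regular-enhancer filter matches the all-pairs oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:25) {
    peaks <- random_intervals(40)
    genes <- random_intervals(12)
    got <- filter_regular_enhancers(peaks, genes)
    want <- oracle_filter(peaks, genes)
    expect_equal(got, want)
  }
})

test_that("merge_regions handles overlap, bookends and disjoint intervals", {
  iv <- function(...) data.frame(chrom = "chr1", start = c(...)[c(TRUE, FALSE)],
                                 end = c(...)[c(FALSE, TRUE)])
  expect_equal(merge_regions(iv(100, 200, 150, 300))$end, 300)
  expect_equal(nrow(merge_regions(iv(100, 200, 200, 300))), 1)   # bookended
  expect_equal(nrow(merge_regions(iv(100, 200, 400, 500))), 2)
})

test_that("merge_regions is idempotent, order-free and preserves covered bases", {
  set.seed(23)
  for (rep in 1:20) {
    a <- random_intervals(30, max_pos = 50000)
    b <- random_intervals(20, max_pos = 50000)
    m <- merge_regions(a, b)
    expect_equal(m, oracle_merge(rbind(a, b)))
    expect_equal(merge_regions(m), m)                     # idempotent
    expect_equal(merge_regions(b, a), m)                  # commutative
    expect_equal(covered_bases(m), covered_bases(rbind(a, b)))
    expect_true(all(m$start[-1] > m$end[-nrow(m)] | m$chrom[-1] != m$chrom[-nrow(m)]))
  }
})

test_that("quantify_region_signal computes rpm and rpm/bp with background subtraction", {
  # value 2 over [0,1000) plus filler so library_total is 2e6
  tr <- signal_track(data.frame(chrom = c("chr1", "chr9"), start = c(0, 0),
                                end = c(1000, 1998000), value = c(2, 1)))
  expect_equal(library_total(tr), 2e6)
  q <- quantify_region_signal(tr, data.frame(chrom = "chr1", start = 0, end = 500))
  expect_equal(q$rpm, 500)        # raw 1000 / 2e6 * 1e6
  expect_equal(q$rpm_per_bp, 1)
  # region with no overlapping interval -> 0
  q0 <- quantify_region_signal(tr, data.frame(chrom = "chr1", start = 5000, end = 6000))
  expect_equal(q0$rpm, 0)
  # absent chromosome -> 0 with a warning
  expect_warning(
    qa <- quantify_region_signal(tr, data.frame(chrom = "chrX", start = 0, end = 10)),
    "absent")
  expect_equal(qa$rpm, 0)
  # clipped control subtraction
  ctl <- signal_track(data.frame(chrom = c("chr1", "chr9"), start = c(0, 0),
                                 end = c(1000, 399000), value = c(10, 1)))
  qc <- quantify_region_signal(tr, data.frame(chrom = "chr1", start = 0, end = 1000),
                               control = ctl)
  expect_equal(qc$rpm, 0)         # treatment 1000 rpm < control 25000 rpm
})

test_that("rpm is invariant to uniform track rescaling", {
  set.seed(3)
  df <- data.frame(chrom = "chr1", start = seq(0, 9000, 1000),
                   end = seq(500, 9500, 1000), value = stats::runif(10, 1, 5))
  regions <- data.frame(chrom = "chr1", start = c(0, 2000), end = c(1500, 4200))
  q1 <- quantify_region_signal(signal_track(df), regions)
  df2 <- df; df2$value <- df2$value * 2
  q2 <- quantify_region_signal(signal_track(df2), regions)
  expect_equal(q1$rpm, q2$rpm)
})

test_that("build_catalog assembles sample columns and keeps all-zero regions", {
  t1 <- signal_track(data.frame(chrom = "chr1", start = 0, end = 1000, value = 1))
  t2 <- signal_track(data.frame(chrom = "chr1", start = 500, end = 1500, value = 2))
  regions <- data.frame(chrom = "chr1", start = c(0, 2000, 900), end = c(400, 3000, 1200))
  cat <- build_catalog(list(A = t1, B = t2), regions)
  expect_equal(dim(cat$rpm), c(3L, 2L))
  expect_equal(colnames(cat$rpm), c("A", "B"))
  expect_equal(cat$regions$start, c(0, 900, 2000))          # sorted
  expect_true(any(rowSums(cat$rpm) == 0))                   # zero row retained
  expect_error(build_catalog(list(K562 = t1, K562 = t2), regions), "duplicate")
  # catalog TSV round trip
  f <- tempfile(fileext = ".tsv")
  write_catalog(cat, f)
  cat2 <- read_catalog(f)
  expect_equal(cat2$rpm, cat$rpm, tolerance = 1e-12)
})

test_that("pca_samples matches an eigendecomposition oracle and reports variance", {
  set.seed(5)
  rpm <- matrix(stats::rexp(40, 1 / 50), nrow = 10,
                dimnames = list(NULL, NULL))
  regions <- data.frame(chrom = "chr1", start = seq(0, 9000, 1000),
                        end = seq(500, 9500, 1000))
  cat <- build_catalog_from_matrix(rpm, regions, paste0("s", 1:4))
  p <- pca_samples(cat, top_k = 10)
  want <- oracle_pca_coords(cat$rpm, 10)
  for (k in seq_len(ncol(p$coordinates))) {
    expect_lt(min(max(abs(p$coordinates[, k] - want[, k])),
                  max(abs(p$coordinates[, k] + want[, k]))), 1e-8)
  }
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_lte(sum(p$variance_fraction), 1 + 1e-9)
  expect_equal(p$k_regions_used, 10)
  # top_k larger than region count uses all regions
  expect_equal(pca_samples(cat, top_k = 999)$k_regions_used, 10)
})

test_that("pca_samples separates two groups with a planted shift and rejects degenerate input", {
  regions <- data.frame(chrom = "chr1", start = seq(0, 19000, 1000),
                        end = seq(500, 19500, 1000))
  base <- stats::rexp(20, 1 / 100)
  rpm <- cbind(base, base, base, base * 4, base * 4, base * 4)
  cat <- build_catalog_from_matrix(rpm, regions, c(paste0("p", 1:3), paste0("r", 1:3)))
  p <- pca_samples(cat, top_k = 20)
  pc1 <- p$coordinates[, 1]
  expect_true(all(sign(pc1[1:3]) == -sign(pc1[4:6])))
  expect_equal(p$variance_fraction[1], 1.0, tolerance = 1e-9)
  # constant matrix and single sample are errors
  flat <- build_catalog_from_matrix(matrix(1, 5, 3), regions[1:5, ], paste0("s", 1:3))
  expect_error(pca_samples(flat), "no-variance")
  one <- build_catalog_from_matrix(matrix(1:5, 5, 1), regions[1:5, ], "s1")
  expect_error(pca_samples(one), "2 samples")
})
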