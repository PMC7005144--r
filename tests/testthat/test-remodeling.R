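make_pair_catalog <- function(k27_res, k27_par, brd4_res, brd4_par) {
  n <- length(k27_res)
  regions <- data.frame(chrom = "chr1", start = seq_len(n) * 10000,
                        end = seq_len(n) * 10000 + 1000)
  build_catalog_from_matrix(
    cbind(k27_res, k27_par, brd4_res, brd4_par), regions,
    c("k27_res", "k27_par", "brd4_res", "brd4_par"))
}

test_that("log2_fold_change applies the pseudocount rule", {
  expect_equal(log2_fold_change(4, 1, 1), log2(5 / 2))
  expect_equal(log2_fold_change(3.7, 3.7), 0)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(-1, 2), ">= 0")
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "> 0")
})

test_that("classify_regions encodes the quadrant rules", {
  # rpm values engineered to hit each class with pseudocount 1, t = 1
  cat <- make_pair_catalog(
    k27_res = c(15, 15, 3, 5, 0),
    k27_par = c(3, 3, 15, 5, 0),
    brd4_res = c(1, 15, 1, 9, 2),
    brd4_par = c(3, 3, 3, 9, 2))
  tab <- classify_regions(cat, c("k27_res", "k27_par"), c("brd4_res", "brd4_par"))
  expect_equal(as.character(tab$class),
               c("GAINED_BRD4_INDEPENDENT",   # k27 +2, brd4 -1
                 "GAINED_BRD4_DEPENDENT",     # k27 +2, brd4 +2
                 "LOST",                      # k27 -2
                 "UNCHANGED",                 # k27 0
                 "UNCHANGED"))                # both zero rpm
  expect_error(classify_regions(cat, c("a", "b"), c("brd4_res", "brd4_par")),
               "unknown sample")
})

test_that("borderline fold changes respect threshold boundaries", {
  # lfc_k27 exactly +t counts as gained; |lfc| < t unchanged; brd4 at +t dependent
  cat <- make_pair_catalog(
    k27_res = c(7, 6.9, 7),
    k27_par = c(3, 3, 3),
    brd4_res = c(7, 1, 6.9),
    brd4_par = c(3, 1, 3))
  tab <- classify_regions(cat, c("k27_res", "k27_par"), c("brd4_res", "brd4_par"))
  expect_equal(as.character(tab$class)[1], "GAINED_BRD4_DEPENDENT")  # both exactly +1
  expect_equal(as.character(tab$class)[2], "UNCHANGED")
  expect_equal(as.character(tab$class)[3], "GAINED_BRD4_INDEPENDENT")  # brd4 just below t
})

test_that("classification is antisymmetric under condition swap", {
  set.seed(13)
  n <- 200
  cat <- make_pair_catalog(stats::rexp(n, 1 / 50), stats::rexp(n, 1 / 50),
                           stats::rexp(n, 1 / 50), stats::rexp(n, 1 / 50))
  fwd <- classify_regions(cat, c("k27_res", "k27_par"), c("brd4_res", "brd4_par"))
  rev <- classify_regions(cat, c("k27_par", "k27_res"), c("brd4_par", "brd4_res"))
  expect_equal(rev$lfc_k27, -fwd$lfc_k27)
  expect_equal(rev$lfc_brd4, -fwd$lfc_brd4)
  gained <- grepl("^GAINED", fwd$class)
  expect_true(all(rev$class[gained] == "LOST"))
  lost <- fwd$class == "LOST"
  expect_true(all(grepl("^GAINED", rev$class[lost])))
})

test_that("class_fractions partitions to 1 over either denominator", {
  cat <- make_pair_catalog(
    k27_res = c(15, 15, 3, 5), k27_par = c(3, 3, 15, 5),
    brd4_res = c(1, 15, 1, 9), brd4_par = c(3, 3, 3, 9))
  tab <- classify_regions(cat, c("k27_res", "k27_par"), c("brd4_res", "brd4_par"))
  fr_diff <- class_fractions(tab, "all_differential")
  expect_equal(sum(fr_diff), 1, tolerance = 1e-12)
  expect_equal(unname(fr_diff["GAINED_BRD4_INDEPENDENT"]), 1 / 3)
  fr_all <- class_fractions(tab, "all_regions")
  expect_equal(sum(fr_all), 1, tolerance = 1e-12)
  expect_equal(unname(fr_all[["UNCHANGED"]]), 1 / 4)
  # all-UNCHANGED table has an empty differential denominator
  flat <- classify_regions(make_pair_catalog(c(5, 5), c(5, 5), c(5, 5), c(5, 5)),
                           c("k27_res", "k27_par"), c("brd4_res", "brd4_par"))
  expect_error(class_fractions(flat, "all_differential"), "empty denominator")
})

test_that("distance_to_nearest_tss uses midpoints and reports undefined regions", {
  genes <- data.frame(chrom = "chr1", start = 1000, end = 5000, strand = "+")
  d <- distance_to_nearest_tss(
    data.frame(chrom = "chr1", start = 30500, end = 31500), genes)
  expect_equal(d$distances, 30000)   # midpoint 31000 vs TSS 1000
  expect_equal(d$mean_bp, 30000)
  # TSS at midpoint -> 0
  d0 <- distance_to_nearest_tss(
    data.frame(chrom = "chr1", start = 500, end = 1500), genes)
  expect_equal(d0$distances, 0)
  # region on a chromosome without genes: NA, counted as undefined
  dm <- distance_to_nearest_tss(
    data.frame(chrom = c("chr1", "chr2"), start = c(30500, 0), end = c(31500, 100)),
    genes)
  expect_equal(dm$n_undefined, 1)
  expect_true(is.na(dm$distances[2]))
  expect_equal(sum(dm$histogram$counts), 1)  # only defined distances binned
  expect_error(distance_to_nearest_tss(
    data.frame(chrom = "chr3", start = 0, end = 10), genes), "chromosome")
  expect_error(distance_to_nearest_tss(
    data.frame(chrom = "chr1", start = 0, end = 10), genes[0, ]), "no genes")
})

test_that("distance_to_nearest_tss matches the all-pairs oracle", {
  set.seed(19)
  for (rep in 1:20) {
    regions <- random_intervals(50)
    genes <- random_genes(15)
    got <- distance_to_nearest_tss(regions, genes)
    expect_equal(got$distances, oracle_distance(regions, genes))
    n_def <- sum(!is.na(got$distances))
    expect_equal(sum(got$histogram$counts), n_def)
    expect_equal(got$mean_bp, mean(got$distances, na.rm = TRUE))
  }
})
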