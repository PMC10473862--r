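test_that("normalized coverage ratios follow the arithmetic definition", {
  # uniform coverage: every ratio is exactly 1
  d <- exact_depth(rate = 0.05)
  r <- normalize_depth(d)
  expect_equal(unname(r[as.character(1:22)]), rep(1, 22))
  expect_equal(unname(r["Y"]), 0)  # zero reads on Y

  # chr21 at a 1.5x rate over the diploid baseline on noiseless counts
  copies <- c(stats::setNames(rep(2, 22), as.character(1:22)), X = 2, Y = 0)
  copies["21"] <- 3
  d3 <- exact_depth(rate = 0.05, copies = copies)
  r3 <- normalize_depth(d3)
  expect_equal(unname(r3["21"] / r3["1"]), 1.5)

  # site-weighted mean autosomal ratio is 1 by construction
  set.seed(5)
  sim <- simulate_depth_table("XY", coverage = 0.05, seed = 5)
  rr <- normalize_depth(sim)
  auto <- sim$chromosome %in% as.character(1:22)
  w <- sim$sites[auto] / sum(sim$sites[auto])
  expect_equal(sum(w * rr[sim$chromosome[auto]]), 1, tolerance = 1e-12)

  # zero autosomal reads is an explicit insufficient-data error
  d0 <- depth_table("z", as.character(1:22), reads = rep(0, 22),
                    sites = rep(100, 22))
  expect_error(normalize_depth(d0), "insufficient")
})

test_that("ratios, z-scores and calls are scale invariant", {
  rs <- exact_reference_stats()
  d1 <- simulate_depth_table("XYY+21", coverage = 0.05, seed = 11)
  d10 <- depth_table(attr(d1, "sample"), d1$chromosome, d1$reads * 10,
                     d1$sites)
  p1 <- estimate_ploidy(d1, rs)
  p10 <- estimate_ploidy(d10, rs)
  expect_equal(p1$ratio, p10$ratio)
  expect_equal(p1$z, p10$z)
  expect_identical(p1$copies, p10$copies)
  expect_identical(p1$flagged, p10$flagged)
})

test_that("XX and XY references yield the same per-copy X expectation", {
  sm <- default_site_map(200000)
  xx <- lapply(1:12, function(i) simulate_depth_table("XX", sm, 2, seed = i,
                                                      sample = paste0("a", i)))
  xy <- lapply(1:12, function(i) simulate_depth_table("XY", sm, 2,
                                                      seed = 100 + i,
                                                      sample = paste0("b", i)))
  kt <- stats::setNames(c(rep("XX", 12), rep("XY", 12)),
                        c(paste0("a", 1:12), paste0("b", 1:12)))
  # an all-XX set carries no Y information: Y is dropped with a warning
  expect_warning(rs_xx <- build_reference_stats(xx, kt), "chromosome Y")
  rs_xy <- build_reference_stats(xy, kt)
  expect_false("Y" %in% rs_xx$chromosome)
  x_xx <- rs_xx$per_copy_mean[rs_xx$chromosome == "X"]
  x_xy <- rs_xy$per_copy_mean[rs_xy$chromosome == "X"]
  expect_equal(x_xx, x_xy, tolerance = 0.01)
  expect_equal(x_xx, 0.5, tolerance = 0.01)
})

test_that("reference-set preconditions are enforced", {
  d <- simulate_depth_table("XX", coverage = 0.1, seed = 1, sample = "solo")
  expect_error(build_reference_stats(list(d), c(solo = "XX")), "at least 2")
  # zero SD from noiseless duplicated references
  e1 <- exact_depth("e1", rate = 0.05,
                    copies = c(stats::setNames(rep(2, 22),
                                               as.character(1:22)),
                               X = 2, Y = 0))
  e2 <- exact_depth("e2", rate = 0.07,
                    copies = c(stats::setNames(rep(2, 22),
                                               as.character(1:22)),
                               X = 2, Y = 0))
  # identical per-copy ratios (scale invariance) -> sd 0 -> error
  expect_error(
    suppressWarnings(build_reference_stats(list(e1, e2),
                                           c(e1 = "XX", e2 = "XX"))),
    "zero coverage-ratio SD")
  # references with Poisson noise give positive SD everywhere
  ref <- simulated_reference_set(site_map = default_site_map(100000),
                                 coverage = 0.1, seed = 40)
  rs <- build_reference_stats(ref$refs, ref$karyotypes)
  expect_true(all(rs$per_copy_sd > 0))
  expect_true(all(rs$n_ref >= 10))
})

test_that("copy numbers and z-scores recover constructed karyotypes", {
  rs <- exact_reference_stats()  # exact per-copy mean 0.5
  # noiseless diploid: all autosomal copies 2, z exactly 0
  d <- exact_depth(rate = 0.05,
                   copies = c(stats::setNames(rep(2, 22),
                                              as.character(1:22)),
                              X = 2, Y = 0))
  p <- estimate_ploidy(d, rs)
  auto <- p$chromosome %in% as.character(1:22)
  expect_true(all(p$copies[auto] == 2L))
  expect_equal(p$z[auto], rep(0, 22))
  expect_false(any(p$flagged))

  # X at one per-copy unit, Y at two per-copy units -> X=1, Y=2 (XYY)
  copies <- c(stats::setNames(rep(2, 22), as.character(1:22)), X = 1, Y = 2)
  pxyy <- estimate_ploidy(exact_depth(rate = 0.05, copies = copies), rs)
  expect_equal(pxyy$copies[pxyy$chromosome == "X"], 1L)
  expect_equal(pxyy$copies[pxyy$chromosome == "Y"], 2L)

  # a chromosome missing from the reference stats is an error
  rs_nox <- rs[rs$chromosome != "X", ]
  class(rs_nox) <- class(rs)
  expect_error(estimate_ploidy(d, rs_nox), "no reference statistics")
})

test_that("simulated trisomy 21 at 0.05x is called and flagged", {
  ref <- simulated_reference_set(seed = 70)
  rs <- build_reference_stats(ref$refs, ref$karyotypes)
  d <- simulate_depth_table("XX+21", coverage = 0.05, seed = 71)
  p <- estimate_ploidy(d, rs)
  expect_equal(p$copies[p$chromosome == "21"], 3L)
  expect_true(p$flagged[p$chromosome == "21"])
  k <- call_karyotype(p)
  expect_equal(k$autosomal_trisomies, "21")
  expect_equal(k$gonosomal, "XX")
})

test_that("karyotype strings assemble from gonosomal copies", {
  rs <- exact_reference_stats()
  mk <- function(nx, ny) {
    copies <- c(stats::setNames(rep(2, 22), as.character(1:22)),
                X = nx, Y = ny)
    call_karyotype(estimate_ploidy(exact_depth(rate = 0.05, copies = copies),
                                   rs))
  }
  xyy <- mk(1, 2)
  expect_equal(xyy$gonosomal, "XYY")
  expect_equal(xyy$genetic_sex, "M")
  xx <- mk(2, 0)
  expect_equal(xx$gonosomal, "XX")
  expect_equal(xx$genetic_sex, "F")
  x0 <- mk(1, 0)
  expect_equal(x0$gonosomal, "X0")
  expect_equal(x0$genetic_sex, "undetermined")

  # below the gonosomal read floor the call degrades to undetermined
  copies <- c(stats::setNames(rep(2, 22), as.character(1:22)), X = 2, Y = 0)
  thin <- exact_depth(rate = 0.0004, copies = copies,
                      sites = stats::setNames(rep(10000, 24),
                                              names(copies)))
  kth <- call_karyotype(estimate_ploidy(thin, rs), min_reads = 100)
  expect_equal(kth$gonosomal, "undetermined")
  expect_equal(kth$genetic_sex, "undetermined")
  expect_false(kth$min_informative)
})

test_that("correct-call rate does not decrease with coverage", {
  ref <- simulated_reference_set(site_map = default_site_map(),
                                 coverage = 0.1, seed = 300)
  rs <- build_reference_stats(ref$refs, ref$karyotypes)
  sm <- default_site_map()
  rate_at <- function(cov, n_rep = 15) {
    ok <- vapply(seq_len(n_rep), function(i) {
      d <- simulate_depth_table("XYY", sm, coverage = cov,
                                seed = 1000 * cov * 1000 + i, sample = "t")
      k <- call_karyotype(estimate_ploidy(d, rs))
      k$gonosomal == "XYY" && length(k$autosomal_trisomies) == 0 &&
        length(k$autosomal_monosomies) == 0
    }, logical(1))
    mean(ok)
  }
  rates <- vapply(c(0.005, 0.01, 0.05, 0.1), rate_at, numeric(1))
  # non-decreasing within binomial noise at 15 replicates (one step slack)
  expect_true(all(diff(rates) >= -1 / 15))
  expect_gte(rates[4], 0.95)
})

test_that("karyotype parsing covers gonosomal and autosomal tokens", {
  expect_equal(parse_karyotype("XY")[["X"]], 1)
  expect_equal(parse_karyotype("XY")[["Y"]], 1)
  expect_equal(parse_karyotype("X0")[["Y"]], 0)
  expect_equal(parse_karyotype("XXY")[["X"]], 2)
  expect_equal(parse_karyotype("trisomy-21")[["21"]], 3)
  expect_equal(parse_karyotype("XY+21")[["21"]], 3)
  expect_equal(parse_karyotype("XX-18")[["18"]], 1)
  expect_error(parse_karyotype("ZZ"), "cannot parse")
  expect_error(parse_karyotype("XY+23"), "unknown autosome")
})
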