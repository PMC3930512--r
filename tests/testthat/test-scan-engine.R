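# Trait transform, HK/EM scans, permutation thresholds, P/q values,
# support intervals.

test_that("normal quantile rank transform matches closed-form quantiles", {
  out <- nqrank(c(3, 1, 2))
  expect_equal(out, qnorm(c(5 / 6, 1 / 6, 0.5)), tolerance = 1e-10)
  expect_equal(out[3], 0)

  x <- rnorm(101)
  tr <- nqrank(x)
  expect_identical(order(tr), order(x))         # rank preserving
  expect_equal(mean(tr), 0, tolerance = 1e-10)  # symmetric grid
  expect_equal(sort(tr), sort(-tr), tolerance = 1e-10)

  withna <- c(5, NA, 1, 3)
  expect_true(is.na(nqrank(withna)[2]))
  expect_warning(z <- nqrank(rep(2, 5)), "identical")
  expect_equal(z, rep(0, 5))
  expect_error(nqrank(c(1, NA, NA)), "3 non-missing")
})

scan_fixture <- function(n = 200, seed = 101, n_auto = 2, x_length = 40) {
  map <- simulate_map(n_auto, lengths = rep(60, n_auto), marker_spacing = 10,
                      x_length = x_length)
  cross <- simulate_f2(map, n, seed = seed)
  gp <- calc_genoprob(cross, step = 2, error_rate = 0,
                      map_function = "haldane")
  list(map = map, cross = cross, gp = gp)
}

test_that("HK LOD equals the closed-form least-squares LOD at typed markers", {
  # the 6-individual worked example: dosages (0,0,1,1,2,2)
  map <- genetic_map(tibble::tibble(chr = "1", marker = c("m1", "m2"),
                                    cM = c(0, 20)))
  codes <- c("AA", "AA", "AB", "AB", "BB", "BB")
  geno <- cbind(m1 = codes, m2 = rev(codes))
  rownames(geno) <- paste0("i", 1:6)
  cross <- f2_cross(map, tibble::tibble(id = rownames(geno),
                                        cross_direction = "DxM"), geno)
  gp <- calc_genoprob(cross, step = 2, error_rate = 0)
  y <- setNames(c(0.0, 0.2, 1.0, 1.1, 2.0, 2.3), rownames(geno))
  sc <- scan_single(y, gp)
  j <- which(sc$marker == "m1")
  expect_equal(sc$lod[j], lm_lod(y, codes), tolerance = 1e-8)

  # random fixtures
  fx <- scan_fixture(n = 40, seed = 7, n_auto = 1, x_length = NULL)
  set.seed(8)
  for (i in 1:5) {
    y <- setNames(rnorm(40), fx$gp$ind)
    sc <- scan_single(y, fx$gp)
    for (mk in c("c1m01", "c1m04")) {
      expect_equal(sc$lod[which(sc$marker == mk)],
                   lm_lod(y, fx$cross$geno[, mk]), tolerance = 1e-8)
    }
  }
})

test_that("EM and HK agree at fully typed markers and nest correctly", {
  fx <- scan_fixture(n = 120, seed = 9, n_auto = 1, x_length = 40)
  set.seed(10)
  g <- fx$cross$geno[, "c1m03"]
  y <- setNames(0.8 * (match(g, c("AA", "AB", "BB")) - 1) + rnorm(120),
                fx$gp$ind)
  hk <- scan_single(y, fx$gp, method = "hk")
  em <- scan_single(y, fx$gp, method = "em")
  typed <- !is.na(hk$marker)
  expect_lt(max(abs(hk$lod[typed] - em$lod[typed])), 0.01)

  # nested covariate models: LOD(full) >= LOD(additive) - 1e-6 everywhere
  add <- scan_single(y, fx$gp, covariate = "cXm02",
                     covariate_model = "additive")
  full <- scan_single(y, fx$gp, covariate = "cXm02",
                      covariate_model = "full")
  expect_true(all(full$lod - add$lod >= -1e-6))

  # a perfect fit is flagged as degenerate and capped
  y2 <- setNames(match(g, c("AA", "AB", "BB")) - 1, fx$gp$ind)
  expect_warning(sc2 <- scan_single(y2, fx$gp), "zero residual variance")
  expect_true(all(is.finite(sc2$lod)))
})

test_that("null traits rarely clear the threshold; real QTL are found", {
  fx <- scan_fixture(n = 300, seed = 12, n_auto = 3, x_length = NULL)
  set.seed(13)
  mx <- replicate(10, max(scan_single(setNames(rnorm(300), fx$gp$ind),
                                      fx$gp)$lod))
  expect_lt(median(mx), 4)

  g <- match(fx$cross$geno[, "c2m04"], c("AA", "AB", "BB")) - 1
  y <- setNames(scale(g)[, 1] * 1.0 + rnorm(300), fx$gp$ind)
  sc <- scan_single(nqrank(y), fx$gp)
  pk <- glance(sc)
  expect_equal(pk$peak_chr, "2")
  expect_lt(abs(pk$peak_pos - 30), 15)
  expect_gt(pk$peak_lod, 4)
})

test_that("permutation thresholds are deterministic with quantile identities", {
  fx <- scan_fixture(n = 100, seed = 14)
  y <- setNames(rnorm(100), fx$gp$ind)
  th1 <- permutation_threshold(y, fx$gp, n_perm = 50, seed = 3,
                               n_perm_x = 50)
  th2 <- permutation_threshold(y, fx$gp, n_perm = 50, seed = 3,
                               n_perm_x = 50)
  expect_identical(glance(th1), glance(th2))
  # alpha -> 1 gives the minimum of the null distribution (single stratum)
  fx_a <- scan_fixture(n = 100, seed = 14, x_length = NULL)
  y_a <- setNames(rnorm(100), fx_a$gp$ind)
  th_all <- permutation_threshold(y_a, fx_a$gp, n_perm = 50, seed = 3,
                                  alpha = 0.999999)
  expect_equal(th_all$autosome, min(th_all$null$autosome))
  # X permutation count scales with the autosome/X length ratio
  th3 <- permutation_threshold(y, fx$gp, n_perm = 40, seed = 3)
  expect_equal(th3$n_perm_x, round(40 * 120 / 40))
})

test_that("larger genomes give larger thresholds on average", {
  fx_small <- scan_fixture(n = 100, seed = 15, n_auto = 1, x_length = NULL)
  fx_big <- scan_fixture(n = 100, seed = 15, n_auto = 6, x_length = NULL)
  y <- setNames(rnorm(100), fx_small$gp$ind)
  th_s <- permutation_threshold(y, fx_small$gp, n_perm = 200, seed = 4)
  names(y) <- fx_big$gp$ind
  th_b <- permutation_threshold(y, fx_big$gp, n_perm = 200, seed = 4)
  expect_gt(th_b$autosome, th_s$autosome)
})

test_that("dataset-wide thresholds dominate single-transcript thresholds", {
  fx <- scan_fixture(n = 100, seed = 16)
  set.seed(17)
  Y <- matrix(rnorm(100 * 50), 100, 50,
              dimnames = list(fx$gp$ind, sprintf("t%02d", 1:50)))
  dt <- dataset_threshold(Y, fx$gp, n_perm = 100, seed = 5)
  st <- permutation_threshold(setNames(Y[, 1], fx$gp$ind), fx$gp,
                              n_perm = 100, seed = 5, n_perm_x = 100)
  expect_gte(dt$autosome, st$autosome)
  expect_gte(dt$x, st$x)
  dt2 <- dataset_threshold(Y, fx$gp, n_perm = 100, seed = 5)
  expect_identical(glance(dt), glance(dt2))
})

test_that("permutation P values and Storey q-values behave", {
  null <- list(autosome = sort(runif(199, 0, 3)), x = numeric())
  thr <- structure(list(null = null), class = "perm_thresholds")
  maxima <- tibble::tibble(trait = c("a", "b"), chr = "1",
                           kind = "autosome", lod = c(10, 0))
  out <- lod_to_pq(maxima, thr)
  expect_equal(out$p[1], 1 / 200)  # above every null value
  expect_equal(out$p[2], 1)
  expect_true(all(diff(out$q[order(out$p)]) >= 0))

  set.seed(18)
  p <- runif(1000)
  qv <- storey_qvalue(p)
  expect_gt(qv$pi0, 0.8)
  expect_lte(qv$pi0, 1)
  o <- order(p)
  expect_true(all(diff(qv$qvalue[o]) >= -1e-12))
})

test_that("LOD support intervals follow the outermost-position rule", {
  mk_scan <- function(lod, pos = c(0, 10, 20, 30, 40)) {
    structure(tibble::tibble(chr = "1", kind = "autosome", pos = pos,
                             marker = NA_character_, lod = lod),
              class = c("qtl_scan", class(tibble::tibble())))
  }
  iv <- lod_support_interval(mk_scan(c(1, 3, 5, 3, 1)), "1")
  expect_equal(c(iv$lo, iv$hi), c(10, 30))
  # peak at chromosome end is clipped
  iv2 <- lod_support_interval(mk_scan(c(5, 4.8, 1, 1, 1)), "1")
  expect_equal(iv2$lo, 0)
  # two-peak profile: outermost positions above the drop span both peaks
  iv3 <- lod_support_interval(mk_scan(c(1, 5, 1, 4.8, 1),
                                      pos = c(0, 20, 40, 60, 80)), "1")
  expect_equal(c(iv3$lo, iv3$hi), c(0, 80))
  expect_warning(iv4 <- lod_support_interval(mk_scan(rep(0, 5)), "1"), "flat")
  expect_equal(c(iv4$lo, iv4$hi), c(0, 40))
})
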