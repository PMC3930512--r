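# Conditional scans, interaction thresholds, interaction eQTL, network.

int_fixture <- function(n = 300, seed = 71) {
  map <- simulate_map(4, lengths = rep(60, 4), marker_spacing = 10,
                      x_length = NULL)
  cross <- simulate_f2(map, n, seed = seed)
  gp <- calc_genoprob(cross, step = 2, error_rate = 0,
                      map_function = "haldane")
  list(map = map, cross = cross, gp = gp)
}

test_that("conditional scan is the paired difference with a self mask", {
  fx <- int_fixture(n = 200)
  set.seed(72)
  y <- setNames(rnorm(200), fx$gp$ind)
  cs <- conditional_scan(y, fx$gp, "c2m03")
  expect_equal(cs$lod_i[!cs$masked], (cs$lod_f - cs$lod_a)[!cs$masked])
  expect_true(all(is.na(cs$lod_i[cs$masked])))
  expect_true(all(cs$masked[cs$chr == "2" & abs(cs$pos - 20) < 5]))
  expect_true(all(cs$lod_i >= -1e-6, na.rm = TRUE))

  # purely additive covariate effect -> LOD_i small everywhere and no
  # interaction eQTL called
  g <- match(fx$cross$geno[, "c2m03"], c("AA", "AB", "BB")) - 1
  y2 <- setNames(g * 1.5 + rnorm(200, 0, 0.5), fx$gp$ind)
  cs2 <- conditional_scan(y2, fx$gp, "c2m03")
  expect_lt(max(cs2$lod_i, na.rm = TRUE), 2.5)
  ith2 <- interaction_thresholds(y2, fx$gp, "c2m03", n_perm = 100, seed = 81)
  expect_equal(nrow(call_interaction_eqtl(cs2, ith2)), 0)
})

test_that("pure epistasis is invisible marginally but found conditionally", {
  fx <- int_fixture(n = 300, seed = 73)
  g1 <- match(fx$cross$geno[, "c1m03"], c("AA", "AB", "BB")) - 2  # -1,0,1
  g2 <- match(fx$cross$geno[, "c3m03"], c("AA", "AB", "BB")) - 2
  set.seed(74)
  y <- setNames(1.5 * g1 * g2 + rnorm(300, 0, 1), fx$gp$ind)
  y <- nqrank(y)
  # marginal scan: nothing at the partner locus
  marg <- scan_single(y, fx$gp)
  thr <- permutation_threshold(y, fx$gp, n_perm = 100, seed = 75)
  expect_lt(max(marg$lod[marg$chr == "3"]), thr$autosome + 1)
  # conditional on one locus, the partner shows a strong interaction LOD
  cs <- conditional_scan(y, fx$gp, "c1m03")
  ith <- interaction_thresholds(y, fx$gp, "c1m03", n_perm = 100, seed = 76)
  rec <- call_interaction_eqtl(cs, ith, trait = "t1")
  expect_true("3" %in% rec$chr)
  expect_lt(abs(rec$pos[rec$chr == "3"] - 20), 15)
})

test_that("interaction thresholds pair full/additive scans per permutation", {
  fx <- int_fixture(n = 150, seed = 77)
  set.seed(78)
  y <- setNames(rnorm(150), fx$gp$ind)
  ith <- interaction_thresholds(y, fx$gp, "c2m03", n_perm = 100, seed = 79)
  ith2 <- interaction_thresholds(y, fx$gp, "c2m03", n_perm = 100, seed = 79)
  expect_identical(ith$f, ith2$f)
  expect_identical(ith$i, ith2$i)
  # by construction each permutation's interaction max cannot exceed its
  # full-model max (lod_i <= lod_f pointwise when lod_a >= 0)
  nn <- ith$null$autosome
  expect_equal(length(nn$i), 100)
  expect_true(all(nn$i <= nn$f + 1e-9))
})

test_that("interaction eQTL calls require both exceedances", {
  mk_cond <- function(lod_f, lod_i) {
    structure(tibble::tibble(chr = "1", kind = "autosome",
                             pos = seq(0, 40, 10), marker = NA,
                             lod_f = lod_f, lod_a = lod_f - lod_i,
                             lod_i = lod_i, masked = FALSE),
              class = c("cond_scan", class(tibble::tibble())),
              covariate = "cov1")
  }
  thr <- structure(list(f = c(autosome = 6, X = NA),
                        i = c(autosome = 3.5, X = NA)),
                   class = "interaction_thresholds")
  both <- mk_cond(c(1, 9, 2, 1, 1), c(1, 4, 1, 1, 1))
  expect_equal(nrow(call_interaction_eqtl(both, thr)), 1)
  expect_equal(call_interaction_eqtl(both, thr)$pos, 10)
  no_i <- mk_cond(c(1, 9, 2, 1, 1), c(1, 2, 1, 1, 1))
  expect_equal(nrow(call_interaction_eqtl(no_i, thr)), 0)
  no_f <- mk_cond(c(1, 5, 2, 1, 1), c(1, 4, 1, 1, 1))
  expect_equal(nrow(call_interaction_eqtl(no_f, thr)), 0)
})

test_that("network nodes merge below the Mb distance and flag reciprocity", {
  tbl <- tibble::tibble(
    covariate = c("cvA", "cvA", "cvB"),
    covariate_chr = c("2", "2", "7"),
    covariate_mb = c(50, 50, 123),
    chr = c("7", "7", "2"),
    lo_mb = c(122.6, 124.0, 48),
    hi_mb = c(125.8, 126.5, 52),
    count = c(10L, 5L, 7L))
  net <- build_network(tbl, merge_mb = 12.8,
                       sterile_alleles = c(cvA = "B"))
  # chr7 regions (hotspots + covariate cvB) merge into one node
  expect_equal(sum(net$nodes$chr == "7"), 1)
  expect_equal(sum(net$nodes$chr == "2"), 1)
  # A -> B and B -> A present: both edges flagged reciprocal
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$reciprocal))
  expect_equal(sum(net$edges$count), 22)
  expect_equal(net$nodes$sterile_allele[net$nodes$chr == "2"], "B")

  # merge is order-independent
  set.seed(80)
  for (i in 1:5) {
    net_i <- build_network(tbl[sample(nrow(tbl)), ], merge_mb = 12.8)
    expect_setequal(net_i$nodes$node, net$nodes$node)
  }
  # far-apart regions stay separate
  tbl2 <- tbl
  tbl2$lo_mb[2] <- 150; tbl2$hi_mb[2] <- 155
  net2 <- build_network(tbl2, merge_mb = 12.8)
  expect_equal(sum(net2$nodes$chr == "7"), 2)
})

test_that("covariate summaries match a hand-traced fixture", {
  covariate_pos <- tibble::tibble(marker = c("cvA", "cvB"),
                                  chr = c("2", "7"), pos = c(50, 20))
  records <- tibble::tibble(trait = c("p1", "p2", "p3", "p4"),
                            covariate = "cvA", chr = c("7", "7", "5", "5"),
                            kind = "autosome", pos = c(20, 22, 10, 30),
                            lod_f = 8, lod_i = 4)
  # original catalogue: p1 has an eQTL at the covariate, p3 at its own peak
  original <- tibble::tibble(trait = c("p1", "p3"), chr = c("2", "5"),
                             pos = c(51, 11))
  # reversed configuration exists for p1 (covariate cvB at chr7@20,
  # peak back at cvA's position)
  all_records <- dplyr::bind_rows(
    records,
    tibble::tibble(trait = "p1", covariate = "cvB", chr = "2",
                   kind = "autosome", pos = 49, lod_f = 7, lod_i = 4))
  smry <- covariate_summary(records, original, all_records, covariate_pos,
                            hotspots = NULL, window = 5)
  expect_equal(smry$n_interaction_eqtl, 4L)
  expect_equal(smry$pct_covariate_marginal, 25)
  expect_equal(smry$pct_peak_marginal, 25)
  expect_equal(smry$pct_reciprocal, 25)
  empty <- covariate_summary(records[0, ], original, all_records,
                             covariate_pos)
  expect_equal(empty$n_interaction_eqtl, 0L)
  expect_equal(empty$pct_reciprocal, 0)
})

test_that("interaction hotspots delegate to the sliding-window machinery", {
  map <- simulate_map(4, lengths = rep(60, 4), marker_spacing = 10,
                      x_length = NULL)
  probes <- tibble::tibble(probe_id = sprintf("p%02d", 1:40),
                           chr = "4", cM = 10)
  # a hub: 30 interaction eQTL stacked at chr2@20, 10 scattered on chr3
  set.seed(82)
  rec <- tibble::tibble(
    trait = probes$probe_id,
    covariate = "c1m03",
    chr = c(rep("2", 30), rep("3", 10)),
    kind = "autosome",
    pos = c(rep(20, 30), sample(seq(0, 60, 2), 10)),
    lod_f = 8, lod_i = 4)
  hs <- interaction_hotspots(rec, probes, map, n_perm = 150, seed = 83)
  expect_equal(unique(hs$chr), "2")
  expect_true(any(hs$lo <= 20 & hs$hi >= 20))
  empty <- interaction_hotspots(rec[0, ], probes, map, n_perm = 150,
                                seed = 84)
  expect_equal(nrow(empty), 0)
})
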