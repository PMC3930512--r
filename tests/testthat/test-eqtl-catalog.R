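# Peak extraction, cis/trans partition, dominance classification,
# enrichment, sterile-allele inference.

test_that("peak extraction keeps one leftmost supra-threshold peak per chr", {
  grid <- tibble::tibble(chr = rep(c("2", "3"), each = 3),
                         kind = "autosome",
                         pos = rep(c(0, 10, 12), 2),
                         marker = NA_character_)
  lod <- matrix(c(2, 5.1, 5.1, 1, 2.0, 1, # trait A
                  1, 2.0, 1.5, 1, 3.0, 2), ncol = 2)
  scans <- structure(list(grid = grid, lod = lod, traits = c("tA", "tB"),
                          method = "hk", covariate = NULL, n = 100),
                     class = "qtl_scan_set")
  thr <- structure(list(autosome = 3.7, x = 2.9), class = "perm_thresholds")
  pk <- extract_peaks(scans, thr)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$trait, "tA")
  expect_equal(pk$pos, 10)  # plateau tie -> leftmost
})

test_that("cis/trans classification partitions every record", {
  probes <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                           chr = c("5", "5", "5"), cM = c(50, 50, 50))
  peaks <- tibble::tibble(trait = c("p1", "p2", "p3"),
                          chr = c("5", "7", "5"), kind = "autosome",
                          pos = c(52, 10, 70), lod = 5)
  cls <- classify_cis_trans(peaks, probes, cis_window = 5)
  expect_equal(cls$class, c("cis", "trans", "excluded"))
  expect_true(all(table(cls$trait) == 1))
})

test_that("dominance classifier follows the SE rules on noisy class data", {
  set.seed(51)
  mk <- function(means, n = 60, sd = 0.2) {
    g <- rep(c("AA", "AB", "BB"), each = n)
    list(v = rnorm(3 * n, rep(means, each = n), sd), g = g)
  }
  d <- mk(c(0, 1, 2))
  expect_equal(classify_dominance_effect(d$v, d$g)$dominance, "additive")
  expect_equal(classify_dominance_effect(d$v, d$g)$effect, 2, tolerance = 0.1)
  d <- mk(c(0, 1.97, 2))
  res <- classify_dominance_effect(d$v, d$g)
  expect_equal(res$dominance, "dominant_B")
  expect_equal(res$high_allele, "B")
  d <- mk(c(0, 3, 2))
  expect_equal(classify_dominance_effect(d$v, d$g)$dominance, "overdominant")
  d <- mk(c(0, -1, 2))
  res <- classify_dominance_effect(d$v, d$g)
  expect_equal(res$dominance, "underdominant")
  expect_equal(res$low_allele, "het")
  # too few per class -> unclassified
  expect_equal(
    classify_dominance_effect(rnorm(5), c("AA", "AA", "AB", "AB", "BB"))$dominance,
    "unclassified")
  # X male records: additive-hemizygous with hemizygote effect
  res_x <- classify_dominance_effect(c(rnorm(10, 0, .1), rnorm(10, 1, .1)),
                                     rep(c("A", "B"), each = 10))
  expect_equal(res_x$dominance, "additive_hemizygous")
  expect_equal(res_x$effect, 1, tolerance = 0.2)
})

test_that("noiseless class means reproduce all five generative modes", {
  modes <- list(additive = c(0, 0.5, 1), dominant_A = c(0, 0, 1),
                dominant_B = c(0, 1, 1), overdominant = c(0, 1, 0),
                underdominant = c(0, -1, 0))
  g <- rep(c("AA", "AB", "BB"), each = 5)
  for (m in names(modes)) {
    v <- rep(modes[[m]], each = 5) * 1.4
    expect_equal(classify_dominance_effect(v, g)$dominance, m)
  }
})

test_that("hypergeometric enrichment matches the direct summation oracle", {
  universe <- sprintf("u%03d", 1:100)
  annotated <- universe[1:20]
  qtt <- universe[c(1:8, 50, 60)]  # overlap 8 of 10
  res <- enrichment_test(qtt, annotated, universe, n_tests = 5)
  oracle <- sum(vapply(8:10, function(k) {
    choose(20, k) * choose(80, 10 - k) / choose(100, 10)
  }, numeric(1)))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$p_adjusted, min(1, oracle * 5))
  # overlap at expectation is unremarkable
  qtt2 <- universe[c(1, 2, 21:28)]
  expect_gt(enrichment_test(qtt2, annotated, universe)$p, 0.3)
  # QTT = universe -> certainty
  expect_equal(enrichment_test(universe, annotated, universe)$p, 1)
  expect_error(enrichment_test("a", "a", character()), "empty")
})

test_that("sterile-allele inference needs size, concordance, and het support", {
  mk_members <- function(n, low, dominance = "additive") {
    tibble::tibble(trait = sprintf("p%03d", seq_len(n)),
                   dominance = dominance,
                   high_allele = ifelse(low == "A", "B", "A"),
                   low_allele = low)
  }
  f1_under <- tibble::tibble(probe_id = sprintf("p%03d", 1:40),
                             status = "under")
  # class B lowers all F1-underexpressed QTT -> allele B, concordance 1
  res <- infer_sterile_allele(mk_members(40, "B"), f1_under)
  expect_equal(res$allele, "B")
  expect_equal(unname(res$concordance["B"]), 1)
  # random directions -> undetermined
  set.seed(52)
  mixed <- mk_members(40, sample(c("A", "B"), 40, replace = TRUE))
  mixed$low_allele <- sample(c("A", "B"), 40, replace = TRUE)
  mixed$high_allele <- ifelse(mixed$low_allele == "A", "B", "A")
  expect_equal(infer_sterile_allele(mixed, f1_under)$allele, "undetermined")
  # size gate
  expect_equal(infer_sterile_allele(mk_members(10, "B"), f1_under)$allele,
               "undetermined")
  # het wins only with enough over/underdominant members
  het_add <- mk_members(40, "het", dominance = "additive")
  expect_equal(infer_sterile_allele(het_add, f1_under)$allele, "undetermined")
  het_ud <- mk_members(40, "het", dominance = "underdominant")
  expect_equal(infer_sterile_allele(het_ud, f1_under)$allele, "het")
})

test_that("simulated cis effects are catalogued as cis on synthetic data", {
  map <- simulate_map(5, lengths = rep(60, 5), marker_spacing = 10,
                      x_length = 40)
  cross <- simulate_f2(map, 300, seed = 53)
  arch <- example_architecture(map, n_probes = 60, n_cis = 30,
                               n_master_targets = 0, cis_effect = 1.0,
                               noise_sd = 1.0, seed = 54)
  arch$masters <- arch$masters[0, ]
  arch$epistasis <- arch$epistasis[0, ]
  expr <- simulate_expression(cross, arch, seed = 55)
  gp <- calc_genoprob(cross, step = 2, error_rate = 0.001,
                      map_function = "haldane")
  vals <- f2_slice(expr, rownames(cross$geno))
  Y <- t(apply(vals, 1, nqrank))
  thr <- permutation_threshold(setNames(Y[1, ], colnames(vals)), gp,
                               n_perm = 100, seed = 56)
  scans <- scan_traits(t(Y), gp)
  records <- classify_cis_trans(extract_peaks(scans, thr), expr$probes)
  cis_found <- records$trait[records$class == "cis"]
  # >= 95% of 1-SD cis effects recovered as cis records
  expect_gte(mean(arch$cis$probe_id %in% cis_found), 0.95)
  # dataset-wide threshold: no simulated-null probe clears it
  dt <- dataset_threshold(t(Y), gp, n_perm = 30, seed = 57)
  null_probes <- setdiff(expr$probes$probe_id, arch$cis$probe_id)
  rec_dt <- extract_peaks(scans, dt)
  expect_equal(sum(rec_dt$trait %in% null_probes), 0)
  dom <- annotate_dominance(records[records$class == "cis", ][1:5, ],
                            expr, cross)
  expect_true(all(dom$dominance %in%
                    c("additive", "dominant_A", "dominant_B",
                      "additive_hemizygous", "unclassified")))
})
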