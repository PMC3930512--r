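# Differential expression, misexpression classification, counts,
# phenotype correlations.

# Expression set with explicit group means/noise for classification tests.
make_expr <- function(f2_vals, pa, pb, f1_dxm = NULL, f1_mxd = NULL,
                      probe_chr = "1", noise = 0, seed = 1) {
  set.seed(seed)
  n_probe <- nrow(f2_vals)
  grp <- function(m, g, prefix) {
    if (is.null(m)) return(NULL)
    colnames(m) <- sprintf("%s_%02d", prefix, seq_len(ncol(m)))
    list(m = m, samples = tibble::tibble(id = colnames(m), group = g))
  }
  parts <- list(
    grp(f2_vals, "F2", "F2"),
    grp(pa, "parentA", "PA"), grp(pb, "parentB", "PB"),
    grp(f1_dxm, "F1_DxM", "F1DxM"), grp(f1_mxd, "F1_MxD", "F1MxD"))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  vals <- do.call(cbind, lapply(parts, `[[`, "m")) +
    matrix(rnorm(n_probe * sum(vapply(parts, function(p) ncol(p$m), 1L)),
                 0, noise), n_probe)
  samples <- dplyr::bind_rows(lapply(parts, `[[`, "samples"))
  probes <- tibble::tibble(probe_id = sprintf("p%03d", seq_len(n_probe)),
                           gene = sprintf("g%03d", seq_len(n_probe)),
                           chr = rep_len(probe_chr, n_probe),
                           cM = 10, Mb = 20)
  rownames(vals) <- probes$probe_id
  expression_set(samples, vals, probes)
}

const_mat <- function(vals, n) matrix(vals, length(vals), n)

test_that("Welch differential expression controls the FDR and finds shifts", {
  set.seed(31)
  n_probe <- 2000
  expr <- make_expr(const_mat(rep(0, n_probe), 2),
                    const_mat(rep(0, n_probe), 8),
                    const_mat(c(rep(3, 50), rep(0, n_probe - 50)), 8),
                    noise = 1)
  de <- differential_expression(expr, "parentA", "parentB", fdr = 0.05)
  expect_gt(mean(de$significant[1:50]), 0.9)       # 3-SD shifts found
  expect_lt(mean(de$significant[-(1:50)]), 0.02)   # null mostly clean
  # p values roughly uniform under the null
  expect_gt(stats::ks.test(de$p[-(1:50)], "punif")$p.value, 1e-4)
  # one-sample group is a named error
  e2 <- make_expr(const_mat(0, 2), const_mat(0, 8), const_mat(0, 8))
  e2$samples$group[e2$samples$group == "parentA"][-1] <- "F2"
  expect_error(differential_expression(e2, "parentA", "parentB"),
               "parentA")
})

test_that("F1 misexpression rule requires direction, significance, and delta", {
  set.seed(32)
  n <- 200
  pa <- rep(5, n); pb <- rep(6, n)
  f1 <- rep(5.5, n)       # between parents
  f1[1:30] <- 6.8         # over, both diffs > 0.5
  f1[31:60] <- 6.4        # above both, but diff to nearer parent 0.4 < 0.5
  f1[61:90] <- 3.0        # under
  expr <- make_expr(const_mat(rep(5.5, n), 2), const_mat(pa, 8),
                    const_mat(pb, 8), f1_mxd = const_mat(f1, 6),
                    noise = 0.05)
  calls <- classify_f1_misexpression(expr, "F1_MxD", delta = 0.5, fdr = 0.05)
  expect_true(all(calls$status[1:30] == "over"))
  expect_true(all(calls$status[31:60] == "none"))
  expect_true(all(calls$status[61:90] == "under"))
  expect_true(all(calls$status[91:n] == "none"))
})

test_that("F2 misexpression rule instantiates the delta and SE criteria", {
  # parents 5.0 (SE 0.1) and 6.0 (SE 0.1)
  expect_equal(classify_f2_misexpression(6.6, 5, 0.1, 6, 0.1), "over")
  expect_equal(classify_f2_misexpression(6.4, 5, 0.1, 6, 0.1), "none")
  expect_equal(classify_f2_misexpression(4.3, 5, 0.1, 6, 0.1), "under")
  # 0.7 > 0.5 but < 2 x SE 0.4 -> none
  expect_equal(classify_f2_misexpression(6.7, 5, 0.4, 6, 0.4), "none")
  # antisymmetry: negating all values swaps over and under
  set.seed(33)
  v <- rnorm(500, 5.5, 1.5)
  fwd <- classify_f2_misexpression(v, 5, 0.1, 6, 0.1)
  rev <- classify_f2_misexpression(-v, -5, 0.1, -6, 0.1)
  expect_identical(fwd == "over", rev == "under")
  expect_identical(fwd == "under", rev == "over")
})

test_that("misexpression counts match a hand trace and ignore probe order", {
  # 3 probes (2 autosomal, 1 X), 2 individuals; parents 5 +- tiny SE and 6
  f2 <- rbind(c(6.8, 5.5),   # ind1 over, ind2 none (autosome)
              c(4.2, 6.8),   # ind1 under, ind2 over (autosome)
              c(5.5, 4.1))   # ind1 none, ind2 under (X)
  expr <- make_expr(f2, const_mat(rep(5, 3), 8), const_mat(rep(6, 3), 8),
                    probe_chr = c("1", "2", "X"), noise = 0.01, seed = 34)
  mc <- misexpression_counts(expr)
  expect_equal(mc$counts$over_autosome, c(1, 1))
  expect_equal(mc$counts$under_autosome, c(1, 0))
  expect_equal(mc$counts$under_x, c(0, 1))
  expect_equal(mc$counts$sqrt_over_autosome, sqrt(mc$counts$over_autosome))
  expect_equal(mc$prevalence$frac_misexpressed, c(0.5, 1, 0.5))

  # probe order invariance
  expr2 <- expr
  ord <- c(3, 1, 2)
  expr2$values <- expr$values[ord, ]
  expr2$probes <- expr$probes[ord, ]
  mc2 <- misexpression_counts(expr2)
  expect_equal(mc2$counts, mc$counts)

  # no probe beyond the parental range -> all zero
  expr0 <- make_expr(const_mat(rep(5.5, 3), 2), const_mat(rep(5, 3), 8),
                     const_mat(rep(6, 3), 8), noise = 0.01, seed = 35)
  expect_true(all(misexpression_counts(expr0)$counts$over_autosome == 0))
})

test_that("under a midparent null the per-probe misexpression rate is < 5%", {
  set.seed(36)
  n_probe <- 400; n_f2 <- 100
  pa <- matrix(rnorm(n_probe * 8, 5, 0.3), n_probe)
  pb <- matrix(rnorm(n_probe * 8, 6, 0.3), n_probe)
  f2 <- matrix(rnorm(n_probe * n_f2, 5.5, 0.3), n_probe)
  expr <- make_expr(f2, pa, pb, noise = 0)
  mc <- misexpression_counts(expr)
  expect_lt(mean(mc$prevalence$frac_misexpressed), 0.05)
})

test_that("phenotype correlations recover signs and control the null rate", {
  set.seed(37)
  n_probe <- 300; n_f2 <- 60
  ph <- rnorm(n_f2)
  f2 <- matrix(rnorm(n_probe * n_f2, 6, 1), n_probe)
  f2[1, ] <- 6 + ph                      # r = +1
  f2[2, ] <- 6 - ph + rnorm(n_f2, 0, 0.01)
  expr <- make_expr(f2, const_mat(rep(6, n_probe), 8),
                    const_mat(rep(6, n_probe), 8))
  names(ph) <- expr$samples$id[expr$samples$group == "F2"]
  res <- correlate_with_phenotype(expr, ph, fdr = 0.05)
  expect_equal(res$probes$r[1], 1, tolerance = 1e-12)
  expect_lt(res$probes$r[2], -0.99)
  expect_lt(mean(res$probes$direction[-(1:2)] != "none"), 0.05)
  expect_error(correlate_with_phenotype(expr, ph[1:5]), "at least 10")
})

test_that("an X-overexpression QTL is recovered from misexpression counts", {
  map <- simulate_map(3, lengths = rep(50, 3), marker_spacing = 10,
                      x_length = 40)
  cross <- simulate_f2(map, 300, seed = 38)
  n_probe <- 120
  probes <- tibble::tibble(probe_id = sprintf("p%03d", 1:n_probe),
                           gene = sprintf("g%03d", 1:n_probe),
                           chr = rep(c("1", "2", "3", "X"), each = 30),
                           cM = rep(seq(1, 40, length.out = 30), 4),
                           Mb = 2 * rep(seq(1, 40, length.out = 30), 4))
  # heterozygotes at an autosomal locus overexpress X-linked transcripts
  arch <- sim_architecture(
    probes,
    masters = tibble::tibble(marker = "c2m03", mode = "overdominant",
                             probes = list(probes$probe_id[probes$chr == "X"]),
                             effect = 1.5),
    noise_sd = 0.3)
  expr <- simulate_expression(cross, arch, seed = 39)
  gp <- calc_genoprob(cross, step = 2, error_rate = 0,
                      map_function = "haldane")
  mc <- misexpression_counts(expr)
  mq <- map_misexpression_qtl(mc, gp, n_perm = 100, seed = 40)
  el <- mq[["sqrt_over_x"]]
  expect_false(is.null(el$scan))
  pk <- glance(el$scan)
  expect_equal(pk$peak_chr, "2")
  expect_lt(abs(pk$peak_pos - 20), 10)
  expect_gt(pk$peak_lod, el$thresholds$autosome)
  # sqrt transform applied exactly once
  expect_equal(max(mc$counts$sqrt_over_x), sqrt(max(mc$counts$over_x)))
  # constant counts yield no scan
  zero <- mc
  zero$counts$sqrt_under_autosome <- 0
  mq0 <- map_misexpression_qtl(zero, gp, n_perm = 100, seed = 41)
  expect_null(mq0[["sqrt_under_autosome"]]$scan)
})
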