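# Sliding-window counting, permutation null, hotspot calling,
# co-localization.

hotspot_map <- function() {
  simulate_map(4, lengths = rep(40, 4), marker_spacing = 10, x_length = NULL)
}

test_that("window counts use half-open windows anchored on the grid", {
  map <- hotspot_map()
  rec <- tibble::tibble(chr = "1", pos = c(10.0, 11.5, 13.9, 14.1))
  wc <- window_counts(rec, map, window = 4, step = 2)
  expect_equal(wc$count[wc$chr == "1" & wc$start == 10], 3)
  # translation equivariance by one grid step
  rec2 <- rec
  rec2$pos <- rec2$pos + 2
  wc2 <- window_counts(rec2, map, window = 4, step = 2)
  expect_equal(wc2$count[wc2$chr == "1" & wc2$start == 12], 3)
  # no trans records -> all zero
  wc0 <- window_counts(rec[0, ], map)
  expect_true(all(wc0$count == 0))
  # every eQTL lands in ceil(window/step) full-size windows away from ends
  rec3 <- tibble::tibble(chr = "2", pos = 20)
  wc3 <- window_counts(rec3, map)
  expect_equal(sum(wc3$count), 2)
  # truncated end windows keep their true size and capture the last position
  expect_lt(min(wc$size), 4)
  rec4 <- tibble::tibble(chr = "3", pos = 40)
  wc4 <- window_counts(rec4, map)
  expect_gt(sum(wc4$count), 0)
})

test_that("null reassignment avoids the probe chromosome, keeps counts", {
  map <- hotspot_map()
  set.seed(61)
  rec <- tibble::tibble(chr = sample(c("2", "3", "4"), 50, replace = TRUE),
                        pos = sample(seq(0, 40, 2), 50, replace = TRUE),
                        probe_chr = "1")
  thr <- hotspot_null_thresholds(rec, map, n_perm = 100, seed = 62)
  null <- attr(thr, "null")
  expect_equal(nrow(null), 100)
  # direct check of the reassignment helper
  grid <- map_grid(map, 2)
  withr::with_seed(63, {
    for (i in 1:5) {
      np <- hybridqtl:::reassign_positions(rec, grid, rec$probe_chr)
      expect_false(any(np$chr == "1"))
      expect_equal(nrow(np), nrow(rec))
    }
  })
  # single-chromosome genome cannot be permuted
  map1 <- simulate_map(1, lengths = 40, marker_spacing = 10, x_length = NULL)
  expect_error(hotspot_null_thresholds(rec, map1, n_perm = 100, seed = 1),
               "2 chromosomes")
})

test_that("flagged windows merge into hotspots and recover a master locus", {
  map <- hotspot_map()
  counts <- tibble::tibble(chr = "1", start = c(10, 12, 30),
                           end = c(14, 16, 34), size = 4,
                           count = c(9L, 8L, 7L))
  thr <- tibble::tibble(size = 4, threshold = 5)
  rec <- tibble::tibble(chr = rep("1", 12),
                        pos = c(rep(12, 9), rep(31, 3)))
  hs <- call_hotspots(counts, thr, rec)
  expect_equal(nrow(hs), 2)
  expect_equal(hs$lo, c(10, 30))
  expect_equal(hs$hi, c(16, 34))
  expect_equal(hs$count[1], 9L)  # members inside the union
  expect_equal(hs$n_windows, c(2L, 1L))

  # master-regulator recovery: a stack of trans eQTL at one marker
  set.seed(64)
  stack <- tibble::tibble(chr = "2", pos = 20, probe_chr = "1")
  scatter <- tibble::tibble(
    chr = sample(c("1", "3", "4"), 60, replace = TRUE),
    pos = sample(seq(0, 40, 2), 60, replace = TRUE))
  scatter$probe_chr <- ifelse(scatter$chr == "1", "2", "1")
  rec2 <- dplyr::bind_rows(stack[rep(1, 100), ], scatter)
  wc <- window_counts(rec2, map)
  thr2 <- hotspot_null_thresholds(rec2, map, n_perm = 150, seed = 65)
  hs2 <- call_hotspots(wc, thr2, rec2, map)
  expect_equal(unique(hs2$chr), "2")
  expect_true(any(hs2$lo <= 20 & hs2$hi >= 20))
  expect_true(all(c("lo_mb", "hi_mb") %in% names(hs2)))
})

test_that("co-localization statistics and saturation/empty edge cases", {
  map <- hotspot_map()
  hs <- structure(tibble::tibble(chr = c("1", "2"), lo = c(10, 20),
                                 hi = c(16, 28), count = c(10L, 8L),
                                 threshold = 5, n_windows = 2L),
                  class = c("hotspot_set", class(tibble::tibble())))
  # intervals covering the whole genome -> P = 1 for every statistic
  full_iv <- tibble::tibble(chr = c("1", "2", "3", "4"), lo_cM = 0,
                            hi_cM = 40, peak_cM = 20, trait = "t",
                            sterile_allele = "A")
  res <- colocalization_test(hs, full_iv, map, n_perm = 50, seed = 66)
  expect_equal(unname(res$p), rep(1, 3))
  expect_equal(unname(res$observed["cm"]), (16 - 10) + (28 - 20))
  # no intervals -> zero observed overlap, P = 1
  res0 <- colocalization_test(hs, full_iv[0, ], map, n_perm = 50, seed = 66)
  expect_equal(unname(res0$observed), c(0, 0, 0))
  expect_equal(unname(res0$p), rep(1, 3))
  # a tight interval around one hotspot gives small P
  iv <- tibble::tibble(chr = "1", lo_cM = 10, hi_cM = 16, peak_cM = 12,
                       trait = "t", sterile_allele = "A")
  res1 <- colocalization_test(hs, iv, map, n_perm = 200, seed = 67)
  expect_lt(res1$p["cm"], 0.2)
  expect_true(all(res1$p >= 1 / 201))
})

test_that("sterility interval IO validates and hotspots export as BED", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("trait\tchr\tpeak_cM\tlo_cM\thi_cM\tsterile_allele",
               "testis_weight\t17\t8\t2\t16\thet"), path)
  iv <- read_sterility_intervals(path)
  expect_equal(iv$hi_cM, 16)
  writeLines(c("trait\tchr\tpeak_cM\tlo_cM\thi_cM\tsterile_allele",
               "tw\t17\t20\t2\t16\thet"), path)
  expect_error(read_sterility_intervals(path), "lo <= peak <= hi")

  hs <- structure(tibble::tibble(chr = "17", lo = 2, hi = 16, count = 50L,
                                 threshold = 10, n_windows = 7L,
                                 lo_mb = 4, hi_mb = 32),
                  class = c("hotspot_set", class(tibble::tibble())))
  bed <- tempfile(fileext = ".bed")
  write_hotspots_bed(hs, bed)
  expect_identical(readLines(bed), "chr17\t4000000\t32000000\thotspot_1\t50")
})
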