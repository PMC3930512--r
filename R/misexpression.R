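# Parental differential expression and F1/F2 misexpression classification.
#
# A transcript is misexpressed when its level falls outside the range
# delimited by both parental means by more than 0.5 (log2) and, for F2
# individuals, more than `se_mult` standard errors of the nearer parental
# group mean; F1 calls additionally require significant Welch tests against
# both parents at the chosen FDR.

group_means_ses <- function(expr, group) {
  idx <- expr$samples$group == group
  if (sum(idx) < 2L) abort(sprintf("group %s has fewer than 2 samples", group))
  m <- expr$values[, idx, drop = FALSE]
  n <- ncol(m)
  mu <- rowMeans(m)
  v <- (rowSums(m^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  list(mean = mu, se = sqrt(v / n), var = v, n = n)
}

#' Per-group expression summary statistics
#'
#' @param expr An [expression_set()].
#' @param groups Groups to summarise.
#' @return Tibble `probe_id`, `group`, `mean`, `se`, `n`.
#' @export
group_stats <- function(expr, groups = c("parentA", "parentB",
                                         "F1_DxM", "F1_MxD")) {
  groups <- intersect(groups, unique(expr$samples$group))
  bind_rows(lapply(groups, function(g) {
    st <- group_means_ses(expr, g)
    tibble(probe_id = rownames(expr$values), group = g,
           mean = st$mean, se = st$se, n = st$n)
  }))
}

welch_test <- function(sa, sb) {
  se2 <- sa$var / sa$n + sb$var / sb$n
  t <- (sa$mean - sb$mean) / sqrt(se2)
  df <- se2^2 / ((sa$var / sa$n)^2 / (sa$n - 1) + (sb$var / sb$n)^2 / (sb$n - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  # degenerate probes: no variance in either group
  zero <- se2 == 0
  p[zero & sa$mean == sb$mean] <- 1
  p[zero & sa$mean != sb$mean] <- .Machine$double.xmin
  t[zero] <- ifelse(sa$mean[zero] == sb$mean[zero], 0, Inf)
  list(t = t, p = p)
}

#' Differential expression between two sample groups
#'
#' Welch t-test per probe with Storey q-values; significance at
#' `q <= fdr`.
#'
#' @param expr An [expression_set()].
#' @param group_a,group_b Group labels.
#' @param fdr False discovery rate.
#' @return Tibble `probe_id`, `t`, `p`, `q`, `significant`.
#' @export
differential_expression <- function(expr, group_a, group_b, fdr = 0.05) {
  sa <- group_means_ses(expr, group_a)
  sb <- group_means_ses(expr, group_b)
  wt <- welch_test(sa, sb)
  qv <- storey_qvalue(wt$p)
  tibble(probe_id = rownames(expr$values), t = wt$t, p = wt$p,
         q = qv$qvalue, significant = qv$qvalue <= fdr)
}

#' Classify F1 misexpression
#'
#' A probe is `over` when the F1 group mean exceeds both parental means,
#' both F1-vs-parent Welch tests are significant at `q <= fdr`, and both mean
#' differences exceed `delta` log2 units; `under` is symmetric.
#'
#' @param expr An [expression_set()].
#' @param f1_group `"F1_MxD"` or `"F1_DxM"`.
#' @param delta Minimum log2 difference from each parent.
#' @param fdr FDR level for the pairwise tests.
#' @return Tibble `probe_id`, `status` (`over`/`under`/`none`).
#' @export
classify_f1_misexpression <- function(expr, f1_group = "F1_MxD", delta = 0.5,
                                      fdr = 0.05) {
  sf <- group_means_ses(expr, f1_group)
  sa <- group_means_ses(expr, "parentA")
  sb <- group_means_ses(expr, "parentB")
  qa <- storey_qvalue(welch_test(sf, sa)$p)$qvalue
  qb <- storey_qvalue(welch_test(sf, sb)$p)$qvalue
  sig <- qa <= fdr & qb <= fdr
  over <- sf$mean > sa$mean & sf$mean > sb$mean & sig &
    (sf$mean - sa$mean) > delta & (sf$mean - sb$mean) > delta
  under <- sf$mean < sa$mean & sf$mean < sb$mean & sig &
    (sa$mean - sf$mean) > delta & (sb$mean - sf$mean) > delta
  tibble(probe_id = rownames(expr$values),
         status = ifelse(over, "over", ifelse(under, "under", "none")))
}

#' Classify a single F2 expression value against the parental ranges
#'
#' `over` when the value exceeds both parental means and its distance to the
#' nearer (higher) parental mean exceeds both `delta` and `se_mult` times
#' that parent's standard error of the mean; `under` symmetric; otherwise
#' `none`.
#'
#' @param value Numeric vector of log2 values (one probe, any number of
#'   individuals).
#' @param mean_a,se_a,mean_b,se_b Parental group means and standard errors.
#' @param delta Minimum log2 difference.
#' @param se_mult SE multiplier.
#' @return Character vector `over`/`under`/`none`.
#' @export
#' @examples
#' classify_f2_misexpression(c(6.6, 6.4, 4.3), 5.0, 0.1, 6.0, 0.1)
classify_f2_misexpression <- function(value, mean_a, se_a, mean_b, se_b,
                                      delta = 0.5, se_mult = 2) {
  hi_mean <- pmax(mean_a, mean_b)
  hi_se <- ifelse(mean_a >= mean_b, se_a, se_b)
  lo_mean <- pmin(mean_a, mean_b)
  lo_se <- ifelse(mean_a <= mean_b, se_a, se_b)
  over <- value > mean_a & value > mean_b &
    (value - hi_mean) > pmax(delta, se_mult * hi_se)
  under <- value < mean_a & value < mean_b &
    (lo_mean - value) > pmax(delta, se_mult * lo_se)
  ifelse(over, "over", ifelse(under, "under", "none"))
}

# Status matrix (probes x F2 individuals) for the whole expression set.
misexpression_status <- function(expr, delta = 0.5, se_mult = 2) {
  sa <- group_means_ses(expr, "parentA")
  sb <- group_means_ses(expr, "parentB")
  vals <- f2_slice(expr)
  out <- matrix("none", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (j in seq_len(ncol(vals))) {
    out[, j] <- classify_f2_misexpression(vals[, j], sa$mean, sa$se,
                                          sb$mean, sb$se, delta, se_mult)
  }
  out
}

#' Misexpression counts per F2 individual
#'
#' Counts over- and under-expressed probes per individual, split into
#' autosomal and X strata, with square-root transformed phenotypes ready for
#' QTL mapping, plus the per-probe F2 prevalence of misexpression.
#'
#' @param expr An [expression_set()].
#' @param delta,se_mult Classification constants.
#' @return List of class `"misexpression_counts"`: `counts` tibble (`id`,
#'   `over_autosome`, `under_autosome`, `over_x`, `under_x` and their
#'   `sqrt_*` transforms) and `prevalence` tibble (`probe_id`, `frac_over`,
#'   `frac_under`, `frac_misexpressed`).
#' @export
misexpression_counts <- function(expr, delta = 0.5, se_mult = 2) {
  status <- misexpression_status(expr, delta, se_mult)
  on_x <- toupper(expr$probes$chr) == "X"
  count <- function(st, rows) unname(colSums(status[rows, , drop = FALSE] == st))
  counts <- tibble(
    id = colnames(status),
    over_autosome = count("over", !on_x),
    under_autosome = count("under", !on_x),
    over_x = count("over", on_x),
    under_x = count("under", on_x)
  )
  for (f in c("over_autosome", "under_autosome", "over_x", "under_x")) {
    counts[[paste0("sqrt_", f)]] <- sqrt(counts[[f]])
  }
  prevalence <- tibble(
    probe_id = rownames(status),
    frac_over = unname(rowMeans(status == "over")),
    frac_under = unname(rowMeans(status == "under")),
    frac_misexpressed = unname(rowMeans(status != "none"))
  )
  structure(list(counts = counts, prevalence = prevalence),
            class = "misexpression_counts")
}

#' Map misexpression-count QTL
#'
#' Scans the four square-root transformed misexpression counts (over/under x
#' autosome/X) as phenotypes and computes a single-transcript permutation
#' threshold per phenotype.
#'
#' @param counts A [misexpression_counts()] result.
#' @param gp A [calc_genoprob()] result.
#' @param n_perm Permutations per phenotype.
#' @param alpha Significance level.
#' @param seed RNG seed.
#' @return List per phenotype: `scan` (a `"qtl_scan"`) and `thresholds`.
#' @export
map_misexpression_qtl <- function(counts, gp, n_perm = 200, alpha = 0.05,
                                  seed = 1L) {
  phenos <- c("sqrt_over_autosome", "sqrt_under_autosome",
              "sqrt_over_x", "sqrt_under_x")
  out <- list()
  for (i in seq_along(phenos)) {
    y <- setNames(counts$counts[[phenos[i]]], counts$counts$id)
    if (var(y) == 0) {
      out[[phenos[i]]] <- list(scan = NULL, thresholds = NULL)
      next
    }
    sc <- scan_single(y, gp, method = "hk")
    th <- permutation_threshold(y, gp, n_perm = n_perm, alpha = alpha,
                                seed = derive_seed(seed, i))
    out[[phenos[i]]] <- list(scan = sc, thresholds = th)
  }
  out
}

#' Correlate expression with a phenotype
#'
#' Pearson correlation of each probe's F2 expression with a phenotype,
#' Storey q-values across probes, and per-chromosome fractions of
#' significantly positive and negative probes.
#'
#' @param expr An [expression_set()].
#' @param phenotype Named numeric vector (names = F2 ids).
#' @param fdr FDR level.
#' @return List: `probes` tibble (`probe_id`, `r`, `p`, `q`, `direction`) and
#'   `by_chr` tibble (`chr`, `frac_positive`, `frac_negative`); the number of
#'   zero-variance probes excluded is in attribute `"n_excluded"`.
#' @export
correlate_with_phenotype <- function(expr, phenotype, fdr = 0.05) {
  ids <- intersect(names(phenotype)[!is.na(phenotype)],
                   expr$samples$id[expr$samples$group == "F2"])
  if (length(ids) < 10L) abort("need at least 10 paired observations")
  vals <- expr$values[, ids, drop = FALSE]
  y <- as.numeric(phenotype[ids])
  n <- length(y)
  cv <- vals - rowMeans(vals)
  yc <- y - mean(y)
  sds <- unname(sqrt(rowSums(cv^2)))
  keep <- sds > 0
  r <- as.vector(cv[keep, , drop = FALSE] %*% yc) / (sds[keep] * sqrt(sum(yc^2)))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  qv <- storey_qvalue(p)
  probes <- tibble(probe_id = rownames(vals)[keep], r = r, p = p,
                   q = qv$qvalue,
                   direction = ifelse(qv$qvalue <= fdr,
                                      ifelse(r > 0, "positive", "negative"),
                                      "none"))
  ann <- expr$probes[match(probes$probe_id, expr$probes$probe_id), ]
  by_chr <- tibble(chr = ann$chr, direction = probes$direction) |>
    group_by(.data$chr) |>
    summarise(frac_positive = mean(.data$direction == "positive"),
              frac_negative = mean(.data$direction == "negative"),
              .groups = "drop")
  structure(list(probes = probes, by_chr = by_chr),
            n_excluded = sum(!keep))
}
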