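# Permutation thresholds with a separate X stratum.
#
# The genome-wide significance level alpha is partitioned between autosomes
# and X in proportion to map length, and the X stratum uses a permutation
# count scaled up by (autosomal length / X length), mirroring the
# 10,000-autosome / 158,550-X convention for mouse panels. Thresholds are
# upper quantiles of the per-permutation maximum LOD within each stratum.

stratum_alphas <- function(map, alpha) {
  len <- map_stratum_lengths(map)
  if (len[["X"]] <= 0) {
    c(autosome = alpha, X = NA_real_)
  } else {
    c(autosome = alpha * len[["autosome"]] / sum(len),
      X = alpha * len[["X"]] / sum(len))
  }
}

null_quantile <- function(maxima, alpha) {
  s <- sort(maxima)
  s[max(1L, ceiling((1 - alpha) * length(s)))]
}

perm_thresholds_obj <- function(null_auto, null_x, alpha, alphas, seed, scope) {
  structure(list(
    autosome = if (length(null_auto)) null_quantile(null_auto, alphas["autosome"]) else NA_real_,
    x = if (length(null_x)) null_quantile(null_x, alphas["X"]) else NA_real_,
    alpha = alpha,
    alpha_autosome = unname(alphas["autosome"]),
    alpha_x = unname(alphas["X"]),
    n_perm = length(null_auto), n_perm_x = length(null_x),
    seed = seed, scope = scope,
    null = list(autosome = sort(null_auto), x = sort(null_x))
  ), class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf(
    "%s permutation thresholds (alpha %.3g): autosome %.3f (%d perms), X %s (%d perms)\n",
    x$scope, x$alpha, x$autosome, x$n_perm,
    if (is.na(x$x)) "-" else sprintf("%.3f", x$x), x$n_perm_x))
  invisible(x)
}

#' Glance at permutation thresholds
#'
#' @param x A `"perm_thresholds"` object.
#' @param ... Unused.
#' @return One-row tibble of thresholds and permutation metadata.
#' @export
glance.perm_thresholds <- function(x, ...) {
  tibble(scope = x$scope, alpha = x$alpha,
         threshold_autosome = x$autosome, threshold_x = x$x,
         alpha_autosome = x$alpha_autosome, alpha_x = x$alpha_x,
         n_perm = x$n_perm, n_perm_x = x$n_perm_x, seed = x$seed)
}

# LOD threshold for a stratum ("autosome"/"X") from a thresholds object.
stratum_threshold <- function(thresholds, kind) {
  if (kind == "X") thresholds$x else thresholds$autosome
}

#' Single-transcript permutation thresholds
#'
#' Shuffles one (transformed) trait across individuals, records the maximum
#' LOD over the autosomes and - with a separately scaled permutation count -
#' over the X, and returns the upper `1 - alpha_stratum` quantiles.
#'
#' @param trait Named numeric vector.
#' @param gp A [calc_genoprob()] result.
#' @param n_perm Autosomal permutation count (>= 20).
#' @param alpha Genome-wide significance level (partitioned by map length).
#' @param seed RNG seed.
#' @param method Scan method for the permutations.
#' @param covariate,covariate_model Optional covariate passed to the scans.
#' @param n_perm_x X-stratum permutation count; defaults to `n_perm` scaled
#'   by the autosome/X map-length ratio.
#' @return A `"perm_thresholds"` object (thresholds plus sorted null maxima).
#' @export
permutation_threshold <- function(trait, gp, n_perm = 1000, alpha = 0.05,
                                  seed = 1L, method = "hk",
                                  covariate = NULL,
                                  covariate_model = "additive",
                                  n_perm_x = NULL) {
  stopifnot(n_perm >= 20)
  alphas <- stratum_alphas(gp$map, alpha)
  len <- map_stratum_lengths(gp$map)
  has_x <- len["X"] > 0
  if (is.null(n_perm_x)) {
    n_perm_x <- if (has_x) round(n_perm * len["autosome"] / len["X"]) else 0L
  }
  y <- trait[gp$ind]
  keep <- which(!is.na(y))
  y <- as.numeric(y[keep])
  covar <- if (!is.null(covariate)) {
    cc <- covariate_columns(gp, covariate)
    list(add = cc$add[keep], het = cc$het[keep], chr = cc$chr, pos = cc$pos,
         kind = cc$kind)
  }
  auto_chrs <- names(gp$chr)[vapply(gp$chr, function(e) e$kind == "autosome",
                                    logical(1))]
  x_chrs <- setdiff(names(gp$chr), auto_chrs)
  perm_max <- function(n_p, chrs) {
    if (!length(chrs) || n_p < 1) return(numeric())
    Y <- vapply(seq_len(n_p), function(i) sample(y), numeric(length(y)))
    if (method == "hk") {
      res <- hk_engine(gp, Y, keep = keep, covar = covar,
                       model = covariate_model, chrs = chrs)
      apply(res$lod, 2, max)
    } else {
      vapply(seq_len(n_p), function(i) {
        sc <- scan_single(setNames(Y[, i], gp$ind[keep]), gp, method = method,
                          covariate = covariate,
                          covariate_model = covariate_model)
        max(sc$lod[sc$chr %in% chrs])
      }, numeric(1))
    }
  }
  withr::with_seed(seed, {
    null_auto <- perm_max(n_perm, auto_chrs)
    null_x <- perm_max(n_perm_x, x_chrs)
  })
  perm_thresholds_obj(null_auto, null_x, alpha, alphas, seed,
                      "single_transcript")
}

#' Dataset-wide permutation thresholds
#'
#' Permutes the assignment of individual ids to expression columns once per
#' replicate - preserving the correlation structure among transcripts - scans
#' every trait, and records the maximum LOD over all transcripts per stratum.
#' The resulting threshold bounds the chance of observing even a single eQTL
#' anywhere in the dataset.
#'
#' @param Y Numeric matrix, individuals x traits (complete; typically
#'   [nqrank()]-transformed expression).
#' @param gp A [calc_genoprob()] result.
#' @param n_perm Number of dataset permutations (>= 20; both strata).
#' @param alpha Genome-wide significance level.
#' @param seed RNG seed.
#' @return A `"perm_thresholds"` object with scope `"dataset"`.
#' @export
dataset_threshold <- function(Y, gp, n_perm = 360, alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 20)
  ord <- match(gp$ind, rownames(Y))
  if (anyNA(ord)) abort("Y must contain every cross individual")
  Y <- Y[ord, , drop = FALSE]
  alphas <- stratum_alphas(gp$map, alpha)
  auto_chrs <- names(gp$chr)[vapply(gp$chr, function(e) e$kind == "autosome",
                                    logical(1))]
  x_chrs <- setdiff(names(gp$chr), auto_chrs)
  withr::with_seed(seed, {
    null_auto <- numeric(); null_x <- numeric()
    for (i in seq_len(n_perm)) {
      Yp <- Y[sample(nrow(Y)), , drop = FALSE]
      if (length(auto_chrs)) {
        res <- hk_engine(gp, Yp, chrs = auto_chrs)
        null_auto[i] <- max(res$lod)
      }
      if (length(x_chrs)) {
        res_x <- hk_engine(gp, Yp, chrs = x_chrs)
        null_x[i] <- max(res_x$lod)
      }
    }
  })
  perm_thresholds_obj(null_auto, null_x, alpha, alphas, seed, "dataset")
}

# ---- P values and Storey q-values ------------------------------------------

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 by evaluating `mean(p > lambda) /
#' (1 - lambda)` on a lambda grid 0.05..0.95 and reading a cubic smoothing
#' spline at the largest lambda, then converts p-values to q-values clamped
#' to `[0, 1]` and monotone in p.
#'
#' @param p Vector of p-values.
#' @return List with `qvalue` (vector) and `pi0` (scalar).
#' @export
storey_qvalue <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (n >= 100 && var(pi0_l) > 0) {
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  } else {
    min(pi0_l[length(pi0_l)], 1)
  }
  pi0 <- min(max(pi0, 1 / n), 1)
  o <- order(p, decreasing = TRUE)
  q <- numeric(n)
  q[o] <- cummin(pi0 * n * p[o] / rank(p, ties.method = "max")[o])
  list(qvalue = pmin(q, 1), pi0 = pi0)
}

#' P and q values for per-chromosome maximum LODs
#'
#' Converts each trait x chromosome maximum LOD to a permutation P value,
#' `P = (1 + #{null >= obs}) / (n_perm + 1)` against the matching stratum's
#' null distribution, then computes Storey q-values across all tests.
#'
#' @param maxima Tibble with columns `trait`, `chr`, `kind`, `lod` (e.g. from
#'   a scan set via the internal per-chromosome maxima helper).
#' @param thresholds A `"perm_thresholds"` object carrying the null
#'   distributions.
#' @return `maxima` with added `p`, `q` columns; pi0 in attribute `"pi0"`.
#' @export
lod_to_pq <- function(maxima, thresholds) {
  null_a <- thresholds$null$autosome
  null_x <- thresholds$null$x
  p <- vapply(seq_len(nrow(maxima)), function(i) {
    nd <- if (maxima$kind[i] == "X") null_x else null_a
    if (!length(nd)) return(NA_real_)
    (1 + sum(nd >= maxima$lod[i])) / (length(nd) + 1)
  }, numeric(1))
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort("permutation P value outside (0, 1]")
  qv <- storey_qvalue(p[!is.na(p)])
  out <- maxima
  out$p <- p
  out$q <- NA_real_
  out$q[!is.na(p)] <- qv$qvalue
  attr(out, "pi0") <- qv$pi0
  out
}

# ---- LOD support intervals -------------------------------------------------

#' LOD support interval
#'
#' The outermost grid positions on a chromosome with LOD within `drop` of the
#' peak, each extended outward by one grid position where available (the
#' conventional approximate confidence region for a QTL location). A
#' two-peak profile whose flanks both clear `peak - drop` yields one wide
#' interval spanning both peaks - the outermost-position rule is applied
#' literally.
#'
#' @param scan A `"qtl_scan"` tibble from [scan_single()].
#' @param chr Chromosome label.
#' @param drop LOD units to descend from the peak (default 1.5).
#' @return One-row tibble: `chr`, `lo`, `hi`, `peak_pos`, `peak_lod`.
#' @export
lod_support_interval <- function(scan, chr, drop = 1.5) {
  sub <- scan[scan$chr == chr, ]
  if (!nrow(sub)) abort(sprintf("chromosome %s not scanned", chr))
  peak_idx <- which.max(sub$lod)  # leftmost maximum
  peak <- sub$lod[peak_idx]
  if (peak <= 0) {
    warn("flat zero LOD profile; returning whole-chromosome interval")
    return(tibble(chr = chr, lo = min(sub$pos), hi = max(sub$pos),
                  peak_pos = sub$pos[peak_idx], peak_lod = peak))
  }
  inside <- which(sub$lod >= peak - drop)
  lo_idx <- max(min(inside) - 1L, 1L)
  hi_idx <- min(max(inside) + 1L, nrow(sub))
  tibble(chr = chr, lo = sub$pos[lo_idx], hi = sub$pos[hi_idx],
         peak_pos = sub$pos[peak_idx], peak_lod = peak)
}
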