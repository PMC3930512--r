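#' Normal quantile rank transform
#'
#' Maps values to `qnorm((rank - 0.5) / n)` over the non-missing entries,
#' with ties given average ranks. After the transform every trait shares the
#' same marginal distribution, so a permutation threshold derived from a
#' single transformed trait applies to all of them.
#'
#' @param x Numeric vector (at least 3 non-missing values).
#' @return Transformed vector; missing entries stay missing.
#' @export
#' @examples
#' nqrank(c(3, 1, 2))
nqrank <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 3L) abort("nqrank needs at least 3 non-missing values")
  v <- x[ok]
  if (length(unique(v)) == 1L) {
    warn("all values identical; normal quantile ranks set to 0")
    x[ok] <- 0
    return(x)
  }
  n <- length(v)
  x[ok] <- qnorm((rank(v, ties.method = "average") - 0.5) / n)
  x
}

# ---- covariate construction ------------------------------------------------

# Covariate design columns from the most probable genotype class at a typed
# marker. Autosome: additive dosage (0,1,2) and het indicator; X-male: a
# single 0/1 dosage. Individuals with ambiguous class get NA.
covariate_columns <- function(gp, marker) {
  mc <- marker_class(gp, marker)
  if (mc$kind == "X") {
    list(add = as.numeric(mc$class == 2L), het = NULL,
         chr = mc$chr, pos = mc$pos, kind = mc$kind)
  } else {
    list(add = as.numeric(mc$class) - 1, het = as.numeric(mc$class == 2L),
         chr = mc$chr, pos = mc$pos, kind = mc$kind)
  }
}

# ---- Haley-Knott core ------------------------------------------------------

# Multi-trait Haley-Knott scan. Y: n x T matrix (complete); rows follow
# gp$ind[keep]. covar: NULL or covariate_columns() output subset to `keep`;
# model "additive" adds the covariate columns to both hypotheses, "full"
# additionally interacts the covariate with the scanned locus (covariate
# additive dosage x scan dosage, plus het x het-probability when both loci
# are autosomal). LOD = (n/2) log10(RSS_null / RSS_model).
hk_engine <- function(gp, Y, keep = NULL, covar = NULL,
                      model = c("additive", "full"), chrs = NULL) {
  model <- match.arg(model)
  if (is.null(keep)) keep <- seq_along(gp$ind)
  n <- length(keep)
  stopifnot(nrow(Y) == n)
  if (is.null(chrs)) chrs <- names(gp$chr)
  X0 <- cbind(rep(1, n), covar$add, covar$het)
  rss0 <- colSums(qr.resid(qr(X0), Y)^2)
  grid_list <- list(); lod_list <- list()
  n_degenerate <- 0L
  for (ch in chrs) {
    el <- gp$chr[[ch]]
    n_pos <- length(el$pos)
    lod <- matrix(NA_real_, n_pos, ncol(Y))
    for (t in seq_len(n_pos)) {
      P <- el$prob[keep, t, , drop = TRUE]
      if (is.null(dim(P))) P <- matrix(P, nrow = n)
      X1 <- cbind(P, covar$add, covar$het)
      if (!is.null(covar) && model == "full") {
        dose <- if (el$kind == "X") P[, 2] else P[, 2] + 2 * P[, 3]
        X1 <- cbind(X1, covar$add * dose)
        if (el$kind == "autosome" && !is.null(covar$het)) {
          X1 <- cbind(X1, covar$het * P[, 2])
        }
      }
      rss1 <- colSums(qr.resid(qr(X1), Y)^2)
      n_degenerate <- n_degenerate + sum(rss1 < 1e-10)
      rss1 <- pmax(rss1, 1e-12)  # perfect fits capped rather than infinite
      lod[t, ] <- (n / 2) * log10(rss0 / rss1)
    }
    lod_list[[ch]] <- lod
    grid_list[[ch]] <- tibble(chr = ch, kind = el$kind, pos = el$pos,
                              marker = el$marker)
  }
  list(grid = bind_rows(grid_list), lod = do.call(rbind, lod_list),
       rss0 = rss0, n = n, n_degenerate = n_degenerate)
}

# ---- EM (normal mixture) interval mapping ----------------------------------

# Single-trait EM at one position. w: n x k genotype weights; covariate
# design columns are shared across classes under the additive model and
# class-specific under the full model.
em_fit <- function(y, w, covar = NULL, model = "additive",
                   tol = 1e-6, maxit = 1000L) {
  n <- length(y); k <- ncol(w)
  # stacked design: n*k rows, class indicators + covariate block
  cls <- rep(seq_len(k), each = n)
  D <- matrix(0, n * k, k)
  D[cbind(seq_len(n * k), cls)] <- 1
  if (!is.null(covar)) {
    cc <- cbind(covar$add, covar$het)
    if (model == "full") {
      for (j in seq_len(ncol(cc))) D <- cbind(D, cc[rep(seq_len(n), k), j] * D[, seq_len(k)])
    } else {
      D <- cbind(D, cc[rep(seq_len(n), k), , drop = FALSE])
    }
  }
  yy <- rep(y, k)
  post <- w / rowSums(w)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    fit <- lm.wfit(D, yy, w = as.vector(post))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0  # classes with no posterior mass are inert
    mu_vec <- as.vector(D %*% beta)
    mu <- matrix(mu_vec, n, k)
    sigma2 <- sum(as.vector(post) * (yy - mu_vec)^2) / n
    sigma2 <- max(sigma2, 1e-12)
    dens <- w * exp(-(y - mu)^2 / (2 * sigma2)) / sqrt(2 * pi * sigma2)
    tot <- rowSums(dens)
    ll <- sum(log(pmax(tot, 1e-300)))
    post <- dens / pmax(tot, 1e-300)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1e-8)) break
    ll_old <- ll
  }
  ll
}

em_null_loglik <- function(y, covar = NULL) {
  n <- length(y)
  X0 <- cbind(rep(1, n), covar$add, covar$het)
  rss0 <- sum(qr.resid(qr(X0), y)^2)
  -n / 2 * (log(2 * pi * max(rss0, 1e-12) / n) + 1)
}

# ---- user-facing scans -----------------------------------------------------

#' Single-QTL genome scan for one trait
#'
#' Interval mapping over the marker + pseudomarker grid, by Haley-Knott
#' regression on expected genotype dosages (`method = "hk"`) or by the
#' EM-algorithm normal mixture (`method = "em"`). With a genotype covariate,
#' the null model contains the covariate terms, so the LOD measures the
#' locus's contribution beyond the covariate; `covariate_model = "full"` adds
#' locus x covariate interaction terms.
#'
#' @param trait Named numeric vector (names = individual ids). Missing values
#'   drop the individual from this scan only.
#' @param gp A [calc_genoprob()] result.
#' @param method `"hk"` or `"em"`.
#' @param covariate Optional marker name used as a genotype covariate (taken
#'   as the most probable class at that marker; ties are treated as missing).
#' @param covariate_model `"additive"` or `"full"`.
#' @return A tibble of class `"qtl_scan"`: `chr`, `kind`, `pos`, `marker`,
#'   `lod`, with method/covariate metadata in attributes.
#' @export
scan_single <- function(trait, gp, method = c("hk", "em"),
                        covariate = NULL,
                        covariate_model = c("additive", "full")) {
  method <- match.arg(method)
  covariate_model <- match.arg(covariate_model)
  y <- trait[gp$ind]
  covar <- if (!is.null(covariate)) covariate_columns(gp, covariate)
  keep <- which(!is.na(y) & (is.null(covar) | !is.na(covar$add %||% 0)))
  if (!is.null(covar)) {
    if (mean(is.na(covar$add)) > 0.2) {
      abort("covariate genotype missing for more than 20% of individuals")
    }
    covar_k <- list(add = covar$add[keep], het = covar$het[keep],
                    chr = covar$chr, pos = covar$pos, kind = covar$kind)
  } else covar_k <- NULL
  y <- as.numeric(y[keep])
  if (method == "hk") {
    res <- hk_engine(gp, matrix(y, ncol = 1), keep = keep, covar = covar_k,
                     model = covariate_model)
    out <- res$grid
    out$lod <- as.vector(res$lod)
    if (res$n_degenerate > 0) {
      warn(sprintf("%d position(s) with zero residual variance; LOD capped",
                   res$n_degenerate))
    }
  } else {
    ll0 <- em_null_loglik(y, covar_k)
    out <- NULL
    rows <- list()
    for (ch in names(gp$chr)) {
      el <- gp$chr[[ch]]
      lods <- vapply(seq_along(el$pos), function(t) {
        w <- el$prob[keep, t, , drop = TRUE]
        if (is.null(dim(w))) w <- matrix(w, nrow = length(keep))
        ll1 <- em_fit(y, w, covar_k, covariate_model)
        max((ll1 - ll0) / log(10), 0)
      }, numeric(1))
      rows[[ch]] <- tibble(chr = ch, kind = el$kind, pos = el$pos,
                           marker = el$marker, lod = lods)
    }
    out <- bind_rows(rows)
  }
  structure(as_tibble(out), class = c("qtl_scan", class(tibble())),
            method = method, covariate = covariate,
            covariate_model = if (!is.null(covariate)) covariate_model,
            n = length(keep))
}

#' Haley-Knott genome scan for a trait matrix
#'
#' Scans many traits at once (shared individuals, no missing values) with
#' the vectorised Haley-Knott engine; this is the workhorse behind
#' dataset-wide permutations and eQTL catalogues.
#'
#' @param Y Numeric matrix, individuals x traits, rownames = individual ids.
#' @param gp A [calc_genoprob()] result.
#' @param covariate,covariate_model As in [scan_single()].
#' @return A list of class `"qtl_scan_set"`: `grid` tibble, `lod` matrix
#'   (grid positions x traits), `traits`, and metadata.
#' @export
scan_traits <- function(Y, gp, covariate = NULL,
                        covariate_model = c("additive", "full")) {
  covariate_model <- match.arg(covariate_model)
  stopifnot(!anyNA(Y))
  ord <- match(gp$ind, rownames(Y))
  if (anyNA(ord)) abort("Y must contain every cross individual")
  Y <- Y[ord, , drop = FALSE]
  covar <- if (!is.null(covariate)) covariate_columns(gp, covariate)
  keep <- seq_along(gp$ind)
  if (!is.null(covar) && anyNA(covar$add)) {
    keep <- which(!is.na(covar$add))
    covar <- list(add = covar$add[keep], het = covar$het[keep],
                  chr = covar$chr, pos = covar$pos, kind = covar$kind)
    Y <- Y[keep, , drop = FALSE]
  }
  res <- hk_engine(gp, Y, keep = keep, covar = covar,
                   model = if (is.null(covar)) "additive" else covariate_model)
  structure(list(grid = res$grid, lod = res$lod, traits = colnames(Y),
                 method = "hk", covariate = covariate,
                 covariate_model = if (!is.null(covariate)) covariate_model,
                 n = nrow(Y)),
            class = "qtl_scan_set")
}

#' @export
print.qtl_scan_set <- function(x, ...) {
  cat(sprintf("HK scan set: %d traits x %d grid positions (n = %d%s)\n",
              ncol(x$lod), nrow(x$grid), x$n,
              if (!is.null(x$covariate)) {
                sprintf(", covariate %s [%s]", x$covariate, x$covariate_model)
              } else ""))
  invisible(x)
}

#' Tidy a scan set into a long tibble
#'
#' @param x A `"qtl_scan_set"`.
#' @param ... Unused.
#' @return Tibble `trait`, `chr`, `kind`, `pos`, `marker`, `lod`.
#' @export
tidy.qtl_scan_set <- function(x, ...) {
  g <- x$grid
  tibble(trait = rep(x$traits, each = nrow(g)),
         chr = rep(g$chr, times = ncol(x$lod)),
         kind = rep(g$kind, times = ncol(x$lod)),
         pos = rep(g$pos, times = ncol(x$lod)),
         marker = rep(g$marker, times = ncol(x$lod)),
         lod = as.vector(x$lod))
}

# Per-trait, per-chromosome maximum LOD (leftmost max).
scan_set_maxima <- function(x) {
  g <- x$grid
  bind_rows(lapply(unique(g$chr), function(ch) {
    idx <- which(g$chr == ch)
    sub <- x$lod[idx, , drop = FALSE]
    best <- max.col(t(sub), ties.method = "first")
    tibble(trait = x$traits, chr = ch, kind = g$kind[idx[1]],
           pos = g$pos[idx[best]],
           lod = sub[cbind(best, seq_len(ncol(sub)))])
  }))
}
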