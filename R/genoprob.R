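# Hidden-Markov genotype probabilities on a marker + pseudomarker grid.
#
# States are true genotypes ({AA, AB, BB} on autosomes, {A, B} on the male
# X). Transitions come from interval recombination fractions under the
# configured map function; the autosomal F2 transition matrix is the tensor
# product of two independent gamete chains. Emissions give probability
# 1 - error_rate to the observed class, error_rate split evenly across
# mismatches; missing observations (and pseudomarkers) emit uniformly.

f2_transition <- function(r) {
  rbind(c((1 - r)^2, 2 * r * (1 - r), r^2),
        c(r * (1 - r), (1 - r)^2 + r^2, r * (1 - r)),
        c(r^2, 2 * r * (1 - r), (1 - r)^2))
}

xmale_transition <- function(r) {
  rbind(c(1 - r, r), c(r, 1 - r))
}

# Forward-backward smoothing for one chromosome, vectorised over
# individuals. obs: integer matrix n x n_pos (class index, NA = missing /
# pseudomarker); trans: list of k x k matrices per interval.
forward_backward <- function(obs, trans, prior, error_rate, k) {
  n <- nrow(obs); n_pos <- ncol(obs)
  emit <- function(t) {
    E <- matrix(1, n, k)
    o <- obs[, t]
    typed <- which(!is.na(o))
    if (length(typed)) {
      E[typed, ] <- error_rate / (k - 1)
      E[cbind(typed, o[typed])] <- 1 - error_rate
    }
    E
  }
  fwd <- vector("list", n_pos)
  f <- matrix(prior, n, k, byrow = TRUE) * emit(1)
  f <- f / rowSums(f)
  fwd[[1]] <- f
  for (t in seq_len(n_pos - 1L)) {
    f <- (f %*% trans[[t]]) * emit(t + 1L)
    f <- f / rowSums(f)
    fwd[[t + 1L]] <- f
  }
  post <- array(NA_real_, c(n, n_pos, k))
  b <- matrix(1, n, k)
  p <- fwd[[n_pos]]
  post[, n_pos, ] <- p / rowSums(p)
  for (t in seq(n_pos - 1L, length.out = n_pos - 1L, by = -1L)) {
    b <- (b * emit(t + 1L)) %*% t(trans[[t]])
    b <- b / rowSums(b)
    p <- fwd[[t]] * b
    post[, t, ] <- p / rowSums(p)
  }
  post
}

#' Genotype probabilities on a marker + pseudomarker grid
#'
#' Runs forward-backward smoothing per chromosome and individual over an
#' intercross hidden Markov model, returning class probabilities at every
#' marker and at pseudomarkers spaced `step` cM apart.
#'
#' @param cross An [f2_cross()].
#' @param step Pseudomarker spacing in cM.
#' @param error_rate Assumed genotyping error rate.
#' @param map_function Map function for interval recombination fractions.
#' @return An object of class `"genoprob"`: per chromosome a list with `pos`,
#'   `marker`, `kind`, `classes`, and `prob` (array individuals x positions x
#'   classes), plus metadata.
#' @export
#' @examples
#' map <- simulate_map(1, lengths = 40, marker_spacing = 20, x_length = NULL)
#' cross <- simulate_f2(map, n = 5, seed = 1)
#' gp <- calc_genoprob(cross, step = 10, error_rate = 0)
#' dim(gp$chr[["1"]]$prob)
calc_genoprob <- function(cross, step = 2, error_rate = 0.001,
                          map_function = "carter_falconer") {
  map <- cross$map
  grid <- map_grid(map, step)
  out <- list()
  for (ch in unique(map$chr)) {
    sub_map <- map[map$chr == ch, ]
    sub_grid <- grid[grid$chr == ch, ]
    kind <- sub_map$kind[1]
    if (!kind %in% c("autosome", "X")) abort("unknown chromosome kind")
    k <- if (kind == "X") 2L else 3L
    classes <- if (kind == "X") c("A", "B") else c("AA", "AB", "BB")
    obs <- matrix(NA_integer_, nrow(cross$geno), nrow(sub_grid))
    at_marker <- !is.na(sub_grid$marker)
    codes <- cross$geno[, sub_grid$marker[at_marker], drop = FALSE]
    obs[, at_marker] <- match(codes, classes)
    r <- map_to_recfrac(diff(sub_grid$pos), map_function)
    trans <- lapply(r, if (kind == "X") xmale_transition else f2_transition)
    prior <- if (kind == "X") c(0.5, 0.5) else c(0.25, 0.5, 0.25)
    post <- forward_backward(obs, trans, prior, error_rate, k)
    dimnames(post) <- list(rownames(cross$geno), NULL, classes)
    out[[ch]] <- list(pos = sub_grid$pos, marker = sub_grid$marker,
                      kind = kind, classes = classes, prob = post)
  }
  structure(list(chr = out, ind = rownames(cross$geno), step = step,
                 error_rate = error_rate, map_function = map_function,
                 map = map),
            class = "genoprob")
}

#' @export
print.genoprob <- function(x, ...) {
  cat(sprintf(
    "genotype probabilities: %d individuals, %d chromosomes, %d grid positions\n",
    length(x$ind), length(x$chr),
    sum(vapply(x$chr, function(ch) length(ch$pos), integer(1)))))
  cat(sprintf("  step %g cM, error rate %g, %s map function\n",
              x$step, x$error_rate, x$map_function))
  invisible(x)
}

#' Tidy genotype probabilities
#'
#' @param x A `"genoprob"` object.
#' @param ... Unused.
#' @return A long tibble: `ind`, `chr`, `pos`, `marker`, `class`, `prob`.
#' @export
tidy.genoprob <- function(x, ...) {
  bind_rows(lapply(names(x$chr), function(ch) {
    el <- x$chr[[ch]]
    n <- dim(el$prob)[1]; p <- dim(el$prob)[2]; k <- dim(el$prob)[3]
    tibble(ind = rep(x$ind, times = p * k),
           chr = ch,
           pos = rep(rep(el$pos, each = n), times = k),
           marker = rep(rep(el$marker, each = n), times = k),
           class = rep(el$classes, each = n * p),
           prob = as.vector(el$prob))
  }))
}

# Grid of a genoprob object as a tibble (chr, kind, pos, marker).
genoprob_grid <- function(gp) {
  bind_rows(lapply(names(gp$chr), function(ch) {
    tibble(chr = ch, kind = gp$chr[[ch]]$kind,
           pos = gp$chr[[ch]]$pos, marker = gp$chr[[ch]]$marker)
  }))
}

# Most probable genotype class at a typed marker (ties -> NA).
marker_class <- function(gp, marker) {
  for (ch in names(gp$chr)) {
    el <- gp$chr[[ch]]
    j <- match(marker, el$marker)
    if (!is.na(j)) {
      pr <- el$prob[, j, , drop = TRUE]
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(el$classes))
      best <- max.col(pr, ties.method = "first")
      runner <- vapply(seq_len(nrow(pr)), function(i) {
        max(pr[i, -best[i]])
      }, numeric(1))
      best[abs(pr[cbind(seq_along(best), best)] - runner) < 1e-12] <- NA
      return(list(class = best, kind = el$kind, chr = ch,
                  pos = el$pos[j], classes = el$classes))
    }
  }
  abort(sprintf("marker %s not found", marker))
}
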