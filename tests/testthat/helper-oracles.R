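# Independent oracles used by the unit and acceptance tests.

# Brute-force genotype posterior for one individual on one chromosome by
# exhaustive enumeration of gamete configurations (independent of the
# forward-backward implementation).
#
# pos: grid positions; obs: observed class index per position (NA = missing
# or pseudomarker); r: recombination fractions between adjacent positions;
# kind: "autosome" or "X"; error_rate as in calc_genoprob.
enum_genoprob <- function(pos, obs, r, kind, error_rate) {
  m <- length(pos)
  k <- if (kind == "X") 2L else 3L
  gam_prob <- function(g) {
    p <- 0.5
    for (j in seq_len(m - 1L)) {
      p <- p * if (g[j] == g[j + 1L]) (1 - r[j]) else r[j]
    }
    p
  }
  emit <- function(geno_class, o) {
    if (is.na(o)) return(1)
    if (geno_class == o) 1 - error_rate else error_rate / (k - 1)
  }
  gametes <- as.matrix(expand.grid(rep(list(0:1), m)))
  post <- matrix(0, m, k)
  if (kind == "X") {
    for (i in seq_len(nrow(gametes))) {
      g <- gametes[i, ]
      cls <- g + 1L
      w <- gam_prob(g)
      for (t in seq_len(m)) w <- w * emit(cls[t], obs[t])
      for (t in seq_len(m)) post[t, cls[t]] <- post[t, cls[t]] + w
    }
  } else {
    for (i in seq_len(nrow(gametes))) {
      for (j in seq_len(nrow(gametes))) {
        cls <- gametes[i, ] + gametes[j, ] + 1L
        w <- gam_prob(gametes[i, ]) * gam_prob(gametes[j, ])
        for (t in seq_len(m)) w <- w * emit(cls[t], obs[t])
        for (t in seq_len(m)) post[t, cls[t]] <- post[t, cls[t]] + w
      }
    }
  }
  post / rowSums(post)
}

# Closed-form two-regression LOD at a fully typed marker.
lm_lod <- function(y, geno) {
  ok <- !is.na(y) & !is.na(geno)
  y <- y[ok]; geno <- geno[ok]
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ factor(geno)))^2)
  length(y) / 2 * log10(rss0 / pmax(rss1, 1e-12))
}

# Small two-chromosome map (one autosome + X) used across tests.
tiny_map <- function() {
  genetic_map(tibble::tibble(
    chr = c("1", "1", "1", "X", "X"),
    marker = c("m1", "m2", "m3", "x1", "x2"),
    cM = c(0, 10, 20, 0, 10),
    Mb = c(0, 20, 40, 0, 20)))
}

# Hand-written canonical cross CSV fixture; returns its path.
write_cross_fixture <- function(path = tempfile(fileext = ".csv"),
                                x_code_bad = FALSE) {
  lines <- c(
    "id,m1,m2,m3,x1,x2",
    ",1,1,1,X,X",
    ",0,10,20,0,10",
    paste0("ind1,AA,AB,BB,A,", if (x_code_bad) "AB" else "B"),
    "ind2,BB,-,AA,B,A")
  writeLines(lines, path)
  path
}
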