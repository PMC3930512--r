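# eQTL catalogue: peak extraction, cis/trans classification, dominance and
# effect annotation, enrichment tests, sterile-allele inference.

#' Extract significant eQTL peaks from a scan set
#'
#' Per trait and chromosome, keeps at most one record: the leftmost position
#' of maximum LOD when it exceeds the stratum threshold.
#'
#' @param scans A `"qtl_scan_set"` from [scan_traits()].
#' @param thresholds A `"perm_thresholds"` object.
#' @return Tibble `trait`, `chr`, `kind`, `pos`, `lod`.
#' @export
extract_peaks <- function(scans, thresholds) {
  maxima <- scan_set_maxima(scans)
  thr <- ifelse(maxima$kind == "X", thresholds$x, thresholds$autosome)
  maxima[!is.na(thr) & maxima$lod > thr, ]
}

#' Classify eQTL peaks as cis, trans, or excluded
#'
#' cis: peak on the probe's chromosome within `cis_window` cM of the probe
#' position; trans: peak on a different chromosome; excluded: same
#' chromosome but beyond the window (possibly long-range cis, so dropped
#' from hotspot analyses).
#'
#' @param peaks Tibble from [extract_peaks()] (trait = probe id).
#' @param probes Probe annotation (`probe_id`, `chr`, `cM`).
#' @param cis_window Window in cM.
#' @return `peaks` with `probe_chr`, `probe_cm`, `class` added.
#' @export
classify_cis_trans <- function(peaks, probes, cis_window = 5) {
  idx <- match(peaks$trait, probes$probe_id)
  if (anyNA(idx)) abort("peak trait(s) missing from probe annotation")
  out <- peaks
  out$probe_chr <- probes$chr[idx]
  out$probe_cm <- probes$cM[idx]
  same <- out$chr == out$probe_chr
  near <- abs(out$pos - out$probe_cm) < cis_window
  out$class <- ifelse(!same, "trans", ifelse(near, "cis", "excluded"))
  out
}

#' Classify dominance and effect size at a peak marker
#'
#' Compares genotype-class means of the trait at an (observed) marker. With
#' class standard errors `se = sd / sqrt(n)`: additive when the heterozygote
#' mean is intermediate and more than `se_mult` SEs from both homozygote
#' means; dominant when it is within `se_mult` SEs of one homozygote and
#' beyond for the other; over-/underdominant when it lies outside the
#' homozygote range and beyond `se_mult` SEs of the extreme homozygote.
#' "Within" comparisons are inclusive so that noiseless class means classify
#' exactly. Effect size is the absolute difference between extreme
#' homozygote (or hemizygote) means.
#'
#' @param values Numeric trait vector.
#' @param geno Genotype codes (`AA`/`AB`/`BB`, or `A`/`B` for the male X) of
#'   the same length.
#' @param se_mult SE multiplier.
#' @param min_n Minimum individuals per class (otherwise `unclassified`).
#' @return List: `dominance`, `effect`, `high_allele`, `low_allele`.
#' @export
classify_dominance_effect <- function(values, geno, se_mult = 2, min_n = 3) {
  ok <- !is.na(values) & !is.na(geno)
  values <- values[ok]; geno <- geno[ok]
  classes <- sort(unique(geno))
  is_x <- all(classes %in% c("A", "B"))
  stat <- function(cl) {
    v <- values[geno == cl]
    list(n = length(v), mean = mean(v),
         se = if (length(v) > 1) sd(v) / sqrt(length(v)) else Inf)
  }
  if (is_x) {
    sA <- stat("A"); sB <- stat("B")
    if (sA$n < min_n || sB$n < min_n) {
      return(list(dominance = "unclassified", effect = NA_real_,
                  high_allele = NA_character_, low_allele = NA_character_))
    }
    return(list(dominance = "additive_hemizygous",
                effect = abs(sB$mean - sA$mean),
                high_allele = if (sB$mean >= sA$mean) "B" else "A",
                low_allele = if (sB$mean >= sA$mean) "A" else "B"))
  }
  sAA <- stat("AA"); sAB <- stat("AB"); sBB <- stat("BB")
  if (sAA$n < min_n || sAB$n < min_n || sBB$n < min_n) {
    return(list(dominance = "unclassified", effect = NA_real_,
                high_allele = NA_character_, low_allele = NA_character_))
  }
  effect <- abs(sBB$mean - sAA$mean)
  het <- sAB$mean
  lo <- min(sAA$mean, sBB$mean); hi <- max(sAA$mean, sBB$mean)
  d_aa <- abs(het - sAA$mean); d_bb <- abs(het - sBB$mean)
  far_aa <- d_aa > se_mult * sAA$se
  far_bb <- d_bb > se_mult * sBB$se
  near_aa <- d_aa <= se_mult * sAA$se
  near_bb <- d_bb <= se_mult * sBB$se
  ext <- if (het > hi) {
    list(se = if (sAA$mean >= sBB$mean) sAA$se else sBB$se, d = het - hi)
  } else if (het < lo) {
    list(se = if (sAA$mean <= sBB$mean) sAA$se else sBB$se, d = lo - het)
  } else NULL
  dominance <-
    if (!is.null(ext) && ext$d > se_mult * ext$se) {
      if (het > hi) "overdominant" else "underdominant"
    } else if (het >= lo && het <= hi && far_aa && far_bb) {
      "additive"
    } else if (near_aa && far_bb) {
      "dominant_A"
    } else if (near_bb && far_aa) {
      "dominant_B"
    } else "unclassified"
  means <- c(AA = sAA$mean, AB = sAB$mean, BB = sBB$mean)
  hi_cl <- names(means)[which.max(means)]
  lo_cl <- names(means)[which.min(means)]
  to_allele <- function(cl) switch(cl, AA = "A", BB = "B", AB = "het")
  list(dominance = dominance, effect = effect,
       high_allele = to_allele(hi_cl), low_allele = to_allele(lo_cl))
}

# Nearest observed (typed) marker to a grid position on a chromosome.
nearest_marker <- function(map, chr, pos) {
  sub <- map[map$chr == chr, ]
  sub$marker[which.min(abs(sub$cM - pos))]
}

#' Annotate eQTL records with dominance, effect size, and alleles
#'
#' Dominance is assessed at the typed marker nearest each peak using
#' the observed genotype classes and the (untransformed) expression values.
#'
#' @param records Tibble from [classify_cis_trans()].
#' @param expr An [expression_set()].
#' @param cross The [f2_cross()].
#' @param se_mult,min_n Passed to [classify_dominance_effect()].
#' @return `records` with `marker`, `dominance`, `effect`, `high_allele`,
#'   `low_allele` added.
#' @export
annotate_dominance <- function(records, expr, cross, se_mult = 2, min_n = 3) {
  vals <- f2_slice(expr, rownames(cross$geno))
  ids <- colnames(vals)
  out <- records
  out$marker <- vapply(seq_len(nrow(records)), function(i) {
    nearest_marker(cross$map, records$chr[i], records$pos[i])
  }, character(1))
  res <- lapply(seq_len(nrow(out)), function(i) {
    geno <- cross$geno[ids, out$marker[i]]
    classify_dominance_effect(vals[out$trait[i], ], geno, se_mult, min_n)
  })
  out$dominance <- vapply(res, `[[`, character(1), "dominance")
  out$effect <- vapply(res, `[[`, numeric(1), "effect")
  out$high_allele <- vapply(res, `[[`, character(1), "high_allele")
  out$low_allele <- vapply(res, `[[`, character(1), "low_allele")
  out
}

#' Hypergeometric enrichment test
#'
#' Upper-tail probability of observing at least the overlap between a QTT
#' set and an annotation set drawn from a common probe universe, with
#' Bonferroni adjustment across `n_tests`.
#'
#' @param qtt,annotation,universe Character vectors of probe ids
#'   (`qtt`, `annotation` must be subsets of `universe`).
#' @param n_tests Number of tests for the Bonferroni correction.
#' @return One-row tibble: `overlap`, `expected`, `p`, `p_adjusted`.
#' @export
enrichment_test <- function(qtt, annotation, universe, n_tests = 1) {
  if (!length(universe)) abort("empty probe universe")
  if (!all(qtt %in% universe) || !all(annotation %in% universe)) {
    abort("qtt and annotation sets must be subsets of the universe")
  }
  N <- length(unique(universe))
  K <- length(unique(annotation))
  n <- length(unique(qtt))
  k <- length(intersect(unique(qtt), unique(annotation)))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(overlap = k, expected = n * K / N, p = p,
         p_adjusted = min(1, p * n_tests))
}

#' Infer the sterile allele of a trans hotspot
#'
#' For each member QTT with an F1 misexpression call, the candidate sterile
#' genotype class is the one matching the F1 direction: F1-underexpressed
#' transcripts vote for the member eQTL's low-expression class,
#' F1-overexpressed for its high class. The majority class wins when its
#' concordance reaches `min_concordance`; the heterozygous class is eligible
#' only when at least `het_fraction` of member eQTL are over- or
#' underdominant. Hotspots with fewer than `min_members` member eQTL are
#' `undetermined`.
#'
#' @param members Annotated member records (from [annotate_dominance()]).
#' @param f1_calls Tibble from [classify_f1_misexpression()].
#' @param min_members Minimum member count.
#' @param min_concordance Winning-vote fraction.
#' @param het_fraction Over/underdominant fraction required for a `het` call.
#' @param phenotype_cor Optional `probes` tibble from
#'   [correlate_with_phenotype()] against a fertility phenotype.
#' @return List: `allele` (`A`/`B`/`het`/`undetermined`), `concordance`
#'   (named fractions), `n_votes`, and `frac_low_positive_cor` when
#'   correlations are supplied.
#' @export
infer_sterile_allele <- function(members, f1_calls, min_members = 20,
                                 min_concordance = 0.6, het_fraction = 0.5,
                                 phenotype_cor = NULL) {
  out <- list(allele = "undetermined", concordance = c(A = NA_real_,
              B = NA_real_, het = NA_real_), n_votes = 0L,
              frac_low_positive_cor = NA_real_)
  if (nrow(members) < min_members) return(out)
  status <- f1_calls$status[match(members$trait, f1_calls$probe_id)]
  vote <- ifelse(status == "under", members$low_allele,
                 ifelse(status == "over", members$high_allele, NA))
  vote <- vote[!is.na(vote)]
  if (!length(vote)) return(out)
  tab <- table(factor(vote, levels = c("A", "B", "het")))
  conc <- as.numeric(tab) / length(vote)
  names(conc) <- names(tab)
  out$concordance <- conc
  out$n_votes <- length(vote)
  winner <- names(conc)[which.max(conc)]
  od_frac <- mean(members$dominance %in% c("overdominant", "underdominant"))
  if (conc[winner] >= min_concordance &&
      (winner != "het" || od_frac >= het_fraction)) {
    out$allele <- winner
  }
  if (!is.null(phenotype_cor)) {
    r <- phenotype_cor$r[match(members$trait, phenotype_cor$probe_id)]
    low_is_winner <- members$low_allele == out$allele
    sel <- !is.na(r) & !is.na(low_is_winner) & low_is_winner
    if (any(sel)) out$frac_low_positive_cor <- mean(r[sel] > 0)
  }
  out
}
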