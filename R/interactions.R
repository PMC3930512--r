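# Covariate-conditional scans, interaction LOD calibration by same-seed
# permutation, interaction-eQTL and interaction-hotspot calling, and network
# assembly.

#' Conditional genome scan for one trait
#'
#' Scans the trait twice with the genotype at `covariate` as a covariate -
#' once under the additive model and once under the full model with locus x
#' covariate interaction terms - on the same individuals, and reports
#' `lod_i = lod_f - lod_a` as interaction evidence. Positions within
#' `mask_cm` of the covariate marker are masked to guard against trivial
#' self-interactions from collinearity.
#'
#' @param trait Named numeric vector.
#' @param gp A [calc_genoprob()] result.
#' @param covariate Covariate marker name.
#' @param mask_cm Self-interaction mask radius in cM.
#' @return Tibble of class `"cond_scan"`: `chr`, `kind`, `pos`, `marker`,
#'   `lod_f`, `lod_a`, `lod_i`, `masked`.
#' @export
conditional_scan <- function(trait, gp, covariate, mask_cm = 5) {
  add <- scan_single(trait, gp, method = "hk", covariate = covariate,
                     covariate_model = "additive")
  full <- scan_single(trait, gp, method = "hk", covariate = covariate,
                      covariate_model = "full")
  out <- add[, c("chr", "kind", "pos", "marker")]
  out$lod_f <- full$lod
  out$lod_a <- add$lod
  out$lod_i <- out$lod_f - out$lod_a
  cc <- covariate_columns(gp, covariate)
  out$masked <- out$chr == cc$chr & abs(out$pos - cc$pos) < mask_cm
  out$lod_i[out$masked] <- NA_real_
  structure(out, class = c("cond_scan", class(tibble())),
            covariate = covariate, mask_cm = mask_cm)
}

#' Conditional genome scan for a trait matrix
#'
#' Matrix version of [conditional_scan()]: full and additive covariate
#' models for many traits at once via the vectorised Haley-Knott engine.
#'
#' @param Y Numeric matrix, individuals x traits (complete).
#' @param gp A [calc_genoprob()] result.
#' @param covariate Covariate marker name.
#' @param mask_cm Self-interaction mask radius in cM.
#' @return A list of class `"cond_scan_set"` with `grid`, `lod_f`, `lod_a`,
#'   `lod_i` matrices (positions x traits), and `masked`.
#' @export
conditional_scan_set <- function(Y, gp, covariate, mask_cm = 5) {
  add <- scan_traits(Y, gp, covariate = covariate,
                     covariate_model = "additive")
  full <- scan_traits(Y, gp, covariate = covariate,
                      covariate_model = "full")
  cc <- covariate_columns(gp, covariate)
  masked <- add$grid$chr == cc$chr & abs(add$grid$pos - cc$pos) < mask_cm
  structure(list(grid = add$grid, lod_f = full$lod, lod_a = add$lod,
                 lod_i = full$lod - add$lod, masked = masked,
                 traits = add$traits, covariate = covariate,
                 mask_cm = mask_cm, n = add$n),
            class = "cond_scan_set")
}

#' Interaction thresholds by same-seed permutation
#'
#' Each permutation shuffles the trait once and scans the same shuffled
#' vector under both the full and additive covariate models, so the
#' per-permutation interaction LOD is the difference of paired profiles -
#' never mixed across permutations. Per-stratum maxima of `lod_f`, `lod_a`,
#' and `lod_i` yield thresholds at the length-partitioned `1 - alpha`
#' quantiles.
#'
#' @param trait Named numeric vector (a representative transformed trait).
#' @param gp A [calc_genoprob()] result.
#' @param covariate Covariate marker.
#' @param n_perm Autosomal permutation count (>= 100).
#' @param alpha Significance level.
#' @param seed RNG seed.
#' @param mask_cm Self-interaction mask radius.
#' @param n_perm_x X-stratum count (defaults to the map-length scaling).
#' @return List of class `"interaction_thresholds"` with `f`, `a`, `i`
#'   threshold pairs (autosome/X) and the null maxima.
#' @export
interaction_thresholds <- function(trait, gp, covariate, n_perm = 1000,
                                   alpha = 0.05, seed = 1L, mask_cm = 5,
                                   n_perm_x = NULL) {
  stopifnot(n_perm >= 100)
  alphas <- stratum_alphas(gp$map, alpha)
  len <- map_stratum_lengths(gp$map)
  has_x <- len["X"] > 0
  if (is.null(n_perm_x)) {
    n_perm_x <- if (has_x) round(n_perm * len["autosome"] / len["X"]) else 0L
  }
  y <- trait[gp$ind]
  cc <- covariate_columns(gp, covariate)
  keep <- which(!is.na(y) & !is.na(cc$add))
  y <- as.numeric(y[keep])
  covar <- list(add = cc$add[keep], het = cc$het[keep], chr = cc$chr,
                pos = cc$pos, kind = cc$kind)
  auto_chrs <- names(gp$chr)[vapply(gp$chr, function(e) e$kind == "autosome",
                                    logical(1))]
  x_chrs <- setdiff(names(gp$chr), auto_chrs)
  perm_max <- function(n_p, chrs) {
    if (!length(chrs) || n_p < 1) {
      return(list(f = numeric(), a = numeric(), i = numeric()))
    }
    Y <- vapply(seq_len(n_p), function(i) sample(y), numeric(length(y)))
    rf <- hk_engine(gp, Y, keep = keep, covar = covar, model = "full",
                    chrs = chrs)
    ra <- hk_engine(gp, Y, keep = keep, covar = covar, model = "additive",
                    chrs = chrs)
    mask <- rf$grid$chr == covar$chr & abs(rf$grid$pos - covar$pos) < mask_cm
    li <- rf$lod - ra$lod
    li[mask, ] <- NA
    lf <- rf$lod; lf[mask, ] <- NA
    list(f = apply(lf, 2, max, na.rm = TRUE),
         a = apply(ra$lod, 2, max),
         i = apply(li, 2, max, na.rm = TRUE))
  }
  withr::with_seed(seed, {
    na <- perm_max(n_perm, auto_chrs)
    nx <- perm_max(n_perm_x, x_chrs)
  })
  thr <- function(v, a) if (length(v)) null_quantile(v, a) else NA_real_
  structure(list(
    f = c(autosome = thr(na$f, alphas["autosome"]), X = thr(nx$f, alphas["X"])),
    a = c(autosome = thr(na$a, alphas["autosome"]), X = thr(nx$a, alphas["X"])),
    i = c(autosome = thr(na$i, alphas["autosome"]), X = thr(nx$i, alphas["X"])),
    alpha = alpha, n_perm = n_perm, n_perm_x = n_perm_x, seed = seed,
    covariate = covariate,
    null = list(autosome = na, x = nx)
  ), class = "interaction_thresholds")
}

#' @export
print.interaction_thresholds <- function(x, ...) {
  cat(sprintf(
    "interaction thresholds (covariate %s): LOD_f %.2f/%.2f, LOD_i %.2f/%.2f (autosome/X)\n",
    x$covariate, x$f["autosome"], x$f["X"], x$i["autosome"], x$i["X"]))
  invisible(x)
}

#' Call interaction eQTL from a conditional scan
#'
#' Per chromosome, at most one record: the position maximising `lod_f` among
#' unmasked positions where both `lod_f` and `lod_i` exceed their stratum
#' thresholds.
#'
#' @param cond A `"cond_scan"` (or one trait of a conditional scan set).
#' @param thresholds An [interaction_thresholds()] result.
#' @param trait Trait id recorded in the output.
#' @return Tibble `trait`, `covariate`, `chr`, `kind`, `pos`, `lod_f`,
#'   `lod_i`.
#' @export
call_interaction_eqtl <- function(cond, thresholds, trait = "trait") {
  covariate <- attr(cond, "covariate")
  rows <- list()
  for (ch in unique(cond$chr)) {
    sub <- cond[cond$chr == ch & !cond$masked, ]
    if (!nrow(sub)) next
    stratum <- if (sub$kind[1] == "X") "X" else "autosome"
    ok <- sub$lod_f > thresholds$f[stratum] &
      sub$lod_i > thresholds$i[stratum]
    ok[is.na(ok)] <- FALSE
    if (!any(ok)) next
    sub <- sub[ok, ]
    best <- which.max(sub$lod_f)
    rows[[ch]] <- tibble(trait = trait, covariate = covariate, chr = ch,
                         kind = sub$kind[1], pos = sub$pos[best],
                         lod_f = sub$lod_f[best], lod_i = sub$lod_i[best])
  }
  bind_rows(rows)
}

# Interaction eQTL for every trait of a conditional scan set.
call_interaction_eqtl_set <- function(cs, thresholds) {
  g <- cs$grid
  rows <- list()
  for (ch in unique(g$chr)) {
    idx <- which(g$chr == ch & !cs$masked)
    if (!length(idx)) next
    stratum <- if (g$kind[g$chr == ch][1] == "X") "X" else "autosome"
    lf <- cs$lod_f[idx, , drop = FALSE]
    li <- cs$lod_i[idx, , drop = FALSE]
    ok <- lf > thresholds$f[stratum] & li > thresholds$i[stratum]
    lf_ok <- ifelse(ok, lf, -Inf)
    best <- max.col(t(lf_ok), ties.method = "first")
    has <- apply(ok, 2, any)
    if (!any(has)) next
    sel <- which(has)
    rows[[ch]] <- tibble(trait = cs$traits[sel], covariate = cs$covariate,
                         chr = ch,
                         kind = g$kind[g$chr == ch][1],
                         pos = g$pos[idx][best[sel]],
                         lod_f = lf[cbind(best[sel], sel)],
                         lod_i = li[cbind(best[sel], sel)])
  }
  bind_rows(rows)
}

#' Interaction hotspots for one covariate
#'
#' Applies the trans-hotspot machinery (sliding windows and the
#' chromosome-reassignment null) to the trans subset of a covariate's
#' interaction eQTL.
#'
#' @param records Interaction eQTL tibble (from [call_interaction_eqtl()])
#'   with probe annotation columns `probe_chr` added via
#'   [classify_cis_trans()] or a probes table.
#' @param probes Probe annotation (`probe_id`, `chr`, `cM`).
#' @param map A [genetic_map()].
#' @param n_perm,alpha,window,step,seed Passed to the hotspot machinery.
#' @return A `"hotspot_set"` tibble (possibly empty).
#' @export
interaction_hotspots <- function(records, probes, map, n_perm = 200,
                                 alpha = 0.05, window = 4, step = 2,
                                 seed = 1L) {
  if (!nrow(records)) {
    return(call_hotspots(window_counts(records[0, ], map, window, step),
                         tibble(size = numeric(), threshold = numeric()),
                         records[0, ], map))
  }
  idx <- match(records$trait, probes$probe_id)
  records$probe_chr <- probes$chr[idx]
  trans <- records[records$chr != records$probe_chr, ]
  counts <- window_counts(trans, map, window, step)
  if (!nrow(trans)) {
    return(call_hotspots(counts, tibble(size = numeric(),
                                        threshold = numeric()), trans, map))
  }
  thr <- hotspot_null_thresholds(trans, map, n_perm = max(n_perm, 100),
                                 alpha = alpha, window = window, step = step,
                                 seed = seed)
  call_hotspots(counts, thr, trans, map)
}

# ---- network assembly ------------------------------------------------------

#' Assemble the interaction network
#'
#' Nodes are genomic regions: interaction-hotspot intervals and covariate
#' marker positions, merged by single linkage when same-chromosome regions
#' are closer than `merge_mb`. Edges point from the covariate's node to each
#' of its hotspot nodes, weighted by the summed interaction-eQTL count;
#' an edge present in both orientations is flagged reciprocal (both
#' directions are flagged).
#'
#' @param hotspot_tbl Tibble with one row per (covariate, hotspot): columns
#'   `covariate`, `covariate_chr`, `covariate_mb`, `chr`, `lo_mb`, `hi_mb`,
#'   `count`.
#' @param merge_mb Merge distance in Mb.
#' @param sterile_alleles Optional named vector covariate -> allele used to
#'   colour nodes.
#' @return List of class `"eqtl_network"`: `nodes` (`node`, `chr`, `lo_mb`,
#'   `hi_mb`, `sterile_allele`) and `edges` (`from`, `to`, `count`,
#'   `reciprocal`).
#' @export
build_network <- function(hotspot_tbl, merge_mb = 12.8,
                          sterile_alleles = NULL) {
  regions <- bind_rows(
    tibble(chr = hotspot_tbl$chr, lo = hotspot_tbl$lo_mb,
           hi = hotspot_tbl$hi_mb),
    distinct(tibble(chr = hotspot_tbl$covariate_chr,
                    lo = hotspot_tbl$covariate_mb,
                    hi = hotspot_tbl$covariate_mb))
  )
  regions <- distinct(regions)
  regions <- regions[order(regions$chr, regions$lo, regions$hi), ]
  # single-linkage merge: same chromosome, boundary gap < merge_mb
  regions$node <- NA_integer_
  node_id <- 0L
  for (ch in unique(regions$chr)) {
    idx <- which(regions$chr == ch)
    cur_hi <- -Inf
    for (i in idx) {
      if (regions$lo[i] - cur_hi < merge_mb && is.finite(cur_hi)) {
        regions$node[i] <- node_id
        cur_hi <- max(cur_hi, regions$hi[i])
      } else {
        node_id <- node_id + 1L
        regions$node[i] <- node_id
        cur_hi <- regions$hi[i]
      }
    }
  }
  nodes <- regions |>
    group_by(.data$node) |>
    summarise(chr = .data$chr[1], lo_mb = min(.data$lo),
              hi_mb = max(.data$hi), .groups = "drop") |>
    mutate(node = sprintf("%s:%.1f-%.1f", .data$chr, .data$lo_mb,
                          .data$hi_mb))
  region_node <- function(chr, lo, hi) {
    hit <- which(nodes$chr == chr & nodes$lo_mb <= hi & nodes$hi_mb >= lo)
    nodes$node[hit[1]]
  }
  edges <- tibble(
    from = vapply(seq_len(nrow(hotspot_tbl)), function(i) {
      region_node(hotspot_tbl$covariate_chr[i], hotspot_tbl$covariate_mb[i],
                  hotspot_tbl$covariate_mb[i])
    }, character(1)),
    to = vapply(seq_len(nrow(hotspot_tbl)), function(i) {
      region_node(hotspot_tbl$chr[i], hotspot_tbl$lo_mb[i],
                  hotspot_tbl$hi_mb[i])
    }, character(1)),
    count = hotspot_tbl$count,
    covariate = hotspot_tbl$covariate
  )
  edges <- edges |>
    group_by(.data$from, .data$to) |>
    summarise(count = sum(.data$count),
              covariate = paste(unique(.data$covariate), collapse = ","),
              .groups = "drop")
  key <- paste(edges$from, edges$to, sep = "->")
  rev_key <- paste(edges$to, edges$from, sep = "->")
  edges$reciprocal <- rev_key %in% key & edges$from != edges$to
  nodes$sterile_allele <- NA_character_
  if (!is.null(sterile_alleles) && nrow(hotspot_tbl)) {
    for (cv in names(sterile_alleles)) {
      row <- hotspot_tbl[hotspot_tbl$covariate == cv, ][1, ]
      if (!is.na(row$covariate_chr)) {
        nd <- region_node(row$covariate_chr, row$covariate_mb,
                          row$covariate_mb)
        nodes$sterile_allele[nodes$node == nd] <- sterile_alleles[[cv]]
      }
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "eqtl_network")
}

#' @export
print.eqtl_network <- function(x, ...) {
  cat(sprintf("interaction network: %d nodes, %d edges (%d reciprocal)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$reciprocal)))
  invisible(x)
}

#' Summarise conditional-mapping results for one covariate
#'
#' Reports the number of interaction eQTL and hotspots and three
#' percentages: interaction eQTL whose trait had a significant
#' original (no-covariate) eQTL within `window` cM of the covariate, the
#' analogue at the peak, and those with a significant interaction eQTL in
#' the reversed covariate/peak configuration.
#'
#' @param records Interaction eQTL for the covariate.
#' @param original Original eQTL catalogue (tibble with `trait`, `chr`,
#'   `pos`).
#' @param all_records Interaction eQTL across all covariates (for the
#'   reciprocal lookup); covariate positions via `covariate_pos` tibble
#'   (`marker`, `chr`, `pos`).
#' @param covariate_pos Tibble mapping covariate markers to `chr`, `pos`.
#' @param hotspots Optional `"hotspot_set"` for this covariate.
#' @param window Matching tolerance in cM.
#' @return One-row tibble of class `"covariate_summary"`.
#' @export
covariate_summary <- function(records, original, all_records, covariate_pos,
                              hotspots = NULL, window = 5) {
  cov <- records$covariate[1] %||% NA_character_
  n <- nrow(records)
  if (!n) {
    return(tibble(covariate = cov, n_interaction_eqtl = 0L,
                  n_hotspots = 0L, n_chr_hotspots = 0L,
                  pct_covariate_marginal = 0, pct_peak_marginal = 0,
                  pct_reciprocal = 0))
  }
  cp <- covariate_pos[covariate_pos$marker == cov, ]
  near <- function(tbl, trait, chr, pos) {
    any(tbl$trait == trait & tbl$chr == chr & abs(tbl$pos - pos) < window)
  }
  cov_marg <- vapply(seq_len(n), function(i) {
    near(original, records$trait[i], cp$chr, cp$pos)
  }, logical(1))
  peak_marg <- vapply(seq_len(n), function(i) {
    near(original, records$trait[i], records$chr[i], records$pos[i])
  }, logical(1))
  # reversed configuration: same trait, covariate at the peak position's
  # marker, peak near this covariate's position
  pos_of_cov <- setNames(covariate_pos$pos, covariate_pos$marker)
  chr_of_cov <- setNames(covariate_pos$chr, covariate_pos$marker)
  recip <- vapply(seq_len(n), function(i) {
    cand <- all_records[all_records$trait == records$trait[i] &
                          all_records$covariate != cov, ]
    if (!nrow(cand)) return(FALSE)
    c_chr <- chr_of_cov[cand$covariate]
    c_pos <- pos_of_cov[cand$covariate]
    any(c_chr == records$chr[i] & abs(c_pos - records$pos[i]) < window &
          cand$chr == cp$chr & abs(cand$pos - cp$pos) < window,
        na.rm = TRUE)
  }, logical(1))
  n_hot <- if (is.null(hotspots)) NA_integer_ else nrow(hotspots)
  n_chr_hot <- if (is.null(hotspots)) NA_integer_ else length(unique(hotspots$chr))
  tibble(covariate = cov, n_interaction_eqtl = n,
         n_hotspots = n_hot, n_chr_hotspots = n_chr_hot,
         pct_covariate_marginal = 100 * mean(cov_marg),
         pct_peak_marginal = 100 * mean(peak_marg),
         pct_reciprocal = 100 * mean(recip))
}
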