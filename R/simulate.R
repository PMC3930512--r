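#' Simulate a mouse-like genetic map
#'
#' Evenly spaced markers on each chromosome; defaults emulate a mouse F2
#' panel: 19 autosomes of 50-90 cM plus an X of 84 cM, with roughly 200
#' markers genome-wide. Physical positions are assigned as `mb_per_cm` times
#' the cM position.
#'
#' @param n_autosomes Number of autosomes.
#' @param lengths Autosome lengths in cM (recycled/truncated to
#'   `n_autosomes`).
#' @param marker_spacing Marker spacing in cM.
#' @param x_length X-chromosome length in cM, or `NULL` for an autosome-only
#'   genome.
#' @param mb_per_cm Mb per cM scale for physical positions.
#' @return A [genetic_map()].
#' @export
#' @examples
#' simulate_map(1, lengths = 40, marker_spacing = 10, x_length = NULL)
simulate_map <- function(n_autosomes = 19,
                         lengths = round(seq(90, 50, length.out = n_autosomes)),
                         marker_spacing = 8,
                         x_length = 84,
                         mb_per_cm = 2) {
  stopifnot(all(lengths > 0), marker_spacing > 0)
  lengths <- rep_len(lengths, n_autosomes)
  if (any(marker_spacing > lengths) ||
      (!is.null(x_length) && marker_spacing > x_length)) {
    abort("marker spacing exceeds a chromosome length (single-marker chromosome)")
  }
  chrs <- c(as.character(seq_len(n_autosomes)), if (!is.null(x_length)) "X")
  lens <- c(lengths, if (!is.null(x_length)) x_length)
  rows <- lapply(seq_along(chrs), function(i) {
    pos <- seq(0, lens[i], by = marker_spacing)
    if (max(pos) < lens[i]) pos <- c(pos, lens[i])
    tibble(chr = chrs[i],
           marker = sprintf("c%sm%02d", chrs[i], seq_along(pos)),
           cM = pos, Mb = mb_per_cm * pos)
  })
  genetic_map(bind_rows(rows))
}

#' Simulate an F2 intercross
#'
#' Gametes are generated by a sequential no-interference crossover process:
#' the allele at the first marker is uniform, and each adjacent interval
#' recombines independently with the fraction given by the configured map
#' function. Autosomal genotypes combine two independent F1 gametes; male X
#' genotypes come from a single recombinant maternal gamete (hemizygous).
#'
#' @param map A [genetic_map()].
#' @param n Number of F2 males.
#' @param seed RNG seed (the generator is a pure function of inputs + seed).
#' @param direction_mix Fraction of individuals from the MxD cross direction.
#' @param map_function Map function for interval recombination fractions; the
#'   default (`"haldane"`) matches the no-interference crossover process.
#' @param error_rate Probability that an emitted genotype code is replaced by
#'   a uniformly chosen wrong code.
#' @return An [f2_cross()]; the pre-error genotypes are kept in attribute
#'   `"true_geno"` and the seed in `"seed"`.
#' @export
simulate_f2 <- function(map, n, seed = 1L, direction_mix = 11 / 305,
                        map_function = "haldane", error_rate = 0) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    chrs <- unique(map$chr)
    geno_cols <- vector("list", length(chrs))
    for (ci in seq_along(chrs)) {
      sub <- map[map$chr == chrs[ci], ]
      m <- nrow(sub)
      r <- map_to_recfrac(diff(sub$cM), map_function)
      gamete <- function() {
        g <- matrix(0L, n, m)
        g[, 1] <- rbinom(n, 1L, 0.5)
        for (j in seq_len(m - 1L)) {
          sw <- rbinom(n, 1L, r[j])
          g[, j + 1L] <- (g[, j] + sw) %% 2L
        }
        g
      }
      if (sub$kind[1] == "X") {
        gx <- gamete()  # maternal gamete; male X is hemizygous
        codes <- matrix(c("A", "B")[gx + 1L], n, m)
      } else {
        g1 <- gamete(); g2 <- gamete()
        codes <- matrix(c("AA", "AB", "BB")[g1 + g2 + 1L], n, m)
      }
      colnames(codes) <- sub$marker
      geno_cols[[ci]] <- codes
    }
    geno <- do.call(cbind, geno_cols)[, map$marker, drop = FALSE]
    ids <- sprintf("F2_%04d", seq_len(n))
    rownames(geno) <- ids
    true_geno <- geno
    if (error_rate > 0) {
      for (kind in c("autosome", "X")) {
        mk <- map$marker[map$kind == kind]
        if (!length(mk)) next
        classes <- if (kind == "X") c("A", "B") else c("AA", "AB", "BB")
        sub <- geno[, mk, drop = FALSE]
        hit <- matrix(runif(length(sub)) < error_rate, nrow(sub), ncol(sub))
        idx <- which(hit & !is.na(sub))
        if (length(idx)) {
          sub[idx] <- vapply(sub[idx], function(g) {
            sample(setdiff(classes, g), 1L)
          }, character(1))
          geno[, mk] <- sub
        }
      }
    }
    n_mxd <- round(n * direction_mix)
    dir <- c(rep("MxD", n_mxd), rep("DxM", n - n_mxd))
    cross <- f2_cross(map, tibble(id = ids, cross_direction = dir), geno)
    attr(cross, "true_geno") <- true_geno
    attr(cross, "seed") <- seed
    cross
  })
}

# ---- simulation architecture ----------------------------------------------

#' Describe a simulated genetic architecture
#'
#' The architecture is the ground truth behind [simulate_expression()] and
#' [simulate_phenotypes()]: per-probe parental baselines, cis effects at
#' linked markers, trans "master regulator" loci of configurable dominance
#' mode, pairwise epistatic effects confined to named two-locus genotype
#' classes, and genotype-dependent sterility-phenotype QTL.
#'
#' Dominance modes translate into genotype-class multipliers of the effect:
#' additive `(0, 0.5, 1)` over (AA, AB, BB), `dominant_A` `(0, 0, 1)`,
#' `dominant_B` `(0, 1, 1)`, `overdominant` `(0, 1, 0)`, and `underdominant`
#' `(0, -1, 0)`. On the male X the two hemizygous classes get `(0, 1)`.
#'
#' @param probes Probe annotation tibble (`probe_id`, `gene`, `chr`, `cM`,
#'   `Mb`).
#' @param baseline Tibble `probe_id`, `parent_a`, `parent_b` (log2 baselines);
#'   defaults to 8 for both parents for every probe.
#' @param cis Tibble `probe_id`, `marker`, `effect`, `dom_dev` (heterozygote
#'   deviation from the additive midpoint).
#' @param masters Tibble `marker`, `mode`, `probes` (list column of probe
#'   ids), `effect` (scalar per row, log2 difference between extreme classes).
#' @param epistasis Tibble `marker1`, `marker2`, `probes` (list column),
#'   `effect`, `classes` (list column of named multipliers over two-locus
#'   classes `"g1:g2"`, e.g. from [epistasis_product_classes()]).
#' @param phenotype_qtl Tibble `marker`, `trait`, `effect`, `mode`.
#' @param phenotype_epistasis Tibble `marker1`, `marker2`, `trait`, `effect`,
#'   `classes` (named multipliers over two-locus classes), for
#'   Dobzhansky-Muller sterility confined to incompatible genotype
#'   combinations.
#' @param trait_baselines Tibble `trait`, `baseline`, `sd`.
#' @param noise_sd Gaussian noise SD for expression (log2 units).
#' @return A list of class `"sim_architecture"`.
#' @export
sim_architecture <- function(probes,
                             baseline = NULL,
                             cis = NULL,
                             masters = NULL,
                             epistasis = NULL,
                             phenotype_qtl = NULL,
                             phenotype_epistasis = NULL,
                             trait_baselines = NULL,
                             noise_sd = 0.5) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  empty <- function(...) tibble(...)
  if (is.null(baseline)) {
    baseline <- tibble(probe_id = probes$probe_id, parent_a = 8, parent_b = 8)
  }
  arch <- structure(list(
    probes = as_tibble(probes),
    baseline = as_tibble(baseline),
    cis = as_tibble(cis %||% empty(probe_id = character(), marker = character(),
                                   effect = numeric(), dom_dev = numeric())),
    masters = masters %||% empty(marker = character(), mode = character(),
                                 probes = list(), effect = numeric()),
    epistasis = epistasis %||% empty(marker1 = character(), marker2 = character(),
                                     probes = list(), effect = numeric(),
                                     classes = list()),
    phenotype_qtl = phenotype_qtl %||% empty(marker = character(),
                                             trait = character(),
                                             effect = numeric(),
                                             mode = character()),
    phenotype_epistasis = phenotype_epistasis %||%
      empty(marker1 = character(), marker2 = character(),
            trait = character(), effect = numeric(), classes = list()),
    trait_baselines = trait_baselines %||% empty(trait = character(),
                                                 baseline = numeric(),
                                                 sd = numeric()),
    noise_sd = noise_sd
  ), class = "sim_architecture")
  if (anyDuplicated(arch$cis$probe_id)) {
    abort("probe referenced in more than one cis entry")
  }
  modes <- c("additive", "dominant_A", "dominant_B", "overdominant",
             "underdominant")
  if (!all(arch$masters$mode %in% modes)) abort("unknown master-locus mode")
  if (!all(arch$phenotype_qtl$mode %in% modes)) abort("unknown phenotype QTL mode")
  arch
}

# Genotype-class multipliers per dominance mode (AA, AB, BB).
mode_multiplier <- function(mode) {
  switch(mode,
         additive = c(0, 0.5, 1),
         dominant_A = c(0, 0, 1),
         dominant_B = c(0, 1, 1),
         overdominant = c(0, 1, 0),
         underdominant = c(0, -1, 0),
         abort(sprintf("unknown mode '%s'", mode)))
}

#' Interaction multipliers with zero marginal effects
#'
#' Product contrast over two autosomal loci: `+1` for double homozygotes of
#' matching sign, `-1` for mismatching, `0` for any heterozygote. Under 1:2:1
#' segregation at both loci the per-locus marginal means are exactly zero, so
#' a pure-epistasis effect built from these classes is invisible to marginal
#' scans.
#'
#' @return Named numeric vector over `"g1:g2"` classes.
#' @export
epistasis_product_classes <- function() {
  s <- c(AA = -1, AB = 0, BB = 1)
  out <- outer(s, s)
  nm <- outer(names(s), names(s), function(a, b) paste(a, b, sep = ":"))
  setNames(as.vector(out), as.vector(nm))[as.vector(out) != 0]
}

# Genotype codes for a fixed-genotype sample group at given markers.
fixed_genotype <- function(group, map, markers) {
  kind <- map$kind[match(markers, map$marker)]
  auto <- switch(group, parentA = "AA", parentB = "BB",
                 F1_DxM = "AB", F1_MxD = "AB")
  # F1/parental males carry a single X: A when the mother is domesticus (A),
  # B when she is musculus (B).
  x <- switch(group, parentA = "A", parentB = "B", F1_DxM = "A", F1_MxD = "B")
  ifelse(kind == "X", x, auto)
}

geno_class_index <- function(codes, kind) {
  if (kind == "X") match(codes, c("A", "B")) else match(codes, c("AA", "AB", "BB"))
}

# Effect contribution matrix (probes x samples) for one architecture entry.
add_effect <- function(vals, probes_idx, contrib) {
  vals[probes_idx, ] <- vals[probes_idx, , drop = FALSE] +
    matrix(contrib, length(probes_idx), length(contrib), byrow = TRUE)
  vals
}

#' Simulate expression data for a cross
#'
#' Expression value = parental-lineage baseline + sum of genotype-dependent
#' effects + Gaussian noise. Parental and F1 control samples are generated
#' from the same generative rules with fixed genotypes, so downstream
#' misexpression classification sees internally consistent group structure.
#'
#' @param cross An [f2_cross()] (uses true pre-error genotypes when present).
#' @param arch A [sim_architecture()].
#' @param n_parent_a,n_parent_b,n_f1_dxm,n_f1_mxd Control sample sizes;
#'   defaults reflect a typical design (8 per parental line, 4 fertile DxM
#'   and 6 sterile MxD F1 males).
#' @param seed RNG seed.
#' @return An [expression_set()] with the realised architecture and seed in
#'   attribute `"ground_truth"`.
#' @export
simulate_expression <- function(cross, arch, n_parent_a = 8, n_parent_b = 8,
                                n_f1_dxm = 4, n_f1_mxd = 6, seed = 1L) {
  map <- cross$map
  refd <- unique(c(arch$cis$marker, arch$masters$marker,
                   arch$epistasis$marker1, arch$epistasis$marker2))
  missing_mk <- setdiff(refd, map$marker)
  if (length(missing_mk)) {
    abort(sprintf("architecture references unknown marker(s): %s",
                  paste(head(missing_mk, 3), collapse = ", ")))
  }
  geno <- attr(cross, "true_geno") %||% cross$geno
  f2_ids <- rownames(geno)
  groups <- c(rep("F2", length(f2_ids)),
              rep("parentA", n_parent_a), rep("parentB", n_parent_b),
              rep("F1_DxM", n_f1_dxm), rep("F1_MxD", n_f1_mxd))
  ids <- c(f2_ids,
           sprintf("PA_%02d", seq_len(n_parent_a)),
           sprintf("PB_%02d", seq_len(n_parent_b)),
           sprintf("F1DxM_%02d", seq_len(n_f1_dxm)),
           sprintf("F1MxD_%02d", seq_len(n_f1_mxd)))
  n_probe <- nrow(arch$probes)
  probe_ids <- arch$probes$probe_id

  # genotype class index at a marker for every sample (F2s from the cross,
  # control groups fixed)
  class_at <- function(marker) {
    kind <- map$kind[match(marker, map$marker)]
    codes <- character(length(ids))
    codes[groups == "F2"] <- geno[, marker]
    for (g in setdiff(unique(groups), "F2")) {
      codes[groups == g] <- fixed_genotype(g, map, marker)
    }
    list(idx = geno_class_index(codes, kind), kind = kind)
  }

  withr::with_seed(seed, {
    base_a <- arch$baseline$parent_a[match(probe_ids, arch$baseline$probe_id)]
    base_b <- arch$baseline$parent_b[match(probe_ids, arch$baseline$probe_id)]
    vals <- matrix((base_a + base_b) / 2, n_probe, length(ids))
    # lineage baselines for the pure parental groups
    vals[, groups == "parentA"] <- base_a
    vals[, groups == "parentB"] <- base_b

    # cis effects: effect * dosage/2 + dom_dev at heterozygotes
    if (nrow(arch$cis)) {
      for (i in seq_len(nrow(arch$cis))) {
        e <- arch$cis[i, ]
        cl <- class_at(e$marker)
        pi_ <- match(e$probe_id, probe_ids)
        if (cl$kind == "X") {
          contrib <- e$effect * c(0, 1)[cl$idx]
        } else {
          contrib <- e$effect * c(0, 0.5, 1)[cl$idx] + e$dom_dev * (cl$idx == 2)
        }
        contrib[is.na(contrib)] <- 0
        vals <- add_effect(vals, pi_, contrib)
      }
    }
    # master regulators
    if (nrow(arch$masters)) {
      for (i in seq_len(nrow(arch$masters))) {
        e <- arch$masters[i, ]
        cl <- class_at(e$marker)
        mult <- if (cl$kind == "X") c(0, 1) else mode_multiplier(e$mode)
        contrib <- e$effect * mult[cl$idx]
        contrib[is.na(contrib)] <- 0
        vals <- add_effect(vals, match(e$probes[[1]], probe_ids), contrib)
      }
    }
    # epistatic pairs: effect applied only in the named two-locus classes
    if (nrow(arch$epistasis)) {
      for (i in seq_len(nrow(arch$epistasis))) {
        e <- arch$epistasis[i, ]
        c1 <- class_at(e$marker1); c2 <- class_at(e$marker2)
        l1 <- if (c1$kind == "X") c("A", "B") else c("AA", "AB", "BB")
        l2 <- if (c2$kind == "X") c("A", "B") else c("AA", "AB", "BB")
        key <- paste(l1[c1$idx], l2[c2$idx], sep = ":")
        mult <- e$classes[[1]][key]
        mult[is.na(mult)] <- 0
        vals <- add_effect(vals, match(e$probes[[1]], probe_ids),
                           e$effect * unname(mult))
      }
    }
    if (arch$noise_sd > 0) {
      vals <- vals + matrix(rnorm(length(vals), 0, arch$noise_sd),
                            n_probe, length(ids))
    }
    dimnames(vals) <- list(probe_ids, ids)
    expr <- expression_set(tibble(id = ids, group = groups), vals, arch$probes)
    attr(expr, "ground_truth") <- list(architecture = arch, seed = seed)
    expr
  })
}

#' Simulate sterility phenotypes for a cross
#'
#' Trait value = baseline + genotype-dependent QTL contributions + Gaussian
#' noise, supporting an underdominant sterility locus (heterozygotes shifted
#' relative to both homozygote classes).
#'
#' @param cross An [f2_cross()].
#' @param arch A [sim_architecture()] with `phenotype_qtl` and
#'   `trait_baselines` filled in.
#' @param seed RNG seed.
#' @return Tibble `id` + one column per trait.
#' @export
simulate_phenotypes <- function(cross, arch, seed = 1L) {
  unknown <- setdiff(c(arch$phenotype_qtl$trait,
                       arch$phenotype_epistasis$trait),
                     arch$trait_baselines$trait)
  if (length(unknown)) {
    abort(sprintf("phenotype QTL references unknown trait(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  geno <- attr(cross, "true_geno") %||% cross$geno
  map <- cross$map
  ids <- rownames(geno)
  withr::with_seed(seed, {
    out <- tibble(id = ids)
    for (i in seq_len(nrow(arch$trait_baselines))) {
      tr <- arch$trait_baselines[i, ]
      y <- rep(tr$baseline, length(ids))
      qtl <- arch$phenotype_qtl[arch$phenotype_qtl$trait == tr$trait, ]
      for (j in seq_len(nrow(qtl))) {
        mk <- qtl$marker[j]
        kind <- map$kind[match(mk, map$marker)]
        idx <- geno_class_index(geno[, mk], kind)
        mult <- if (kind == "X") c(0, 1) else mode_multiplier(qtl$mode[j])
        contrib <- qtl$effect[j] * mult[idx]
        contrib[is.na(contrib)] <- 0
        y <- y + contrib
      }
      epi <- arch$phenotype_epistasis[arch$phenotype_epistasis$trait ==
                                        tr$trait, ]
      for (j in seq_len(nrow(epi))) {
        key <- paste(geno[, epi$marker1[j]], geno[, epi$marker2[j]],
                     sep = ":")
        mult <- epi$classes[[j]][key]
        mult[is.na(mult)] <- 0
        y <- y + epi$effect[j] * unname(mult)
      }
      out[[tr$trait]] <- y + rnorm(length(ids), 0, tr$sd)
    }
    out
  })
}

#' A mouse-like example architecture
#'
#' Builds the default study conditions used by the pipeline and worked
#' examples: a panel of probes spread over the genome, half of which carry cis
#' effects; an autosomal "sterility" master regulator with underdominant
#' phenotype effects (emulating the chromosome-17 pattern); an X-linked master
#' regulator; a pure-epistasis pair with zero marginal effects; and four
#' sterility traits with a shared underdominant QTL at the autosomal master.
#'
#' @param map A [genetic_map()].
#' @param n_probes Total number of probes.
#' @param n_cis Number of probes with cis effects.
#' @param n_master_targets Targets per master regulator.
#' @param cis_effect,master_effect,epistasis_effect Effect sizes (log2).
#' @param master_mode Dominance mode of the autosomal master regulator.
#' @param noise_sd Expression noise SD.
#' @param seed RNG seed for probe placement and target assignment.
#' @return A [sim_architecture()].
#' @export
example_architecture <- function(map, n_probes = 400,
                                 n_cis = round(0.375 * n_probes),
                                 n_master_targets = round(0.25 * n_probes),
                                 cis_effect = 1.0, master_effect = 0.8,
                                 epistasis_effect = 1.2,
                                 master_mode = "overdominant",
                                 noise_sd = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    chrs <- map_chromosomes(map)
    autos <- chrs$chr[chrs$kind == "autosome"]
    pick_chr <- sample(chrs$chr, n_probes, replace = TRUE,
                       prob = chrs$length / sum(chrs$length))
    pos <- vapply(pick_chr, function(ch) {
      runif(1, 0, chrs$length[chrs$chr == ch])
    }, numeric(1))
    probes <- tibble(probe_id = sprintf("probe_%04d", seq_len(n_probes)),
                     gene = sprintf("gene_%04d", seq_len(n_probes)),
                     chr = pick_chr, cM = round(pos, 2), Mb = round(2 * pos, 3))
    cis_idx <- sample.int(n_probes, n_cis)
    cis <- tibble(
      probe_id = probes$probe_id[cis_idx],
      marker = vapply(cis_idx, function(i) {
        sub <- map[map$chr == probes$chr[i], ]
        sub$marker[which.min(abs(sub$cM - probes$cM[i]))]
      }, character(1)),
      effect = cis_effect * sample(c(-1, 1), n_cis, replace = TRUE),
      dom_dev = 0
    )
    # autosomal sterility master (chr17-like) and an X master
    auto_master <- map$marker[map$chr == autos[min(17, length(autos))]][2]
    x_marker <- if (any(chrs$kind == "X")) {
      map$marker[map$kind == "X"][2]
    } else NULL
    non_cis <- setdiff(probes$probe_id, cis$probe_id)
    targets_a <- sample(non_cis, min(n_master_targets, length(non_cis)))
    masters <- tibble(marker = auto_master, mode = master_mode,
                      probes = list(targets_a), effect = master_effect)
    if (!is.null(x_marker)) {
      rest <- setdiff(non_cis, targets_a)
      targets_x <- sample(rest, min(n_master_targets %/% 2, length(rest)))
      masters <- bind_rows(masters,
                           tibble(marker = x_marker, mode = "additive",
                                  probes = list(targets_x),
                                  effect = master_effect))
    }
    # pure epistatic pair on two other autosomes
    ep_m1 <- map$marker[map$chr == autos[2]][3]
    ep_m2 <- map$marker[map$chr == autos[5]][3]
    ep_pool <- setdiff(non_cis, unlist(masters$probes))
    ep_targets <- sample(ep_pool, min(20, n_probes %/% 20, length(ep_pool)))
    epistasis <- tibble(marker1 = ep_m1, marker2 = ep_m2,
                        probes = list(ep_targets), effect = epistasis_effect,
                        classes = list(epistasis_product_classes()))
    traits <- c("testis_weight", "sperm_count", "abnormal_sperm",
                "tubule_area")
    trait_baselines <- tibble(trait = traits,
                              baseline = c(100, 40, 20, 50),
                              sd = c(8, 5, 4, 5))
    # underdominant multiplier is -1 at heterozygotes, so a positive effect
    # lowers the het mean (sterile hets) and a negative one raises it
    phenotype_qtl <- tibble(marker = auto_master, trait = traits,
                            effect = c(25, 12, -12, 12),
                            mode = "underdominant")
    sim_architecture(probes, cis = cis, masters = masters,
                     epistasis = epistasis, phenotype_qtl = phenotype_qtl,
                     trait_baselines = trait_baselines, noise_sd = noise_sd)
  })
}
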