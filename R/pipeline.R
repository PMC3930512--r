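# Pipeline orchestration: simulate -> analyze -> fertile-subset contrast.
# Stage seeds are derived from the master seed with fixed offsets so stages
# can be rerun independently yet reproducibly.

STAGE_SEEDS <- c(cross = 1L, architecture = 2L, expression = 3L,
                 phenotypes = 4L, thresholds = 10L, dataset = 11L,
                 misexpression = 12L, hotspots = 13L, colocalization = 14L,
                 interactions = 15L, fertile = 16L)

stage_seed <- function(config, stage) derive_seed(config$seed, STAGE_SEEDS[[stage]])

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a full study to disk
#'
#' Generates the default synthetic study - a mouse-like map, an F2 cross,
#' the example architecture, expression for F2s plus parental/F1 controls,
#' and sterility phenotypes - and writes the cross CSV, expression/probe/
#' sample TSVs, phenotype CSV, ground-truth JSON, and a run manifest with
#' file digests.
#'
#' @param out_dir Output directory.
#' @param config A [qtl_config()].
#' @param n Number of F2 males.
#' @param n_probes Number of probes.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
pipeline_simulate <- function(out_dir, config = qtl_config(), n = 300,
                              n_probes = 400, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    abort(sprintf("output directory %s exists; use force = TRUE", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  map <- simulate_map()
  cross <- simulate_f2(map, n = n, seed = stage_seed(config, "cross"))
  arch <- example_architecture(map, n_probes = n_probes,
                               seed = stage_seed(config, "architecture"))
  expr <- simulate_expression(cross, arch,
                              seed = stage_seed(config, "expression"))
  pheno <- simulate_phenotypes(cross, arch,
                               seed = stage_seed(config, "phenotypes"))
  cross$phenotypes <- pheno
  paths <- file.path(out_dir, c(
    geno = "cross.csv", pheno = "phenotypes.csv", map = "map.tsv",
    values = "expression.tsv", samples = "samples.tsv", probes = "probes.tsv",
    truth = "truth.json", manifest = "manifest.json"))
  names(paths) <- c("geno", "pheno", "map", "values", "samples", "probes",
                    "truth", "manifest")
  write_cross(cross, paths["geno"], paths["pheno"])
  write_table(map, paths["map"])
  write_expression(expr, paths["values"], paths["samples"], paths["probes"])
  truth <- list(
    seed = config$seed,
    stage_seeds = as.list(STAGE_SEEDS[1:4]),
    n_f2 = n, n_probes = n_probes,
    noise_sd = arch$noise_sd,
    cis = lapply(seq_len(nrow(arch$cis)), function(i) as.list(arch$cis[i, ])),
    masters = lapply(seq_len(nrow(arch$masters)), function(i) {
      list(marker = arch$masters$marker[i], mode = arch$masters$mode[i],
           effect = arch$masters$effect[i],
           probes = arch$masters$probes[[i]])
    }),
    epistasis = lapply(seq_len(nrow(arch$epistasis)), function(i) {
      list(marker1 = arch$epistasis$marker1[i],
           marker2 = arch$epistasis$marker2[i],
           effect = arch$epistasis$effect[i],
           probes = arch$epistasis$probes[[i]],
           classes = as.list(arch$epistasis$classes[[i]]))
    }),
    phenotype_qtl = lapply(seq_len(nrow(arch$phenotype_qtl)), function(i) {
      as.list(arch$phenotype_qtl[i, ])
    })
  )
  write_json_file(truth, paths["truth"])
  files <- setdiff(paths, paths["manifest"])
  write_json_file(list(
    kind = "simulate", seed = config$seed,
    config = unclass(config)[c("step", "error_rate", "map_function")],
    digests = as.list(setNames(tools::md5sum(sort(unname(files))),
                               basename(sort(unname(files)))))
  ), paths["manifest"])
  invisible(list(map = map, cross = cross, arch = arch, expr = expr,
                 phenotypes = pheno, paths = paths))
}

read_study <- function(data_dir) {
  p <- function(f) file.path(data_dir, f)
  cross <- read_cross(p("cross.csv"), p("phenotypes.csv"), p("map.tsv"))
  expr <- read_expression(p("expression.tsv"), p("samples.tsv"),
                          p("probes.tsv"))
  list(cross = cross, expr = expr)
}

# Core eQTL analysis shared by pipeline_analyze() and the fertile-subset
# rerun: genotype probabilities, normal-quantile transform, single-transcript
# thresholds, all-trait scans, peak extraction, cis/trans and dominance
# annotation, and trans-hotspot calling.
run_eqtl_analysis <- function(cross, expr, config, ids = NULL) {
  if (!is.null(ids)) {
    keep <- rownames(cross$geno) %in% ids
    cross <- f2_cross(cross$map,
                      cross$individuals[keep, ],
                      cross$geno[keep, , drop = FALSE],
                      cross$phenotypes[cross$phenotypes$id %in%
                                         rownames(cross$geno)[keep], ])
  }
  gp <- calc_genoprob(cross, step = config$step,
                      error_rate = config$error_rate,
                      map_function = config$map_function)
  vals <- f2_slice(expr, rownames(cross$geno))
  Y <- t(apply(vals, 1, nqrank))
  Yt <- t(Y)  # individuals x traits
  thr <- permutation_threshold(setNames(Yt[, 1], rownames(Yt)), gp,
                               n_perm = config$n_perm_single,
                               alpha = config$alpha,
                               seed = stage_seed(config, "thresholds"))
  scans <- scan_traits(Yt, gp)
  maxima <- scan_set_maxima(scans)
  peaks <- extract_peaks(scans, thr)
  records <- classify_cis_trans(peaks, expr$probes, config$cis_window)
  records <- annotate_dominance(records, expr, cross,
                                se_mult = config$se_mult)
  trans <- records[records$class == "trans", ]
  counts <- window_counts(trans, cross$map, config$hotspot_window,
                          config$step)
  hotspots <- if (nrow(trans)) {
    hthr <- hotspot_null_thresholds(trans, cross$map,
                                    n_perm = config$n_perm_hotspot,
                                    alpha = config$alpha,
                                    window = config$hotspot_window,
                                    step = config$step,
                                    seed = stage_seed(config, "hotspots"))
    call_hotspots(counts, hthr, trans, cross$map)
  } else {
    call_hotspots(counts, tibble(size = numeric(), threshold = numeric()),
                  trans, cross$map)
  }
  list(cross = cross, gp = gp, Y = Yt, thresholds = thr, scans = scans,
       maxima = maxima, records = records, trans = trans,
       window_counts = counts, hotspots = hotspots)
}

catalog_report <- function(records, thresholds) {
  by <- function(cls, kind) {
    sum(records$class == cls & (records$kind == "X") == (kind == "X"))
  }
  tibble(
    metric = c("threshold_autosome", "threshold_x",
               "n_cis_autosome", "n_cis_x", "n_trans_autosome", "n_trans_x",
               "n_excluded", "n_eqtl"),
    value = c(thresholds$autosome, thresholds$x,
              by("cis", "autosome"), by("cis", "X"),
              by("trans", "autosome"), by("trans", "X"),
              sum(records$class == "excluded"), nrow(records))
  )
}

#' Run the analysis pipeline on a simulated (or compatible) study
#'
#' Executes the requested stages in dependency order - `scan`,
#' `misexpression`, `catalog`, `hotspots`, `colocalize`, `interactions`,
#' `network` - writing TSV outputs and a manifest to `out_dir`.
#'
#' @param data_dir Directory produced by [pipeline_simulate()] (or files in
#'   the same layout).
#' @param out_dir Output directory (created as needed).
#' @param config A [qtl_config()].
#' @param stages Character vector of stages to run.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with the in-memory results.
#' @export
pipeline_analyze <- function(data_dir, out_dir,
                             config = qtl_config(),
                             stages = c("scan", "misexpression", "catalog",
                                        "hotspots", "colocalize",
                                        "interactions", "network"),
                             force = FALSE) {
  all_stages <- c("scan", "misexpression", "catalog", "hotspots",
                  "colocalize", "interactions", "network")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(catalog = "scan", hotspots = "catalog",
               colocalize = "hotspots", interactions = "hotspots",
               network = "interactions")
  for (s in stages) {
    missing_dep <- setdiff(deps[[s]], stages)
    if (length(missing_dep)) {
      abort(sprintf("stage '%s' requires stage '%s' to run first",
                    s, missing_dep[1]))
    }
  }
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    abort(sprintf("output directory %s exists; use force = TRUE", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- read_study(data_dir)
  cross <- study$cross; expr <- study$expr
  results <- list()
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_table(df, path)
    outputs <<- c(outputs, path)
  }

  core <- run_eqtl_analysis(cross, expr, config)
  if ("scan" %in% stages) {
    emit(core$maxima, "scan_maxima.tsv")
    emit(glance(core$thresholds), "thresholds.tsv")
  }
  results$core <- core

  if ("misexpression" %in% stages) {
    mis <- misexpression_counts(expr, config$mis_delta, config$se_mult)
    f1 <- classify_f1_misexpression(expr, "F1_MxD", config$mis_delta,
                                    config$fdr)
    mq <- map_misexpression_qtl(mis, core$gp,
                                n_perm = config$n_perm_single,
                                alpha = config$alpha,
                                seed = stage_seed(config, "misexpression"))
    emit(mis$counts, "misexpression_counts.tsv")
    emit(mis$prevalence, "misexpression_prevalence.tsv")
    emit(f1, "f1_misexpression.tsv")
    mq_peaks <- bind_rows(lapply(names(mq), function(ph) {
      el <- mq[[ph]]
      if (is.null(el$scan)) return(NULL)
      pk <- scan_set_maxima(structure(
        list(grid = el$scan[, c("chr", "kind", "pos", "marker")],
             lod = matrix(el$scan$lod, ncol = 1), traits = ph),
        class = "qtl_scan_set"))
      pk$threshold <- ifelse(pk$kind == "X", el$thresholds$x,
                             el$thresholds$autosome)
      pk[pk$lod > pk$threshold, ]
    }))
    emit(mq_peaks, "misexpression_qtl.tsv")
    results$misexpression <- list(counts = mis, f1 = f1, qtl = mq)
  }

  if ("catalog" %in% stages) {
    records <- core$records
    records$peak_mb <- vapply(seq_len(nrow(records)), function(i) {
      cm_to_mb(cross$map, records$chr[i], records$pos[i])
    }, numeric(1))
    emit(records, "eqtl_table.tsv")
    emit(catalog_report(records, core$thresholds), "report.tsv")
  }

  f1_calls <- results$misexpression$f1 %||%
    classify_f1_misexpression(expr, "F1_MxD", config$mis_delta, config$fdr)

  if ("hotspots" %in% stages) {
    hs <- core$hotspots
    if (nrow(hs)) {
      hs$sterile_allele <- vapply(seq_len(nrow(hs)), function(i) {
        mem <- core$trans[core$trans$chr == hs$chr[i] &
                            core$trans$pos >= hs$lo[i] &
                            core$trans$pos <= hs$hi[i], ]
        infer_sterile_allele(mem, f1_calls)$allele
      }, character(1))
    }
    emit(core$window_counts, "window_counts.tsv")
    emit(as_tibble(unclass(hs)), "hotspots.tsv")
    results$hotspots <- hs
  }

  if ("colocalize" %in% stages) {
    traits <- setdiff(names(cross$phenotypes), "id")
    intervals <- list()
    for (tr in traits) {
      y <- setNames(cross$phenotypes[[tr]], cross$phenotypes$id)
      if (all(is.na(y)) || var(y, na.rm = TRUE) == 0) next
      sc <- scan_single(y, core$gp, method = "hk")
      th <- permutation_threshold(y, core$gp,
                                  n_perm = config$n_perm_single,
                                  alpha = config$alpha,
                                  seed = stage_seed(config, "colocalization"))
      mx <- sc[which.max(sc$lod), ]
      thr0 <- if (mx$kind == "X") th$x else th$autosome
      if (mx$lod > thr0) {
        iv <- lod_support_interval(sc, mx$chr)
        intervals[[tr]] <- tibble(trait = tr, chr = iv$chr,
                                  peak_cM = iv$peak_pos, lo_cM = iv$lo,
                                  hi_cM = iv$hi, sterile_allele = "het")
      }
    }
    intervals <- bind_rows(intervals)
    emit(intervals, "sterility_intervals.tsv")
    if (nrow(intervals) && nrow(results$hotspots %||% core$hotspots)) {
      cr <- colocalization_test(results$hotspots %||% core$hotspots,
                                intervals, cross$map,
                                n_perm = config$n_perm_coloc,
                                step = config$step,
                                seed = stage_seed(config, "colocalization"))
      coloc_path <- file.path(out_dir, "colocalization.json")
      write_json_file(list(observed = as.list(cr$observed),
                           p = as.list(cr$p), n_perm = cr$n_perm), coloc_path)
      outputs <- c(outputs, coloc_path)
      results$colocalization <- cr
    }
    results$sterility_intervals <- intervals
  }

  if ("interactions" %in% stages) {
    hs <- results$hotspots %||% core$hotspots
    covariates <- character()
    if (nrow(hs)) {
      ord <- order(hs$count, decreasing = TRUE)
      top <- hs[head(ord, config$max_covariates), ]
      covariates <- vapply(seq_len(nrow(top)), function(i) {
        nearest_marker(cross$map, top$chr[i], (top$lo[i] + top$hi[i]) / 2)
      }, character(1))
    }
    int_records <- list(); int_hotspots <- list()
    for (ci in seq_along(covariates)) {
      cv <- covariates[ci]
      cs <- conditional_scan_set(core$Y, core$gp, cv)
      ith <- interaction_thresholds(
        setNames(core$Y[, 1], rownames(core$Y)), core$gp, cv,
        n_perm = config$n_perm_interaction, alpha = config$alpha,
        seed = derive_seed(stage_seed(config, "interactions"), ci))
      rec <- call_interaction_eqtl_set(cs, ith)
      int_records[[cv]] <- rec
      int_hotspots[[cv]] <- interaction_hotspots(
        rec, expr$probes, cross$map, n_perm = config$n_perm_interaction,
        alpha = config$alpha, window = config$hotspot_window,
        step = config$step,
        seed = derive_seed(stage_seed(config, "interactions"), 100 + ci))
    }
    all_rec <- bind_rows(int_records)
    emit(all_rec, "interaction_eqtl.tsv")
    covariate_pos <- tibble(
      marker = covariates,
      chr = cross$map$chr[match(covariates, cross$map$marker)],
      pos = cross$map$cM[match(covariates, cross$map$marker)])
    summaries <- bind_rows(lapply(covariates, function(cv) {
      covariate_summary(int_records[[cv]], core$records, all_rec,
                        covariate_pos, int_hotspots[[cv]],
                        window = config$cis_window)
    }))
    emit(summaries, "interaction_summary.tsv")
    results$interactions <- list(records = int_records,
                                 hotspots = int_hotspots,
                                 covariates = covariates,
                                 covariate_pos = covariate_pos,
                                 summaries = summaries)
  }

  if ("network" %in% stages) {
    ia <- results$interactions
    rows <- list()
    for (cv in ia$covariates) {
      hs <- ia$hotspots[[cv]]
      if (!nrow(hs)) next
      cp <- ia$covariate_pos[ia$covariate_pos$marker == cv, ]
      rows[[cv]] <- tibble(
        covariate = cv, covariate_chr = cp$chr,
        covariate_mb = cm_to_mb(cross$map, cp$chr, cp$pos),
        chr = hs$chr, lo_mb = hs$lo_mb, hi_mb = hs$hi_mb, count = hs$count)
    }
    tbl <- bind_rows(rows)
    if (nrow(tbl)) {
      net <- build_network(tbl, merge_mb = config$node_merge_mb)
      emit(net$nodes, "network_nodes.tsv")
      emit(net$edges, "network_edges.tsv")
      results$network <- net
    }
  }

  write_json_file(list(
    kind = "analyze", seed = config$seed, stages = stages,
    config = unclass(config),
    digests = as.list(setNames(tools::md5sum(sort(outputs)),
                               basename(sort(outputs))))
  ), file.path(out_dir, "manifest.json"))
  invisible(results)
}

#' Fertile-subset reanalysis
#'
#' Selects the fertile subset of F2s (first principal component of the four
#' sterility traits above the given percentile), reruns the scan/catalog/
#' hotspot analysis on the subset, and writes a comparison against the
#' full-data analysis (counts of cis/trans eQTL and hotspots).
#'
#' @param data_dir Directory from [pipeline_simulate()].
#' @param out_dir Output directory.
#' @param config A [qtl_config()].
#' @param traits Sterility trait names (default: the four simulated traits).
#' @param percentile PC1 percentile cut (default 0.20).
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with both analyses and the comparison tibble.
#' @export
pipeline_fertile_subset <- function(data_dir, out_dir,
                                    config = qtl_config(),
                                    traits = c("testis_weight", "sperm_count",
                                               "abnormal_sperm",
                                               "tubule_area"),
                                    percentile = 0.20, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    abort(sprintf("output directory %s exists; use force = TRUE", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- read_study(data_dir)
  fertile <- select_fertile_subset(study$cross$phenotypes, traits, percentile)
  full <- run_eqtl_analysis(study$cross, study$expr, config)
  sub <- run_eqtl_analysis(study$cross, study$expr, config, ids = fertile)
  cmp <- tibble(
    metric = c("n_individuals", "n_cis", "n_trans", "n_hotspots"),
    full = c(nrow(full$cross$geno), sum(full$records$class == "cis"),
             sum(full$records$class == "trans"), nrow(full$hotspots)),
    fertile = c(nrow(sub$cross$geno), sum(sub$records$class == "cis"),
                sum(sub$records$class == "trans"), nrow(sub$hotspots))
  )
  cmp$delta <- cmp$fertile - cmp$full
  write_table(cmp, file.path(out_dir, "fertile_comparison.tsv"))
  write_table(tibble(id = fertile), file.path(out_dir, "fertile_ids.tsv"))
  invisible(list(full = full, fertile = sub, comparison = cmp,
                 fertile_ids = fertile))
}
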