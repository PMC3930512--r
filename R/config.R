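#' Analysis configuration
#'
#' Collects the tunable constants shared across the pipeline stages. Defaults
#' are the conventional choices for mouse intercross eQTL studies: genotype
#' probabilities on a 2 cM grid with a genotyping error rate of 0.001, a 5 cM
#' cis window, misexpression calls requiring a log2 difference above 0.5 and
#' two standard errors, 4 cM sliding hotspot windows, and a 12.8 Mb
#' node-merging distance for the interaction network. Permutation counts
#' default to desk-scale values; set them to the publication-scale counts
#' (10,000 single-transcript, 360 dataset-wide, 10,000 hotspot/co-localization,
#' 1,000 interaction) for full-scale runs.
#'
#' @param step Pseudomarker grid step in cM.
#' @param error_rate Assumed genotyping error rate for the genotype-probability
#'   HMM.
#' @param map_function Map function used when converting cM distances to
#'   recombination fractions in analysis (`"carter_falconer"`, `"haldane"`, or
#'   `"kosambi"`).
#' @param cis_window Maximum distance (cM) between an eQTL peak and its probe
#'   for a cis call.
#' @param mis_delta Minimum log2 difference from the nearer parental mean for a
#'   misexpression call.
#' @param se_mult Multiplier on the parental standard error in the F2
#'   misexpression rule (and in dominance classification).
#' @param hotspot_window Sliding-window width (cM) for trans-eQTL counting.
#' @param node_merge_mb Merge distance (Mb) for collapsing interaction-hotspot
#'   regions into single network nodes.
#' @param alpha Genome-wide significance level, partitioned between autosomes
#'   and X by map length.
#' @param fdr False discovery rate used for differential expression and
#'   correlation calls.
#' @param n_perm_single,n_perm_dataset,n_perm_hotspot,n_perm_coloc,n_perm_interaction
#'   Permutation counts per stage.
#' @param max_covariates Maximum number of hotspot-derived covariates used in
#'   the conditional-mapping stage of [pipeline_analyze()].
#' @param seed Master seed; stage seeds are derived from it with fixed offsets.
#'
#' @return A list of class `"qtl_config"`.
#' @export
#' @examples
#' cfg <- qtl_config(n_perm_single = 100)
#' cfg$step
qtl_config <- function(step = 2,
                       error_rate = 0.001,
                       map_function = "carter_falconer",
                       cis_window = 5,
                       mis_delta = 0.5,
                       se_mult = 2,
                       hotspot_window = 4,
                       node_merge_mb = 12.8,
                       alpha = 0.05,
                       fdr = 0.05,
                       n_perm_single = 200,
                       n_perm_dataset = 50,
                       n_perm_hotspot = 200,
                       n_perm_coloc = 100,
                       n_perm_interaction = 100,
                       max_covariates = 3,
                       seed = 1L) {
  cfg <- list(
    step = step, error_rate = error_rate, map_function = map_function,
    cis_window = cis_window, mis_delta = mis_delta, se_mult = se_mult,
    hotspot_window = hotspot_window, node_merge_mb = node_merge_mb,
    alpha = alpha, fdr = fdr,
    n_perm_single = n_perm_single, n_perm_dataset = n_perm_dataset,
    n_perm_hotspot = n_perm_hotspot, n_perm_coloc = n_perm_coloc,
    n_perm_interaction = n_perm_interaction,
    max_covariates = max_covariates,
    seed = as.integer(seed)
  )
  num <- c("step", "cis_window", "mis_delta", "se_mult", "hotspot_window",
           "node_merge_mb", "n_perm_single", "n_perm_dataset",
           "n_perm_hotspot", "n_perm_coloc", "n_perm_interaction")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      abort(sprintf("config field `%s` must be a positive scalar", f))
    }
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    abort("`error_rate` must be in [0, 1)")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (cfg$fdr <= 0 || cfg$fdr >= 1) abort("`fdr` must be in (0, 1)")
  cfg$map_function <- match.arg(cfg$map_function,
                                c("carter_falconer", "haldane", "kosambi"))
  structure(cfg, class = "qtl_config")
}
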