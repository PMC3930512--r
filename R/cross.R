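#' Construct an F2 cross object
#'
#' Bundles a genetic map, individual metadata, the genotype matrix, and
#' phenotypes. Genotypes are coded `"AA"`, `"AB"`, `"BB"` on autosomes and
#' `"A"`, `"B"` on the X (all individuals are male, so X genotypes are
#' hemizygous), with `NA` for missing.
#'
#' @param map A [genetic_map()].
#' @param individuals Tibble with columns `id` and `cross_direction`
#'   (`"DxM"` or `"MxD"`); a `sex` column defaults to `"male"`.
#' @param geno Character matrix, individuals x markers, with rownames matching
#'   `individuals$id` and colnames matching `map$marker`.
#' @param phenotypes Tibble with an `id` column plus named numeric traits.
#' @return A list of class `"f2_cross"`.
#' @export
f2_cross <- function(map, individuals, geno, phenotypes = NULL) {
  individuals <- as_tibble(individuals)
  if (!"sex" %in% names(individuals)) individuals$sex <- "male"
  if (is.null(phenotypes)) phenotypes <- tibble(id = individuals$id)
  phenotypes <- as_tibble(phenotypes)
  cross <- structure(list(map = map, individuals = individuals,
                          geno = geno, phenotypes = phenotypes),
                     class = "f2_cross")
  validate_f2_cross(cross)
  cross
}

validate_f2_cross <- function(cross) {
  map <- cross$map; geno <- cross$geno
  if (!identical(colnames(geno), map$marker)) {
    abort("genotype columns do not match map markers")
  }
  if (!identical(rownames(geno), as.character(cross$individuals$id))) {
    abort("genotype rows do not match individuals")
  }
  x_markers <- map$marker[map$kind == "X"]
  if (length(x_markers)) {
    sub <- geno[, x_markers, drop = FALSE]
    bad <- which(sub == "AB", arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf(
        "heterozygous code on male X: individual %s at marker %s",
        rownames(geno)[bad[1, 1]], x_markers[bad[1, 2]]))
    }
    bad2 <- which(!(sub %in% c("A", "B") | is.na(sub)))
    if (length(bad2)) abort("invalid X genotype code")
  }
  auto_markers <- map$marker[map$kind == "autosome"]
  if (length(auto_markers)) {
    sub <- geno[, auto_markers, drop = FALSE]
    bad <- which(!(sub %in% c("AA", "AB", "BB") | is.na(sub)))
    if (length(bad)) abort("invalid autosomal genotype code")
  }
  extra <- setdiff(cross$phenotypes$id, cross$individuals$id)
  if (length(extra)) {
    abort(sprintf("phenotype rows for unknown individual(s): %s",
                  paste(head(extra, 3), collapse = ", ")))
  }
  invisible(cross)
}

#' @export
print.f2_cross <- function(x, ...) {
  chrs <- map_chromosomes(x$map)
  cat(sprintf("F2 intercross: %d individuals, %d markers on %d chromosomes (%s)\n",
              nrow(x$geno), ncol(x$geno), nrow(chrs),
              if (any(chrs$kind == "X")) "incl. X" else "autosomes only"))
  invisible(x)
}

# ---- cross CSV IO ----------------------------------------------------------
# Rotated-header dialect: row 1 = "id" + marker names; row 2 = chromosome
# labels; row 3 = cM positions; remaining rows = one individual each.

#' Read an F2 cross from CSV files
#'
#' @param geno_path Genotype CSV in the rotated-header dialect (see Details).
#' @param pheno_path Optional phenotype CSV (`id` column plus numeric traits).
#' @param map_path Optional marker TSV (`marker`, `chr`, `cM`, `Mb`) supplying
#'   physical positions absent from the cross CSV.
#' @param directions Optional named character vector id -> cross direction;
#'   defaults to `"DxM"`.
#'
#' @details The genotype file stores markers in columns: the first row holds
#' `id` followed by marker names, the second row chromosome labels, the third
#' row cM positions, and each following row one individual's codes
#' (`AA`/`AB`/`BB` on autosomes, `A`/`B` on the male X, `-` or empty for
#' missing). Unknown codes are converted to missing with a warning reporting
#' the count.
#'
#' @return An [f2_cross()].
#' @export
read_cross <- function(geno_path, pheno_path = NULL, map_path = NULL,
                       directions = NULL) {
  lines <- readLines(geno_path, encoding = "UTF-8")
  if (length(lines) < 4L) abort("cross CSV needs header rows plus individuals")
  cells <- strsplit(lines, ",", fixed = TRUE)
  markers <- cells[[1]][-1]
  chrs <- cells[[2]][-1]
  cms <- as.numeric(cells[[3]][-1])
  map <- genetic_map(tibble(chr = chrs, marker = markers, cM = cms))
  if (!is.null(map_path)) {
    ann <- readr_tsv(map_path)
    map$Mb <- ann$Mb[match(map$marker, ann$marker)]
    validate_genetic_map(map)
  }
  body <- cells[-(1:3)]
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids)) abort("duplicate individual ids in cross CSV")
  geno <- t(vapply(body, function(row) {
    row <- row[-1]
    length(row) <- length(markers)
    row
  }, character(length(markers))))
  geno[geno %in% c("-", "")] <- NA_character_
  valid <- c("AA", "AB", "BB", "A", "B")
  n_bad <- sum(!is.na(geno) & !(geno %in% valid))
  if (n_bad > 0) {
    warn(sprintf("%d unknown genotype code(s) set to missing", n_bad))
    geno[!is.na(geno) & !(geno %in% valid)] <- NA_character_
  }
  dimnames(geno) <- list(ids, markers)
  pheno <- if (!is.null(pheno_path)) {
    ph <- utils::read.csv(pheno_path, check.names = FALSE,
                          colClasses = c(id = "character"))
    as_tibble(ph)
  } else NULL
  dir <- rep("DxM", length(ids))
  if (!is.null(directions)) {
    dir <- unname(directions[ids])
    dir[is.na(dir)] <- "DxM"
  }
  f2_cross(map, tibble(id = ids, cross_direction = dir), geno, pheno)
}

#' Write an F2 cross to CSV files
#'
#' Inverse of [read_cross()]; writing then re-reading a canonical fixture is
#' the identity.
#'
#' @param cross An [f2_cross()].
#' @param geno_path,pheno_path Output paths (phenotypes skipped if `NULL`).
#' @return `geno_path`, invisibly.
#' @export
write_cross <- function(cross, geno_path, pheno_path = NULL) {
  map <- cross$map
  geno <- cross$geno
  geno[is.na(geno)] <- "-"
  lines <- c(
    paste(c("id", map$marker), collapse = ","),
    paste(c("", map$chr), collapse = ","),
    paste(c("", format_num(map$cM)), collapse = ","),
    vapply(seq_len(nrow(geno)), function(i) {
      paste(c(rownames(geno)[i], geno[i, ]), collapse = ",")
    }, character(1))
  )
  writeLines(lines, geno_path, useBytes = TRUE)
  if (!is.null(pheno_path) && ncol(cross$phenotypes) > 1L) {
    write_table(cross$phenotypes, pheno_path, sep = ",")
  }
  invisible(geno_path)
}

format_num <- function(x) {
  out <- vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      digits = 15), character(1))
  out[is.na(x)] <- "NA"
  out
}

write_table <- function(df, path, sep = "\t") {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format_num(df[[j]])
    if (is.logical(df[[j]])) df[[j]] <- ifelse(df[[j]], "TRUE", "FALSE")
  }
  lines <- c(paste(names(df), collapse = sep),
             do.call(paste, c(df, sep = sep)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

readr_tsv <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE))
}

# ---- expression data -------------------------------------------------------

#' Construct an expression set
#'
#' @param samples Tibble with columns `id` and `group` (one of `"F2"`,
#'   `"parentA"`, `"parentB"`, `"F1_DxM"`, `"F1_MxD"`).
#' @param values Numeric matrix, probes x samples (log2 scale), with dimnames.
#' @param probes Tibble with columns `probe_id`, `gene`, `chr`, `cM`, `Mb`.
#' @return A list of class `"expression_set"`.
#' @export
expression_set <- function(samples, values, probes) {
  samples <- as_tibble(samples); probes <- as_tibble(probes)
  stopifnot(identical(colnames(values), as.character(samples$id)),
            identical(rownames(values), as.character(probes$probe_id)))
  if (!all(is.finite(values))) abort("expression values must be finite")
  if (anyNA(probes$chr) || anyNA(probes$cM)) {
    abort("every probe needs a chromosome and cM position")
  }
  ok <- c("F2", "parentA", "parentB", "F1_DxM", "F1_MxD")
  if (!all(samples$group %in% ok)) abort("unknown sample group")
  structure(list(samples = samples, values = values, probes = probes),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression set: %d probes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  invisible(x)
}

# Matrix slice of the F2 samples, columns ordered as `ids` when given.
f2_slice <- function(expr, ids = NULL) {
  f2 <- expr$samples$id[expr$samples$group == "F2"]
  if (!is.null(ids)) f2 <- intersect(ids, f2)
  expr$values[, as.character(f2), drop = FALSE]
}

#' Write / read an expression set as TSV files
#'
#' The matrix TSV has `probe_id` in the first column and one column per
#' sample; the samples TSV holds `id` and `group`; the probe TSV holds the
#' annotation columns.
#'
#' @param expr An [expression_set()].
#' @param values_path,samples_path,probes_path File paths.
#' @return `values_path`, invisibly.
#' @export
write_expression <- function(expr, values_path, samples_path, probes_path) {
  vals <- as_tibble(cbind(tibble(probe_id = rownames(expr$values)),
                          as.data.frame(expr$values)))
  write_table(vals, values_path)
  write_table(expr$samples, samples_path)
  write_table(expr$probes, probes_path)
  invisible(values_path)
}

#' @rdname write_expression
#' @export
read_expression <- function(values_path, samples_path, probes_path) {
  vals <- readr_tsv(values_path)
  probes <- readr_tsv(probes_path)
  samples <- readr_tsv(samples_path)
  samples$id <- as.character(samples$id)
  probes$probe_id <- as.character(probes$probe_id)
  probes$chr <- as.character(probes$chr)
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- as.character(vals$probe_id)
  expression_set(samples, m, probes)
}

#' Read a sterility-QTL interval table
#'
#' @param path TSV with columns `trait`, `chr`, `peak_cM`, `lo_cM`, `hi_cM`,
#'   `sterile_allele` (one of `A`, `B`, `het`).
#' @return A validated tibble.
#' @export
read_sterility_intervals <- function(path) {
  df <- readr_tsv(path)
  df$chr <- as.character(df$chr)
  stopifnot(all(c("trait", "chr", "peak_cM", "lo_cM", "hi_cM",
                  "sterile_allele") %in% names(df)))
  if (any(df$lo_cM > df$peak_cM | df$peak_cM > df$hi_cM)) {
    abort("sterility interval must satisfy lo <= peak <= hi")
  }
  if (!all(df$sterile_allele %in% c("A", "B", "het"))) {
    abort("sterile_allele must be A, B, or het")
  }
  df
}

# ---- fertile-subset selection ---------------------------------------------

#' Select the fertile subset of F2 individuals
#'
#' Standardises the four sterility traits over complete-case individuals,
#' extracts the first principal component oriented so that a higher score
#' means more fertile (positive loading on the first listed trait, canonically
#' testis weight), and returns the ids scoring strictly above the given
#' percentile of PC1. Individuals missing any trait are excluded before the
#' PCA and never selected.
#'
#' @param phenotypes Tibble with an `id` column and the trait columns.
#' @param traits Character vector of (four) sterility trait names.
#' @param percentile Fraction of individuals to drop from the bottom of the
#'   fertility score (default 0.20).
#' @return Character vector of selected ids.
#' @export
select_fertile_subset <- function(phenotypes, traits, percentile = 0.20) {
  stopifnot(all(traits %in% names(phenotypes)))
  X <- as.matrix(phenotypes[, traits])
  complete <- stats::complete.cases(X)
  ids <- as.character(phenotypes$id[complete])
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 5L) abort("fewer than 5 individuals with complete sterility phenotypes")
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) {
    warn("all sterility phenotypes constant; returning all complete-case ids")
    return(ids)
  }
  X <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (pc$rotation[1, 1] < 0) score <- -score
  cut <- quantile(score, percentile, type = 1, names = FALSE)
  ids[score > cut]
}
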