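#' Construct a genetic map
#'
#' A genetic map is a tibble with one row per marker and columns `chr`, `kind`
#' (`"autosome"` or `"X"`), `marker`, `cM`, and `Mb` (which may be `NA`).
#' Positions are chromosome-local, in cM, with the origin at the first marker.
#'
#' @param df Data frame with columns `chr`, `marker`, `cM`, and optionally
#'   `kind` and `Mb`. If `kind` is absent, chromosomes named `"X"`
#'   (case-insensitive) are treated as the X.
#' @return A tibble of class `"genetic_map"`.
#' @export
#' @examples
#' genetic_map(data.frame(chr = "1", marker = c("m1", "m2"), cM = c(0, 10)))
genetic_map <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("chr", "marker", "cM") %in% names(df)))
  df$chr <- as.character(df$chr)
  df$marker <- as.character(df$marker)
  if (!"kind" %in% names(df)) {
    df$kind <- ifelse(toupper(df$chr) == "X", "X", "autosome")
  }
  if (!"Mb" %in% names(df)) df$Mb <- NA_real_
  df <- df[, c("chr", "kind", "marker", "cM", "Mb")]
  validate_genetic_map(df)
  structure(df, class = c("genetic_map", class(tibble())))
}

validate_genetic_map <- function(df) {
  if (anyDuplicated(df$marker)) {
    abort(sprintf("duplicate marker name(s): %s",
                  paste(unique(df$marker[duplicated(df$marker)]), collapse = ", ")))
  }
  if (!all(df$kind %in% c("autosome", "X"))) {
    abort("chromosome kind must be 'autosome' or 'X'")
  }
  for (ch in unique(df$chr)) {
    sub <- df[df$chr == ch, ]
    if (nrow(sub) < 2L) {
      abort(sprintf("chromosome %s has fewer than 2 markers", ch))
    }
    bad <- which(diff(sub$cM) < 0)
    if (length(bad)) {
      abort(sprintf("cM positions decrease at marker %s on chromosome %s",
                    sub$marker[bad[1] + 1L], ch))
    }
    mb <- sub$Mb[!is.na(sub$Mb)]
    if (length(mb) > 1L && any(diff(mb) < 0)) {
      abort(sprintf("Mb positions decrease on chromosome %s", ch))
    }
  }
  invisible(df)
}

#' Chromosome summary of a genetic map
#'
#' @param map A [genetic_map()].
#' @return A tibble with one row per chromosome: `chr`, `kind`, `n_markers`,
#'   `start`, `end`, and `length` (cM span).
#' @export
map_chromosomes <- function(map) {
  map |>
    group_by(chr = factor(.data$chr, levels = unique(.data$chr))) |>
    summarise(kind = .data$kind[1], n_markers = n(),
              start = min(.data$cM), end = max(.data$cM),
              length = max(.data$cM) - min(.data$cM), .groups = "drop") |>
    mutate(chr = as.character(.data$chr))
}

# Total map length (cM) by stratum; used to partition alpha between
# autosomes and X and to scale X permutation counts.
map_stratum_lengths <- function(map) {
  chrs <- map_chromosomes(map)
  c(autosome = sum(chrs$length[chrs$kind == "autosome"]),
    X = sum(chrs$length[chrs$kind == "X"]))
}

#' Interpolate physical position from map position
#'
#' Linearly interpolates the Mb coordinate of a cM position between the two
#' flanking markers that carry Mb coordinates. Positions outside the marker
#' range are clamped to the terminal markers with a warning.
#'
#' @param map A [genetic_map()].
#' @param chr Chromosome label.
#' @param pos Positions in cM (vectorised).
#' @return Numeric vector of Mb positions.
#' @export
#' @examples
#' m <- genetic_map(data.frame(chr = "1", marker = c("a", "b"),
#'                             cM = c(10, 20), Mb = c(20, 40)))
#' cm_to_mb(m, "1", 15)
cm_to_mb <- function(map, chr, pos) {
  sub <- map[map$chr == chr & !is.na(map$Mb), ]
  if (nrow(sub) == 0L && !chr %in% map$chr) {
    abort(sprintf("chromosome %s not in map", chr))
  }
  if (nrow(sub) < 2L) {
    abort(sprintf("chromosome %s has fewer than 2 markers with Mb positions", chr))
  }
  rng <- range(sub$cM)
  if (any(pos < rng[1] | pos > rng[2])) {
    warn(sprintf("position(s) outside marker range on chromosome %s clamped", chr))
    pos <- pmin(pmax(pos, rng[1]), rng[2])
  }
  approx(sub$cM, sub$Mb, xout = pos, ties = "ordered")$y
}

# ---- map functions ---------------------------------------------------------

# Forward map functions: recombination fraction -> cM.
# Carter-Falconer models positive interference; its forward form has a closed
# expression while the reverse direction requires root finding.
recfrac_to_cm <- function(r, fn = c("haldane", "kosambi", "carter_falconer")) {
  fn <- match.arg(fn)
  r <- pmin(pmax(r, 0), 0.5 - 1e-14)
  switch(fn,
    haldane = -50 * log(1 - 2 * r),
    kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
    carter_falconer = 12.5 * (log(1 + 2 * r) - log(1 - 2 * r)) + 25 * atan(2 * r)
  )
}

#' Convert map distance to recombination fraction
#'
#' Inverts the chosen map function. Haldane and Kosambi have closed-form
#' inverses; the Carter-Falconer fraction is found by bracketed root finding
#' on the forward function to within 1e-10 cM.
#'
#' @param d Distances in cM (vectorised, `d >= 0`).
#' @param fn Map function name.
#' @return Recombination fractions in `[0, 0.5)`.
#' @export
#' @examples
#' map_to_recfrac(10, "haldane")
#' map_to_recfrac(10, "carter_falconer")
map_to_recfrac <- function(d, fn = c("haldane", "kosambi", "carter_falconer")) {
  fn <- match.arg(fn)
  stopifnot(all(d >= 0))
  switch(fn,
    haldane = 0.5 * (1 - exp(-2 * d / 100)),
    kosambi = 0.5 * tanh(2 * d / 100),
    carter_falconer = vapply(d, function(di) {
      if (di <= 0) return(0)
      if (di >= recfrac_to_cm(0.5 - 1e-12, "carter_falconer")) return(0.5 - 1e-12)
      uniroot(function(r) recfrac_to_cm(r, "carter_falconer") - di,
              interval = c(0, 0.5 - 1e-12), tol = 1e-14)$root
    }, numeric(1))
  )
}

# ---- pseudomarker grid -----------------------------------------------------

#' Marker + pseudomarker grid
#'
#' @param map A [genetic_map()].
#' @param step Grid step in cM.
#' @return A tibble with columns `chr`, `kind`, `pos`, `marker` (`NA` at
#'   pseudomarkers).
#' @export
map_grid <- function(map, step = 2) {
  chrs <- unique(map$chr)
  out <- lapply(chrs, function(ch) {
    sub <- map[map$chr == ch, ]
    pos <- sort(unique(c(sub$cM, seq(min(sub$cM), max(sub$cM), by = step))))
    mk <- sub$marker[match(pos, sub$cM)]
    tibble(chr = ch, kind = sub$kind[1], pos = pos, marker = mk)
  })
  bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
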