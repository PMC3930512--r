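# Sliding-window trans-eQTL counting, the chromosome-reassignment
# permutation null, hotspot calling, and co-localization testing against
# sterility-QTL intervals.
#
# Windows of width `window` cM are anchored at every marker/pseudomarker
# grid position and are half-open [start, start + w), truncated at the
# chromosome end; the terminal position itself is included in truncated
# windows so no peak can escape every window. Truncated windows keep their
# true (shorter) size and are thresholded against permutation maxima of
# equal-size windows.

# Precomputed window geometry for one grid. Returns per-chromosome grid
# positions plus, per anchor, the index range of grid positions counted.
window_geometry <- function(grid, window = 4) {
  chrs <- unique(grid$chr)
  geo <- lapply(chrs, function(ch) {
    pos <- grid$pos[grid$chr == ch]
    end <- max(pos)
    upper <- pmin(pos + window, end)
    truncated <- pos + window > end
    # first/last grid index counted by the window anchored at each position
    first <- seq_along(pos)
    last <- vapply(seq_along(pos), function(i) {
      if (truncated[i]) length(pos)
      else max(which(pos < pos[i] + window))
    }, integer(1))
    # zero-width windows (anchored exactly at the chromosome end) carry no
    # interval and are dropped; the terminal position is still covered by
    # the preceding truncated window, which is closed at the end
    keep <- upper > pos
    list(chr = ch, pos = pos, start = pos[keep], size = (upper - pos)[keep],
         first = first[keep], last = last[keep])
  })
  names(geo) <- chrs
  geo
}

# Window counts from per-grid-position peak tallies (fast path shared with
# the permutation null). tallies: list chr -> integer vector over grid.
window_counts_from_tallies <- function(geo, tallies) {
  bind_rows(lapply(names(geo), function(ch) {
    g <- geo[[ch]]
    cs <- cumsum(tallies[[ch]])
    cnt <- cs[g$last] - c(0, cs)[g$first]
    tibble(chr = ch, start = g$start, end = g$start + g$size,
           size = g$size, count = as.integer(cnt))
  }))
}

peak_tallies <- function(geo, chr, pos) {
  lapply(geo, function(g) {
    idx <- findInterval(pos[chr == g$chr], g$pos)
    # peaks sit on the grid; findInterval maps them to their grid index
    tabulate(idx, nbins = length(g$pos))
  })
}

#' Sliding-window trans-eQTL counts
#'
#' @param records Tibble of trans eQTL with columns `chr`, `pos` (peaks on
#'   the marker/pseudomarker grid).
#' @param map A [genetic_map()].
#' @param window Window width in cM.
#' @param step Grid step in cM.
#' @return Tibble `chr`, `start`, `end`, `size`, `count`.
#' @export
window_counts <- function(records, map, window = 4, step = 2) {
  grid <- map_grid(map, step)
  geo <- window_geometry(grid, window)
  window_counts_from_tallies(geo, peak_tallies(geo, records$chr, records$pos))
}

# Uniform reassignment of each record to a grid position on a chromosome
# other than its probe's (or its own eQTL's) chromosome.
reassign_positions <- function(records, grid, anchor_chr) {
  chrs <- unique(grid$chr)
  idx_by_chr <- lapply(chrs, function(ch) which(grid$chr == ch))
  names(idx_by_chr) <- chrs
  n_total <- nrow(grid)
  new_idx <- integer(nrow(records))
  for (ch in chrs) {
    sel <- which(anchor_chr == ch)
    if (!length(sel)) next
    allowed <- setdiff(seq_len(n_total), idx_by_chr[[ch]])
    new_idx[sel] <- allowed[sample.int(length(allowed), length(sel),
                                       replace = TRUE)]
  }
  other <- which(!(anchor_chr %in% chrs))
  if (length(other)) {
    new_idx[other] <- sample.int(n_total, length(other), replace = TRUE)
  }
  tibble(chr = grid$chr[new_idx], pos = grid$pos[new_idx])
}

#' Permutation null thresholds for hotspot calling
#'
#' Each trans eQTL is independently reassigned to a uniformly chosen grid
#' position on a chromosome other than its probe's chromosome (preserving
#' its trans status and the per-probe eQTL count); the maximum window count
#' per permutation is recorded separately for each distinct window size, and
#' the threshold is the `1 - alpha` quantile of those maxima.
#'
#' @param records Trans eQTL tibble with `chr`, `pos`, `probe_chr`.
#' @param map A [genetic_map()].
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level.
#' @param window,step Window geometry.
#' @param seed RNG seed.
#' @param anchor `"probe"` reassigns away from the probe's chromosome (the
#'   default reading); `"eqtl"` away from the
#'   observed eQTL's chromosome.
#' @return Tibble `size`, `threshold`; per-permutation maxima in attribute
#'   `"null"`.
#' @export
hotspot_null_thresholds <- function(records, map, n_perm = 1000, alpha = 0.05,
                                    window = 4, step = 2, seed = 1L,
                                    anchor = c("probe", "eqtl")) {
  stopifnot(n_perm >= 100)
  anchor <- match.arg(anchor)
  grid <- map_grid(map, step)
  if (length(unique(grid$chr)) < 2L) {
    abort("hotspot null needs at least 2 chromosomes")
  }
  geo <- window_geometry(grid, window)
  # flattened geometry: global grid indices per window, grouped by size
  chrs <- names(geo)
  n_pos <- vapply(geo, function(g) length(g$pos), integer(1))
  offs <- cumsum(c(0L, n_pos))[seq_along(chrs)]
  names(offs) <- chrs
  first_g <- unlist(lapply(chrs, function(ch) geo[[ch]]$first + offs[[ch]]),
                    use.names = FALSE)
  last_g <- unlist(lapply(chrs, function(ch) geo[[ch]]$last + offs[[ch]]),
                   use.names = FALSE)
  sizes_all <- unlist(lapply(geo, `[[`, "size"), use.names = FALSE)
  sizes <- sort(unique(sizes_all))
  size_idx <- lapply(sizes, function(s) which(sizes_all == s))
  G <- sum(n_pos)
  # per anchor chromosome: record indices and allowed target grid indices
  anchor_chr <- if (anchor == "probe") records$probe_chr else records$chr
  rec_by_chr <- split(seq_len(nrow(records)), anchor_chr)
  allowed <- lapply(names(rec_by_chr), function(ch) {
    if (ch %in% chrs) {
      setdiff(seq_len(G), offs[[ch]] + seq_len(n_pos[[ch]]))
    } else seq_len(G)
  })
  names(allowed) <- names(rec_by_chr)
  new_idx <- integer(nrow(records))
  null_max <- matrix(0L, n_perm, length(sizes),
                     dimnames = list(NULL, format_num(sizes)))
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      for (ch in names(rec_by_chr)) {
        sel <- rec_by_chr[[ch]]
        new_idx[sel] <- allowed[[ch]][sample.int(length(allowed[[ch]]),
                                                 length(sel),
                                                 replace = TRUE)]
      }
      cs <- cumsum(tabulate(new_idx, nbins = G))
      counts <- cs[last_g] - c(0L, cs)[first_g]
      null_max[i, ] <- vapply(size_idx, function(ix) max(counts[ix]),
                              numeric(1))
    }
  })
  thr <- vapply(seq_along(sizes), function(j) {
    null_quantile(null_max[, j], alpha)
  }, numeric(1))
  structure(tibble(size = sizes, threshold = thr), null = null_max)
}

#' Call trans-eQTL hotspots
#'
#' Windows whose count exceeds the size-matched permutation threshold are
#' flagged; overlapping or adjacent flagged windows on a chromosome merge
#' into a single hotspot spanning their union, whose member count is the
#' number of trans eQTL inside the union.
#'
#' @param counts Tibble from [window_counts()].
#' @param thresholds Tibble from [hotspot_null_thresholds()].
#' @param records The trans eQTL records the counts were computed from.
#' @param map Optional [genetic_map()] with Mb positions for reporting.
#' @return Tibble of class `"hotspot_set"`: `chr`, `lo`, `hi`, `count`,
#'   `threshold`, `n_windows`, and `lo_mb`/`hi_mb` when a map is given.
#' @export
call_hotspots <- function(counts, thresholds, records, map = NULL) {
  thr <- thresholds$threshold[match(counts$size, thresholds$size)]
  flagged <- counts[!is.na(thr) & counts$count > thr, ]
  flagged$threshold <- thr[!is.na(thr) & counts$count > thr]
  if (!nrow(flagged)) {
    out <- tibble(chr = character(), lo = numeric(), hi = numeric(),
                  count = integer(), threshold = numeric(),
                  n_windows = integer())
    return(structure(out, class = c("hotspot_set", class(tibble()))))
  }
  merged <- list()
  for (ch in unique(flagged$chr)) {
    sub <- flagged[flagged$chr == ch, ]
    sub <- sub[order(sub$start), ]
    lo <- sub$start[1]; hi <- sub$end[1]; thr0 <- sub$threshold[1]; nw <- 1L
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= hi) {
        hi <- max(hi, sub$end[i]); thr0 <- min(thr0, sub$threshold[i])
        nw <- nw + 1L
      } else {
        merged[[length(merged) + 1L]] <- tibble(chr = ch, lo = lo, hi = hi,
                                                threshold = thr0,
                                                n_windows = nw)
        lo <- sub$start[i]; hi <- sub$end[i]; thr0 <- sub$threshold[i]
        nw <- 1L
      }
    }
    merged[[length(merged) + 1L]] <- tibble(chr = ch, lo = lo, hi = hi,
                                            threshold = thr0, n_windows = nw)
  }
  out <- bind_rows(merged)
  out$count <- vapply(seq_len(nrow(out)), function(i) {
    sum(records$chr == out$chr[i] & records$pos >= out$lo[i] &
          records$pos <= out$hi[i])
  }, integer(1))
  out <- out[, c("chr", "lo", "hi", "count", "threshold", "n_windows")]
  if (!is.null(map) && any(!is.na(map$Mb))) {
    out$lo_mb <- vapply(seq_len(nrow(out)), function(i) {
      cm_to_mb(map, out$chr[i], out$lo[i])
    }, numeric(1))
    out$hi_mb <- vapply(seq_len(nrow(out)), function(i) {
      cm_to_mb(map, out$chr[i], out$hi[i])
    }, numeric(1))
  }
  structure(out, class = c("hotspot_set", class(tibble())))
}

#' Write hotspots as a BED track
#'
#' Physical coordinates (Mb converted to bp), 0-based half-open, one row per
#' hotspot, scored by member eQTL count - suitable for genome browsers.
#'
#' @param hotspots A `"hotspot_set"` with `lo_mb`/`hi_mb` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  stopifnot(all(c("lo_mb", "hi_mb") %in% names(hotspots)))
  lines <- sprintf("chr%s\t%d\t%d\thotspot_%d\t%d",
                   hotspots$chr,
                   as.integer(round(hotspots$lo_mb * 1e6)),
                   as.integer(round(hotspots$hi_mb * 1e6)),
                   seq_len(nrow(hotspots)), hotspots$count)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- hotspot / sterility-QTL co-localization -------------------------------

# Total length of the intersection of [lo, hi] with a set of merged
# intervals (tibble chr, lo, hi).
interval_overlap_cm <- function(chr, lo, hi, intervals) {
  sub <- intervals[intervals$chr == chr, ]
  if (!nrow(sub)) return(0)
  sum(pmax(0, pmin(hi, sub$hi) - pmax(lo, sub$lo)))
}

merge_intervals <- function(df) {
  bind_rows(lapply(unique(df$chr), function(ch) {
    sub <- df[df$chr == ch, ]
    sub <- sub[order(sub$lo), ]
    lo <- sub$lo[1]; hi <- sub$hi[1]; out <- list()
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$lo[i] <= hi) hi <- max(hi, sub$hi[i])
      else { out[[length(out) + 1L]] <- c(lo, hi); lo <- sub$lo[i]; hi <- sub$hi[i] }
    }
    out[[length(out) + 1L]] <- c(lo, hi)
    m <- do.call(rbind, out)
    tibble(chr = ch, lo = m[, 1], hi = m[, 2])
  }))
}

coloc_statistics <- function(hotspots, intervals, grid) {
  n_overlap <- sum(vapply(seq_len(nrow(hotspots)), function(i) {
    interval_overlap_cm(hotspots$chr[i], hotspots$lo[i], hotspots$hi[i],
                        intervals) > 0 ||
      any(intervals$chr == hotspots$chr[i] &
            intervals$lo <= hotspots$hi[i] & intervals$hi >= hotspots$lo[i])
  }, logical(1)))
  cm <- sum(vapply(seq_len(nrow(hotspots)), function(i) {
    interval_overlap_cm(hotspots$chr[i], hotspots$lo[i], hotspots$hi[i],
                        intervals)
  }, numeric(1)))
  in_hot <- vapply(seq_len(nrow(grid)), function(j) {
    any(hotspots$chr == grid$chr[j] & hotspots$lo <= grid$pos[j] &
          hotspots$hi >= grid$pos[j])
  }, logical(1))
  in_ster <- vapply(seq_len(nrow(grid)), function(j) {
    any(intervals$chr == grid$chr[j] & intervals$lo <= grid$pos[j] &
          intervals$hi >= grid$pos[j])
  }, logical(1))
  c(n_hotspots = n_overlap, n_positions = sum(in_hot & in_ster), cm = cm)
}

# Place intervals of the given cM sizes at uniform grid anchors without
# overlap (rejection sampling).
place_random_hotspots <- function(sizes, grid, chr_ends, max_tries = 10000L) {
  for (try in seq_len(max_tries)) {
    anchors <- sample.int(nrow(grid), length(sizes), replace = TRUE)
    cand <- tibble(chr = grid$chr[anchors], lo = grid$pos[anchors])
    cand$hi <- cand$lo + sizes
    if (any(cand$hi > chr_ends[cand$chr])) next
    ok <- TRUE
    for (ch in unique(cand$chr)) {
      sub <- cand[cand$chr == ch, ]
      if (nrow(sub) > 1L) {
        sub <- sub[order(sub$lo), ]
        if (any(sub$lo[-1] < sub$hi[-nrow(sub)])) { ok <- FALSE; break }
      }
    }
    if (ok) return(cand)
  }
  abort("could not place non-overlapping hotspot intervals in 10,000 attempts")
}

#' Hotspot / sterility-QTL co-localization permutation test
#'
#' Keeps the sterility-QTL intervals fixed and redraws the hotspot positions:
#' each permutation places the observed number of non-overlapping intervals
#' of the observed cM sizes uniformly at grid anchor positions, and three
#' statistics are recorded - the number of hotspots overlapping any sterility
#' interval, the number of grid positions inside both, and the total
#' overlapping cM. Upper-tail permutation P values per statistic.
#'
#' @param hotspots A `"hotspot_set"` tibble.
#' @param intervals Sterility intervals (`chr`, `lo_cM`, `hi_cM` or
#'   `lo`/`hi`).
#' @param map A [genetic_map()].
#' @param n_perm Number of permutations.
#' @param step Grid step.
#' @param seed RNG seed.
#' @return List of class `"coloc_result"`: `observed`, `p` (per statistic),
#'   `n_perm`, `seed`.
#' @export
colocalization_test <- function(hotspots, intervals, map, n_perm = 1000,
                                step = 2, seed = 1L) {
  if (!nrow(hotspots)) abort("no hotspots to test")
  if ("lo_cM" %in% names(intervals)) {
    intervals <- tibble(chr = as.character(intervals$chr),
                        lo = intervals$lo_cM, hi = intervals$hi_cM)
  }
  grid <- map_grid(map, step)
  chrs <- map_chromosomes(map)
  chr_ends <- setNames(chrs$end, chrs$chr)
  if (nrow(intervals)) intervals <- merge_intervals(intervals)
  obs <- if (nrow(intervals)) {
    coloc_statistics(hotspots, intervals, grid)
  } else c(n_hotspots = 0, n_positions = 0, cm = 0)
  sizes <- hotspots$hi - hotspots$lo
  perm <- matrix(0, n_perm, 3)
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      cand <- place_random_hotspots(sizes, grid, chr_ends)
      perm[i, ] <- if (nrow(intervals)) {
        coloc_statistics(cand, intervals, grid)
      } else c(0, 0, 0)
    }
  })
  p <- vapply(1:3, function(j) (1 + sum(perm[, j] >= obs[j])) / (n_perm + 1),
              numeric(1))
  names(p) <- c("n_hotspots", "n_positions", "cm")
  structure(list(observed = obs, p = p, n_perm = n_perm, seed = seed),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "co-localization: %d hotspots overlap, %d grid positions, %.1f cM (P = %.3g / %.3g / %.3g, %d permutations)\n",
    x$observed["n_hotspots"], x$observed["n_positions"], x$observed["cm"],
    x$p["n_hotspots"], x$p["n_positions"], x$p["cm"], x$n_perm))
  invisible(x)
}
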