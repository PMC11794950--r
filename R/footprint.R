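#' Partition cells into expression quantiles
#'
#' Equal-size rank bins (sizes differ by at most one); ties are broken by
#' stable cell order, so the labels are invariant under monotone transforms
#' of the values.
#'
#' @param values Per-cell numeric values (e.g. normalized ADT levels).
#' @param q Number of quantile bins (default 10).
#' @return Integer vector of labels 1..q (1 = lowest), named like `values`.
#' @export
quantile_partition <- function(values, q = 10) {
  if (q < 2) abort("`q` must be at least 2.")
  n <- length(values)
  if (n < q) abort("Need at least `q` cells.")
  ord <- order(values)  # stable for ties
  bin_of_rank <- rep(seq_len(q), times = diff(floor(n * (0:q) / q)))
  out <- integer(n)
  out[ord] <- bin_of_rank
  setNames(out, names(values))
}

# Expand fragments into Tn5 insertion events (positions start and end-1).
insertion_events <- function(fragments) {
  tibble::tibble(
    chrom = rep(fragments$chrom, 2),
    pos = c(fragments$start, fragments$end - 1),
    barcode = rep(fragments$barcode, 2),
    count = rep(fragments$count, 2)
  )
}

#' Aggregate Tn5 footprint profiles around motif instances
#'
#' Sums insertion events per position relative to the motif center over all
#' instances of one motif inside each supplied peak subset, per cell group
#' (minus-strand instances are coordinate-flipped first). Profiles are
#' normalized by the mean over the outer flank band (positions with
#' `|pos|` in `[window - flank, window]`), which removes depth differences
#' between groups; the core mean over the motif span summarizes the
#' depletion. Groups with zero flank insertions are reported missing.
#'
#' @param fragments Fragment tibble (chrom, start, end, barcode, count).
#' @param hits A `phr_hits`; only hits of `motif` with score above
#'   `min_score` are used.
#' @param motif Motif name.
#' @param peaks Peak tibble covering the hit peaks.
#' @param peak_sets Named list of peak-id vectors (e.g. `high`, `negative`).
#' @param groups Named vector of group labels per barcode.
#' @param motif_length Motif length in bp (for core extent and strand flips).
#' @param window Half-width of the profile window (bp).
#' @param flank Width of the outer flank band used for normalization.
#' @param min_score Minimum hit relative score.
#' @return A list of class `phr_footprint`: `profile` tibble (`peak_set`,
#'   `group`, `position`, `insertions`, `norm`) and `summary` tibble
#'   (`peak_set`, `group`, `core_flank_ratio`, `n_sites`, `missing`).
#' @export
footprint <- function(fragments, hits, motif, peaks, peak_sets, groups,
                      motif_length, window = 250, flank = 50,
                      min_score = 400) {
  h <- hits$hits[hits$hits$motif == motif & hits$hits$score > min_score, ]
  ins <- insertion_events(fragments)
  ins$group <- groups[ins$barcode]
  ins <- ins[!is.na(ins$group), ]
  pk <- peaks[match(h$peak_id, peaks$peak_id), ]
  center <- pk$start + h$offset + (motif_length - 1) / 2
  prof <- list()
  summ <- list()
  half_core <- motif_length / 2
  positions <- seq(-window, window)
  for (set_name in names(peak_sets)) {
    in_set <- h$peak_id %in% peak_sets[[set_name]]
    if (!any(in_set)) next
    idx <- which(in_set)
    # collect insertions within window of each instance center, and track how
    # many instances cover each relative position (fragments exist only
    # inside peaks, so windows truncated by a peak edge must not deflate the
    # per-position rate)
    coverage <- setNames(numeric(length(positions)), positions)
    pieces <- lapply(idx, function(i) {
      lo_rel <- max(-window, pk$start[i] - center[i])
      hi_rel <- min(window, pk$end[i] - 1 - center[i])
      covered <- if (h$strand[i] == "-") {
        seq(ceiling(-hi_rel), floor(-lo_rel))
      } else {
        seq(ceiling(lo_rel), floor(hi_rel))
      }
      coverage[as.character(covered)] <<- coverage[as.character(covered)] + 1
      sel <- ins$pos >= center[i] - window & ins$pos <= center[i] + window
      if (!any(sel)) return(NULL)
      rel <- ins$pos[sel] - center[i]
      if (h$strand[i] == "-") rel <- -rel
      tibble::tibble(rel = round(rel), group = ins$group[sel],
                     count = ins$count[sel])
    })
    tab <- dplyr::bind_rows(pieces)
    if (!nrow(tab)) next
    grid <- tidyr::expand_grid(group = unique(groups), position = positions)
    agg <- tab |>
      dplyr::count(.data$group, rel, wt = .data$count, name = "insertions") |>
      dplyr::rename(position = "rel")
    agg <- dplyr::left_join(grid, agg, by = c("group", "position")) |>
      dplyr::mutate(insertions = tidyr::replace_na(.data$insertions, 0),
                    rate = ifelse(coverage[as.character(.data$position)] > 0,
                                  .data$insertions /
                                    coverage[as.character(.data$position)],
                                  NA_real_))
    agg <- agg |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(
        flank_mean = mean(.data$rate[abs(.data$position) >=
                                       (window - flank)], na.rm = TRUE),
        norm = ifelse(is.finite(.data$flank_mean) & .data$flank_mean > 0,
                      .data$rate / .data$flank_mean, NA_real_)
      ) |>
      dplyr::ungroup()
    miss <- agg |>
      dplyr::distinct(.data$group, .data$flank_mean) |>
      dplyr::mutate(missing = !is.finite(.data$flank_mean) |
                      .data$flank_mean == 0)
    if (any(miss$missing)) {
      warn(sprintf("Footprint profile missing (zero flank insertions): %s",
                   paste(miss$group[miss$missing], collapse = ", ")))
    }
    prof[[set_name]] <- dplyr::mutate(agg, peak_set = set_name)
    summ[[set_name]] <- agg |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        core_flank_ratio = mean(.data$norm[abs(.data$position) <= half_core],
                                na.rm = TRUE),
        .groups = "drop") |>
      dplyr::mutate(peak_set = set_name, n_sites = sum(in_set),
                    missing = .data$group %in% miss$group[miss$missing])
  }
  structure(
    list(profile = dplyr::bind_rows(prof)[, c("peak_set", "group", "position",
                                              "insertions", "norm")],
         summary = dplyr::bind_rows(summ)[, c("peak_set", "group",
                                              "core_flank_ratio", "n_sites",
                                              "missing")],
         motif = motif, window = window, flank = flank),
    class = "phr_footprint"
  )
}

#' @export
#' @method print phr_footprint
print.phr_footprint <- function(x, ...) {
  cat(sprintf("<phr_footprint> motif %s, window +/-%d bp\n",
              x$motif, x$window))
  print(x$summary)
  invisible(x)
}

#' Per-quantile depth-normalized coverage over a region
#'
#' Fragment overlap counts per bin inside the region for each cell group,
#' scaled to counts per 10,000 fragments of that group (group totals are
#' taken over the full fragment set, so tracks are comparable across groups
#' of different depth).
#'
#' @param fragments Fragment tibble.
#' @param region List or one-row data frame with `chrom`, `start`, `end`.
#' @param labels Named vector of group labels per barcode (e.g. from
#'   [quantile_partition()]).
#' @param binsize Bin width (bp).
#' @return Tibble: `group`, `pos` (bin start), `coverage`.
#' @export
quantile_coverage <- function(fragments, region, labels, binsize = 1) {
  frg <- fragments[fragments$chrom == region$chrom, ]
  frg$group <- labels[frg$barcode]
  frg <- frg[!is.na(frg$group), ]
  groups <- sort(unique(labels))
  bins <- seq(region$start, region$end - 1, by = binsize)
  totals <- tapply(fragments$count, labels[fragments$barcode], sum)
  out <- list()
  for (g in groups) {
    fg <- frg[frg$group == g, ]
    cov <- numeric(length(bins))
    if (!nrow(fg)) {
      warn(sprintf("Empty group %s: zero coverage track.", g))
    } else {
      # difference-accumulate fragment overlaps at base resolution
      lo <- pmax(fg$start, region$start) - region$start + 1
      hi <- pmin(fg$end, region$end) - region$start
      ok <- lo <= hi
      delta <- numeric(region$end - region$start + 1)
      for (i in which(ok)) {
        delta[lo[i]] <- delta[lo[i]] + fg$count[i]
        delta[hi[i] + 1] <- delta[hi[i] + 1] - fg$count[i]
      }
      basecov <- cumsum(delta)[seq_len(region$end - region$start)]
      cov <- vapply(seq_along(bins), function(b) {
        i0 <- (b - 1) * binsize + 1
        mean(basecov[i0:min(i0 + binsize - 1, length(basecov))])
      }, 0)
    }
    tot <- totals[as.character(g)]
    scale <- if (!is.na(tot) && tot > 0) 1e4 / tot else 0
    out[[length(out) + 1L]] <- tibble::tibble(group = g, pos = bins,
                                              coverage = cov * scale)
  }
  dplyr::bind_rows(out)
}
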