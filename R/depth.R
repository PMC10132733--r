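#' Define a per-technique read-depth window
#'
#' Exclusive bounds on total counts per cell inside which the
#' genes-per-cell versus counts-per-cell relationship is expected to be
#' linear. The same bounds may be used for both techniques or given per
#' technique.
#'
#' @param min_counts,max_counts Exclusive lower/upper bounds (> 0,
#'   `min < max`).
#' @return A `depth_window` list.
#' @export
depth_window <- function(min_counts = 1100, max_counts = 2000) {
  if (min_counts <= 0 || max_counts <= 0 || min_counts >= max_counts)
    stop_lenbias("need 0 < min_counts < max_counts",
                 class = "lenbias_invalid_argument")
  structure(list(min_counts = min_counts, max_counts = max_counts),
            class = "depth_window")
}

in_window <- function(cells, window) {
  cells$total_counts > window$min_counts &
    cells$total_counts < window$max_counts
}

#' Check depth/feature linearity inside a window
#'
#' Computes, per technique, the Pearson correlation between a cell's
#' total counts and its number of detected genes among cells whose depth
#' lies inside the window. A diagnostic for choosing a window in the
#' linear regime, not an automatic window finder.
#'
#' @param exp A `paired_experiment`.
#' @param window A `depth_window`.
#' @param r_threshold Pass threshold on Pearson r (default 0.6).
#' @return Data frame with one row per technique: `technique`, `n`, `r`,
#'   `pass`.
#' @export
linearity_check <- function(exp, window = depth_window(),
                            r_threshold = 0.6) {
  stopifnot(inherits(exp, "paired_experiment"),
            inherits(window, "depth_window"))
  cells <- exp$cells[in_window(exp$cells, window), , drop = FALSE]
  techniques <- sort(unique(exp$cells$technique))
  out <- lapply(techniques, function(tech) {
    d <- cells[cells$technique == tech, , drop = FALSE]
    if (nrow(d) < 10L)
      stop_lenbias("fewer than 10 in-window cells for ", tech,
                   class = "lenbias_insufficient_data")
    if (var(d$n_features) == 0 || var(d$total_counts) == 0)
      stop_lenbias("no variation in depth or features for ", d$technique[1],
                   class = "lenbias_insufficient_variation")
    r <- cor(d$total_counts, d$n_features)
    data.frame(technique = d$technique[1], n = nrow(d), r = r,
               pass = r >= r_threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Draw a depth-matched, size-balanced subsample
#'
#' Restricts each technique to cells inside its depth window and draws
#' `n_per_technique` of them uniformly without replacement, giving a
#' balanced object of `2 * n_per_technique` cells with matched read
#' depth. Gene order is preserved.
#'
#' @param exp A `paired_experiment`.
#' @param window A `depth_window`, or a named list
#'   `list(single_cell = , single_nucleus = )` of windows.
#' @param n_per_technique Cells to keep per technique (default 1,000).
#' @param seed Seed for the draw.
#' @return A `paired_experiment` with `2 * n_per_technique` cells.
#' @export
balanced_subsample <- function(exp, window = depth_window(),
                               n_per_technique = 1000L, seed = 1L) {
  stopifnot(inherits(exp, "paired_experiment"))
  check_scalar_count(n_per_technique, "n_per_technique", 1L)
  wins <- if (inherits(window, "depth_window"))
    list(single_cell = window, single_nucleus = window)
  else window
  idx <- with_seed(seed, {
    unlist(lapply(c("single_cell", "single_nucleus"), function(tech) {
      pool <- which(exp$cells$technique == tech &
                      in_window(exp$cells, wins[[tech]]))
      if (length(pool) < n_per_technique)
        stop_lenbias("only ", length(pool), " in-window ", tech,
                     " cells; need ", n_per_technique,
                     class = "lenbias_insufficient_data")
      sort(sample(pool, n_per_technique))
    }))
  })
  exp[, idx]
}
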