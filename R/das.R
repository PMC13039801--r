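#' Diversity-aware sub-sampling (greedy farthest-point selection)
#'
#' Orders a pool of conformers by structural diversity under superposition
#' RMSD. The selection is seeded at a reference geometry: the first pick is
#' the pool member nearest the seed, and every following pick maximizes the
#' minimum RMSD to everything already selected (greedy maximin), with ties
#' broken by lowest pool index. The result is deterministic.
#'
#' @param pool list of geometries sharing one element list.
#' @param seed_geometry reference [geometry()]; selected item 0 (reported
#'   separately, not part of the returned indices).
#' @param k number of pool members to select (k <= length(pool)).
#' @param heavy_only use only non-hydrogen atoms in the RMSD metric.
#' @return list of class `das_selection`: `indices` (ordered pool indices),
#'   `min_dist` (each pick's distance to the previously selected set, the
#'   seed included) and `k`.
#' @export
das_select <- function(pool, seed_geometry, k, heavy_only = FALSE) {
  n <- length(pool)
  if (n == 0L) stop("empty pool")
  stopifnot(k >= 1L, k <= n)
  if (!identical(pool[[1]]$elements, seed_geometry$elements))
    stop("seed geometry element list does not match the pool")
  min_dist <- vapply(pool, function(g) rmsd(g, seed_geometry, heavy_only), 0)
  selected <- integer(k)
  pick_dist <- numeric(k)
  for (step in seq_len(k)) {
    cand <- if (step == 1L) which.min(min_dist) else which.max(min_dist)
    selected[step] <- cand
    pick_dist[step] <- min_dist[cand]
    min_dist[cand] <- -Inf
    if (step < k) {
      d_new <- vapply(seq_len(n), function(i) {
        if (is.infinite(min_dist[i])) -Inf
        else rmsd(pool[[i]], pool[[cand]], heavy_only)
      }, 0)
      min_dist <- pmin(min_dist, d_new)
    }
  }
  structure(list(indices = selected, min_dist = pick_dist, k = k),
            class = "das_selection")
}

#' @export
print.das_selection <- function(x, ...) {
  cat(sprintf("<das_selection> %d picks: %s%s\n", x$k,
              paste(utils::head(x$indices, 10), collapse = ", "),
              if (x$k > 10) ", ..." else ""))
  invisible(x)
}
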