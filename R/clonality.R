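#' Distance-resolved same-colour pair probability
#'
#' For every pair of clones in one pancreas, the 3D distance between
#' clone positions is binned, and within each bin the probability of the
#' pair sharing a confetti colour is estimated as (# same-colour pairs) /
#' (# pairs).  Dividing by the any-colour pair count makes the curve
#' insensitive to the organ's convoluted shape: if clones were induced
#' independently the rescaled probability is flat in distance, whereas
#' under-called clone fragmentation shows up as an excess of same-colour
#' pairs at short range.
#'
#' @param clones clone table of a single mouse (>= 2 rows).
#' @param bin_edges strictly increasing distance bin edges (micrometres);
#'   default: 10 equal-width bins from 0 to the 95th percentile of
#'   observed pair distances.  Bins are left-closed, right-open, except
#'   the last which is closed.
#' @return object of class `pair_probability_curve`: list with
#'   `bin_edges`, `n_pairs`, `n_same`, and `rescaled` (`NA` and flagged in
#'   `undefined` where a bin holds no pairs).
#' @export
pair_probability <- function(clones, bin_edges = NULL) {
  if (nrow(clones) < 2) stop("need >= 2 clones")
  pos <- as.matrix(clones[, c("x_um", "y_um", "z_um")])
  d <- as.vector(stats::dist(pos))
  if (is.null(bin_edges)) {
    hi <- stats::quantile(d, 0.95, names = FALSE)
    if (hi <= 0) hi <- max(d)
    bin_edges <- seq(0, hi, length.out = 11L)
  }
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  col <- as.character(clones$color)
  same <- as.vector(.pair_same(col))
  bin <- .bin_index(d, bin_edges)
  nb <- length(bin_edges) - 1L
  n_pairs <- tabulate(bin, nbins = nb)
  n_same <- tabulate(bin[same], nbins = nb)
  rescaled <- ifelse(n_pairs > 0, n_same / n_pairs, NA_real_)
  structure(list(bin_edges = bin_edges, n_pairs = n_pairs, n_same = n_same,
                 rescaled = rescaled, undefined = n_pairs == 0L),
            class = "pair_probability_curve")
}

# logical vector over pairs (same order as dist()) of colour equality
.pair_same <- function(col) {
  n <- length(col)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  col[i] == col[j]
}

# left-closed right-open bins, last bin closed; NA outside the range
.bin_index <- function(d, edges) {
  b <- findInterval(d, edges, rightmost.closed = TRUE)
  b[b < 1L | b > length(edges) - 1L] <- NA_integer_
  b
}

#' @export
print.pair_probability_curve <- function(x, ...) {
  cat("pair_probability_curve:", length(x$n_pairs), "bins,",
      sum(x$n_pairs), "pairs; rescaled:",
      paste(signif(x$rescaled, 2), collapse = " "), "\n")
  invisible(x)
}

#' Bootstrap colour-reassignment null envelope for clonality
#'
#' Under the null hypothesis that the tracing assay is clonal, clones are
#' independently induced and the same-colour pair probability is
#' independent of distance.  Each bootstrap resample redraws every
#' clone's colour i.i.d. from the mouse's empirical colour frequencies at
#' fixed positions, recomputes the rescaled curve, and the pointwise
#' (alpha/2, 1 - alpha/2) quantiles over `n_boot` resamples form the
#' confidence envelope.  An observed curve escaping the envelope upper
#' bound at short distance indicates clone fragmentation; the remedy is
#' [merger_correction()].
#'
#' @param clones clone table of a single mouse.
#' @param bin_edges as in [pair_probability()].
#' @param n_boot number of resamples (default 1000; fewer than 100 gives
#'   unstable quantiles and a warning).
#' @param alpha envelope tail mass (default 0.05 for a 95% envelope).
#' @param seed optional integer seed.
#' @param color_probs optional named colour probabilities to resample
#'   from; default: the per-mouse empirical frequencies (pass pooled
#'   frequencies over mice for a pooled analysis).
#' @return list with `observed` (the [pair_probability()] curve), `lo`,
#'   `hi` (per-bin envelope), `inside` (per-bin logical, `NA` where
#'   undefined), and `n_boot`.
#' @export
bootstrap_null <- function(clones, bin_edges = NULL, n_boot = 1000L,
                           alpha = 0.05, seed = NULL, color_probs = NULL) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable envelope quantiles")
  if (!is.null(seed)) set.seed(seed)
  obs <- pair_probability(clones, bin_edges)
  bin_edges <- obs$bin_edges
  pos <- as.matrix(clones[, c("x_um", "y_um", "z_um")])
  d <- as.vector(stats::dist(pos))
  bin <- .bin_index(d, bin_edges)
  nb <- length(bin_edges) - 1L
  n_pairs <- obs$n_pairs
  if (is.null(color_probs)) {
    tab <- table(as.character(clones$color))
    color_probs <- as.numeric(tab) / sum(tab)
    names(color_probs) <- names(tab)
  }
  n <- nrow(clones)
  keep <- !is.na(bin)
  bini <- bin[keep]
  # pair index vectors, precomputed once (positions are fixed)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)[keep]
  j <- (sequence((n - 1L):1L) + rep(seq_len(n - 1L), times = (n - 1L):1L))[keep]
  curves <- matrix(NA_real_, n_boot, nb)
  for (b in seq_len(n_boot)) {
    col <- sample(names(color_probs), n, replace = TRUE, prob = color_probs)
    same <- col[i] == col[j]
    ns <- tabulate(bini[same], nbins = nb)
    curves[b, ] <- ifelse(n_pairs > 0, ns / n_pairs, NA_real_)
  }
  lo <- apply(curves, 2, function(v)
    if (all(is.na(v))) NA_real_ else stats::quantile(v, alpha / 2, names = FALSE))
  hi <- apply(curves, 2, function(v)
    if (all(is.na(v))) NA_real_ else stats::quantile(v, 1 - alpha / 2, names = FALSE))
  inside <- ifelse(obs$undefined, NA,
                   obs$rescaled >= lo - 1e-12 & obs$rescaled <= hi + 1e-12)
  list(observed = obs, lo = lo, hi = hi, inside = inside, n_boot = n_boot)
}

#' Merger correction: group same-colour clones within a radius
#'
#' Fragmented clones (one induction event scored as several nearby
#' same-colour objects) bias clonality statistics.  The correction groups
#' all clones of the same colour whose pairwise distance is at most
#' `radius` by single linkage (transitive closure: a chain A-B-C with
#' consecutive gaps within the radius merges even if A and C are far
#' apart).  Each group becomes one clone with summed compartment volumes,
#' summed branch counts, and a total-volume-weighted centroid position;
#' clones of different colours never merge.  The operation is idempotent
#' and conserves the total labelled volume of every colour.
#'
#' @param clones clone table of a single mouse.
#' @param radius grouping radius (> 0), micrometres.
#' @return corrected clone table; merged rows keep the lexicographically
#'   first `clone_id` of their group.
#' @export
merger_correction <- function(clones, radius) {
  if (radius <= 0) stop("radius must be > 0")
  # merged centroids can drift into range of one another, so iterate the
  # grouping pass to a fixed point; this makes the correction idempotent
  repeat {
    merged <- .merger_pass(clones, radius)
    if (nrow(merged) == nrow(clones)) break
    clones <- merged
  }
  merged
}

.merger_pass <- function(clones, radius) {
  if (nrow(clones) < 2) return(clones)
  out <- NULL
  for (cl in unique(as.character(clones$color))) {
    sub <- clones[clones$color == cl, , drop = FALSE]
    comp <- .single_linkage(as.matrix(sub[, c("x_um", "y_um", "z_um")]), radius)
    for (g in unique(comp)) {
      rows <- sub[comp == g, , drop = FALSE]
      out <- rbind(out, .merge_rows(rows))
    }
  }
  out <- out[order(as.character(out$clone_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# connected components of the distance-threshold graph via union-find
.single_linkage <- function(pos, radius) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1) {
    d <- as.matrix(stats::dist(pos))
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (d[a, b] <= radius) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

.merge_rows <- function(rows) {
  if (nrow(rows) == 1) return(rows)
  w <- rowSums(as.matrix(rows[, .VOL_COLS]))
  if (sum(w) == 0) w <- rep(1, nrow(rows))
  merged <- rows[order(as.character(rows$clone_id))[1], , drop = FALSE]
  merged$x_um <- sum(rows$x_um * w) / sum(w)
  merged$y_um <- sum(rows$y_um * w) / sum(w)
  merged$z_um <- sum(rows$z_um * w) / sum(w)
  for (v in .VOL_COLS) merged[[v]] <- sum(rows[[v]])
  if ("n_branches" %in% names(rows))
    merged$n_branches <- if (all(is.na(rows$n_branches))) NA_integer_
                         else sum(rows$n_branches, na.rm = TRUE)
  merged
}
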