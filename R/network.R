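#' Construct a ductal network
#'
#' A `ductal_network` is a geometric forest of duct segments hanging off a
#' single central duct.  Every segment is a polyline in the plane; segments
#' diverging directly from the central duct are subtree roots
#' (`parent_id = NULL`), and each bifurcation produces exactly two daughter
#' segments one generation deeper.  Coordinates are expressed in units of
#' the mean separation of adjacent subtree roots along the central duct
#' (the branching model's single key length scale).
#'
#' @param central_duct two-column numeric matrix of (x, y) vertices of the
#'   central duct polyline.
#' @param segments list of segments, each a list with fields `id` (integer),
#'   `parent_id` (integer or `NULL` for subtree roots), `subtree_id`
#'   (integer), `generation` (integer >= 0, depth below the subtree root),
#'   `polyline` (two-column numeric matrix, >= 2 rows), and optionally
#'   `pool` (character vector of precursor labels, added by [run_drift()]).
#' @param termini data frame with columns `id`, `x`, `y`, `dx`, `dy`,
#'   `active`, `segment_id` describing the ductal tips.  An inactive
#'   terminus is irreversibly terminated and never re-activates.
#' @param validate check structural invariants (forest property, polyline
#'   and generation consistency)?
#'
#' @return an object of class `ductal_network`.
#' @seealso [subtree_sizes()], [min_distance()], [tip_front_radius()],
#'   [simulate_ducts()]
#' @export
ductal_network <- function(central_duct, segments, termini, validate = TRUE) {
  central_duct <- as.matrix(central_duct)
  storage.mode(central_duct) <- "double"
  net <- structure(
    list(central_duct = central_duct, segments = segments, termini = termini),
    class = "ductal_network"
  )
  if (validate) validate_network(net)
  net
}

#' Validate the structural invariants of a ductal network
#'
#' Checks that parent links form a forest rooted on the central duct (no
#' cycles, no dangling parents), that generations increase by one from
#' parent to child, that polylines have at least two distinct consecutive
#' vertices, and that each subtree id maps to exactly one root segment.
#'
#' @param net a [ductal_network()].
#' @return `net`, invisibly; stops with a structural error otherwise.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "ductal_network"))
  if (nrow(net$central_duct) < 2)
    stop("central duct polyline needs at least 2 points")
  segs <- net$segments
  n <- length(segs)
  if (n == 0L) return(invisible(net))
  ids <- vapply(segs, function(s) as.integer(s$id), integer(1))
  if (!identical(ids, seq_len(n)))
    stop("segment ids must be 1..n in order")
  parent <- vapply(segs, function(s)
    if (is.null(s$parent_id)) NA_integer_ else as.integer(s$parent_id),
    integer(1))
  if (any(!is.na(parent) & (parent < 1L | parent > n)))
    stop("structural error: dangling parent_id")
  gen <- vapply(segs, function(s) as.integer(s$generation), integer(1))
  sub <- vapply(segs, function(s) as.integer(s$subtree_id), integer(1))
  # forest check: follow parent pointers, must reach a root in <= n hops
  depth <- integer(n)
  for (i in seq_len(n)) {
    j <- i; hops <- 0L
    while (!is.na(parent[j])) {
      j <- parent[j]; hops <- hops + 1L
      if (hops > n) stop("structural error: cycle in parent links")
    }
    depth[i] <- hops
  }
  if (!all(depth == gen))
    stop("structural error: generation must equal depth below the subtree root")
  if (any(is.na(parent) & gen != 0L))
    stop("structural error: root segments must have generation 0")
  ok_sub <- !is.na(parent) & sub != sub[ifelse(is.na(parent), 1L, parent)]
  if (any(ok_sub))
    stop("structural error: subtree_id must be inherited from the parent")
  if (anyDuplicated(sub[is.na(parent)]))
    stop("structural error: a subtree_id maps to more than one root")
  for (s in segs) {
    pl <- s$polyline
    if (!is.matrix(pl) || ncol(pl) != 2 || nrow(pl) < 2)
      stop("polylines need >= 2 points with 2 columns")
    if (any(!is.finite(pl))) stop("non-finite polyline coordinates")
    d <- diff(pl)
    if (any(rowSums(d^2) == 0))
      stop("consecutive polyline points must be distinct")
  }
  invisible(net)
}

#' @export
print.ductal_network <- function(x, ...) {
  nseg <- length(x$segments)
  nsub <- if (nseg) length(unique(vapply(x$segments, function(s)
    as.integer(s$subtree_id), integer(1)))) else 0L
  nact <- sum(x$termini$active)
  cat("ductal_network:", nseg, "segments in", nsub, "subtrees;",
      nrow(x$termini), "termini (", nact, "active )\n")
  invisible(x)
}

#' Number of branches in each subtree
#'
#' A subtree is a duct and all of its daughter ducts diverging from the
#' central duct; its size is the number of branches (segments between two
#' bifurcation points) it contains.  Because each bifurcation produces
#' exactly two daughters, a completed subtree with b bifurcations holds
#' 2b + 1 segments, so sizes are always odd.
#'
#' @param network a [ductal_network()].
#' @return named integer vector of branch counts, one per subtree, named by
#'   `subtree_id`; sizes sum to the total segment count.
#' @export
subtree_sizes <- function(network) {
  validate_network(network)
  if (length(network$segments) == 0L)
    return(stats::setNames(integer(0), character(0)))
  sub <- vapply(network$segments, function(s) as.integer(s$subtree_id),
                integer(1))
  tab <- table(sub)
  stats::setNames(as.integer(tab), names(tab))
}

# squared distance from point p = c(x, y) to the polyline `pl` (point-to-edge)
.dist2_point_polyline <- function(p, pl) {
  a <- pl[-nrow(pl), , drop = FALSE]
  b <- pl[-1, , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  len2 <- rowSums(ab^2)
  t <- pmin(1, pmax(0, ifelse(len2 > 0, rowSums(ap * ab) / len2, 0)))
  cx <- a[, 1] + t * ab[, 1]
  cy <- a[, 2] + t * ab[, 2]
  min((p[1] - cx)^2 + (p[2] - cy)^2)
}

#' Minimum distance from a point to a ductal network
#'
#' Euclidean distance from `point` to the nearest polyline edge of any
#' non-excluded segment or of the central duct.  Used by the simulator's
#' termination-by-proximity rule (which excludes a terminus's own trailing
#' path) and available for ad hoc geometric queries.
#'
#' @param point numeric length-2 vector (x, y).
#' @param network a [ductal_network()].
#' @param exclude integer vector of segment ids to ignore; use the special
#'   id 0 to exclude the central duct as well.
#' @return a length; `Inf` when everything is excluded.
#' @export
min_distance <- function(point, network, exclude = integer(0)) {
  stopifnot(length(point) == 2, all(is.finite(point)))
  best <- Inf
  if (!(0L %in% exclude))
    best <- min(best, .dist2_point_polyline(point, network$central_duct))
  for (s in network$segments) {
    if (s$id %in% exclude) next
    best <- min(best, .dist2_point_polyline(point, s$polyline))
  }
  sqrt(best)
}

#' Duct density in bands between the central duct and the tip region
#'
#' Total duct length per unit area in `n_bands` equal-width bands of
#' distance from the central duct, spanning from 0 (optionally from
#' `inner`) to the `tip_quantile` quantile of the final termini radii.
#' A spatially stationary trailing network shows no trend of density with
#' band index.  Note that the band adjacent to the central duct is
#' structurally sparser: no duct other than a subtree's own root stem can
#' approach the central duct closer than the annihilation radius, and
#' subtrees start as isolated stems that need several branch rounds to
#' reach steady-state packing.
#'
#' @param network a completed [ductal_network()].
#' @param n_bands number of bands (>= 2).
#' @param tip_quantile quantile of termini distances defining the outer
#'   edge.
#' @param inner inner edge of the banded region (default 0, the central
#'   duct).
#' @return data frame with `band`, `lo`, `hi`, `density` (duct length per
#'   unit area, using the deposited-vertex spacing as length element).
#' @export
duct_density_bands <- function(network, n_bands = 4L, tip_quantile = 0.1,
                               inner = 0) {
  stopifnot(n_bands >= 2, nrow(network$termini) > 0)
  ys <- abs(network$termini$y)
  outer_edge <- stats::quantile(ys, tip_quantile, names = FALSE)
  if (outer_edge <= inner) stop("tip region does not extend past 'inner'")
  pts <- do.call(rbind, lapply(network$segments, function(s) s$polyline))
  # vertices are deposited every elongation step, so step spacing is the
  # arc-length element
  step_len <- sqrt(sum((network$segments[[1]]$polyline[2, ] -
                          network$segments[[1]]$polyline[1, ])^2))
  xext <- diff(range(network$central_duct[, 1]))
  edges <- seq(inner, outer_edge, length.out = n_bands + 1L)
  dens <- vapply(seq_len(n_bands), function(b) {
    sum(pts[, 2] >= edges[b] & pts[, 2] < edges[b + 1]) * step_len /
      ((edges[b + 1] - edges[b]) * xext)
  }, numeric(1))
  data.frame(band = seq_len(n_bands), lo = edges[-length(edges)],
             hi = edges[-1], density = dens)
}

#' Mean radial position of the active tip front
#'
#' Active termini self-organize during growth into a traveling pulse at
#' the periphery of the expanding network; this returns the mean distance
#' of active termini from the central duct (a straight horizontal line by
#' construction, so the distance is |y|).
#'
#' @param network a [ductal_network()].
#' @return mean tip distance (length units).
#' @export
tip_front_radius <- function(network) {
  act <- network$termini$active
  if (!any(act)) stop("empty front: no active termini")
  mean(abs(network$termini$y[act]))
}
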