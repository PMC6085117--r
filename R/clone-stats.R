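#' Mean-rescaled empirical size distribution
#'
#' Clone and subtree sizes span orders of magnitude; dividing a sample by
#' its mean exposes the shape of the distribution so that compartments or
#' timepoints with very different average sizes can be compared.  The
#' cumulative tail at x is the fraction of rescaled sizes exceeding x,
#' e.g. a tail of 0.1 at x = 3 means that 10% of clones or subtrees are
#' more than three times larger than average.
#'
#' @param values numeric vector of positive sizes (>= 2 values).
#' @return object of class `empirical_distribution` with fields `values`,
#'   `mean`, and `rescaled`; evaluate the tail with [dist_tail()].
#' @export
empirical_distribution <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need >= 2 positive sizes")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("sizes must be positive and finite")
  structure(list(values = values, mean = mean(values),
                 rescaled = values / mean(values)),
            class = "empirical_distribution")
}

#' Cumulative tail of a mean-rescaled distribution
#'
#' @param dist an [empirical_distribution()].
#' @param x rescaled size(s) at which to evaluate.
#' @return fraction of rescaled values strictly greater than each `x`.
#' @export
dist_tail <- function(dist, x) {
  stopifnot(inherits(dist, "empirical_distribution"))
  vapply(x, function(xi) mean(dist$rescaled > xi), numeric(1))
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat("empirical_distribution: n =", length(x$values),
      " mean =", signif(x$mean, 4),
      " tail(1) =", signif(dist_tail(x, 1), 3),
      " tail(3) =", signif(dist_tail(x, 3), 3), "\n")
  invisible(x)
}

.LINEAGES <- c("acinar", "ductal", "islet")
.VOL_COLS <- c(acinar = "vol_acinar_um3", ductal = "vol_ductal_um3",
               islet = "vol_islet_um3")

#' Classify clone potency from compartment volumes
#'
#' A lineage (acinar, ductal, islet) is present in a clone when its volume
#' strictly exceeds `presence_threshold`; the potency is the number of
#' lineages present (uni-, bi-, or tripotent).
#'
#' @param clones clone table (see [read_clone_table()] for the schema).
#' @param presence_threshold volume cutoff in cubic micrometres (default
#'   0, i.e. strict positivity).
#' @return data frame with `clone_id`, `potency` (factor uni/bi/tri), and
#'   `lineages` (comma-separated present lineages).  A clone with no
#'   lineage present is an error.
#' @export
classify_potency <- function(clones, presence_threshold = 0) {
  vols <- as.matrix(clones[, .VOL_COLS])
  present <- vols > presence_threshold
  npot <- rowSums(present)
  if (any(npot == 0))
    stop("empty clone (all compartment volumes <= threshold): row ",
         paste(which(npot == 0), collapse = ", "))
  data.frame(
    clone_id = clones$clone_id,
    potency = factor(c("uni", "bi", "tri")[npot],
                     levels = c("uni", "bi", "tri")),
    lineages = apply(present, 1, function(p)
      paste(.LINEAGES[p], collapse = ",")),
    stringsAsFactors = FALSE)
}

#' Summarize potency fractions, optionally per mouse or per colour
#'
#' @param clones clone table.
#' @param group_by `"none"`, `"mouse"`, or `"color"`.
#' @param presence_threshold passed to [classify_potency()].
#' @return data frame with columns `group`, `n`, `uni`, `bi`, `tri`
#'   (fractions summing to 1 per group) and counts `n_uni`, `n_bi`,
#'   `n_tri`.
#' @export
potency_summary <- function(clones, group_by = c("none", "mouse", "color"),
                            presence_threshold = 0) {
  group_by <- match.arg(group_by)
  if (nrow(clones) == 0) stop("no clones")
  pot <- classify_potency(clones, presence_threshold)$potency
  grp <- switch(group_by,
                none = rep("all", nrow(clones)),
                mouse = as.character(clones$mouse_id),
                color = as.character(clones$color))
  tab <- table(grp, pot)
  n <- rowSums(tab)
  keep <- n > 0
  if (any(!keep)) warning("omitting empty group(s)")
  tab <- tab[keep, , drop = FALSE]
  n <- n[keep]
  data.frame(group = rownames(tab), n = as.integer(n),
             uni = tab[, "uni"] / n, bi = tab[, "bi"] / n,
             tri = tab[, "tri"] / n,
             n_uni = as.integer(tab[, "uni"]),
             n_bi = as.integer(tab[, "bi"]),
             n_tri = as.integer(tab[, "tri"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean-rescaled size distribution of a clone compartment
#'
#' Extracts the chosen size measure from a clone table (a compartment
#' volume, the total labelled volume, or the branch count) and returns its
#' mean-rescaled distribution.  Clones with zero size in the chosen
#' compartment are excluded from that compartment's sample.
#'
#' @param clones clone table.
#' @param compartment one of `"acinar"`, `"ductal"`, `"islet"`,
#'   `"total"`, `"branches"`.
#' @return an [empirical_distribution()].
#' @export
rescaled_distribution <- function(clones,
                                  compartment = c("acinar", "ductal", "islet",
                                                  "total", "branches")) {
  compartment <- match.arg(compartment)
  v <- switch(compartment,
              total = rowSums(as.matrix(clones[, .VOL_COLS])),
              branches = as.numeric(clones$n_branches),
              as.numeric(clones[[.VOL_COLS[compartment]]]))
  v <- v[!is.na(v) & v > 0]
  if (length(v) < 2)
    stop("fewer than 2 clones with positive ", compartment, " size")
  empirical_distribution(v)
}

# sample quantile by linear interpolation between order statistics placed
# at p_i = (i - 0.5) / n, clamped at the extremes
.quantile_half <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  stats::approx((seq_len(n) - 0.5) / n, v, xout = p, rule = 2)$y
}

#' Quantile-quantile R-squared against the identity
#'
#' Compares two mean-rescaled samples by evaluating both empirical
#' quantile functions on the common grid p = (i - 0.5)/m, i = 1..m with m
#' the smaller sample size (linear interpolation between order
#' statistics), and scoring the agreement of the QQ plot with the line
#' f(x) = x: R^2 = 1 - sum((qb - qa)^2) / sum((qb - mean(qb))^2).
#' Identical distributions give R^2 = 1; because samples are rescaled by
#' their means first, the comparison is invariant to an overall scale.
#'
#' @param a,b [empirical_distribution()] objects (or numeric samples,
#'   which are rescaled internally).
#' @return R-squared value in (-Inf, 1].
#' @export
qq_r2 <- function(a, b) {
  if (!inherits(a, "empirical_distribution")) a <- empirical_distribution(a)
  if (!inherits(b, "empirical_distribution")) b <- empirical_distribution(b)
  m <- min(length(a$rescaled), length(b$rescaled))
  p <- (seq_len(m) - 0.5) / m
  qa <- .quantile_half(a$rescaled, p)
  qb <- .quantile_half(b$rescaled, p)
  denom <- sum((qb - mean(qb))^2)
  if (denom == 0) stop("degenerate reference sample: zero quantile variance")
  1 - sum((qb - qa)^2) / denom
}

#' Bin very small sizes to a common value
#'
#' Rank tests on rescaled clone sizes can be dominated by the very small
#' clones of one compartment (acinar rescaled sizes reach much smaller
#' values than ductal or subtree sizes).  This floors all values below a
#' chosen sample quantile to that quantile, pooling the smallest sizes
#' into a single bin.  Off by default everywhere (`q = 0` is the
#' identity).
#'
#' @param values numeric sizes.
#' @param q quantile in \[0, 1) below which values are pooled.
#' @return numeric vector of the same length.
#' @export
bin_small_sizes <- function(values, q = 0) {
  stopifnot(q >= 0, q < 1)
  if (q == 0) return(values)
  floor_at <- stats::quantile(values, q, names = FALSE)
  pmax(values, floor_at)
}

# U statistic: #{(i, j): a_i > b_j} + 1/2 #{ties}
.u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney rank test (exact enumeration for small samples)
#'
#' Two-sided test of distributional equality based on
#' U = #\{(i,j): a_i > b_j\} + 1/2 #\{ties\}.  In `"exact"` mode the
#' p-value is obtained by full enumeration of all C(n+m, n) assignments of
#' the pooled values, counting assignments whose U deviates from nm/2 at
#' least as much as observed; `"asymptotic"` mode uses the normal
#' approximation with tie and continuity corrections.  `"auto"` picks
#' exact when n + m <= 12.
#'
#' @param a,b numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"`, or `"asymptotic"`.
#' @return list with `U`, `p`, and `mode` (the mode actually used).
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  n <- length(a); m <- length(b)
  if (mode == "auto") mode <- if (n + m <= 12) "exact" else "asymptotic"
  U <- .u_stat(a, b)
  if (mode == "exact") {
    pool <- c(a, b)
    mid <- n * m / 2
    dev <- abs(U - mid)
    idx <- utils::combn(n + m, n)
    us <- apply(idx, 2, function(i) .u_stat(pool[i], pool[-i]))
    p <- mean(abs(us - mid) >= dev - 1e-9)
  } else {
    Ntot <- n + m
    ties <- table(c(a, b))
    sigma2 <- n * m / 12 *
      ((Ntot + 1) - sum(ties^3 - ties) / (Ntot * (Ntot - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - n * m / 2) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  list(U = U, p = p, mode = mode)
}

.ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(grid, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |F_a - F_b| over the pooled sample, with an exact permutation
#' p-value (full enumeration of C(n+m, n) assignments) for n + m <= 12 in
#' `"auto"` mode and the asymptotic Kolmogorov distribution with the
#' small-sample effective-size correction otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"`, or `"asymptotic"`.
#' @return list with `D`, `p`, and `mode`.
#' @export
ks_two_sample <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  n <- length(a); m <- length(b)
  if (mode == "auto") mode <- if (n + m <= 12) "exact" else "asymptotic"
  D <- .ks_stat(a, b)
  if (mode == "exact") {
    pool <- c(a, b)
    idx <- utils::combn(n + m, n)
    ds <- apply(idx, 2, function(i) .ks_stat(pool[i], pool[-i]))
    p <- mean(ds >= D - 1e-9)
  } else {
    ne <- n * m / (n + m)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(1, max(0, p))
  }
  list(D = D, p = p, mode = mode)
}

#' Chi-square comparison of potency tables
#'
#' Pearson chi-square test of homogeneity of uni/bi/tri counts across
#' groups (e.g. two tracing experiments or quantification methods).
#'
#' @param table matrix of counts, potency classes x groups.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_potency <- function(table) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0))
    stop("zero expected count; pool sparse potency categories first")
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Split clones into organ centre and periphery
#'
#' Clones whose normalized radial coordinate (distance to the organ
#' centre divided by the organ radius estimate) is at most 2/3 are
#' "center" (the inner two-thirds of the organ); the rest are
#' "periphery" (the outer third).
#'
#' @param clones clone table with `x_um`, `y_um`, `z_um`.
#' @param organ_center numeric length-3 (x, y, z) in micrometres.
#' @param organ_radius organ radius estimate (> 0), micrometres.
#' @return list of two clone tables, `center` and `periphery`; the two
#'   partition the input.
#' @export
center_periphery_split <- function(clones, organ_center, organ_radius) {
  if (organ_radius <= 0) stop("organ radius estimate must be > 0")
  stopifnot(length(organ_center) == 3)
  d <- sqrt((clones$x_um - organ_center[1])^2 +
            (clones$y_um - organ_center[2])^2 +
            (clones$z_um - organ_center[3])^2)
  r <- d / organ_radius
  list(center = clones[r <= 2 / 3, , drop = FALSE],
       periphery = clones[r > 2 / 3, , drop = FALSE])
}
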