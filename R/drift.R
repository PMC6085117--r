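#' Segregate and duplicate a terminus precursor pool at a bifurcation
#'
#' Each growing ductal terminus carries a pool of N self-renewing
#' precursors.  At a bifurcation the pool is partitioned uniformly at
#' random into groups of floor(N/2) and ceiling(N/2) cells (group-to-
#' daughter assignment random when N is odd), after which each daughter's
#' cells undergo a round of symmetric duplication to restore the pool to
#' its original size.  For odd N the duplicated pool is one cell over or
#' under target: the larger daughter drops one uniformly chosen copy from
#' its duplicates, the smaller daughter adds one extra copy of a uniformly
#' chosen cell.  Either way the expected labelled fraction of a daughter
#' equals the parent's (the drift is a martingale), and fully labelled or
#' fully unlabelled pools are absorbing.
#'
#' @param pool character vector of length N of cell labels (e.g. colour
#'   names, clone ids, or `"unlabeled"`).
#' @return list of two character vectors of length N, the daughter pools.
#' @export
bifurcate_pool <- function(pool) {
  n <- length(pool)
  if (n < 1) stop("empty precursor pool")
  if (n == 1L) return(list(pool, pool))  # a lone precursor copies into both
  m1 <- n %/% 2L
  perm <- if (n > 1) sample(pool) else pool
  # random side assignment of the two groups (matters only for odd n)
  if (stats::runif(1) < 0.5) {
    g1 <- perm[seq_len(m1)]
    g2 <- perm[-seq_len(m1)]
  } else {
    g2 <- perm[seq_len(m1)]
    g1 <- perm[-seq_len(m1)]
  }
  list(.duplicate_to(g1, n), .duplicate_to(g2, n))
}

# symmetric duplication of a daughter group back to pool size n
.duplicate_to <- function(g, n) {
  m <- length(g)
  dup <- c(g, g)
  if (2L * m == n + 1L) {
    # drop one uniformly chosen copy from the duplicate set
    dup <- dup[-(m + sample.int(m, 1L))]
  } else if (2L * m == n - 1L) {
    # add one extra copy of a uniformly chosen cell
    dup <- c(dup, g[sample.int(m, 1L)])
  }
  stopifnot(length(dup) == n)
  dup
}

# --- vectorized single-label transitions -------------------------------
# For the monoclonal-conversion machinery only the labelled count k of a
# pool matters.  These kernels apply the same segregation/duplication rule
# as bifurcate_pool() to many pools at once.

# one daughter drawn per parent: the transition of a lineage chain that
# follows a uniformly chosen daughter at each bifurcation
.drift_chain_step <- function(k, N) {
  if (N == 1L) return(as.integer(k))
  M <- length(k)
  m1 <- N %/% 2L
  m2 <- N - m1
  s <- if (m1 == m2) rep(m1, M) else ifelse(stats::runif(M) < 0.5, m1, m2)
  kd <- stats::rhyper(M, k, N - k, s)
  .dup_adjust(kd, s, N)
}

# both daughters per parent (returns a vector of length 2 * length(k))
.drift_children <- function(k, N) {
  if (N == 1L) return(as.integer(c(k, k)))
  M <- length(k)
  m1 <- N %/% 2L
  m2 <- N - m1
  sA <- if (m1 == m2) rep(m1, M) else ifelse(stats::runif(M) < 0.5, m1, m2)
  kA <- stats::rhyper(M, k, N - k, sA)
  kB <- k - kA
  c(.dup_adjust(kA, sA, N), .dup_adjust(kB, N - sA, N))
}

.dup_adjust <- function(kd, s, N) {
  k2 <- 2L * kd
  over <- 2L * s == N + 1L
  under <- 2L * s == N - 1L
  if (any(over)) {
    p <- ifelse(s[over] > 0, kd[over] / s[over], 0)
    k2[over] <- k2[over] - stats::rbinom(sum(over), 1L, p)
  }
  if (any(under)) {
    p <- ifelse(s[under] > 0, kd[under] / s[under], 0)
    k2[under] <- k2[under] + stats::rbinom(sum(under), 1L, p)
  }
  as.integer(k2)
}

#' Exact lineage-chain transition matrix of the labelled count
#'
#' Builds the (N+1) x (N+1) Markov transition matrix of the labelled
#' precursor count k in {0, ..., N} along a lineage chain (one daughter
#' followed per bifurcation), by exact enumeration over the random side
#' assignment, the hypergeometric segregation draw, and the odd-N
#' duplication adjustment.
#'
#' @param N pool size (integer >= 1).
#' @return matrix `P` with `P[k + 1, k2 + 1] = P(k -> k2)`.
#' @export
drift_transition_matrix <- function(N) {
  stopifnot(N >= 1)
  if (N == 1L) return(diag(2))  # a lone precursor copies into both daughters
  P <- matrix(0, N + 1L, N + 1L)
  m1 <- N %/% 2L
  m2 <- N - m1
  sides <- if (m1 == m2) list(c(m1, 1)) else list(c(m1, 0.5), c(m2, 0.5))
  for (k in 0:N) {
    for (sd in sides) {
      s <- sd[1]; w <- sd[2]
      for (kd in max(0, k + s - N):min(k, s)) {
        ph <- stats::dhyper(kd, k, N - k, s)
        if (2 * s == N) {
          P[k + 1, 2 * kd + 1] <- P[k + 1, 2 * kd + 1] + w * ph
        } else if (2 * s == N + 1) {
          pl <- if (s > 0) kd / s else 0
          if (pl > 0)
            P[k + 1, 2 * kd]     <- P[k + 1, 2 * kd]     + w * ph * pl
          if (pl < 1)
            P[k + 1, 2 * kd + 1] <- P[k + 1, 2 * kd + 1] + w * ph * (1 - pl)
        } else { # 2s == N - 1
          pl <- if (s > 0) kd / s else 0
          if (pl > 0)
            P[k + 1, 2 * kd + 2] <- P[k + 1, 2 * kd + 2] + w * ph * pl
          if (pl < 1)
            P[k + 1, 2 * kd + 1] <- P[k + 1, 2 * kd + 1] + w * ph * (1 - pl)
        }
      }
    }
  }
  P
}

#' Exact fixation probabilities of a labelled precursor population
#'
#' Probability that a lineage starting from k of N labelled precursors is
#' eventually fully labelled, obtained by solving the absorbing Markov
#' chain of [drift_transition_matrix()] exactly.  Neutral drift makes the
#' labelled fraction a martingale, so the result equals k / N.
#'
#' @param N pool size.
#' @return numeric vector of length N + 1, entry k + 1 giving the fixation
#'   probability from k labelled cells.
#' @export
fixation_probabilities <- function(N) {
  P <- drift_transition_matrix(N)
  if (N == 1L) return(c(0, 1))
  trans <- 2:N  # transient states k = 1..N-1
  Q <- P[trans, trans, drop = FALSE]
  b <- P[trans, N + 1L]
  f <- solve(diag(length(trans)) - Q, b)
  c(0, as.numeric(f), 1)
}

#' Replay neutral precursor drift over a ductal network
#'
#' Couples the precursor-pool dynamics to the bifurcation forest of a
#' simulated (or otherwise constructed) network: each subtree root is
#' seeded with a pool of `N` precursors, every bifurcation applies
#' [bifurcate_pool()], and each segment records the pool state at the
#' moment its construction began.  Because the termination of ducts is
#' independent of their labels, replaying drift on a stored network is
#' statistically equivalent to simulating it jointly with branching.
#'
#' @param network a [ductal_network()].
#' @param N precursor pool size per terminus (integer >= 1).
#' @param init initial labelling of each root pool: `"one"` labels a
#'   single precursor (label `"L"`), `"none"` leaves all unlabelled, or a
#'   named numeric vector of per-cell induction probabilities per colour
#'   (e.g. `c(RFP = 0.01, CFP = 0.002)`), the remainder staying
#'   `"unlabeled"`.
#' @param seed optional integer seed.
#' @return the network with a `pool` character vector attached to every
#'   segment and attribute `N_precursors` set.
#' @export
run_drift <- function(network, N, init = "one", seed = NULL) {
  stopifnot(inherits(network, "ductal_network"), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  segs <- network$segments
  n <- length(segs)
  if (n == 0L) stop("network has no segments")
  parent <- vapply(segs, function(s)
    if (is.null(s$parent_id)) NA_integer_ else as.integer(s$parent_id),
    integer(1))
  gen <- vapply(segs, function(s) as.integer(s$generation), integer(1))
  children <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(parent[i]))
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  pools <- vector("list", n)
  make_root_pool <- function() {
    if (identical(init, "one")) {
      if (N == 1L) "L" else c("L", rep("unlabeled", N - 1L))
    } else if (identical(init, "none")) {
      rep("unlabeled", N)
    } else if (is.numeric(init) && !is.null(names(init))) {
      if (sum(init) > 1) stop("induction probabilities must sum to <= 1")
      probs <- c(init, unlabeled = 1 - sum(init))
      sample(names(probs), N, replace = TRUE, prob = probs)
    } else stop("invalid 'init'")
  }
  for (i in order(gen)) {
    if (is.na(parent[i]) && is.null(pools[[i]]))
      pools[[i]] <- make_root_pool()
    kids <- children[[i]]
    if (length(kids) == 2L) {
      d <- bifurcate_pool(pools[[i]])
      pools[[kids[1]]] <- d[[1]]
      pools[[kids[2]]] <- d[[2]]
    } else if (length(kids) == 1L) {
      stop("structural error: segment with exactly one child")
    }
  }
  for (i in seq_len(n)) network$segments[[i]]$pool <- pools[[i]]
  attr(network, "N_precursors") <- N
  network
}

.pool_monoclonal <- function(pool) length(unique(pool)) == 1L

#' Monoclonal-conversion profile of a labelled network
#'
#' For each branch generation g, the fraction of segments whose pool at
#' construction was monoclonal, i.e. fully labelled by a single colour or
#' completely unlabelled.  Chance segregation and re-expansion of
#' precursors during serial bifurcations makes this fraction increase (in
#' expectation) with generation, at a rate inversely proportional to the
#' pool size N.
#'
#' @param network a network labelled by [run_drift()].
#' @return data frame with columns `generation`, `n_segments`,
#'   `fraction_monoclonal`.
#' @export
conversion_profile <- function(network) {
  segs <- network$segments
  if (length(segs) == 0L || is.null(segs[[1]]$pool))
    stop("network carries no pool labels; run run_drift() first")
  gen <- vapply(segs, function(s) as.integer(s$generation), integer(1))
  mono <- vapply(segs, function(s) .pool_monoclonal(s$pool), logical(1))
  gens <- sort(unique(gen))
  data.frame(
    generation = gens,
    n_segments = vapply(gens, function(g) sum(gen == g), integer(1)),
    fraction_monoclonal = vapply(gens, function(g) mean(mono[gen == g]),
                                 numeric(1)))
}

#' Simulate ensemble monoclonal-conversion profiles
#'
#' Ensemble-mean fraction of monoclonal branches per generation for a
#' terminus pool of `N` precursors with one initially labelled cell,
#' obtained by propagating the labelled count through complete binary
#' trees of bifurcations (pruning of branches by termination is
#' independent of labels and so does not bias the per-generation
#' fraction).
#'
#' @param N pool size.
#' @param generations deepest generation simulated.
#' @param n_subtrees number of independent subtrees.
#' @return data frame `generation`, `n_segments`, `fraction_monoclonal`.
#' @export
simulate_conversion_profile <- function(N, generations, n_subtrees = 1000L) {
  stopifnot(N >= 1, generations >= 0)
  N <- as.integer(N)
  k <- rep(1L, n_subtrees)
  out <- data.frame(generation = 0:generations,
                    n_segments = NA_integer_,
                    fraction_monoclonal = NA_real_)
  for (g in 0:generations) {
    out$n_segments[g + 1] <- length(k)
    out$fraction_monoclonal[g + 1] <- mean(k == 0L | k == N)
    if (g < generations) k <- .drift_children(k, N)
  }
  out
}

#' Generations until a duct lineage becomes monoclonal
#'
#' Follows lineage chains of terminus pools (one daughter per
#' bifurcation) started from a single labelled precursor among N and
#' records the branch generation at which each chain reaches an absorbing
#' state.  With `labeled_only = TRUE` (the default) only chains that fix
#' the label are kept, mirroring what a tracing experiment observes: the
#' generation along a labelled clone at which ducts become fully
#' single-coloured.  The characteristic conversion generation grows in
#' proportion to the pool size N, which is the basis for inferring N from
#' clonal data.
#'
#' @param N pool size.
#' @param n_lineages number of chains simulated.
#' @param labeled_only condition on fixation of the label?
#' @param max_generations safety cap.
#' @return integer vector of absorption generations (length `n_lineages`
#'   when unconditioned, about `n_lineages / N` otherwise).
#' @export
generations_to_monoclonality <- function(N, n_lineages = 10000L,
                                         labeled_only = TRUE,
                                         max_generations = 1000L) {
  stopifnot(N >= 1)
  N <- as.integer(N)
  if (N == 1L) {
    return(rep(0L, if (labeled_only) n_lineages else n_lineages))
  }
  k <- rep(1L, n_lineages)
  gens <- rep(NA_integer_, n_lineages)
  g <- 0L
  while (anyNA(gens) && g < max_generations) {
    g <- g + 1L
    k <- .drift_chain_step(k, N)
    newly <- is.na(gens) & (k == 0L | k == N)
    gens[newly] <- g
  }
  if (labeled_only) gens[!is.na(gens) & k == N] else gens[!is.na(gens)]
}

#' Infer the terminus precursor number from a conversion profile
#'
#' Compares an observed monoclonal-conversion profile against simulated
#' ensemble profiles for each candidate pool size N and returns the best
#' fit.  The score is the segment-count-weighted sum of squared
#' differences of the per-generation monoclonal fraction over the shared
#' generations.
#'
#' @param observed data frame as returned by [conversion_profile()].
#' @param candidates integer vector of candidate N values.
#' @param n_sims number of simulated subtrees per candidate.
#' @param seed optional integer seed for the candidate simulations.
#' @return list with `N` (the argmin candidate) and `scores` (data frame
#'   `N`, `score`).
#' @export
infer_precursor_number <- function(observed, candidates, n_sims = 1000L,
                                   seed = NULL) {
  if (length(candidates) == 0) stop("no candidate N values")
  if (!all(c("generation", "n_segments", "fraction_monoclonal") %in%
           names(observed)))
    stop("observed profile must have generation, n_segments, fraction_monoclonal")
  if (nrow(observed) < 2) stop("observed profile needs >= 2 generations")
  if (!is.null(seed)) set.seed(seed)
  gmax <- max(observed$generation)
  scores <- vapply(candidates, function(N) {
    sim <- simulate_conversion_profile(N, gmax, n_subtrees = n_sims)
    m <- merge(observed, sim, by = "generation", suffixes = c("_obs", "_sim"))
    sum(m$n_segments_obs *
          (m$fraction_monoclonal_obs - m$fraction_monoclonal_sim)^2)
  }, numeric(1))
  list(N = candidates[which.min(scores)],
       scores = data.frame(N = candidates, score = scores))
}
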