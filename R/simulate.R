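#' Parameters of the branching-annihilating duct growth model
#'
#' The model has a single key length scale: the mean separation of adjacent
#' subtree roots along the central duct (`spacing`), to which every other
#' length is a ratio.  Active termini elongate by `step_length` per update
#' along a direction that wobbles by `Normal(0, angle_noise)`; with
#' probability `branch_prob` per step the current branch closes and two
#' daughters are spawned at `+/- branch_angle`; a terminus terminates
#' irreversibly when it comes within `annihilation_radius` of another duct
#' (its own trailing path within `self_exclusion_length`, and the junction
#' region it just emerged from, are ignored so that tips are not killed by
#' their own wake).
#'
#' Defaults (all relative to `spacing = 1`): `step_length = 0.05` and
#' `branch_prob = 0.05`, so the mean branch length equals the subtree
#' spacing; `branch_angle = pi/6` per daughter; `angle_noise = 0.15` rad;
#' `annihilation_radius = 0.25`; `self_exclusion_length = 0.75`.
#'
#' @param spacing mean separation of adjacent subtree roots (length unit).
#' @param n_initial_termini number of side branches seeded on the central
#'   duct (default 40).
#' @param step_length tip advance per update.
#' @param branch_prob probability of bifurcation per elongation step, in
#'   (0, 1).
#' @param annihilation_radius termination distance.
#' @param branch_angle half-angle of a bifurcation (radians per daughter).
#' @param angle_noise sd of the per-step direction wobble (radians).
#' @param self_exclusion_length trailing path length ignored in the
#'   proximity check.
#' @param max_steps cap on global updates; reaching it with live termini
#'   sets the `hit_step_cap` attribute on the result instead of failing.
#' @param root_gaps `"exponential"` draws inter-root gaps i.i.d. from a
#'   shifted exponential with mean `spacing` (truncated below at the
#'   annihilation radius, so neighbouring roots never start in contact);
#'   `"fixed"` places roots at exactly `spacing` for deterministic tests.
#' @param seed integer seed; `NULL` uses the current RNG state.
#'
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(spacing = 1,
                       n_initial_termini = 40L,
                       step_length = 0.05,
                       branch_prob = 0.05,
                       annihilation_radius = 0.25,
                       branch_angle = pi / 6,
                       angle_noise = 0.15,
                       self_exclusion_length = 3 * annihilation_radius,
                       max_steps = 500L,
                       root_gaps = c("exponential", "fixed"),
                       seed = NULL) {
  root_gaps <- match.arg(root_gaps)
  p <- list(spacing = spacing,
            n_initial_termini = as.integer(n_initial_termini),
            step_length = step_length,
            branch_prob = branch_prob,
            annihilation_radius = annihilation_radius,
            branch_angle = branch_angle,
            angle_noise = angle_noise,
            self_exclusion_length = self_exclusion_length,
            max_steps = as.integer(max_steps),
            root_gaps = root_gaps,
            seed = seed)
  stopifnot(p$spacing > 0, p$step_length > 0, p$annihilation_radius > 0,
            p$step_length < p$spacing, p$annihilation_radius < p$spacing,
            p$branch_prob >= 0, p$branch_prob < 1,
            p$n_initial_termini >= 1L, p$max_steps >= 1L,
            p$angle_noise >= 0, p$self_exclusion_length > 0)
  class(p) <- "sim_params"
  p
}

#' Seed the initial network of side branches on a central duct
#'
#' Lays down a straight horizontal central duct and
#' `n_initial_termini` active side termini, each launching one root
#' segment perpendicular to it.  Inter-root gaps are i.i.d. with mean
#' `spacing` (see [sim_params()] `root_gaps`).  Uses the current RNG
#' state; call `set.seed()` first for reproducibility.
#'
#' @param params a [sim_params()].
#' @return a [ductal_network()] with one size-1 subtree per terminus, all
#'   termini active.
#' @export
init_network <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_initial_termini
  gaps <- if (params$root_gaps == "fixed") {
    rep(params$spacing, n)
  } else {
    # shifted exponential: mean = spacing, support > annihilation_radius
    params$annihilation_radius +
      stats::rexp(n, rate = 1 / (params$spacing - params$annihilation_radius))
  }
  xs <- cumsum(gaps)
  duct_len <- xs[n] + params$spacing
  cd_x <- seq(0, duct_len, by = params$step_length)
  central <- cbind(cd_x, rep(0, length(cd_x)))
  colnames(central) <- NULL
  d <- params$step_length
  segments <- lapply(seq_len(n), function(i) {
    list(id = i, parent_id = NULL, subtree_id = i, generation = 0L,
         polyline = rbind(c(xs[i], 0), c(xs[i], d)))
  })
  termini <- data.frame(id = seq_len(n), x = xs, y = rep(d, n),
                        dx = rep(0, n), dy = rep(1, n),
                        active = rep(TRUE, n), segment_id = seq_len(n))
  ductal_network(central, segments, termini)
}

.cpp_par <- function(params) {
  params[c("step_length", "branch_prob", "annihilation_radius",
           "branch_angle", "angle_noise", "self_exclusion_length")]
}

.as_network <- function(res) {
  net <- ductal_network(res$central_duct, res$segments, res$termini,
                        validate = FALSE)
  attr(net, "steps_done") <- res$steps_done
  attr(net, "hit_step_cap") <- res$hit_step_cap
  if (!is.null(res$front_radius_trace)) {
    attr(net, "front_radius_trace") <- res$front_radius_trace
    attr(net, "n_active_trace") <- res$n_active_trace
  }
  net
}

#' Advance a network by one global update
#'
#' Every active terminus, in randomized order, (1) advances by the step
#' length along its wobbled direction, (2) terminates irreversibly if the
#' new position lies within the annihilation radius of another duct,
#' (3) otherwise bifurcates with probability `branch_prob`, closing the
#' current branch and spawning two daughters, or (4) simply elongates.
#' Termination is checked before branching, so a step that could do both
#' terminates.  Inactive termini are never updated.
#'
#' @param network a [ductal_network()].
#' @param params a [sim_params()].
#' @param n_steps number of global updates to perform (stops early when no
#'   termini remain active).
#' @return the updated [ductal_network()].
#' @export
sim_step <- function(network, params, n_steps = 1L) {
  stopifnot(inherits(network, "ductal_network"), inherits(params, "sim_params"))
  .as_network(.barw_run(unclass(network), .cpp_par(params),
                        as.integer(n_steps), FALSE))
}

#' Simulate ductal branching morphogenesis to completion
#'
#' Runs the three-rule model (elongate, branch stochastically, terminate
#' on proximity) from the seeded side branches of [init_network()] until
#' no active termini remain or `max_steps` is reached.  The returned
#' network carries attributes `steps_done`, `hit_step_cap`, and (when
#' `record_front = TRUE`) `front_radius_trace` / `n_active_trace`, the
#' per-step mean active-tip distance from the central duct and the active
#' tip count.
#'
#' @param params a [sim_params()]; `params$seed` (when non-`NULL`) fully
#'   determines the run.
#' @param record_front record the tip-front trajectory?
#' @return a completed [ductal_network()].
#' @export
simulate_ducts <- function(params, record_front = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  net <- init_network(params)
  out <- .as_network(.barw_run(unclass(net), .cpp_par(params),
                               params$max_steps, isTRUE(record_front)))
  if (isTRUE(attr(out, "hit_step_cap")))
    warning("max_steps reached with active termini; network is incomplete")
  out
}

#' Pooled subtree-size distribution over a simulation ensemble
#'
#' Runs `n_sims` independent simulations, pools all subtree sizes, and
#' returns their mean-rescaled empirical distribution together with a
#' pointwise 95% ensemble band of the cumulative tail across runs.
#'
#' @param params a [sim_params()]; `params$seed` seeds the whole ensemble.
#' @param n_sims number of simulations (default 500).
#' @param band_x grid of rescaled sizes at which the ensemble band of the
#'   tail function is evaluated.
#' @return an [empirical_distribution()] with extra fields `sizes_by_run`
#'   (list of integer vectors) and `band` (data frame `x`, `lo`, `hi` of
#'   the 2.5% and 97.5% across-run quantiles of the tail).
#' @export
ensemble_subtree_distribution <- function(params, n_sims = 500L,
                                          band_x = seq(0, 8, by = 0.25)) {
  stopifnot(inherits(params, "sim_params"), n_sims >= 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  run_params <- params
  run_params$seed <- NULL
  sizes_by_run <- vector("list", n_sims)
  for (r in seq_len(n_sims)) {
    net <- suppressWarnings(simulate_ducts(run_params))
    sizes_by_run[[r]] <- as.integer(subtree_sizes(net))
  }
  pooled <- unlist(sizes_by_run)
  dist <- empirical_distribution(pooled)
  mu <- dist$mean
  tails <- vapply(sizes_by_run, function(v) {
    vapply(band_x, function(x) mean(v / mu > x), numeric(1))
  }, numeric(length(band_x)))
  tails <- matrix(tails, nrow = length(band_x))
  dist$sizes_by_run <- sizes_by_run
  dist$band <- data.frame(
    x = band_x,
    lo = apply(tails, 1, stats::quantile, probs = 0.025, names = FALSE),
    hi = apply(tails, 1, stats::quantile, probs = 0.975, names = FALSE))
  dist
}
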