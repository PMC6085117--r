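#' Configuration of the synthetic confetti-tracing generator
#'
#' Bundles everything needed to emulate a clonal-density confetti tracing
#' experiment on top of the branching and drift models: the ductal growth
#' parameters, the terminus pool size, the four-colour induction
#' probabilities (strongly RFP-biased, as in real confetti tracings), the
#' target labelled volume fraction (clonal density, < 3% by volume), and
#' the mix of precursor potencies hosted by a terminus.
#'
#' Volume bookkeeping uses order-of-magnitude placeholder conversions
#' (documented, configurable): a cell volume of 1000 um^3, 50 ductal
#' cells deposited per subtree-spacing of duct length, an acinar mass
#' output 3x the ductal one, and a 5% per-cell delamination fraction of
#' trunk output into the islet compartment.
#'
#' @param sim a [sim_params()] for the underlying branching model.
#' @param N_precursors precursor pool size per terminus (default 4).
#' @param induction_fraction target labelled volume fraction in (0, 0.1];
#'   default 0.025.
#' @param color_probs named per-cell induction probability for each
#'   confetti colour, summing to `induction_fraction`; default splits it
#'   5:3:3:1 over RFP:GFP:YFP:CFP.
#' @param potency_mix fractions of multipotent / acinar-committed /
#'   ductal-committed precursors among induced cells (sums to 1).
#' @param cell_volume um^3 per cell.
#' @param duct_cells_per_spacing ductal cells deposited per unit duct
#'   length (one subtree spacing).
#' @param acinar_output_factor acinar mass deposited per unit duct length
#'   relative to ductal mass.
#' @param delamination_frac fraction of trunk-pool cells delaminating
#'   into the islet compartment.
#' @param um_per_spacing micrometres per subtree-spacing unit.
#' @param position_noise sd (um) of Gaussian jitter on reported clone
#'   centroids, emulating measurement error.
#' @param n_mice number of independent simulated animals.
#' @param induction,collection labels stamped on the clone table.
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(sim = sim_params(),
                         N_precursors = 4L,
                         induction_fraction = 0.025,
                         color_probs = NULL,
                         potency_mix = c(multipotent = 0.2, acinar = 0.5,
                                         ductal = 0.3),
                         cell_volume = 1000,
                         duct_cells_per_spacing = 50,
                         acinar_output_factor = 3,
                         delamination_frac = 0.05,
                         um_per_spacing = 50,
                         position_noise = 10,
                         n_mice = 1L,
                         induction = "E12.5",
                         collection = "P14",
                         seed = 1L) {
  if (is.null(color_probs))
    color_probs <- induction_fraction *
      c(RFP = 5, GFP = 3, YFP = 3, CFP = 1) / 12
  stopifnot(induction_fraction >= 0, induction_fraction <= 0.1,
            all(color_probs >= 0), sum(color_probs) <= 1,
            all(names(color_probs) %in% .COLORS),
            abs(sum(potency_mix) - 1) < 1e-9, N_precursors >= 1)
  structure(list(sim = sim, N_precursors = as.integer(N_precursors),
                 induction_fraction = induction_fraction,
                 color_probs = color_probs, potency_mix = potency_mix,
                 cell_volume = cell_volume,
                 duct_cells_per_spacing = duct_cells_per_spacing,
                 acinar_output_factor = acinar_output_factor,
                 delamination_frac = delamination_frac,
                 um_per_spacing = um_per_spacing,
                 position_noise = position_noise,
                 n_mice = as.integer(n_mice),
                 induction = induction, collection = collection,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic confetti clone table
#'
#' Runs the branching simulation, seeds every subtree root terminus with a
#' ductal and an acinar precursor pool of `N_precursors` cells each,
#' induces colour labels in single cells at the configured clonal
#' density, propagates the labels by neutral drift at every bifurcation,
#' and books deposited cell mass into acinar / ductal / islet compartment
#' volumes per clone.  A multipotent induced cell seeds both pools of its
#' terminus; ductal output sheds a configurable fraction of delaminating
#' islet cells (Poisson per segment), so bi- and tripotent clones emerge
#' from the mechanism rather than being painted on.  Clone positions are
#' mass-weighted centroids with Gaussian measurement jitter.
#'
#' @param config a [synth_config()].
#' @return list with `clones` (clone table in the [read_clone_table()]
#'   schema) and `truth` (ground-truth sidecar: per-clone type, subtree,
#'   true potency, the true pool size `N`, and the realized labelled
#'   volume fraction).
#' @export
generate_clone_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  clones_all <- NULL
  truth_all <- NULL
  labeled_vol <- 0
  total_vol <- 0
  for (mouse in seq_len(config$n_mice)) {
    res <- .generate_one_mouse(config, paste0("M", mouse))
    clones_all <- rbind(clones_all, res$clones)
    truth_all <- rbind(truth_all, res$truth)
    labeled_vol <- labeled_vol + res$labeled_vol
    total_vol <- total_vol + res$total_vol
  }
  if (!is.null(clones_all)) rownames(clones_all) <- NULL
  list(clones = clones_all,
       truth = list(N = config$N_precursors,
                    clones = truth_all,
                    labeled_volume_fraction =
                      if (total_vol > 0) labeled_vol / total_vol else 0))
}

.generate_one_mouse <- function(config, mouse_id) {
  net <- suppressWarnings(simulate_ducts(config$sim))
  segs <- net$segments
  n <- length(segs)
  parent <- vapply(segs, function(s)
    if (is.null(s$parent_id)) NA_integer_ else as.integer(s$parent_id),
    integer(1))
  gen <- vapply(segs, function(s) as.integer(s$generation), integer(1))
  sub <- vapply(segs, function(s) as.integer(s$subtree_id), integer(1))
  children <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(parent[i]))
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  seg_len <- vapply(segs, function(s) {
    d <- diff(s$polyline); sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  seg_mid <- t(vapply(segs, function(s) {
    s$polyline[ceiling(nrow(s$polyline) / 2), ]
  }, numeric(2)))

  N <- config$N_precursors
  mix <- config$potency_mix
  # calibrate the per-slot induction probability so that the expected
  # labelled *volume* fraction matches the configured induction fraction:
  # a multipotent induction occupies a slot in both pools, and acinar mass
  # per duct length outweighs ductal mass by acinar_output_factor
  m_rel <- mix[["multipotent"]] / (mix[["multipotent"]] + mix[["ductal"]])
  w_duct <- 1 + config$delamination_frac
  w_acin <- config$acinar_output_factor
  boost <- (w_duct + w_acin * (1 + m_rel)) / (w_duct + w_acin)
  color_probs <- config$color_probs / boost
  p_label <- sum(color_probs)
  col_names <- names(color_probs)
  # clone registry
  reg_color <- character(0); reg_type <- character(0); reg_sub <- integer(0)
  new_clone <- function(color, type, subtree) {
    reg_color[length(reg_color) + 1L] <<- color
    reg_type[length(reg_type) + 1L] <<- type
    reg_sub[length(reg_sub) + 1L] <<- subtree
    sprintf("%s_c%03d", mouse_id, length(reg_color))
  }
  draw_color <- function() {
    sample(col_names, 1L, prob = color_probs / p_label)
  }
  # induction at generation 0: label single cells in the root pools
  duct_pools <- vector("list", n)
  acin_pools <- vector("list", n)
  for (r in which(is.na(parent))) {
    dp <- rep("U", N)
    ap <- rep("U", N)
    for (slot in seq_len(N)) {
      if (stats::runif(1) < p_label) {
        type <- if (stats::runif(1) < mix["multipotent"] /
                      (mix["multipotent"] + mix["ductal"])) "multipotent"
                else "ductal"
        id <- new_clone(draw_color(), type, sub[r])
        dp[slot] <- id
        if (type == "multipotent") {
          # seed an unlabelled acinar slot so no earlier induction is lost
          free <- which(ap == "U")
          if (length(free)) ap[free[sample.int(length(free), 1L)]] <- id
        }
      }
      if (stats::runif(1) < p_label && ap[slot] == "U") {
        ap[slot] <- new_clone(draw_color(), "acinar", sub[r])
      }
    }
    duct_pools[[r]] <- dp
    acin_pools[[r]] <- ap
  }
  # neutral drift of both pools along the bifurcation forest
  for (i in order(gen)) {
    kids <- children[[i]]
    if (length(kids) == 2L) {
      d <- bifurcate_pool(duct_pools[[i]])
      duct_pools[[kids[1]]] <- d[[1]]; duct_pools[[kids[2]]] <- d[[2]]
      a <- bifurcate_pool(acin_pools[[i]])
      acin_pools[[kids[1]]] <- a[[1]]; acin_pools[[kids[2]]] <- a[[2]]
    }
  }
  # volume bookkeeping
  ncl <- length(reg_color)
  vol <- matrix(0, max(ncl, 1L), 3,
                dimnames = list(NULL, c("acinar", "ductal", "islet")))
  posw <- matrix(0, max(ncl, 1L), 2)  # running weighted centroid (x, y)
  wsum <- numeric(max(ncl, 1L))
  nbr_duct <- integer(max(ncl, 1L))
  nbr_acin <- integer(max(ncl, 1L))
  cellv <- config$cell_volume
  labeled_vol <- 0
  unlabeled_islet <- 0
  clone_index <- function(ids) match(ids, sprintf("%s_c%03d", mouse_id,
                                                  seq_len(max(ncl, 1L))))
  for (i in seq_len(n)) {
    n_cells <- seg_len[i] * config$duct_cells_per_spacing
    duct_mass <- n_cells * cellv
    acin_mass <- duct_mass * config$acinar_output_factor
    dp <- duct_pools[[i]]; ap <- acin_pools[[i]]
    total_islet_lambda <- config$delamination_frac * n_cells
    for (id in unique(dp[dp != "U"])) {
      ci <- clone_index(id)
      frac <- mean(dp == id)
      m <- duct_mass * frac
      vol[ci, "ductal"] <- vol[ci, "ductal"] + m
      n_isl <- stats::rpois(1, total_islet_lambda * frac)
      vol[ci, "islet"] <- vol[ci, "islet"] + n_isl * cellv
      w <- m + n_isl * cellv
      posw[ci, ] <- posw[ci, ] + w * seg_mid[i, ]
      wsum[ci] <- wsum[ci] + w
      nbr_duct[ci] <- nbr_duct[ci] + 1L
    }
    unlab_frac <- mean(dp == "U")
    unlabeled_islet <- unlabeled_islet +
      stats::rpois(1, total_islet_lambda * unlab_frac) * cellv
    for (id in unique(ap[ap != "U"])) {
      ci <- clone_index(id)
      frac <- mean(ap == id)
      m <- acin_mass * frac
      vol[ci, "acinar"] <- vol[ci, "acinar"] + m
      posw[ci, ] <- posw[ci, ] + m * seg_mid[i, ]
      wsum[ci] <- wsum[ci] + m
      nbr_acin[ci] <- nbr_acin[ci] + 1L
    }
  }
  total_vol <- sum(seg_len) * config$duct_cells_per_spacing * cellv *
    (1 + config$acinar_output_factor) + sum(vol[, "islet"]) + unlabeled_islet
  labeled_vol <- sum(vol)
  if (ncl == 0L) {
    return(list(clones = NULL, truth = NULL, labeled_vol = 0,
                total_vol = total_vol))
  }
  # a multipotent cell whose acinar seed found no free slot deposits no
  # acinar mass but always has ductal output; guard anyway against clones
  # that never deposited so table and registry stay aligned
  alive <- rowSums(vol) > 0
  if (!all(alive)) {
    vol <- vol[alive, , drop = FALSE]
    posw <- posw[alive, , drop = FALSE]
    wsum <- wsum[alive]
    nbr_duct <- nbr_duct[alive]
    nbr_acin <- nbr_acin[alive]
    reg_color <- reg_color[alive]
    reg_type <- reg_type[alive]
    reg_sub <- reg_sub[alive]
    ncl <- sum(alive)
    if (ncl == 0L)
      return(list(clones = NULL, truth = NULL, labeled_vol = 0,
                  total_vol = total_vol))
  }
  um <- config$um_per_spacing
  cx <- ifelse(wsum > 0, posw[, 1] / wsum, 0) * um
  cy <- ifelse(wsum > 0, posw[, 2] / wsum, 0) * um
  jitter <- function(v) v + stats::rnorm(ncl, 0, config$position_noise)
  clones <- data.frame(
    clone_id = sprintf("%s_c%03d", mouse_id, seq_len(ncl)),
    mouse_id = mouse_id,
    color = reg_color,
    x_um = jitter(cx), y_um = jitter(cy), z_um = jitter(rep(0, ncl)),
    vol_acinar_um3 = vol[, "acinar"],
    vol_ductal_um3 = vol[, "ductal"],
    vol_islet_um3 = vol[, "islet"],
    n_branches = ifelse(reg_type == "acinar", nbr_acin, nbr_duct),
    induction = config$induction,
    collection = config$collection,
    stringsAsFactors = FALSE)
  potency_true <- c("uni", "bi", "tri")[rowSums(vol > 0)]
  truth <- data.frame(
    clone_id = clones$clone_id, mouse_id = mouse_id, color = reg_color,
    type = reg_type, subtree_id = reg_sub, potency_true = potency_true,
    stringsAsFactors = FALSE)
  list(clones = clones, truth = truth, labeled_vol = labeled_vol,
       total_vol = total_vol)
}

#' Generate per-subtree branch counts for an ensemble of organs
#'
#' @param config a [synth_config()] (only `sim` and `seed` are used).
#' @param n_organs number of independent simulated organs.
#' @return data frame with columns `organ_id`, `subtree_id`,
#'   `n_branches`, one row per subtree per organ.
#' @export
generate_subtree_table <- function(config, n_organs = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  out <- NULL
  for (org in seq_len(n_organs)) {
    net <- suppressWarnings(simulate_ducts(config$sim))
    sz <- subtree_sizes(net)
    out <- rbind(out, data.frame(organ_id = org,
                                 subtree_id = as.integer(names(sz)),
                                 n_branches = as.integer(sz)))
  }
  rownames(out) <- NULL
  out
}

#' Write the fixed-seed fixture suite
#'
#' Emits four small, bit-reproducible datasets used throughout the test
#' suite and examples: (1) a four-colour clone table with planted potency
#' fractions and colours independent of position, plus a JSON sidecar of
#' the planted fractions; (2) a clone table with planted short-range
#' fragmentation of same-colour clones, which violates the clonality
#' envelope in the first distance bin; (3) a monoclonal-conversion
#' profile simulated with a pool of 4 precursors, for inference recovery;
#' (4) a tiny hand-checkable 3-segment network JSON.
#'
#' @param out_dir writable directory (created if missing).
#' @param seed integer seed controlling all four fixtures.
#' @return named character vector of the files written, invisibly.
#' @export
fixture_suite <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  paths <- c(
    potency = file.path(out_dir, "fixture_potency_clones.csv"),
    potency_truth = file.path(out_dir, "fixture_potency_truth.json"),
    fragmented = file.path(out_dir, "fixture_fragmented_clones.csv"),
    drift = file.path(out_dir, "fixture_drift_profile_N4.csv"),
    network = file.path(out_dir, "fixture_tiny_network.json"))

  # (1) planted potency, colours independent of position
  planted <- c(uni = 0.68, bi = 0.22, tri = 0.10)
  n1 <- 150L
  pot <- sample(names(planted), n1, replace = TRUE, prob = planted)
  col <- sample(.COLORS, n1, replace = TRUE, prob = c(1, 3, 3, 5) / 12)
  vols <- matrix(0, n1, 3)
  for (i in seq_len(n1)) {
    k <- match(pot[i], c("uni", "bi", "tri"))
    which_lin <- sample.int(3, k)
    vols[i, which_lin] <- stats::rlnorm(k, meanlog = 11, sdlog = 1.5)
  }
  clones1 <- data.frame(
    clone_id = sprintf("P_c%03d", seq_len(n1)),
    mouse_id = sample(paste0("M", 1:3), n1, replace = TRUE),
    color = col,
    x_um = stats::runif(n1, 0, 3000), y_um = stats::runif(n1, 0, 2000),
    z_um = stats::runif(n1, 0, 500),
    vol_acinar_um3 = vols[, 1], vol_ductal_um3 = vols[, 2],
    vol_islet_um3 = vols[, 3],
    n_branches = stats::rpois(n1, 4) + 1L,
    induction = "E12.5", collection = "P14", stringsAsFactors = FALSE)
  write_clone_table(clones1, paths["potency"])
  jsonlite::write_json(
    list(planted_potency = as.list(planted),
         n_clones = n1,
         potency_by_clone = stats::setNames(as.list(pot), clones1$clone_id)),
    paths["potency_truth"], auto_unbox = TRUE, digits = NA)

  # (2) planted fragmentation: mothers split into nearby same-colour parts
  n_indep <- 60L
  n_mothers <- 25L
  indep <- data.frame(
    x_um = stats::runif(n_indep, 0, 3000),
    y_um = stats::runif(n_indep, 0, 3000),
    z_um = stats::runif(n_indep, 0, 300),
    color = sample(.COLORS, n_indep, replace = TRUE, prob = c(1, 3, 3, 5) / 12))
  frags <- NULL
  for (m in seq_len(n_mothers)) {
    cx <- stats::runif(1, 0, 3000); cy <- stats::runif(1, 0, 3000)
    cz <- stats::runif(1, 0, 300)
    colm <- sample(.COLORS, 1, prob = c(1, 3, 3, 5) / 12)
    k <- sample(2:3, 1)
    frags <- rbind(frags, data.frame(
      x_um = cx + stats::rnorm(k, 0, 15), y_um = cy + stats::rnorm(k, 0, 15),
      z_um = cz + stats::rnorm(k, 0, 15), color = colm))
  }
  pts <- rbind(indep, frags)
  n2 <- nrow(pts)
  clones2 <- data.frame(
    clone_id = sprintf("F_c%03d", seq_len(n2)),
    mouse_id = "M1", color = pts$color,
    x_um = pts$x_um, y_um = pts$y_um, z_um = pts$z_um,
    vol_acinar_um3 = stats::rlnorm(n2, 10, 1), vol_ductal_um3 = 0,
    vol_islet_um3 = 0, n_branches = 1L,
    induction = "E12.5", collection = "P14", stringsAsFactors = FALSE)
  write_clone_table(clones2, paths["fragmented"])

  # (3) conversion profile of a pool of 4 with one labelled precursor
  prof <- simulate_conversion_profile(4L, generations = 8L,
                                      n_subtrees = 1000L)
  utils::write.csv(prof, paths["drift"], row.names = FALSE, quote = FALSE)

  # (4) tiny hand-checkable network: one root bifurcating once
  tiny <- ductal_network(
    central_duct = rbind(c(0, 0), c(2, 0)),
    segments = list(
      list(id = 1L, parent_id = NULL, subtree_id = 1L, generation = 0L,
           polyline = rbind(c(1, 0), c(1, 1))),
      list(id = 2L, parent_id = 1L, subtree_id = 1L, generation = 1L,
           polyline = rbind(c(1, 1), c(0.5, 1.8))),
      list(id = 3L, parent_id = 1L, subtree_id = 1L, generation = 1L,
           polyline = rbind(c(1, 1), c(1.5, 1.8)))),
    termini = data.frame(id = 1:2, x = c(0.5, 1.5), y = c(1.8, 1.8),
                         dx = c(-0.53, 0.53), dy = c(0.85, 0.85),
                         active = c(FALSE, FALSE), segment_id = 2:3))
  write_network(tiny, paths["network"])
  invisible(paths)
}
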