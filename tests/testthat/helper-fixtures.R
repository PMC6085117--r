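# In-code fixtures shared across test files.

# a hand-checkable forest: subtree 1 = root bifurcating once (3 segments),
# subtree 2 = a lone unbranched side duct
tiny_forest <- function() {
  ductal_network(
    central_duct = rbind(c(0, 0), c(3, 0)),
    segments = list(
      list(id = 1L, parent_id = NULL, subtree_id = 1L, generation = 0L,
           polyline = rbind(c(1, 0), c(1, 1))),
      list(id = 2L, parent_id = 1L, subtree_id = 1L, generation = 1L,
           polyline = rbind(c(1, 1), c(0.5, 1.8))),
      list(id = 3L, parent_id = 1L, subtree_id = 1L, generation = 1L,
           polyline = rbind(c(1, 1), c(1.5, 1.8))),
      list(id = 4L, parent_id = NULL, subtree_id = 2L, generation = 0L,
           polyline = rbind(c(2, 0), c(2, 0.7)))),
    termini = data.frame(id = 1:3, x = c(0.5, 1.5, 2), y = c(1.8, 1.8, 0.7),
                         dx = c(-0.5, 0.5, 0), dy = c(0.85, 0.85, 1),
                         active = c(TRUE, FALSE, FALSE),
                         segment_id = c(2L, 3L, 4L)))
}

# minimal well-formed clone table
small_clone_table <- function() {
  data.frame(
    clone_id = c("c1", "c2", "c3", "c4"),
    mouse_id = c("M1", "M1", "M1", "M2"),
    color = c("RFP", "GFP", "RFP", "CFP"),
    x_um = c(0, 100, 200, 50), y_um = c(0, 0, 0, 10), z_um = c(0, 0, 0, 0),
    vol_acinar_um3 = c(1000, 0, 500, 200),
    vol_ductal_um3 = c(0, 300, 500, 100),
    vol_islet_um3 = c(0, 0, 200, 0),
    n_branches = c(1L, 2L, 3L, 1L),
    induction = "E12.5", collection = "P14",
    stringsAsFactors = FALSE)
}

# grow a random full binary forest by repeatedly bifurcating random leaves;
# used as an independent topology for subtree-size identities
random_forest <- function(n_subtrees, n_bifurcations) {
  segs <- list()
  nid <- 0L
  leaves <- integer(0)
  for (s in seq_len(n_subtrees)) {
    nid <- nid + 1L
    segs[[nid]] <- list(id = nid, parent_id = NULL, subtree_id = s,
                        generation = 0L,
                        polyline = rbind(c(s, 0), c(s, 0.5)))
    leaves <- c(leaves, nid)
  }
  for (b in seq_len(n_bifurcations)) {
    pick <- leaves[sample.int(length(leaves), 1)]
    leaves <- setdiff(leaves, pick)
    base <- segs[[pick]]$polyline[nrow(segs[[pick]]$polyline), ]
    for (d in 1:2) {
      nid <- nid + 1L
      off <- c(0.2 * (2 * d - 3), 0.3) * stats::runif(1, 0.5, 1)
      segs[[nid]] <- list(id = nid, parent_id = segs[[pick]]$id,
                          subtree_id = segs[[pick]]$subtree_id,
                          generation = segs[[pick]]$generation + 1L,
                          polyline = rbind(base, base + off))
      leaves <- c(leaves, nid)
    }
  }
  term <- data.frame(id = seq_along(leaves),
                     x = vapply(leaves, function(l)
                       segs[[l]]$polyline[2, 1], numeric(1)),
                     y = vapply(leaves, function(l)
                       segs[[l]]$polyline[2, 2], numeric(1)),
                     dx = 0, dy = 1, active = FALSE, segment_id = leaves)
  ductal_network(rbind(c(0, 0), c(n_subtrees + 1, 0)), segs, term)
}

# small, fast simulation parameters for unit tests
fast_params <- function(...) {
  sim_params(n_initial_termini = 8L, max_steps = 120L, ...)
}
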