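test_that("degenerate inductions behave as documented", {
  base_sim <- sim_params(n_initial_termini = 10L, max_steps = 150L)
  # zero induction -> no clones
  cfg0 <- synth_config(sim = base_sim, induction_fraction = 0,
                       color_probs = c(RFP = 0, GFP = 0, YFP = 0, CFP = 0),
                       seed = 3)
  res0 <- generate_clone_table(cfg0)
  expect_null(res0$clones)
  expect_equal(res0$truth$labeled_volume_fraction, 0)

  # single-colour induction -> all clones RFP
  cfg1 <- synth_config(sim = base_sim, induction_fraction = 0.08,
                       color_probs = c(RFP = 0.08), seed = 4)
  res1 <- generate_clone_table(cfg1)
  expect_gt(nrow(res1$clones), 0)
  expect_true(all(res1$clones$color == "RFP"))
})

test_that("emitted tables are valid and agree with the ground-truth sidecar", {
  cfg <- synth_config(sim = sim_params(n_initial_termini = 15L,
                                       max_steps = 250L),
                      n_mice = 2, seed = 7)
  res <- generate_clone_table(cfg)
  cl <- validate_clone_table(res$clones)
  expect_identical(nrow(cl), nrow(res$truth$clones))
  # sidecar potency equals potency classification of the emitted table
  pot <- classify_potency(cl)
  expect_identical(as.character(pot$potency), res$truth$clones$potency_true)
  expect_identical(res$truth$N, cfg$N_precursors)
  # acinar-committed induced cells yield acinar-only clones
  acin <- res$truth$clones$type == "acinar"
  expect_true(all(cl$vol_ductal_um3[acin] == 0))
  expect_true(all(cl$vol_acinar_um3[acin] > 0))
  # multipotent cells always carry ductal output
  multi <- res$truth$clones$type == "multipotent"
  expect_true(all(cl$vol_ductal_um3[multi] > 0))
})

test_that("realized labelled volume fraction tracks the configured density", {
  fracs <- vapply(1:12, function(s) {
    cfg <- synth_config(sim = sim_params(n_initial_termini = 12L,
                                         max_steps = 200L),
                        induction_fraction = 0.03, seed = 100 + s)
    generate_clone_table(cfg)$truth$labeled_volume_fraction
  }, numeric(1))
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.03), 4 * se + 0.005)
})

test_that("colour imbalance follows the configured induction ratios", {
  cfg <- synth_config(sim = sim_params(n_initial_termini = 25L,
                                       max_steps = 250L),
                      induction_fraction = 0.1, n_mice = 4, seed = 11)
  res <- generate_clone_table(cfg)
  counts <- table(factor(res$clones$color, levels = c("CFP", "GFP", "YFP",
                                                      "RFP")))
  # RFP vs CFP proportion among the two colours: configured 5:1
  n_rc <- counts[["RFP"]] + counts[["CFP"]]
  ci <- stats::binom.test(counts[["RFP"]], n_rc)$conf.int
  expect_true(5 / 6 >= ci[1] && 5 / 6 <= ci[2])
  expect_gt(counts[["RFP"]], counts[["CFP"]])
})

test_that("subtree tables mirror the simulator and its degenerate limits", {
  cfg <- synth_config(sim = sim_params(n_initial_termini = 9L,
                                       branch_prob = 0, max_steps = 100L),
                      seed = 5)
  st <- generate_subtree_table(cfg, n_organs = 3)
  expect_true(all(st$n_branches == 1))
  expect_identical(nrow(st), 27L)  # one row per initial terminus per organ

  cfg2 <- synth_config(sim = sim_params(n_initial_termini = 10L,
                                        max_steps = 200L), seed = 6)
  st2 <- generate_subtree_table(cfg2, n_organs = 2)
  expect_true(all(st2$n_branches %% 2 == 1))
  expect_identical(sort(unique(st2$organ_id)), 1:2)
})

test_that("fixture suite is bit-reproducible and self-consistent", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  p1 <- fixture_suite(td1, seed = 1)
  p2 <- fixture_suite(td2, seed = 1)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  }
  # planted potency fractions match the sidecar exactly
  cl <- read_clone_table(p1[["potency"]])
  truth <- jsonlite::fromJSON(p1[["potency_truth"]])
  pot <- classify_potency(cl)
  planted <- unlist(truth$potency_by_clone)[cl$clone_id]
  expect_identical(as.character(pot$potency), unname(planted))
  # drift fixture recovers N = 4
  prof <- utils::read.csv(p1[["drift"]])
  expect_identical(infer_precursor_number(prof, c(2, 4, 8, 16),
                                          n_sims = 800, seed = 2)$N, 4)
  # tiny network parses with the expected generations
  tn <- read_network(p1[["network"]])
  expect_identical(vapply(tn$segments, function(s) s$generation, integer(1)),
                   c(0L, 1L, 1L))
})

test_that("synthetic clones stay cohesive within a single subtree", {
  cfg <- synth_config(sim = sim_params(n_initial_termini = 15L,
                                       max_steps = 250L),
                      induction_fraction = 0.05, seed = 13)
  res <- generate_clone_table(cfg)
  # every clone is seeded in one terminus pool and all deposition follows
  # that subtree's bifurcation forest, so membership is a single subtree
  expect_identical(anyDuplicated(res$truth$clones$clone_id), 0L)
  expect_true(all(!is.na(res$truth$clones$subtree_id)))
  expect_identical(length(unique(res$truth$clones$subtree_id)) <=
                     cfg$sim$n_initial_termini, TRUE)
})
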