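test_that("pair probability matches brute-force pair enumeration", {
  cl <- small_clone_table()[1:3, ]  # one mouse: RFP, GFP, RFP on a line
  cl$x_um <- c(0, 1, 10) * 100
  # hand example: R at 0, R at 1, C at 10 (rescaled to um), bins [0,5),[5,15)
  cl$color <- c("RFP", "RFP", "CFP")
  cl$x_um <- c(0, 1, 10)
  cl$y_um <- 0; cl$z_um <- 0
  pp <- pair_probability(cl, bin_edges = c(0, 5, 15))
  expect_equal(pp$rescaled, c(1, 0))
  expect_identical(pp$n_pairs, c(1L, 2L))

  # all one colour -> rescaled 1 wherever defined
  cl$color <- "YFP"
  pp1 <- pair_probability(cl, bin_edges = c(0, 5, 15))
  expect_true(all(pp1$rescaled[!pp1$undefined] == 1))

  # random data vs O(n^2) oracle
  set.seed(31)
  n <- 40
  rc <- data.frame(clone_id = sprintf("c%02d", 1:n), mouse_id = "M1",
                   color = sample(c("CFP", "GFP", "YFP", "RFP"), n, TRUE),
                   x_um = stats::runif(n, 0, 100),
                   y_um = stats::runif(n, 0, 100),
                   z_um = stats::runif(n, 0, 100),
                   vol_acinar_um3 = 1, vol_ductal_um3 = 0, vol_islet_um3 = 0,
                   n_branches = 1L, induction = "E12.5", collection = "P14")
  edges <- seq(0, 180, length.out = 7)
  pp2 <- pair_probability(rc, edges)
  same_ct <- numeric(6); all_ct <- numeric(6)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((rc[i, c("x_um", "y_um", "z_um")] -
                     rc[j, c("x_um", "y_um", "z_um")])^2))
    b <- findInterval(d, edges, rightmost.closed = TRUE)
    if (b >= 1 && b <= 6) {
      all_ct[b] <- all_ct[b] + 1
      if (rc$color[i] == rc$color[j]) same_ct[b] <- same_ct[b] + 1
    }
  }
  expect_equal(pp2$n_pairs, as.integer(all_ct))
  expect_equal(pp2$n_same, as.integer(same_ct))
  expect_equal(pp2$rescaled, ifelse(all_ct > 0, same_ct / all_ct, NA_real_))
  expect_error(pair_probability(rc[1, , drop = FALSE]), ">= 2")
})

test_that("single-colour data give a degenerate envelope at 1", {
  cl <- small_clone_table()
  cl$color <- "RFP"
  bn <- bootstrap_null(cl, n_boot = 200, seed = 1)
  ok <- !bn$observed$undefined
  expect_true(all(bn$lo[ok] == 1 & bn$hi[ok] == 1))
  expect_true(all(bn$inside[ok]))
})

test_that("independent colours sit inside the envelope; planted fragmentation escapes", {
  td <- withr::local_tempdir()
  paths <- fixture_suite(td, seed = 1)
  indep <- read_clone_table(paths[["potency"]])
  m1 <- indep[indep$mouse_id == "M1", ]
  bn <- bootstrap_null(m1, n_boot = 400, seed = 2)
  expect_gte(mean(bn$inside, na.rm = TRUE), 0.9)

  frag <- read_clone_table(paths[["fragmented"]])
  bn2 <- bootstrap_null(frag, n_boot = 400, seed = 3)
  expect_gt(bn2$observed$rescaled[1], bn2$hi[1])

  # flat-null regression: slope of the rescaled curve over bins ~ 0
  ok <- !bn$observed$undefined
  slope <- stats::coef(stats::lm(bn$observed$rescaled[ok] ~ which(ok)))[2]
  expect_lt(abs(slope), 0.05)
})

test_that("merger correction is transitive, idempotent and conservative", {
  # chain A-B-C: consecutive gaps within radius, |AC| beyond it
  cl <- small_clone_table()[c(1, 1, 1), ]
  cl$clone_id <- c("A", "B", "C")
  cl$color <- "RFP"
  cl$x_um <- c(0, 8, 16); cl$y_um <- 0; cl$z_um <- 0
  cl$vol_acinar_um3 <- c(100, 200, 700)
  out <- merger_correction(cl, radius = 10)
  expect_identical(nrow(out), 1L)
  expect_identical(out$clone_id, "A")
  expect_equal(out$vol_acinar_um3, 1000)
  # volume-weighted centroid
  expect_equal(out$x_um, sum(c(0, 8, 16) * c(100, 200, 700)) / 1000)

  # different colours never merge
  cl2 <- cl
  cl2$color <- c("RFP", "GFP", "RFP")
  out2 <- merger_correction(cl2, radius = 10)
  expect_identical(nrow(out2), 3L)

  # against an igraph connected-components oracle on random data
  skip_if_not_installed("igraph")
  set.seed(32)
  n <- 60
  rc <- data.frame(clone_id = sprintf("c%02d", 1:n), mouse_id = "M1",
                   color = sample(c("RFP", "GFP"), n, TRUE),
                   x_um = stats::runif(n, 0, 60), y_um = stats::runif(n, 0, 60),
                   z_um = 0, vol_acinar_um3 = stats::runif(n, 1, 5),
                   vol_ductal_um3 = 0, vol_islet_um3 = 0, n_branches = 1L,
                   induction = "E12.5", collection = "P14")
  radius <- 8
  merged <- merger_correction(rc, radius)
  # oracle lower bound: single-linkage components of the first pass
  n_comp <- 0L
  for (colr in unique(rc$color)) {
    sub <- rc[rc$color == colr, ]
    d <- as.matrix(stats::dist(sub[, c("x_um", "y_um", "z_um")]))
    g <- igraph::graph_from_adjacency_matrix(d <= radius, mode = "undirected")
    n_comp <- n_comp + igraph::components(g)$no
  }
  expect_lte(nrow(merged), n_comp)
  # idempotence and per-colour volume conservation
  expect_identical(merger_correction(merged, radius), merged)
  for (colr in unique(rc$color)) {
    expect_equal(sum(merged$vol_acinar_um3[merged$color == colr]),
                 sum(rc$vol_acinar_um3[rc$color == colr]))
  }
})

test_that("envelope quantiles are calibrated against fresh null draws", {
  # a curve generated by the null colour-reassignment process itself must
  # fall inside the 95% envelope in ~95% of bins; the observed curve of a
  # truly clonal dataset is covered more conservatively because it
  # conditions on the realized colour counts
  set.seed(61)
  probs <- c(CFP = 1, GFP = 3, YFP = 3, RFP = 5) / 12
  cov <- logical(0)
  for (d in 1:60) {
    n <- 60
    cl <- data.frame(clone_id = sprintf("c%03d", 1:n), mouse_id = "M1",
                     color = sample(names(probs), n, TRUE, prob = probs),
                     x_um = stats::runif(n, 0, 1000),
                     y_um = stats::runif(n, 0, 1000),
                     z_um = stats::runif(n, 0, 200),
                     vol_acinar_um3 = 1, vol_ductal_um3 = 0,
                     vol_islet_um3 = 0, n_branches = 1L,
                     induction = "E12.5", collection = "P14")
    bn <- bootstrap_null(cl, n_boot = 600)
    f <- table(cl$color) / nrow(cl)
    cl2 <- cl
    cl2$color <- sample(names(f), n, TRUE, prob = f)
    fresh <- pair_probability(cl2, bn$observed$bin_edges)
    ok <- !is.na(bn$lo) & !fresh$undefined
    cov <- c(cov, fresh$rescaled[ok] >= bn$lo[ok] - 1e-12 &
               fresh$rescaled[ok] <= bn$hi[ok] + 1e-12)
  }
  expect_gt(mean(cov), 0.91)
  expect_lt(mean(cov), 0.99)
})
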