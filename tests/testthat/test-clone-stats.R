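test_that("potency classification covers all presence patterns strictly", {
  base <- small_clone_table()[1, ]
  pats <- expand.grid(a = c(0, 1), d = c(0, 1), i = c(0, 1))[-1, ]
  for (r in seq_len(nrow(pats))) {
    cl <- base
    cl$vol_acinar_um3 <- pats$a[r] * 10
    cl$vol_ductal_um3 <- pats$d[r] * 10
    cl$vol_islet_um3 <- pats$i[r] * 10
    res <- classify_potency(cl)
    k <- sum(pats[r, ] > 0)
    expect_identical(as.character(res$potency), c("uni", "bi", "tri")[k])
    expect_identical(res$lineages,
                     paste(c("acinar", "ductal", "islet")[unlist(pats[r, ]) > 0],
                           collapse = ","))
  }
  # volumes exactly at the threshold count as absent
  cl <- base
  cl$vol_acinar_um3 <- 5; cl$vol_ductal_um3 <- 10; cl$vol_islet_um3 <- 0
  res <- classify_potency(cl, presence_threshold = 5)
  expect_identical(as.character(res$potency), "uni")
  expect_error(classify_potency(cl, presence_threshold = 10), "empty clone")
})

test_that("potency summaries give per-group fractions that sum to one", {
  cl <- small_clone_table()
  # c1 uni, c2 uni, c3 tri, c4 bi
  ps <- potency_summary(cl)
  expect_equal(ps$uni + ps$bi + ps$tri, 1)
  expect_identical(ps$n, 4L)
  expect_equal(ps$uni, 0.5)
  expect_equal(ps$bi, 0.25)
  expect_equal(ps$tri, 0.25)
  by_col <- potency_summary(cl, group_by = "color")
  expect_identical(sum(by_col$n), nrow(cl))
  by_mouse <- potency_summary(cl, group_by = "mouse")
  expect_identical(sum(by_mouse$n), nrow(cl))
  expect_true(all(abs(by_col$uni + by_col$bi + by_col$tri - 1) < 1e-12))
})

test_that("rescaled distributions have unit mean and a counting tail", {
  d <- empirical_distribution(c(1, 1, 1, 1))
  expect_true(all(d$rescaled == 1))
  expect_equal(dist_tail(d, 0.5), 1)
  expect_equal(dist_tail(d, 1.5), 0)

  set.seed(20)
  for (rep in 1:5) {
    v <- stats::rlnorm(50, 1, 1)
    d <- empirical_distribution(v)
    expect_equal(mean(d$rescaled), 1, tolerance = 1e-12)
    for (x in c(0, 0.3, 1, 2.5)) {
      expect_equal(dist_tail(d, x), sum(v > x * mean(v)) / length(v))
    }
    # tail is non-increasing with tail(0) = 1
    xs <- seq(0, 5, by = 0.1)
    tl <- dist_tail(d, xs)
    expect_equal(tl[1], 1)
    expect_true(all(diff(tl) <= 0))
  }

  cl <- small_clone_table()
  da <- rescaled_distribution(cl, "acinar")
  expect_length(da$values, 3)  # c2 has zero acinar volume and is excluded
  expect_error(rescaled_distribution(cl[1:2, ], "islet"), "fewer than 2")
})

test_that("QQ R-squared is 1 for identical or rescaled-equal samples", {
  a <- c(1, 2, 3, 7, 9)
  expect_equal(qq_r2(a, a), 1)
  expect_equal(qq_r2(a, 3.7 * a), 1)  # mean-rescaling removes the scale

  # independent re-implementation of the same grid and interpolation
  qq_oracle <- function(a, b) {
    ra <- a / mean(a); rb <- b / mean(b)
    m <- min(length(ra), length(rb))
    p <- (seq_len(m) - 0.5) / m
    qf <- function(v, pp) {
      v <- sort(v); n <- length(v)
      knots <- (seq_len(n) - 0.5) / n
      sapply(pp, function(q) {
        if (q <= knots[1]) return(v[1])
        if (q >= knots[n]) return(v[n])
        i <- max(which(knots <= q))
        v[i] + (v[i + 1] - v[i]) * (q - knots[i]) / (knots[i + 1] - knots[i])
      })
    }
    qa <- qf(ra, p); qb <- qf(rb, p)
    1 - sum((qb - qa)^2) / sum((qb - mean(qb))^2)
  }
  expect_equal(qq_r2(c(1, 2, 3), c(1, 2, 10)),
               qq_oracle(c(1, 2, 3), c(1, 2, 10)), tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:5) {
    x <- stats::rlnorm(sample(5:30, 1)); y <- stats::rlnorm(sample(5:30, 1))
    expect_equal(qq_r2(x, y), qq_oracle(x, y), tolerance = 1e-10)
  }
  # near-symmetry for similar samples
  set.seed(22)
  x <- stats::rlnorm(40); y <- x * exp(stats::rnorm(40, 0, 0.05))
  expect_lt(abs(qq_r2(x, y) - qq_r2(y, x)), 0.02)
  expect_error(qq_r2(c(1, 2), c(3, 3)), "degenerate")
})

test_that("Mann-Whitney exact enumeration matches hand counts and wilcox", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_identical(r$mode, "exact")

  # identical multisets are exchangeable
  expect_equal(mann_whitney(c(2, 5, 5), c(2, 5, 5))$p, 1)

  # cross-check against stats::wilcox.test on continuous data
  set.seed(23)
  for (rep in 1:8) {
    a <- stats::rnorm(sample(3:6, 1)); b <- stats::rnorm(sample(3:6, 1), 0.5)
    ours <- mann_whitney(a, b, mode = "exact")
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }

  # exact and asymptotic p agree within 0.05 at n = m = 6
  set.seed(24)
  for (rep in 1:8) {
    a <- stats::rnorm(6); b <- stats::rnorm(6, 0.3)
    pe <- mann_whitney(a, b, mode = "exact")$p
    pa <- mann_whitney(a, b, mode = "asymptotic")$p
    expect_lt(abs(pe - pa), 0.05)
  }
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("KS statistic and permutation p match enumeration", {
  r <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(r$D, 1)
  expect_equal(r$p, 1 / 3)  # 2 of the 6 assignments separate completely
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  set.seed(25)
  for (rep in 1:6) {
    a <- stats::rnorm(sample(4:20, 1)); b <- stats::rnorm(sample(4:20, 1))
    ours <- ks_two_sample(a, b, mode = "asymptotic")
    ref <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(1, numeric(0)), "empty")
})

test_that("chi-square potency comparison matches the direct formula", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  ours <- chi_square_potency(tab)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value)
  # identical column proportions -> zero statistic
  same <- chi_square_potency(matrix(c(30, 15, 60, 30), 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # permuting columns of a proportional table leaves the statistic invariant
  expect_equal(chi_square_potency(tab[, 2:1])$statistic, ours$statistic)
  expect_error(chi_square_potency(matrix(c(0, 0, 5, 5), 2)), "expected")
})

test_that("centre/periphery split partitions at two-thirds of the radius", {
  cl <- small_clone_table()
  cl$x_um <- c(0, 500, 800, 100); cl$y_um <- 0; cl$z_um <- 0
  sp <- center_periphery_split(cl, organ_center = c(0, 0, 0),
                               organ_radius = 1000)
  expect_identical(sort(c(sp$center$clone_id, sp$periphery$clone_id)),
                   sort(cl$clone_id))
  expect_true(all(sp$center$x_um <= 2 / 3 * 1000))
  expect_identical(sp$periphery$clone_id, "c3")
  expect_error(center_periphery_split(cl, c(0, 0, 0), -1), "radius")
  # moving the boundary by epsilon only moves clones within epsilon of it
  set.seed(26)
  cl2 <- do.call(rbind, replicate(25, cl, simplify = FALSE))
  cl2$clone_id <- sprintf("c%03d", seq_len(nrow(cl2)))
  cl2$x_um <- stats::runif(nrow(cl2), 0, 1000)
  a <- center_periphery_split(cl2, c(0, 0, 0), 1000)
  b <- center_periphery_split(cl2, c(0, 0, 0), 1000 / (1 + 0.01))
  moved <- setdiff(a$center$clone_id, b$center$clone_id)
  r <- cl2$x_um[match(moved, cl2$clone_id)] / 1000
  expect_true(all(r > 2 / 3 - 0.02 & r <= 2 / 3 + 1e-9))
})

test_that("small-size binning floors only the chosen lower quantile", {
  v <- c(0.01, 0.02, 0.5, 1, 2, 5)
  expect_identical(bin_small_sizes(v), v)
  b <- bin_small_sizes(v, q = 0.3)
  expect_true(all(b >= stats::quantile(v, 0.3, names = FALSE)))
  expect_identical(b[v >= stats::quantile(v, 0.3, names = FALSE)],
                   v[v >= stats::quantile(v, 0.3, names = FALSE)])
})
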