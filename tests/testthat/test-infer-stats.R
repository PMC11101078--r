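test_that("welch_t reproduces the closed-form statistic, df and p", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  got <- welch_t(x, y)
  ora <- welch_oracle(x, y)
  expect_equal(got$t, ora$t, tolerance = 1e-12)
  expect_equal(got$df, ora$df, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)
  # antisymmetry
  rev <- welch_t(y, x)
  expect_equal(rev$t, -got$t)
  expect_equal(rev$p, got$p)
  # identical samples: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # one-tailed halves the two-tailed p
  expect_equal(welch_t(x, y, tails = 1)$p, got$p / 2)
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least two")
})

test_that("paired t test matches the one-sample test on differences", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9); y <- c(4.2, 4.9, 5.1, 5.0, 5.2)
  got <- welch_t(x, y, paired = TRUE)
  d <- x - y
  t_ora <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_ora, tolerance = 1e-12)
  expect_equal(got$df, length(d) - 1)
  expect_equal(got$p, 2 * pt(-abs(t_ora), length(d) - 1),
               tolerance = 1e-12)
  expect_error(welch_t(x, y[1:4], paired = TRUE), "equal length")
})

test_that("larger |t| implies smaller exact permutation p", {
  set.seed(9)
  base <- rnorm(4)
  ctrl <- rnorm(4, 0, 0.5)
  sets <- lapply(c(0.2, 0.8, 1.6, 3.2), function(s)
    list(x = base + s, y = ctrl))
  tt <- sapply(sets, function(d) abs(welch_t(d$x, d$y)$t))
  pp <- sapply(sets, function(d) perm_p(d$x, d$y))
  expect_true(cor(rank(tt), rank(pp)) < 0)
})

test_that("holm_sidak applies the step-down Sidak formula", {
  # single p is returned unchanged
  expect_equal(holm_sidak(0.2)$p_adjusted, 0.2)
  # three p values against direct arithmetic
  p <- c(0.01, 0.04, 0.03)
  adj_sorted <- c(1 - 0.99^3, 1 - 0.97^2, 1 - 0.96^1)
  adj_sorted <- cummax(adj_sorted)       # sorted p: 0.01, 0.03, 0.04
  got <- holm_sidak(p)
  expect_equal(got$p_adjusted, adj_sorted[c(1, 3, 2)], tolerance = 1e-12)
  # all p = 1: no rejections, all adjusted 1
  all1 <- holm_sidak(rep(1, 4))
  expect_true(all(all1$p_adjusted == 1))
  expect_false(any(all1$reject))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("holm_sidak is monotone and never below the raw p", {
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_sidak(p)$p_adjusted
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("marker scores sum the diagnostic fractions", {
  mids <- list(Ru5P_R5P = c(m0 = 0.3, m1 = 0.1, m2 = 0.15, m3 = 0.2,
                            m4 = 0.05, m5 = 0.2),
               S7P = c(m0 = 0.4, m1 = 0, m2 = 0.1, m3 = 0.1, m4 = 0.2,
                       m5 = 0.15, m6 = 0, m7 = 0.05))
  sc <- marker_scores(mids)
  expect_equal(sc$oxidative, 0.2 + 0.2 + 0.15)
  expect_equal(sc$nonoxidative, 0.15 + 0.2)
  zero <- marker_scores(list(Ru5P_R5P = c(m0 = 1, m1 = 0, m2 = 0, m3 = 0,
                                          m4 = 0, m5 = 0),
                             S7P = c(1, rep(0, 7))))
  expect_equal(zero$oxidative, 0)
  expect_equal(zero$nonoxidative, 0)
  expect_error(marker_scores(list(S7P = c(1, rep(0, 7)))), "Ru5P_R5P")
})

test_that("regime-pure MIDs put zero mass on the opposite branch's markers", {
  net <- the_net
  for (r in c("oxppp_single_pass", "cyclic_ppp")) {
    sc <- marker_scores(simulate_regime(net, regime_spec(r)))
    expect_equal(sc$nonoxidative, 0)
  }
  no <- simulate_regime(net, regime_spec("nonox_ppp"))
  expect_equal(unname(no$S7P["m5"]), 0)
})

test_that("mixture fit recovers exact and mixed templates", {
  tpl <- template_mids(the_net, enrichment = 0.6)
  # observed equal to one template: unit weight on that regime
  for (r in colnames(tpl$matrix)) {
    fit <- fit_pathway_mixture(tpl$matrix[, r], tpl)
    expect_equal(unname(coef(fit)[r]), 1, tolerance = 1e-6)
  }
  # 0.6 cyclic + 0.4 direct, noise-free
  w <- c(direct_glycolysis = 0.4, oxppp_single_pass = 0,
         cyclic_ppp = 0.6, nonox_ppp = 0)
  y <- drop(tpl$matrix %*% w)
  fit <- fit_pathway_mixture(y, tpl)
  expect_lt(max(abs(coef(fit) - w)), 1e-4)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  expect_lt(fit$residual, 1e-6)
  expect_equal(fitted(fit), y, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("mixture fit recovers the whole simplex grid noise-free", {
  tpl <- template_mids(the_net, enrichment = 0.6)
  A <- tpl$matrix
  grid <- expand.grid(w1 = seq(0, 1, 0.1), w2 = seq(0, 1, 0.1),
                      w3 = seq(0, 1, 0.1))
  grid$w4 <- 1 - rowSums(grid)
  grid <- grid[grid$w4 > -1e-9, ]
  grid$w4 <- pmax(grid$w4, 0)
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    w <- as.numeric(grid[i, ])
    fit <- fit_pathway_mixture(drop(A %*% w), tpl)
    worst <- max(worst, max(abs(coef(fit) - w)))
  }
  expect_lt(worst, 1e-3)
})

test_that("mixture weights stay within 0.05 under additive fraction noise", {
  tpl <- template_mids(the_net, enrichment = 0.6)
  A <- tpl$matrix
  w <- c(0.4, 0, 0.6, 0)
  set.seed(101)
  errs <- replicate(100, {
    y <- drop(A %*% w) + rnorm(nrow(A), 0, 0.01)
    max(abs(coef(fit_pathway_mixture(y, tpl)) - w))
  })
  expect_lt(max(errs), 0.05)
})

test_that("degenerate templates are flagged as collinear", {
  tpl <- template_mids(the_net, enrichment = 0.6)
  A <- tpl$matrix[, c(1, 1, 3)]
  colnames(A) <- c("a", "b", "c")
  expect_warning(fit <- fit_pathway_mixture(A[, 3], A),
                 "indistinguishable")
  expect_true(fit$collinear)
  expect_error(fit_pathway_mixture(tpl$matrix[, 1],
                                   tpl$matrix[, 1, drop = FALSE]),
               "at least two")
})

test_that("compare_groups tests each isotopologue and adjusts per metabolite", {
  set.seed(8)
  mk <- function(g, mu_m3) {
    do.call(rbind, lapply(1:5, function(i) {
      m3 <- min(max(rnorm(1, mu_m3, 0.02), 0), 1)
      data.frame(sample_id = paste0(g, "_", i), group = g,
                 metabolite = rep(c("G6P", "lactate"), each = 2),
                 mass_shift = c(0L, 3L, 0L, 3L),
                 fraction = c(1 - m3, m3, 1 - m3, m3))
    }))
  }
  fr <- rbind(mk("ctl", 0.1), mk("inf", 0.4))
  cmp <- compare_groups(fr, "inf", "ctl")
  expect_identical(nrow(cmp), 4L)
  m3 <- cmp[cmp$metabolite == "G6P" & cmp$mass_shift == 3L, ]
  expect_gt(m3$mean_x, m3$mean_y)
  expect_true(m3$reject)
  expect_true(all(cmp$p_adjusted >= cmp$p - 1e-12, na.rm = TRUE))
  expect_error(compare_groups(fr, "inf", "nope"), "both groups")
})
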