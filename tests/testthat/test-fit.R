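test_that("closed-form PR root solves its quadratic and matches the loss minimizer", {
  set.seed(11)
  for (i in 1:25) {
    d <- block_design()
    box <- as.numeric(d$labels == "on")
    fm <- runif(1, 0, 6)
    fp <- runif(1, 0, 6)
    Sm <- zscore(fm * box + rnorm(224))
    Sp <- zscore(fp * box + rnorm(224))
    fit <- fit_pr_chisq(Sm, Sp)
    # root satisfies the quadratic
    expect_lt(abs(fit$A * fit$b1_star^2 + fit$B * fit$b1_star + fit$C), 1e-8)
    # and minimizes the loss itself
    expect_equal(fit$b1_star, minimize_chisq_loss(Sm, Sp), tolerance = 1e-4)
    # the printed coefficient set also solves its own quadratic
    fp_ <- fit_pr_chisq(Sm, Sp, coefficients = "printed")
    expect_lt(abs(fp_$A * fp_$b1_star^2 + fp_$B * fp_$b1_star + fp_$C), 1e-8)
  }
})

test_that("identical series give the analytic slopes", {
  set.seed(5)
  x <- zscore(rnorm(50))
  # published coefficient set: b1* = sqrt(3) - 1
  expect_equal(fit_pr_chisq(x, x, coefficients = "printed")$b1_star,
               sqrt(3) - 1, tolerance = 1e-10)
  # exact minimizer of the loss: complete suppression, b1* = 1
  fit <- fit_pr_chisq(x, x)
  expect_equal(fit$b1_star, 1, tolerance = 1e-10)
  expect_equal(minimize_chisq_loss(x, x), 1, tolerance = 1e-4)
  # antisymmetry under sign flip of the phase
  fneg <- fit_pr_chisq(x, -x)
  expect_equal(fneg$r, -1)
  expect_equal(fneg$b1_star, -fit$b1_star, tolerance = 1e-10)
})

test_that("chi-squared slope exceeds the OLS slope in magnitude (over-suppression)", {
  set.seed(21)
  d <- block_design()
  box <- as.numeric(d$labels == "on")
  for (i in 1:10) {
    Sm <- zscore(5 * box + rnorm(224))
    Sp <- zscore(5 * box + rnorm(224))
    fit <- fit_pr_chisq(Sm, Sp)
    expect_gt(abs(fit$b1_star), abs(cor(Sm, Sp)))
  }
})

test_that("zero-correlation fallback and input validation work", {
  # exactly orthogonal pair: corr = 0 -> r = 0 -> flagged b1 = 0
  Sm <- zscore(c(1, -1, 1, -1))
  Sp <- zscore(c(1, 1, -1, -1))
  fit <- fit_pr_chisq(Sm, Sp)
  expect_equal(fit$b1_star, 0)
  expect_equal(fit$flag, "zero_correlation")
  expect_error(fit_pr_chisq(1:5, 1:4), class = "phasereg_error_data")
  expect_error(fit_pr_chisq(rep(1, 5), zscore(rnorm(5))),
               class = "phasereg_error_degenerate")
})

test_that("applying PR reproduces hand-computed residuals", {
  set.seed(2)
  Sm <- zscore(rnorm(50))
  Sp <- zscore(rnorm(50))
  expect_equal(apply_pr(Sm, Sp, 0), Sm)
  expect_equal(apply_pr(Sm, Sm, 1), rep(0, 50))
  fit <- fit_pr_chisq(Sm, Sp)
  expect_equal(apply_pr(Sm, Sp, fit), Sm - fit$b1_star * Sp, tolerance = 1e-12)
  expect_error(apply_pr(Sm, Sp[1:10], fit), class = "phasereg_error_data")
})

test_that("sPR selects the most correlated phase source", {
  set.seed(9)
  d <- block_design()
  box <- as.numeric(d$labels == "on")
  Sm <- zscore(4 * box + rnorm(224))
  own <- zscore(0.3 * box + rnorm(224))
  neighbor <- zscore(-6 * box + rnorm(224))
  fit <- fit_spr(Sm, list(own, neighbor), self = 1)
  expect_equal(fit$source_index, 2)
  expect_lt(fit$correlation, -0.8)
  expect_equal(fit$correlation, cor(Sm, neighbor))

  # single-voxel neighbourhood: k* = i, the simulation-study configuration
  fit1 <- fit_spr(Sm, list(own))
  expect_equal(fit1$source_index, 1)
  expect_equal(fit1$correlation, cor(Sm, own))

  # ties prefer self
  fit2 <- fit_spr(Sm, list(own, own), self = 1)
  expect_equal(fit2$source_index, 1)
})

test_that("orthogonal phase sources yield near-zero suppression", {
  set.seed(13)
  Sm <- zscore(rnorm(100))
  Sp <- zscore(rnorm(100))
  fit <- fit_spr(Sm, list(Sp))
  out <- apply_spr(Sm, Sp, fit)
  expect_lt(max(abs(out - Sm)), 0.3 * max(abs(Sm)))
  expect_equal(apply_spr(Sm, Sp, 0), Sm)
  expect_equal(apply_spr(Sm, Sm, 1), rep(0, 100))
  expect_error(fit_spr(Sm, list(rep(1, 100))),
               class = "phasereg_error_degenerate")
})

test_that("tidy and glance methods return well-formed tibbles", {
  set.seed(4)
  Sm <- zscore(rnorm(30))
  Sp <- zscore(rnorm(30))
  pr <- fit_pr_chisq(Sm, Sp)
  expect_named(tidy(pr), c("term", "estimate"))
  expect_equal(glance(pr)$b1_star, pr$b1_star)
  spr <- fit_spr(Sm, list(Sp, zscore(rnorm(30))))
  expect_equal(sum(tidy(spr)$selected), 1)
  expect_equal(glance(spr)$n_candidates, 2)
})
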