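test_that("heritability formulas behave at the boundaries and monotonically", {
  vc <- function(g, e, ge = NA, E = 1, R = 2)
    variance_components(g, e, sigma2_GE = ge, n_environments = E,
                        n_replicates = R)
  expect_equal(heritability_single(vc(10, 0)), 1)    # noiseless limit
  expect_equal(heritability_single(vc(0, 0)), 0)     # all-zero denominator
  expect_equal(heritability_across(vc(10, 0, ge = 0, E = 3)), 1)
  # monotone: up in genetic variance, down in error
  h <- sapply(c(1, 5, 25), function(g) heritability_single(vc(g, 10)))
  expect_true(all(diff(h) > 0))
  h2 <- sapply(c(10, 50, 250), function(e) heritability_single(vc(5, e)))
  expect_true(all(diff(h2) < 0))
  # always a proportion
  set.seed(2)
  for (i in 1:50) {
    x <- runif(3, 0, 100)
    expect_true(heritability_across(vc(x[1], x[3], ge = x[2], E = 3)) >= 0)
    expect_true(heritability_across(vc(x[1], x[3], ge = x[2], E = 3)) <= 1)
  }
  expect_error(variance_components(-1, 2), "nonnegative")
  expect_error(heritability_across(vc(1, 1)), "sigma2_GE")
})

test_that("BLUEs collapse to raw entry means on balanced orthogonal designs", {
  fx <- tiny_trial(n_lines = 60, n_markers = 200, n_env = 1, n_rep = 2,
                   vg = 80, verr = 40, seed = 5)
  ts <- fit_single_site(fx$plots, "y")
  raw <- tapply(fx$plots$y, fx$plots$line, mean)
  expect_equal(unname(ts$blues), as.vector(raw[names(ts$blues)]),
               tolerance = 1e-6)
  # BLUP shrinkage
  expect_lte(var(ts$blups), var(ts$blues))
  expect_true(ts$heritability > 0 && ts$heritability < 1)
})

test_that("constant responses give boundary variance components and equal BLUEs", {
  d <- expand.grid(line = paste0("g", 1:6), rep = c("r1", "r2"),
                   stringsAsFactors = FALSE)
  d$y <- 5
  ts <- fit_single_site(d, "y")
  expect_equal(ts$varcomps$sigma2_G, 0)
  expect_equal(ts$varcomps$sigma2_error, 0)
  expect_true(all(ts$blues == 5))
  expect_equal(ts$heritability, 0)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- expand.grid(line = paste0("g", 1:6), rep = "r1",
                   stringsAsFactors = FALSE)
  d$y <- rnorm(6)
  expect_error(fit_single_site(d, "y"), "2 replicates")
  expect_error(fit_single_site(d, "nope"), "missing column")
  d2 <- rbind(cbind(d, location = "A"), cbind(d, location = "B"))
  expect_error(fit_single_site(d2, "y"), "fit_across_sites")
  expect_error(fit_across_sites(cbind(d, location = "A"), "y"),
               "2 environments")
})

test_that("balanced-design REML agrees with expected-mean-squares ANOVA", {
  set.seed(10)
  L <- 40; R <- 3
  d <- expand.grid(line = sprintf("g%02d", 1:L), rep = paste0("r", 1:R),
                   stringsAsFactors = FALSE)
  ge <- rnorm(L, 0, 4); re <- rnorm(R, 0, 2)
  d$y <- 10 + ge[match(d$line, sprintf("g%02d", 1:L))] +
    re[match(d$rep, paste0("r", 1:R))] + rnorm(nrow(d), 0, 3)
  ts <- fit_single_site(d, "y")
  ms <- anova(aov(y ~ line + rep, d))
  s2e <- ms["Residuals", "Mean Sq"]
  s2g <- (ms["line", "Mean Sq"] - s2e) / R
  expect_equal(ts$varcomps$sigma2_G, s2g, tolerance = 1e-4)
  expect_equal(ts$varcomps$sigma2_error, s2e, tolerance = 1e-4)
})

test_that("single-site REML recovers the generative genetic variance on average", {
  n_sim <- 60
  est <- numeric(n_sim)
  set.seed(77)
  for (s in seq_len(n_sim)) {
    L <- 200; R <- 2
    d <- expand.grid(line = sprintf("g%03d", 1:L), rep = paste0("r", 1:R),
                     stringsAsFactors = FALSE)
    ge <- rnorm(L, 0, sqrt(80))
    d$y <- 20 + ge[match(d$line, sprintf("g%03d", 1:L))] +
      rnorm(nrow(d), 0, sqrt(320))
    est[s] <- fit_single_site(d, "y")$varcomps$sigma2_G
  }
  expect_lt(abs(mean(est) - 80) / 80, 0.10)
})

test_that("across-site REML separates genetic and interaction variance", {
  # ratio of recovered components vs generative 80/23, averaged over seeds
  n_sim <- 40
  vg <- ve <- vge <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    fx <- tiny_trial(n_lines = 150, n_markers = 300, n_env = 3, n_rep = 2,
                     n_testers = 1, vg = 80, vgxe = 23, venv = 40, vrep = 10,
                     vblk = 0, verr = 160, seed = 2000 + s, block_size = 10)
    vc <- fit_across_sites(fx$plots, "y")$varcomps
    vg[s] <- vc$sigma2_G; vge[s] <- vc$sigma2_GE; ve[s] <- vc$sigma2_error
  }
  expect_lt(abs(mean(vg) / mean(vge) - 80 / 23) / (80 / 23), 0.25)
  expect_lt(abs(mean(ve) - 160) / 160, 0.10)
})

test_that("a null interaction is estimated near the boundary", {
  n_sim <- 20
  vge <- vg <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    fx <- tiny_trial(n_lines = 100, n_markers = 200, n_env = 3, n_rep = 2,
                     n_testers = 1, vg = 80, vgxe = 0, venv = 40, vrep = 10,
                     vblk = 0, verr = 160, seed = 3000 + s, block_size = 10)
    vc <- fit_across_sites(fx$plots, "y")$varcomps
    vge[s] <- vc$sigma2_GE; vg[s] <- vc$sigma2_G
  }
  expect_lt(median(vge), 0.10 * median(vg))
})

test_that("across-site heritability and BLUEs are produced per line", {
  fx <- tiny_trial(n_lines = 50, n_markers = 150, n_env = 3, n_rep = 2,
                   vg = 80, vgxe = 23, venv = 40, vrep = 10, vblk = 20,
                   verr = 160, seed = 13)
  ts <- fit_across_sites(fx$plots, "y")
  expect_length(ts$blues, 50)
  expect_true(ts$heritability > 0 && ts$heritability <= 1)
  expect_true(ts$lsd05 > 0)
  bl <- blues_by_environment(fx$plots, "y")
  expect_equal(nrow(bl), 150)
  expect_setequal(unique(bl$env), c("E1", "E2", "E3"))
})

test_that("trait correlations match the textbook Pearson formula", {
  set.seed(4)
  X <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  C <- trait_correlations(X)
  pearson <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(C[i, j], pearson(X[, i], X[, j]), tolerance = 1e-12)
  expect_equal(diag(C), c(a = 1, b = 1, c = 1))
  # a trait against its negation
  C2 <- trait_correlations(cbind(t = X[, 1], neg = -X[, 1]))
  expect_equal(C2["t", "neg"], -1)
  # constant trait flagged, not silently zeroed
  expect_warning(C3 <- trait_correlations(cbind(t = X[, 1], k = rep(2, 20))),
                 "constant")
  expect_true(is.na(C3["t", "k"]))
})
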