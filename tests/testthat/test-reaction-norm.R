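test_that("design assembly encodes incidence algebra and masking correctly", {
  G <- diag(2)
  dimnames(G) <- list(c("a", "b"), c("a", "b"))
  blues <- expand.grid(line = c("a", "b"), env = c("E1", "E2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blues$value <- 1:4
  des <- build_design(blues, G)
  expect_equal(des$N, 4)
  # rows sharing an environment is exactly the ZE ZE' pattern
  ZEZE <- outer(des$env_of_row, des$env_of_row, "==") * 1
  expect_equal(ZEZE[1, 2], 1)
  expect_equal(ZEZE[1, 3], 0)
  # implicit interaction kernel: blockdiag(G) per environment = identity here
  Kblock <- des$U %*% diag(des$d) %*% t(des$U)
  expect_equal(unname(Kblock), diag(2), tolerance = 1e-12)

  # masking removes a cell from the likelihood but keeps the line in G
  des2 <- build_design(blues, G, masks = data.frame(line = "a", env = "E1"))
  expect_false(des2$obs[1])
  expect_true(des2$mask[1])
  expect_equal(des2$y_full[1], 1)
  expect_true("a" %in% des2$lines)

  expect_error(build_design(rbind(blues, data.frame(line = "zz", env = "E1",
                                                    value = 0)), G), "zz")
  expect_error(build_design(rbind(blues, blues[1, ]), G), "duplicate")
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = dimnames(G))
  expect_error(build_design(blues, bad), "positive semidefinite")
})

test_that("with frozen variances the posterior mean of g matches closed-form GBLUP", {
  G <- random_kernel(20, p = 60, seed = 42)
  set.seed(1)
  y <- as.vector(crossprod(chol(G + diag(1e-8, 20)), rnorm(20))) * 2 +
    rnorm(20, 0, sqrt(2))
  blues <- data.frame(line = rownames(G), env = "E1", value = y)
  des <- build_design(blues, G)
  fit <- fit_gibbs(des, iterations = 6000, burn_in = 1000, thin = 1, seed = 7,
                   fixed_variances = list(sigma2_g = 4, sigma2_e = 2),
                   include_env = FALSE, include_gxe = FALSE,
                   include_intercept = FALSE)
  ghat <- colMeans(fit$g)
  closed <- solve(diag(20) / 2 + solve(G + diag(1e-10, 20)) / 4, y / 2)
  mcse <- apply(fit$g, 2, sd) / sqrt(fit$n_retained)
  expect_true(all(abs(ghat - closed) <= pmax(3 * mcse, 1e-8)))
})

test_that("an all-zero response gives effects centred on zero", {
  G <- random_kernel(15, seed = 3)
  blues <- expand.grid(line = rownames(G), env = c("E1", "E2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blues$value <- 0
  des <- build_design(blues, G)
  fit <- fit_gibbs(des, iterations = 3000, burn_in = 1000, thin = 2, seed = 5)
  mcse_g <- apply(fit$g, 2, sd) / sqrt(fit$n_retained)
  expect_true(all(abs(colMeans(fit$g)) <= pmax(5 * mcse_g, 1e-6)))
  expect_lt(abs(mean(fit$mu)), sd(fit$mu) + 1e-6)
})

test_that("the chain is seed-deterministic and retains the scheduled draw count", {
  G <- random_kernel(10, seed = 8)
  blues <- expand.grid(line = rownames(G), env = c("E1", "E2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(2); blues$value <- rnorm(20)
  des <- build_design(blues, G)
  f1 <- fit_gibbs(des, iterations = 500, burn_in = 200, thin = 3, seed = 11)
  f2 <- fit_gibbs(des, iterations = 500, burn_in = 200, thin = 3, seed = 11)
  expect_identical(f1$g, f2$g)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_equal(f1$n_retained, (500 - 200) %/% 3)  # floor when not divisible
  expect_equal(fit_gibbs(des, iterations = 400, burn_in = 100, thin = 10,
                         seed = 1)$n_retained, 30)
  expect_error(fit_gibbs(des, iterations = 100, burn_in = 100), "exceed")
  expect_error(fit_gibbs(des, thin = 0), "thin")
})

test_that("an unphenotyped clone inherits its twin's breeding value", {
  set.seed(6)
  m <- matrix(rbinom(12 * 80, 1, 0.5), 12, 80,
              dimnames = list(sprintf("l%02d", 1:12), sprintf("t%02d", 1:80)))
  m <- rbind(m, clone = m["l01", ])  # unphenotyped identical twin of l01
  G <- compute_grm(qc_markers(m))
  blues <- expand.grid(line = sprintf("l%02d", 1:12), env = c("E1", "E2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(7); blues$value <- rnorm(24, 10, 3)
  des <- build_design(blues, G)
  fit <- fit_gibbs(des, iterations = 1500, burn_in = 500, thin = 2, seed = 4)
  # identical kernel rows make the draws themselves identical
  expect_equal(fit$g[, "clone"], fit$g[, "l01"], tolerance = 1e-8)
  tab <- predict_gebv(fit, des)
  expect_equal(tab$gebv[tab$line == "clone"], tab$gebv[tab$line == "l01"],
               tolerance = 1e-8)
  expect_equal(tab$set[tab$line == "clone"], "TST")
  expect_equal(tab$set[tab$line == "l01"], "TRN")
})

test_that("without relatedness, unphenotyped lines shrink to the population mean", {
  n <- 14
  G <- diag(n)
  dimnames(G) <- list(sprintf("l%02d", 1:n), sprintf("l%02d", 1:n))
  obs_lines <- sprintf("l%02d", 1:10)  # 4 lines never phenotyped
  blues <- expand.grid(line = obs_lines, env = c("E1", "E2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(9); blues$value <- rnorm(20, 5, 4)
  des <- build_design(blues, G)
  fit <- fit_gibbs(des, iterations = 4000, burn_in = 1000, thin = 3, seed = 2)
  tab <- predict_gebv(fit, des)
  tst <- tab$line %in% sprintf("l%02d", 11:14)
  mcse <- apply(fit$g[, sprintf("l%02d", 11:14)], 2, sd) / sqrt(fit$n_retained)
  expect_true(all(abs(tab$g_main[tst]) <= pmax(5 * mcse, 1e-6)))
})

test_that("training and testing sets drawn from one population predict alike", {
  dat <- cell_level_data(n_lines = 80, n_markers = 240, seed = 21)
  obs <- sort(unique(dat$blues$line))[1:40]
  blues <- dat$blues[dat$blues$line %in% obs, ]
  des <- build_design(blues, dat$grm)
  fit <- fit_gibbs(des, iterations = 2000, burn_in = 800, thin = 2, seed = 14)
  tab <- predict_gebv(fit, des)
  trn <- tab$gebv[tab$set == "TRN"]
  tst <- tab$gebv[tab$set == "TST"]
  pooled_se <- sqrt(var(trn) / length(trn) + var(tst) / length(tst))
  expect_lt(abs(mean(trn) - mean(tst)), 3 * pooled_se)
})

test_that("permuting line order permutes posterior summaries consistently", {
  G <- random_kernel(12, seed = 30)
  blues <- expand.grid(line = rownames(G), env = c("E1", "E2"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(31); blues$value <- rnorm(24, 0, 3)
  perm <- sample(12)
  Gp <- G[perm, perm]
  f <- fit_gibbs(build_design(blues, G), iterations = 4000, burn_in = 1000,
                 thin = 2, seed = 3)
  fp <- fit_gibbs(build_design(blues, Gp), iterations = 4000, burn_in = 1000,
                  thin = 2, seed = 3)
  a <- colMeans(f$g)[rownames(Gp)]
  b <- colMeans(fp$g)
  tolr <- 5 * (apply(f$g, 2, sd) / sqrt(f$n_retained) +
               apply(fp$g, 2, sd) / sqrt(fp$n_retained))[rownames(Gp)]
  expect_true(all(abs(a - b) <= tolr))
})
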