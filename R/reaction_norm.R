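#' Assemble the reaction-norm design
#'
#' Stacks line-by-environment values (typically single-site BLUEs) over the
#' complete grid of all lines in the relationship kernel times all
#' environments, in environment-major order. Cells without a phenotype —
#' unphenotyped lines, unobserved environments, or cells held out through
#' `masks` — are treated as missing and carried through the sampler by data
#' augmentation, so every line in the kernel receives breeding-value draws.
#' The interaction kernel `(Zg G Zg') # (ZE ZE')` ("#" the element-wise
#' product) is block-diagonal over environments with one copy of `G` per
#' block, and is represented implicitly through the eigendecomposition of
#' `G`, computed once here and reused by [fit_gibbs()].
#'
#' @param blues data frame with columns `line`, `env`, `value` (one row per
#'   observed cell).
#' @param grm relationship kernel over all lines, phenotyped or not
#'   ([compute_grm()]); every phenotyped line must appear in its row names.
#' @param masks optional data frame with columns `line`, `env`: cells
#'   removed from the likelihood but kept for hold-out comparison.
#' @param eig optional precomputed `eigen()` of the (symmetrized) kernel,
#'   to share across cross-validation folds.
#' @param tol relative eigenvalue tolerance: the kernel must have no
#'   eigenvalue below `-tol * max(eigenvalue)`, and components below
#'   `tol * max` are dropped (rank-deficient kernels are fine).
#' @return Object of class `rn_design`.
#' @export
build_design <- function(blues, grm, masks = NULL, eig = NULL, tol = 1e-8) {
  stopifnot(is.data.frame(blues),
            all(c("line", "env", "value") %in% names(blues)))
  lines <- rownames(grm)
  if (is.null(lines)) stop("the relationship kernel must carry line IDs")
  absent <- setdiff(unique(as.character(blues$line)), lines)
  if (length(absent))
    stop("phenotyped line(s) absent from the relationship kernel: ",
         paste(head(absent, 5), collapse = ", "))
  envs <- sort(unique(as.character(blues$env)))
  L <- length(lines)
  E <- length(envs)
  N <- L * E
  row_of <- function(line, env)
    (match(env, envs) - 1L) * L + match(line, lines)

  y <- rep(NA_real_, N)
  idx <- row_of(as.character(blues$line), as.character(blues$env))
  if (anyDuplicated(idx))
    stop("duplicate line x environment cells in the input values")
  y[idx] <- blues$value
  y_full <- y
  mask <- rep(FALSE, N)
  if (!is.null(masks) && nrow(masks)) {
    midx <- row_of(as.character(masks$line), as.character(masks$env))
    if (anyNA(midx))
      stop("mask refers to a line or environment not in the design")
    mask[midx] <- TRUE
    y[mask] <- NA_real_
  }
  obs <- !is.na(y)
  if (!any(obs)) stop("no observed cells remain after masking")

  if (is.null(eig)) {
    if (max(abs(grm - t(grm))) > 1e-6 * max(1, max(abs(grm))))
      stop("relationship kernel is not symmetric")
    eig <- eigen((grm + t(grm)) / 2, symmetric = TRUE)
  }
  dmax <- max(eig$values)
  if (min(eig$values) < -tol * max(1, dmax))
    stop("relationship kernel is not positive semidefinite")
  keep <- eig$values > tol * dmax
  structure(list(y = y, y_full = y_full, obs = obs, mask = mask,
                 lines = lines, envs = envs, L = L, E = E, N = N,
                 line_of_row = rep(seq_len(L), E),
                 env_of_row = rep(seq_len(E), each = L),
                 U = eig$vectors[, keep, drop = FALSE],
                 d = eig$values[keep]),
            class = "rn_design")
}

#' Gibbs sampler for the Bayesian reaction-norm model
#'
#' Fits `y = mu + ZE betaE + Zg g + u + e` with `betaE ~ N(0, s2E I)`,
#' `g ~ N(0, s2g G)`, `u ~ N(0, s2gxE (Zg G Zg') # (ZE ZE'))` and
#' `e ~ N(0, s2e I)` by Gibbs sampling. Each gaussian block is updated from
#' its full conditional in the eigenbasis of its kernel (cached in the
#' design), where — thanks to the complete augmented grid — the conditional
#' is diagonal, so one iteration costs a handful of dense matrix-vector
#' products. Missing cells are imputed from the current conditional each
#' sweep; the four variances get scaled-inverse-chi-square updates.
#'
#' Priors: every variance has a scaled-inverse-chi-square prior with
#' `df_prior` degrees of freedom, scale set so the prior mode equals
#' `R2_error` times the sample phenotypic variance for the residual and
#' `(1 - R2_error)` split equally over the remaining blocks — the usual
#' Bayesian-GBLUP software convention.
#'
#' @param design an [build_design()] object.
#' @param iterations,burn_in,thin chain schedule; `(iterations - burn_in) /
#'   thin` draws are retained (floor when not divisible), 1,500 at the
#'   defaults.
#' @param seed integer seed for the chain; same seed, same draws.
#' @param df_prior prior degrees of freedom for all variances.
#' @param R2_error prior proportion of phenotypic variance assigned to the
#'   residual.
#' @param fixed_variances optional named list freezing any of `sigma2_E`,
#'   `sigma2_g`, `sigma2_gxE`, `sigma2_e` at known values (their update is
#'   skipped) — mainly for conjugate closed-form checks.
#' @param include_env,include_gxe,include_intercept drop the environment
#'   block, the interaction block, or the intercept; with one environment,
#'   no interaction and no intercept the model reduces to standard GBLUP.
#' @return Object of class `rn_posterior` holding the retained draws of
#'   `mu`, `beta_E`, `g`, `u` and the four variances.
#' @export
fit_gibbs <- function(design, iterations = 30000, burn_in = 15000, thin = 10,
                      seed = NULL, df_prior = 5, R2_error = 0.5,
                      fixed_variances = NULL,
                      include_env = TRUE, include_gxe = TRUE,
                      include_intercept = TRUE) {
  stopifnot(inherits(design, "rn_design"))
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (thin < 1) stop("thin must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  U <- design$U; d <- design$d; r <- length(d)
  L <- design$L; E <- design$E; N <- design$N
  obs <- design$obs
  env_of <- design$env_of_row
  line_of <- design$line_of_row
  yobs <- design$y[obs]
  n_mis <- N - sum(obs)
  vy <- var(yobs)
  if (!is.finite(vy) || vy == 0) vy <- 1

  nblocks <- 1 + include_env + include_gxe
  S_e <- vy * R2_error * (df_prior + 2)
  S_r <- vy * (1 - R2_error) / nblocks * (df_prior + 2)
  fv <- fixed_variances %||% list()
  s2e <- fv$sigma2_e %||% (R2_error * vy)
  s2E <- fv$sigma2_E %||% ((1 - R2_error) / nblocks * vy)
  s2g <- fv$sigma2_g %||% ((1 - R2_error) / nblocks * vy)
  s2u <- fv$sigma2_gxE %||% ((1 - R2_error) / nblocks * vy)

  mu <- if (include_intercept) mean(yobs) else 0
  beta <- numeric(E)
  delta <- numeric(r)
  Eta <- matrix(0, r, E)
  g <- numeric(L)
  Umat_u <- matrix(0, L, E)
  ytilde <- design$y
  ytilde[!obs] <- mu

  n_ret <- (iterations - burn_in) %/% thin
  mu_d <- numeric(n_ret)
  beta_d <- matrix(0, n_ret, E, dimnames = list(NULL, design$envs))
  g_d <- matrix(0, n_ret, L, dimnames = list(NULL, design$lines))
  u_d <- matrix(0, n_ret, N)
  s2_d <- matrix(0, n_ret, 4,
                 dimnames = list(NULL, c("sigma2_E", "sigma2_g",
                                         "sigma2_gxE", "sigma2_e")))
  k <- 0L
  for (it in seq_len(iterations)) {
    bvec <- beta[env_of]
    gvec <- g[line_of]
    uvec <- as.vector(Umat_u)
    if (n_mis) {
      fitted_mis <- (mu + bvec + gvec + uvec)[!obs]
      ytilde[!obs] <- fitted_mis + rnorm(n_mis, 0, sqrt(s2e))
    }
    if (include_intercept)
      mu <- rnorm(1, mean(ytilde - bvec - gvec - uvec), sqrt(s2e / N))
    if (include_env) {
      r1 <- matrix(ytilde - mu - gvec - uvec, L, E)
      prec <- L / s2e + 1 / s2E
      beta <- rnorm(E, (colSums(r1) / s2e) / prec, sqrt(1 / prec))
      bvec <- beta[env_of]
    }
    # genomic main effects, sampled in the eigenbasis of G
    r2 <- rowSums(matrix(ytilde - mu - bvec - uvec, L, E))
    cg <- as.vector(crossprod(U, r2))
    precg <- E / s2e + 1 / (s2g * d)
    delta <- rnorm(r, (cg / s2e) / precg, sqrt(1 / precg))
    g <- as.vector(U %*% delta)
    gvec <- g[line_of]
    if (include_gxe) {
      R3 <- matrix(ytilde - mu - bvec - gvec, L, E)
      C <- crossprod(U, R3)
      precu <- 1 / s2e + 1 / (s2u * d)
      Eta <- (C / s2e) / precu + matrix(rnorm(r * E), r, E) / sqrt(precu)
      Umat_u <- U %*% Eta
      uvec <- as.vector(Umat_u)
    }
    if (include_env && is.null(fv$sigma2_E))
      s2E <- (sum(beta^2) + S_r) / rchisq(1, df_prior + E)
    if (is.null(fv$sigma2_g))
      s2g <- (sum(delta^2 / d) + S_r) / rchisq(1, df_prior + r)
    if (include_gxe && is.null(fv$sigma2_gxE))
      s2u <- (sum(Eta^2 / d) + S_r) / rchisq(1, df_prior + r * E)
    if (is.null(fv$sigma2_e)) {
      resid <- ytilde - mu - bvec - gvec - uvec
      s2e <- (sum(resid^2) + S_e) / rchisq(1, df_prior + N)
    }
    if (!all(is.finite(c(s2e, s2E, s2g, s2u))) || s2e > 1e12 * vy)
      stop("variance draw diverged at iteration ", it)
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      k <- k + 1L
      mu_d[k] <- mu
      beta_d[k, ] <- beta
      g_d[k, ] <- g
      u_d[k, ] <- as.vector(Umat_u)
      s2_d[k, ] <- c(s2E, s2g, s2u, s2e)
    }
  }
  structure(list(mu = mu_d, beta_E = beta_d, g = g_d, u = u_d,
                 sigma2 = s2_d, n_retained = k,
                 lines = design$lines, envs = design$envs,
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 thin = thin, seed = seed,
                                 df_prior = df_prior, R2_error = R2_error)),
            class = "rn_posterior")
}

#' Posterior-mean predicted value for every grid cell
#'
#' `mu + beta_E + g + u` averaged over retained draws, in the design's
#' environment-major row order. This is the model's conditional mean for a
#' cell whether it was observed, masked, or belongs to an unphenotyped line.
#'
#' @param fit object returned by the fitter.
#' @param design the matching [build_design()] object.
#' @return Numeric vector of length `design$N`.
#' @export
predict_cells <- function(fit, design) UseMethod("predict_cells")

#' @export
predict_cells.rn_posterior <- function(fit, design) {
  mu <- mean(fit$mu)
  beta <- colMeans(fit$beta_E)
  g <- colMeans(fit$g)
  u <- colMeans(fit$u)
  mu + beta[design$env_of_row] + g[design$line_of_row] + u
}

#' Genomic estimated breeding values for all lines
#'
#' Summarizes the posterior into a GEBV table covering every line in the
#' kernel. Lines with at least one cell in the training likelihood are
#' labelled TRN, the rest (never phenotyped, or fully masked) TST. The
#' across-environment GEBV is `mu + mean(beta_E) + g + mean_env(u)`; the
#' per-environment columns add the environment effect and that
#' environment's interaction deviation.
#'
#' @param fit an `rn_posterior` from [fit_gibbs()].
#' @param design the matching [build_design()] object.
#' @return Data frame with columns `line`, `set`, `g_main`, `gebv` and one
#'   `gebv_<env>` column per environment.
#' @export
predict_gebv <- function(fit, design) {
  stopifnot(inherits(fit, "rn_posterior"), inherits(design, "rn_design"))
  if (fit$n_retained < 1) stop("no retained draws to summarize")
  gm <- colMeans(fit$g)
  um <- matrix(colMeans(fit$u), design$L, design$E)
  mum <- mean(fit$mu)
  bm <- colMeans(fit$beta_E)
  trn <- rowSums(matrix(design$obs, design$L, design$E)) > 0
  out <- data.frame(line = design$lines,
                    set = ifelse(trn, "TRN", "TST"),
                    g_main = unname(gm),
                    gebv = mum + mean(bm) + unname(gm) + rowMeans(um),
                    stringsAsFactors = FALSE)
  perenv <- sweep(um + gm + mum, 2, bm, "+")
  colnames(perenv) <- paste0("gebv_", design$envs)
  cbind(out, as.data.frame(perenv, row.names = NULL))
}
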