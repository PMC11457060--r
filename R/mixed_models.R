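#' Variance components of a trial mixed model
#'
#' Light container for REML (or configured) variance components together
#' with the design counts that enter the heritability formulas.
#'
#' @param sigma2_G genotypic variance.
#' @param sigma2_error residual variance.
#' @param sigma2_GE genotype-by-environment variance (`NA` for single-site
#'   fits).
#' @param sigma2_rep,sigma2_block replicate and block-within-replicate
#'   variances (informational).
#' @param n_environments,n_replicates design counts `E` and `R`.
#' @return Object of class `variance_components`.
#' @export
variance_components <- function(sigma2_G, sigma2_error, sigma2_GE = NA_real_,
                                sigma2_rep = NA_real_, sigma2_block = NA_real_,
                                n_environments = 1L, n_replicates = 2L) {
  sigma2_G <- unname(sigma2_G); sigma2_error <- unname(sigma2_error)
  sigma2_GE <- unname(sigma2_GE); sigma2_rep <- unname(sigma2_rep)
  sigma2_block <- unname(sigma2_block)
  comps <- c(sigma2_G, sigma2_error, sigma2_GE, sigma2_rep, sigma2_block)
  if (any(!is.na(comps) & comps < 0))
    stop("variance components must be nonnegative")
  if (n_environments < 1 || n_replicates < 1)
    stop("design counts must be at least 1")
  structure(list(sigma2_G = sigma2_G, sigma2_GE = sigma2_GE,
                 sigma2_rep = sigma2_rep, sigma2_block = sigma2_block,
                 sigma2_error = sigma2_error,
                 n_environments = as.integer(n_environments),
                 n_replicates = as.integer(n_replicates)),
            class = "variance_components")
}

#' Broad-sense heritability, single environment
#'
#' `H^2 = sigma2_G / (sigma2_G + sigma2_error / R)` on an entry-mean basis
#' with `R` replicates. Defined as 0 when the denominator is 0.
#'
#' @param vc a [variance_components()] object (single-site: `sigma2_GE`
#'   unused).
#' @return Heritability in \[0, 1\].
#' @examples
#' heritability_single(variance_components(16.75, 63.51, n_replicates = 2))
#' @export
heritability_single <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  den <- vc$sigma2_G + vc$sigma2_error / vc$n_replicates
  if (den <= 0) return(0)
  vc$sigma2_G / den
}

#' Broad-sense heritability, combined environments
#'
#' `H^2 = sigma2_G / (sigma2_G + sigma2_GE / E + sigma2_error / (E * R))`
#' on an entry-mean basis over `E` environments with `R` replicates each.
#'
#' @inheritParams heritability_single
#' @return Heritability in \[0, 1\].
#' @examples
#' heritability_across(variance_components(181.61, 520.38, sigma2_GE = 32.99,
#'                                         n_environments = 3, n_replicates = 2))
#' @export
heritability_across <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (is.na(vc$sigma2_GE))
    stop("sigma2_GE is required for across-environment heritability")
  E <- vc$n_environments
  R <- vc$n_replicates
  den <- vc$sigma2_G + vc$sigma2_GE / E + vc$sigma2_error / (E * R)
  if (den <= 0) return(0)
  vc$sigma2_G / den
}

#' Fit the single-site alpha-lattice model
#'
#' Fits `y = mu + line + rep + block(rep) + error` by REML for one
#' environment. Two fits are run: line random (variance components, BLUPs,
#' heritability) and line fixed (BLUEs by generalized least squares at the
#' REML variances). A tester column, when present with more than one level,
#' enters both fits as a fixed effect and line values are averaged over
#' testers. Replicates and blocks-within-replicates are always random.
#'
#' @param records plot-level data frame with columns `line`, `rep`, the
#'   trait, and optionally `block`, `tester`, `location` (must be a single
#'   location).
#' @param trait name of the trait column.
#' @return Object of class `trait_summary`: named vectors `blues` and
#'   `blups`, a [variance_components()] object, `heritability`, and `lsd05`.
#' @export
fit_single_site <- function(records, trait) {
  d <- .prep_records(records, trait)
  if (length(unique(d$location)) > 1)
    stop("records span several locations; use fit_across_sites()")
  R <- length(unique(d$rep))
  if (R < 2)
    stop("at least 2 replicates are needed to separate the error variance")
  if (var(d$.y) == 0)
    return(.constant_summary(d, trait, R, n_env = 1L))

  has_tester <- .has_factor(d, "tester")
  has_block <- .has_factor(d, "block")
  rand <- c("(1 | rep)", if (has_block) "(1 | rep:block)")
  f_rand <- stats::reformulate(c(if (has_tester) "tester", "(1 | line)", rand),
                               response = ".y")
  f_fix <- stats::reformulate(c("0 + line", if (has_tester) "tester", rand),
                              response = ".y")
  fit_r <- .lmer_quiet(f_rand, d)
  fit_f <- .lmer_quiet(f_fix, d)

  vcs <- .vc_table(fit_r)
  vc <- variance_components(sigma2_G = vcs["line"],
                            sigma2_error = vcs["Residual"],
                            sigma2_rep = vcs["rep"],
                            sigma2_block = if (has_block) vcs["rep:block"] else NA_real_,
                            n_environments = 1L, n_replicates = R)
  blues <- .line_blues(fit_f)
  blups <- .line_blups(fit_r)
  h2 <- heritability_single(vc)
  df_err <- stats::nobs(fit_f) - length(lme4::fixef(fit_f))
  lsd <- qt(0.975, df_err) * sqrt(2 * vc$sigma2_error / R)
  .trait_summary(trait, blues, blups, vc, h2, lsd)
}

#' Fit the across-site model
#'
#' Fits `y = mu + line + env + rep(env) + block(env:rep) + line:env + error`
#' by REML over several environments. Environment is fixed; line, the
#' line-by-environment interaction, replicates and blocks are random (line
#' switches to fixed for the BLUE fit). Lines without any observation are
#' dropped with a warning.
#'
#' @param records plot-level data frame with columns `location`, `line`,
#'   `rep`, the trait, and optionally `block` and `tester`.
#' @param trait name of the trait column.
#' @return A `trait_summary` (see [fit_single_site()]) whose variance
#'   components include `sigma2_GE` and whose heritability uses the
#'   combined-environment formula.
#' @export
fit_across_sites <- function(records, trait) {
  d <- .prep_records(records, trait, require_env = TRUE)
  E <- length(unique(d$location))
  if (E < 2) stop("at least 2 environments are needed; use fit_single_site()")
  R <- length(unique(d$rep))
  if (var(d$.y) == 0)
    return(.constant_summary(d, trait, R, n_env = E))

  has_tester <- .has_factor(d, "tester")
  has_block <- .has_factor(d, "block")
  rand <- c("(1 | location:rep)", if (has_block) "(1 | location:rep:block)")
  f_rand <- stats::reformulate(c("location", if (has_tester) "tester",
                                 "(1 | line)", "(1 | line:location)", rand),
                               response = ".y")
  f_fix <- stats::reformulate(c("0 + line", "location",
                                if (has_tester) "tester",
                                "(1 | line:location)", rand),
                              response = ".y")
  fit_r <- .lmer_quiet(f_rand, d)
  fit_f <- .lmer_quiet(f_fix, d)

  vcs <- .vc_table(fit_r)
  vc <- variance_components(sigma2_G = vcs["line"],
                            sigma2_error = vcs["Residual"],
                            sigma2_GE = vcs["line:location"],
                            sigma2_rep = vcs["location:rep"],
                            sigma2_block = if (has_block) vcs["location:rep:block"] else NA_real_,
                            n_environments = E, n_replicates = R)
  blues <- .line_blues(fit_f)
  blups <- .line_blups(fit_r)
  h2 <- heritability_across(vc)
  df_err <- stats::nobs(fit_f) - length(lme4::fixef(fit_f))
  lsd <- qt(0.975, df_err) * sqrt(2 * vc$sigma2_error / (R * E))
  .trait_summary(trait, blues, blups, vc, h2, lsd)
}

#' Per-environment line BLUEs for genomic prediction
#'
#' Runs the single-site BLUE fit in every environment and stacks the results
#' as one row per line x environment, the input layout of the reaction-norm
#' model ([build_design()]).
#'
#' @inheritParams fit_across_sites
#' @return Data frame with columns `line`, `env`, `value`.
#' @export
blues_by_environment <- function(records, trait) {
  d <- .prep_records(records, trait, require_env = TRUE)
  envs <- sort(unique(d$location))
  out <- lapply(envs, function(e) {
    ts <- fit_single_site(d[d$location == e, , drop = FALSE], trait)
    data.frame(line = names(ts$blues), env = e, value = unname(ts$blues),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlations between trait BLUPs
#'
#' @param blups data frame or matrix, lines in rows and traits in columns
#'   (across-site BLUPs, one value per line).
#' @return Symmetric correlation matrix with unit diagonal. Correlations
#'   involving a constant trait are flagged with a warning and returned as
#'   `NA` rather than silently zeroed.
#' @export
trait_correlations <- function(blups) {
  X <- as.matrix(blups)
  if (nrow(X) < 3)
    stop("at least 3 lines are needed to correlate traits")
  sds <- apply(X, 2, sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("constant trait(s): ",
            paste(colnames(X)[which(sds == 0)], collapse = ", "),
            "; their correlations are undefined (NA)")
  suppressWarnings(cor(X, use = "pairwise.complete.obs"))
}

# ---- internal helpers -------------------------------------------------------

.prep_records <- function(records, trait, require_env = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("line", "rep", if (require_env) "location", trait)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- records
  if (!"location" %in% names(d)) d$location <- "E1"
  for (col in intersect(c("location", "rep", "block", "line", "tester", "entry"),
                        names(d)))
    d[[col]] <- as.character(d[[col]])
  d$.y <- as.numeric(d[[trait]])
  keep <- !is.na(d$.y)
  if (!any(keep)) stop("no non-missing observations for trait '", trait, "'")
  d <- d[keep, , drop = FALSE]
  lost <- setdiff(unique(records$line), unique(d$line))
  if (length(lost))
    warning(length(lost), " line(s) without any observation dropped: ",
            paste(head(lost, 5), collapse = ", "))
  d
}

.has_factor <- function(d, col) {
  col %in% names(d) && length(unique(d[[col]])) > 1
}

.lmer_quiet <- function(formula, data) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = TRUE,
                                control = ctrl)),
    warning = function(w) {
      if (grepl("singular|converge|Hessian", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

.vc_table <- function(fit) {
  v <- as.data.frame(lme4::VarCorr(fit))
  setNames(v$vcov, v$grp)
}

# BLUE per line = its fixed-effect coefficient plus the average adjustment of
# the other fixed factors (treatment contrasts: reference levels contribute 0).
.line_blues <- function(fit_fixed) {
  fe <- lme4::fixef(fit_fixed)
  is_line <- grepl("^line", names(fe))
  adj <- 0
  for (fac in c("location", "tester")) {
    idx <- grepl(paste0("^", fac), names(fe))
    if (any(idx)) {
      nlev <- sum(idx) + 1  # reference level absorbed
      adj <- adj + sum(fe[idx]) / nlev
    }
  }
  blues <- fe[is_line] + adj
  names(blues) <- sub("^line", "", names(blues))
  blues[order(names(blues))]
}

.line_blups <- function(fit_random) {
  fe <- lme4::fixef(fit_random)
  base <- unname(fe["(Intercept)"])
  for (fac in c("location", "tester")) {
    idx <- grepl(paste0("^", fac), names(fe))
    if (any(idx)) base <- base + sum(fe[idx]) / (sum(idx) + 1)
  }
  re <- lme4::ranef(fit_random)$line
  blups <- setNames(re[, 1] + base, rownames(re))
  blups[order(names(blups))]
}

.trait_summary <- function(trait, blues, blups, vc, h2, lsd) {
  structure(list(trait = trait, blues = blues, blups = blups, varcomps = vc,
                 heritability = h2, lsd05 = lsd),
            class = "trait_summary")
}

.constant_summary <- function(d, trait, R, n_env) {
  lines <- sort(unique(d$line))
  val <- d$.y[1]
  vc <- variance_components(0, 0, sigma2_GE = if (n_env > 1) 0 else NA_real_,
                            sigma2_rep = 0, n_environments = n_env,
                            n_replicates = R)
  .trait_summary(trait, setNames(rep(val, length(lines)), lines),
                 setNames(rep(val, length(lines)), lines), vc, 0, 0)
}

#' @export
print.trait_summary <- function(x, ...) {
  vc <- x$varcomps
  cat("Trait summary:", x$trait, "\n",
      sprintf("  sigma2_G = %.4g", vc$sigma2_G),
      if (!is.na(vc$sigma2_GE)) sprintf(" sigma2_GE = %.4g", vc$sigma2_GE),
      sprintf(" sigma2_error = %.4g\n", vc$sigma2_error),
      sprintf("  H2 = %.3f  LSD05 = %.3g  (%d lines)\n",
              x$heritability, x$lsd05, length(x$blues)), sep = "")
  invisible(x)
}
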