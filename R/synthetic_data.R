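#' Configuration for the synthetic testcross trial generator
#'
#' Bundles every knob of the marker-panel and multi-location alpha-lattice
#' trial simulator. The defaults emulate a tropical DH maize testcross
#' screening trial: 606 lines genotyped with a dominant presence/absence
#' panel, 116-line-scale trials at 3 locations with 2 replicates, 2 testers,
#' incomplete blocks of 4 entries, and variance components of the magnitude
#' seen for emerged *Striga* counts around 10 weeks after planting.
#'
#' @param n_lines number of DH lines.
#' @param n_markers number of dominant (0/1) markers.
#' @param maf_range lower/upper bound of the minor-class frequency, each in
#'   (0, 0.5]. Per-marker presence frequencies are drawn uniformly from this
#'   range or its complement (so "present" may be the major class).
#' @param n_environments,n_replicates,n_testers trial dimensions.
#' @param block_size entries per incomplete block; must divide
#'   `n_lines * n_testers` (alpha-lattice completeness).
#' @param var_genetic variance of line main genetic values (exactly realized,
#'   see Details).
#' @param var_gxe variance of line-by-environment deviations.
#' @param var_env,var_replicate,var_block variance of environment main
#'   effects, replicate-within-environment effects, and
#'   block-within-replicate effects.
#' @param var_error residual plot-level variance.
#' @param n_qtl number of markers with nonzero effect.
#' @param trait_kind `"gaussian"` for a continuous trait or `"count"` for a
#'   *Striga*-count-like trait (latent gaussian floored at zero and rounded).
#' @param mu trial intercept (grand mean).
#' @param seed integer seed; all generator output is a deterministic function
#'   of the configuration.
#'
#' @details Marker effects at the `n_qtl` causal markers are drawn standard
#' normal and rescaled so the realized variance of line main values equals
#' `var_genetic` exactly, which makes parameter-recovery tests sharp.
#' Line-by-environment deviations are genomic: within each environment they
#' are drawn from `N(0, var_gxe * G)` with `G` the marker-derived
#' relationship kernel (marginal variance `var_gxe` since `mean(diag(G)) =
#' 1`), independently across environments — the interaction structure the
#' reaction-norm model assumes. Testers contribute a fixed additive offset
#' each (no line-by-tester interaction).
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_markers()], [simulate_trial()], [simulate_striga_dataset()]
#' @export
sim_config <- function(n_lines = 606L, n_markers = 5000L,
                       maf_range = c(0.05, 0.5),
                       n_environments = 3L, n_replicates = 2L,
                       block_size = 4L, n_testers = 2L,
                       var_genetic = 80, var_gxe = 23, var_env = 40,
                       var_replicate = 10, var_block = 20, var_error = 323,
                       n_qtl = min(300L, n_markers),
                       trait_kind = c("gaussian", "count"),
                       mu = 20, seed = 1L) {
  trait_kind <- match.arg(trait_kind)
  counts <- c(n_lines = n_lines, n_markers = n_markers,
              n_environments = n_environments, n_replicates = n_replicates,
              block_size = block_size, n_testers = n_testers, n_qtl = n_qtl)
  if (any(counts < c(2, 1, 1, 1, 1, 1, 0)))
    stop("invalid design counts: need >= 2 lines and positive dimensions")
  vars <- c(var_genetic, var_gxe, var_env, var_replicate, var_block, var_error)
  if (any(!is.finite(vars)) || any(vars < 0))
    stop("all variance components must be finite and nonnegative")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]")
  if (n_qtl > n_markers)
    stop("n_qtl cannot exceed n_markers")
  if ((n_lines * n_testers) %% block_size != 0)
    stop("block_size must divide the number of entries per replicate ",
         "(n_lines * n_testers)")
  structure(list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
                 maf_range = maf_range,
                 n_environments = as.integer(n_environments),
                 n_replicates = as.integer(n_replicates),
                 block_size = as.integer(block_size),
                 n_testers = as.integer(n_testers),
                 var_genetic = var_genetic, var_gxe = var_gxe,
                 var_env = var_env, var_replicate = var_replicate,
                 var_block = var_block, var_error = var_error,
                 n_qtl = as.integer(n_qtl), trait_kind = trait_kind,
                 mu = mu, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a dominant presence/absence marker panel
#'
#' Generates a lines-by-markers matrix of 0/1 calls. Each marker's presence
#' frequency is drawn uniformly from `maf_range` or its complement, then
#' enforced exactly by permutation fill: the column is a random permutation
#' of `round(f * n_lines)` ones.
#'
#' @param config a [sim_config()] object.
#' @return Integer matrix in \{0, 1\} with synthetic line IDs as row names
#'   and marker tags as column names.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines
  p <- config$n_markers
  f <- runif(p, config$maf_range[1], config$maf_range[2])
  flip <- runif(p) < 0.5
  f[flip] <- 1 - f[flip]
  k <- as.integer(round(f * n))
  M <- vapply(k, function(ki) sample(rep.int(c(1L, 0L), c(ki, n - ki))),
              integer(n))
  dimnames(M) <- list(sprintf("DH%04d", seq_len(n)),
                      sprintf("tag%05d", seq_len(p)))
  M
}

#' Lay out the alpha-lattice field design
#'
#' Builds the plot grid for a resolvable incomplete-block trial: every
#' (environment, replicate) contains every entry (line x tester) exactly
#' once, and blocks of `block_size` entries partition each replicate. Entry
#' order within each replicate is randomized independently.
#'
#' @param config a [sim_config()] object.
#' @return A data frame with columns `location`, `rep`, `block`, `entry`,
#'   `line`, `tester`, one row per plot.
#' @export
make_trial_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  lines <- sprintf("DH%04d", seq_len(config$n_lines))
  testers <- sprintf("T%d", seq_len(config$n_testers))
  grid <- expand.grid(line = lines, tester = testers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_entry <- nrow(grid)
  envs <- sprintf("E%d", seq_len(config$n_environments))
  reps <- sprintf("R%d", seq_len(config$n_replicates))
  out <- vector("list", length(envs) * length(reps))
  i <- 0L
  for (e in envs) {
    for (r in reps) {
      ord <- sample.int(n_entry)
      i <- i + 1L
      out[[i]] <- data.frame(
        location = e, rep = r,
        block = sprintf("B%03d", ceiling(seq_len(n_entry) / config$block_size)),
        entry = paste(grid$line[ord], grid$tester[ord], sep = ":"),
        line = grid$line[ord], tester = grid$tester[ord],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a multi-location testcross trial with known truth
#'
#' Generates one plot record per line x tester x environment x replicate
#' following the across-site mixed model used for analysis: phenotype =
#' intercept + environment effect + replicate-in-environment +
#' block-in-replicate + line main genetic value + tester offset +
#' line-by-environment deviation + residual. Line main values are the sum of
#' marker effects at the causal markers, rescaled so their realized variance
#' equals `var_genetic` exactly. For `trait_kind = "count"` the latent value
#' is mapped through `round(pmax(0, .))` so count-like traits are
#' nonnegative integers.
#'
#' @param config a [sim_config()] object.
#' @param markers marker matrix from [simulate_markers()] (rows = lines).
#' @param design optional plot layout from [make_trial_design()]; generated
#'   from `config` when omitted. Passing a shared design lets several traits
#'   be simulated on the same field layout.
#' @return A list with `plots` (data frame of plot records with trait column
#'   `y`) and `truth` (class `synthetic_truth`: the realized effects).
#' @export
simulate_trial <- function(config, markers, design = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(markers) != config$n_lines)
    stop("marker matrix has ", nrow(markers), " rows but config declares ",
         config$n_lines, " lines")
  set.seed(config$seed + 1L)
  lines <- rownames(markers)
  envs <- sprintf("E%d", seq_len(config$n_environments))
  testers <- sprintf("T%d", seq_len(config$n_testers))

  beta <- setNames(numeric(config$n_markers), colnames(markers))
  g <- setNames(numeric(config$n_lines), lines)
  if (config$var_genetic > 0 && config$n_qtl > 0) {
    qtl <- sample.int(config$n_markers, config$n_qtl)
    b <- rnorm(config$n_qtl)
    graw <- as.vector(scale(markers[, qtl, drop = FALSE], center = TRUE,
                            scale = FALSE) %*% b)
    sdg <- sd(graw)
    if (sdg == 0)
      stop("causal markers carry no variation; widen maf_range or raise n_qtl")
    sc <- sqrt(config$var_genetic) / sdg
    beta[qtl] <- b * sc
    g[] <- graw * sc
    g <- g - mean(g)
  }
  tester_eff <- setNames(rnorm(config$n_testers, 0, sqrt(config$var_genetic) / 2),
                         testers)
  env_eff <- setNames(rnorm(config$n_environments, 0, sqrt(config$var_env)), envs)
  rep_keys <- as.vector(outer(sprintf("R%d", seq_len(config$n_replicates)),
                              envs, function(r, e) paste(e, r, sep = ":")))
  rep_eff <- setNames(rnorm(length(rep_keys), 0, sqrt(config$var_replicate)),
                      rep_keys)
  gxe <- matrix(0, config$n_lines, config$n_environments,
                dimnames = list(lines, envs))
  if (config$var_gxe > 0) {
    poly <- qc_markers(suppressWarnings(qc_markers(markers, 0)), 0)
    Ck <- if (ncol(poly) > 0) {
      Gk <- compute_grm(impute_markers(poly))
      chol(Gk + diag(1e-8, nrow(Gk)))
    } else {
      diag(config$n_lines)  # no polymorphism: fall back to iid deviations
    }
    Z <- matrix(rnorm(config$n_lines * config$n_environments),
                config$n_lines, config$n_environments)
    gxe[] <- sqrt(config$var_gxe) * crossprod(Ck, Z)
  }

  if (is.null(design)) design <- make_trial_design(config)

  set.seed(config$seed + 3L)
  blk_key <- paste(design$location, design$rep, design$block, sep = ":")
  blk_levels <- unique(blk_key)
  blk_eff <- setNames(rnorm(length(blk_levels), 0, sqrt(config$var_block)),
                      blk_levels)
  eps <- rnorm(nrow(design), 0, sqrt(config$var_error))

  latent <- config$mu +
    env_eff[design$location] +
    rep_eff[paste(design$location, design$rep, sep = ":")] +
    blk_eff[blk_key] +
    g[design$line] +
    tester_eff[design$tester] +
    gxe[cbind(match(design$line, lines), match(design$location, envs))] +
    eps
  y <- if (config$trait_kind == "count") round(pmax(0, latent)) else latent

  plots <- design
  plots$y <- unname(y)
  truth <- structure(list(mu = config$mu, line_effects = g, gxe = gxe,
                          env_effects = env_eff, rep_effects = rep_eff,
                          block_effects = blk_eff, tester_effects = tester_eff,
                          marker_effects = beta),
                     class = "synthetic_truth")
  list(plots = plots, truth = truth)
}

#' Simulate a deposited-style multi-trait Striga screening dataset
#'
#' Builds a phenotype table shaped like a real *Striga* screening trial
#' export: emerged *Striga* counts at 8/10/12 weeks after planting, damage
#' ratings at 10 and 12 WAP (1-9 scale), and ear weight plus grain moisture
#' from which grain yield is recovered by [grain_yield()]. All traits share
#' one field layout and one marker panel; per-trait variance components are
#' fixed at the magnitudes typical of such trials (counts get large
#' variances, ratings small ones). Nuisance variances (environment,
#' replicate, block) are scaled per trait in proportion to its error
#' variance so every trait has a comparable design signal-to-noise.
#'
#' @param config a [sim_config()]; its size/seed fields drive everything,
#'   its variance fields are overridden per trait as described.
#' @param plot_area plot area in square metres used to back out ear weight.
#' @return List with `phenotypes` (plot-level data frame), `markers`, and
#'   `truth` (per-trait `synthetic_truth` objects).
#' @export
simulate_striga_dataset <- function(config = sim_config(), plot_area = 3) {
  stopifnot(inherits(config, "sim_config"))
  markers <- simulate_markers(config)
  design <- make_trial_design(config)
  specs <- list(
    str8wap  = list(vg = 9.24,   vgxe = 9.94,  ve = 72.39,  mu = 8,   kind = "count"),
    str10wap = list(vg = 80.02,  vgxe = 22.65, ve = 322.99, mu = 27,  kind = "count"),
    str12wap = list(vg = 181.61, vgxe = 32.99, ve = 520.38, mu = 39,  kind = "count"),
    sdr1     = list(vg = 0.12,   vgxe = 0.05,  ve = 0.57,   mu = 2.1, kind = "gaussian"),
    sdr2     = list(vg = 0.13,   vgxe = 0.06,  ve = 0.68,   mu = 2.6, kind = "gaussian"),
    gy       = list(vg = 0.40,   vgxe = 0.22,  ve = 1.61,   mu = 4.5, kind = "gaussian"))
  phen <- design
  truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    cfg <- config
    scale_nuis <- sp$ve / config$var_error
    cfg$var_genetic <- sp$vg
    cfg$var_gxe <- sp$vgxe
    cfg$var_error <- sp$ve
    cfg$var_env <- config$var_env * scale_nuis
    cfg$var_replicate <- config$var_replicate * scale_nuis
    cfg$var_block <- config$var_block * scale_nuis
    cfg$mu <- sp$mu
    cfg$trait_kind <- sp$kind
    cfg$seed <- config$seed + 100L * i
    sim <- simulate_trial(cfg, markers, design)
    phen[[names(specs)[i]]] <- sim$plots$y
    truth[[names(specs)[i]]] <- sim$truth
  }
  phen$sdr1 <- pmin(9, pmax(1, phen$sdr1))
  phen$sdr2 <- pmin(9, pmax(1, phen$sdr2))
  phen$moisture <- 12.5
  phen$ear_weight <- pmax(0, phen$gy) * plot_area / (0.8 * 10)
  phen$gy <- NULL
  list(phenotypes = phen, markers = markers, truth = truth)
}
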