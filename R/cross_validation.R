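#' Build CV0 / CV1 / CV2 cross-validation partitions
#'
#' * **CV0** (leave-one-environment-out): one fold per environment, masking
#'   that environment for every line — prediction of tested lines in an
#'   untested environment. `n_folds` is ignored.
#' * **CV1** (untested lines): each fold samples
#'   `floor(test_fraction * n_lines)` lines without replacement and masks
#'   all their cells.
#' * **CV2** (sparse testing): each fold masks
#'   `floor(test_fraction * n_cells)` line-by-environment cells uniformly,
#'   repaired so every line keeps at least one observed environment.
#'
#' @param scheme one of `"CV0"`, `"CV1"`, `"CV2"`.
#' @param lines character vector of phenotyped line IDs.
#' @param environments character vector of environment IDs.
#' @param n_folds folds for CV1/CV2 (the study convention is 50).
#' @param test_fraction fraction of lines (CV1) or cells (CV2) masked per
#'   fold.
#' @param seed seed controlling the whole partition sequence.
#' @return List of `cv_partition` objects, each holding `scheme`, `fold`
#'   and a `cells` data frame of masked `(line, env)` pairs.
#' @export
make_partitions <- function(scheme = c("CV0", "CV1", "CV2"), lines,
                            environments, n_folds = 50, test_fraction = 0.2,
                            seed = 1L) {
  scheme <- match.arg(scheme)
  lines <- as.character(lines)
  environments <- as.character(environments)
  L <- length(lines)
  E <- length(environments)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  if (scheme != "CV1" && E < 2)
    stop(scheme, " needs at least 2 environments")
  set.seed(seed)

  part <- function(fold, cells)
    structure(list(scheme = scheme, fold = fold, cells = cells, seed = seed),
              class = "cv_partition")

  if (scheme == "CV0") {
    return(lapply(seq_len(E), function(e)
      part(e, data.frame(line = lines, env = environments[e],
                         stringsAsFactors = FALSE))))
  }
  if (scheme == "CV1") {
    n_test <- floor(test_fraction * L)
    if (n_test < 1) stop("test_fraction leaves no test lines")
    return(lapply(seq_len(n_folds), function(f) {
      test <- sample(lines, n_test)
      part(f, expand.grid(line = test, env = environments,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
    }))
  }
  # CV2: uniform cell masking with the >= 1 observed environment guarantee
  n_cells <- L * E
  n_mask <- floor(test_fraction * n_cells)
  if (n_mask < 1) stop("test_fraction leaves no test cells")
  if (n_mask > n_cells - L)
    stop("test_fraction too large: every line must keep at least one ",
         "observed environment")
  line_of_cell <- rep(seq_len(L), E)
  env_of_cell <- rep(seq_len(E), each = L)
  lapply(seq_len(n_folds), function(f) {
    idx <- sample.int(n_cells, n_mask)
    repeat {
      per_line <- tabulate(line_of_cell[idx], L)
      viol <- which(per_line == E)
      if (!length(viol)) break
      for (ln in viol) {
        own <- idx[line_of_cell[idx] == ln]
        release <- own[sample.int(length(own), 1)]
        pool <- setdiff(seq_len(n_cells), idx)
        pool <- pool[per_line[line_of_cell[pool]] <= E - 2]
        replacement <- pool[sample.int(length(pool), 1)]
        idx <- c(setdiff(idx, release), replacement)
        per_line <- tabulate(line_of_cell[idx], L)
      }
    }
    part(f, data.frame(line = lines[line_of_cell[idx]],
                       env = environments[env_of_cell[idx]],
                       stringsAsFactors = FALSE))
  })
}

#' Run a cross-validation scheme over reaction-norm fits
#'
#' For every partition of the chosen scheme, refits the reaction-norm model
#' with the fold's cells held out, predicts them, and computes the Pearson
#' correlation between observed and predicted values per environment within
#' the fold. Fold-level correlations are then averaged per environment, and
#' combined into an across-environment accuracy weighted by the number of
#' held-out pairs.
#'
#' @param blues data frame `line`, `env`, `value` (the observed cell values).
#' @param grm relationship kernel over at least the phenotyped lines.
#' @param scheme `"CV0"`, `"CV1"` or `"CV2"`.
#' @param n_folds,test_fraction,seed partitioning controls
#'   ([make_partitions()]).
#' @param iterations,burn_in,thin sampler schedule passed to [fit_gibbs()]
#'   (the study convention is 30,000 / 15,000 / 10; scale down for quick
#'   runs).
#' @param fitter optional replacement fitter, a
#'   `function(design, seed)` returning predicted values for all design
#'   cells — used for oracle checks; `NULL` means [fit_gibbs()] +
#'   [predict_cells()].
#' @param min_pairs folds contribute an environment only when at least this
#'   many held-out pairs are available there (skipped with a warning below).
#' @param ... further arguments for [fit_gibbs()].
#' @return Object of class `cv_accuracy`: `per_environment` (mean fold
#'   correlation), `across` (weighted), `folds` (the per-fold log).
#' @export
run_cv <- function(blues, grm, scheme, n_folds = 50, test_fraction = 0.2,
                   seed = 1L, iterations = 30000, burn_in = 15000, thin = 10,
                   fitter = NULL, min_pairs = 3, ...) {
  envs <- sort(unique(as.character(blues$env)))
  cand <- sort(unique(as.character(blues$line)))
  parts <- make_partitions(scheme, cand, envs, n_folds = n_folds,
                           test_fraction = test_fraction, seed = seed)
  Gs <- (grm + t(grm)) / 2
  eig <- eigen(Gs, symmetric = TRUE)
  rows <- list()
  for (p in parts) {
    design <- build_design(blues, grm, masks = p$cells, eig = eig)
    fold_seed <- as.integer(seed + 7919L * p$fold)
    pred <- if (is.null(fitter)) {
      fit <- fit_gibbs(design, iterations = iterations, burn_in = burn_in,
                       thin = thin, seed = fold_seed, ...)
      predict_cells(fit, design)
    } else {
      fitter(design, fold_seed)
    }
    hold <- design$mask & !is.na(design$y_full)
    for (e in seq_along(design$envs)) {
      sel <- hold & design$env_of_row == e
      n_e <- sum(sel)
      if (n_e < min_pairs) {
        if (n_e > 0)
          warning("fold ", p$fold, ", environment ", design$envs[e],
                  ": only ", n_e, " held-out pair(s); skipped")
        next
      }
      o <- design$y_full[sel]
      pr <- pred[sel]
      r_e <- if (sd(o) == 0 || sd(pr) == 0) NA_real_ else cor(o, pr)
      rows[[length(rows) + 1L]] <-
        data.frame(fold = p$fold, env = design$envs[e], r = r_e, n = n_e,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no fold produced enough held-out pairs")
  log_df <- do.call(rbind, rows)
  per_env <- tapply(log_df$r, log_df$env, mean, na.rm = TRUE)
  n_env <- tapply(log_df$n, log_df$env, sum)
  across <- weighted_across_r(as.vector(per_env), as.vector(n_env))
  structure(list(scheme = scheme,
                 per_environment = setNames(as.vector(per_env), names(per_env)),
                 across = across, n_folds = length(parts), folds = log_df),
            class = "cv_accuracy")
}

#' Pair-count-weighted across-environment accuracy
#'
#' Convex combination of per-environment correlations with weights
#' proportional to the number of held-out pairs each environment
#' contributed.
#'
#' @param r per-environment correlations.
#' @param n weights (pair counts); equal weights by default.
#' @return Single weighted correlation; `NA` (with a warning) when no
#'   environment has a defined value.
#' @export
weighted_across_r <- function(r, n = rep(1, length(r))) {
  if (length(r) != length(n)) stop("r and n must have equal length")
  ok <- !is.na(r)
  if (!any(ok)) {
    warning("no defined per-environment accuracy")
    return(NA_real_)
  }
  if (any(!ok))
    warning("dropping ", sum(!ok), " environment(s) with undefined accuracy")
  sum(r[ok] * n[ok]) / sum(n[ok])
}

#' @export
print.cv_accuracy <- function(x, ...) {
  cat("Cross-validation accuracy (", x$scheme, ", ", x$n_folds, " folds)\n",
      sep = "")
  print(round(x$per_environment, 3))
  cat("Across environments (weighted r):", round(x$across, 3), "\n")
  invisible(x)
}
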