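#' Quality-control dominant presence/absence markers
#'
#' Drops monomorphic markers (zero variance) and markers whose minor-class
#' frequency falls below `maf_threshold`. For dominant markers the two
#' presence/absence classes play the allele roles, so MAF is
#' `min(freq(1), freq(0))` computed over non-missing calls. Column order of
#' surviving markers is preserved; the filter is idempotent.
#'
#' @param markers lines x markers matrix with entries in \{0, 1, NA\}.
#' @param maf_threshold minimum minor-class frequency (default 0.05).
#' @return The filtered marker matrix. A warning is raised (and a zero-column
#'   matrix returned) if nothing survives.
#' @export
qc_markers <- function(markers, maf_threshold = 0.05) {
  .check_binary(markers)
  f1 <- colMeans(markers == 1, na.rm = TRUE)
  maf <- pmin(f1, 1 - f1)
  keep <- !is.na(maf) & maf >= maf_threshold & f1 > 0 & f1 < 1
  out <- markers[, keep, drop = FALSE]
  if (ncol(out) == 0)
    warning("no markers survived quality control")
  out
}

#' Mean-impute missing marker calls
#'
#' Replaces missing calls by the per-marker presence frequency. This is
#' variance-neutral under column standardization and is the only imputation
#' step the downstream relationship matrix assumes.
#'
#' @param markers lines x markers matrix with entries in \{0, 1, NA\}.
#' @return Numeric matrix without missing values.
#' @export
impute_markers <- function(markers) {
  .check_binary(markers)
  out <- markers * 1.0
  if (anyNA(out)) {
    cm <- colMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    if (any(is.nan(cm[idx[, 2]])))
      stop("marker column(s) with all calls missing cannot be imputed")
    out[idx] <- cm[idx[, 2]]
  }
  out
}

#' Center and standardize markers by column
#'
#' Each marker column is centered to mean 0 and scaled to variance 1 using
#' the population (divide-by-n) variance, the convention under which the
#' relationship matrix of [compute_grm()] has mean diagonal exactly 1.
#'
#' @param markers numeric lines x markers matrix, every column polymorphic,
#'   no missing values (run [qc_markers()] and [impute_markers()] first).
#' @return Real-valued matrix with column means 0 and variances 1.
#' @export
standardize_markers <- function(markers) {
  if (anyNA(markers))
    stop("missing calls present; run impute_markers() first")
  markers <- markers * 1.0
  mu <- colMeans(markers)
  v <- colMeans(markers^2) - mu^2
  if (any(v <= 0))
    stop("zero-variance marker column(s); run qc_markers() first")
  sweep(sweep(markers, 2, mu), 2, sqrt(v), "/")
}

#' Genomic relationship matrix from standardized markers
#'
#' Computes the VanRaden-style relationship kernel `G = S %*% t(S) / p`
#' where `S` is the column-standardized marker matrix and `p` the number of
#' markers. Under population-variance standardization the mean diagonal is
#' exactly 1; `G` is symmetric positive semidefinite by construction.
#'
#' @param markers QCed marker matrix (0/1 with missing calls imputed, or any
#'   numeric matrix with polymorphic columns).
#' @return `n x n` kernel with line IDs as dimnames and attribute
#'   `n_markers`.
#' @export
compute_grm <- function(markers) {
  if (ncol(markers) == 0) stop("no markers to build a relationship matrix from")
  if (anyDuplicated(rownames(markers)))
    stop("duplicate line IDs in marker matrix")
  S <- standardize_markers(markers)
  G <- tcrossprod(S) / ncol(S)
  dimnames(G) <- list(rownames(markers), rownames(markers))
  attr(G, "n_markers") <- ncol(S)
  G
}

.check_binary <- function(markers) {
  if (!is.matrix(markers)) stop("markers must be a matrix")
  vals <- markers[!is.na(markers)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("marker entries must be 0, 1 or NA")
  invisible(TRUE)
}
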