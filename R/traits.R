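#' Area under the Striga number progress curve
#'
#' Trapezoid-rule integral of emerged parasite counts over time, the same
#' construction as the area under the disease progress curve: the sum over
#' consecutive observation pairs of mean count times interval width.
#'
#' @param times observation times in days after planting, strictly increasing.
#' @param counts emerged *Striga* plant counts, nonnegative, same length.
#' @return The area, in count-days.
#' @examples
#' ausnpc(c(56, 70, 84), c(8, 27, 39))  # 707
#' @export
ausnpc <- function(times, counts) {
  if (length(times) != length(counts))
    stop("times and counts must have equal length")
  if (length(times) < 2)
    stop("insufficient data: at least 2 time points are required")
  if (anyNA(times) || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be nonnegative")
  sum((counts[-1] + counts[-length(counts)]) / 2 * diff(times))
}

#' Average Striga damage rating
#'
#' Arithmetic mean of the two damage ratings taken at 10 and 12 weeks after
#' planting on the 1 (healthy) to 9 (severely damaged) scale.
#'
#' @param sdr1,sdr2 ratings in \[1, 9\] (vectorized; `NA` allowed and
#'   propagated).
#' @return Mean rating.
#' @export
average_sdr <- function(sdr1, sdr2) {
  out_of_scale <- function(x) any(!is.na(x) & (x < 1 | x > 9))
  if (out_of_scale(sdr1) || out_of_scale(sdr2))
    stop("damage ratings must lie on the 1-9 scale")
  (sdr1 + sdr2) / 2
}

#' Grain yield from ear weight
#'
#' Converts plot ear weight to grain yield in t/ha assuming a fixed shelling
#' percentage and adjusting to a standard grain moisture content:
#' `ear_weight * shelling * (100 - moisture) / (100 - target_moisture) *
#' (10000 / plot_area) / 1000`.
#'
#' @param ear_weight ear weight per plot in kg (vectorized).
#' @param moisture percent grain moisture at harvest, in \[0, 100).
#' @param plot_area plot area in square metres (default 4 m row x 0.75 m
#'   spacing = 3 m^2).
#' @param shelling_fraction grain fraction of ear weight (default 0.80).
#' @param target_moisture standard moisture percentage (default 12.5).
#' @return Grain yield in t/ha.
#' @examples
#' grain_yield(2.0, 12.5)  # 5.333 t/ha on a 3 m^2 plot
#' @export
grain_yield <- function(ear_weight, moisture, plot_area = 3,
                        shelling_fraction = 0.8, target_moisture = 12.5) {
  if (any(!is.na(ear_weight) & ear_weight < 0))
    stop("ear_weight must be nonnegative")
  if (any(!is.na(moisture) & (moisture < 0 | moisture >= 100)))
    stop("moisture must lie in [0, 100)")
  if (plot_area <= 0) stop("plot_area must be positive")
  if (target_moisture < 0 || target_moisture >= 100)
    stop("target_moisture must lie in [0, 100)")
  ear_weight * shelling_fraction * (100 - moisture) / (100 - target_moisture) *
    (10000 / plot_area) / 1000
}

#' Add derived trait columns to a phenotype table
#'
#' Computes AUSNPC from the emerged-count columns (weeks after planting are
#' converted to days at 7 days/week), the average damage rating SDR, and
#' grain yield GY from ear weight and moisture. Columns that are absent are
#' skipped silently, so partial tables are fine.
#'
#' @param phenotypes plot-level data frame.
#' @param count_cols names of the emerged *Striga* count columns, in time
#'   order.
#' @param wap weeks after planting matching `count_cols`.
#' @param days_per_week conversion used to put `wap` on the day scale.
#' @param sdr_cols names of the two damage-rating columns.
#' @param ear_weight_col,moisture_col columns feeding [grain_yield()].
#' @param plot_area plot area in m^2 for the yield conversion.
#' @return `phenotypes` with `ausnpc`, `sdr` and `gy` columns appended where
#'   their inputs exist.
#' @export
derive_traits <- function(phenotypes,
                          count_cols = c("str8wap", "str10wap", "str12wap"),
                          wap = c(8, 10, 12), days_per_week = 7,
                          sdr_cols = c("sdr1", "sdr2"),
                          ear_weight_col = "ear_weight",
                          moisture_col = "moisture",
                          plot_area = 3) {
  stopifnot(is.data.frame(phenotypes), length(count_cols) == length(wap))
  if (all(count_cols %in% names(phenotypes))) {
    times <- wap * days_per_week
    if (any(diff(times) <= 0)) stop("wap must be strictly increasing")
    Y <- as.matrix(phenotypes[count_cols])
    k <- ncol(Y)
    phenotypes$ausnpc <- as.vector(((Y[, -1, drop = FALSE] +
                                     Y[, -k, drop = FALSE]) / 2) %*% diff(times))
  }
  if (all(sdr_cols %in% names(phenotypes))) {
    phenotypes$sdr <- average_sdr(phenotypes[[sdr_cols[1]]],
                                  phenotypes[[sdr_cols[2]]])
  }
  if (all(c(ear_weight_col, moisture_col) %in% names(phenotypes))) {
    phenotypes$gy <- grain_yield(phenotypes[[ear_weight_col]],
                                 phenotypes[[moisture_col]],
                                 plot_area = plot_area)
  }
  phenotypes
}
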