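#' Default synonymous substitution rate for Brassicaceae
#'
#' Synonymous substitutions per site per year used to convert Ks into
#' absolute divergence times.
#' @export
BRASSICACEAE_MU <- 6.51648e-9

# half-up rounding to `digits` decimals (round() rounds half to even)
.round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Date a divergence event from a Ks peak
#'
#' Applies the molecular-clock formula T (years) = Ks / (2 * mu), where mu
#' is the synonymous substitution rate per site per year. The factor 2
#' accounts for substitutions accumulating on both lineages since the
#' split.
#'
#' @param ks Synonymous divergence (peak or median of a Ks distribution);
#'   must be >= 0.
#' @param mu Rate in substitutions/site/year (default [BRASSICACEAE_MU]).
#' @return List with `ks_used`, `mu`, `T_years`, `T_mya` (= T_years/1e6)
#'   and `T_mya_rounded` (half-up to 1 decimal, for display).
#' @examples
#' date_from_ks(0.102)$T_mya_rounded # 7.8
#' date_from_ks(0.073)$T_mya_rounded # 5.6
#' @export
date_from_ks <- function(ks, mu = BRASSICACEAE_MU) {
  if (any(ks < 0)) stop("'ks' must be >= 0")
  if (any(mu <= 0)) stop("'mu' must be > 0")
  T_years <- ks / (2 * mu)
  list(ks_used = ks, mu = mu, T_years = T_years, T_mya = T_years / 1e6,
       T_mya_rounded = .round_half_up(T_years / 1e6, 1L))
}

#' Locate the peak of a Ks distribution
#'
#' `median` (the default) returns the sample median; `kde_mode` returns the
#' argmax of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) evaluated on `[0, 0.75]`. Non-finite values are dropped.
#'
#' @param ks_values Numeric vector of Ks estimates (typically ok-flagged
#'   records only).
#' @param method `"median"` or `"kde_mode"`.
#' @return The peak estimate (single numeric).
#' @export
ks_peak <- function(ks_values, method = c("median", "kde_mode")) {
  method <- match.arg(method)
  x <- ks_values[is.finite(ks_values)]
  if (length(x) == 0L) stop("no finite Ks values")
  if (method == "median") return(stats::median(x))
  if (length(x) == 1L) return(x)
  d <- stats::density(x, bw = "nrd0", from = 0, to = 0.75, n = 2048L)
  d$x[which.max(d$y)]
}
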