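#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' Linear-quadratic conversion of a total dose delivered in `n_fractions`
#' equal fractions to the isoeffective dose in 2-Gy fractions:
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)` with `d = D/n_fractions`.
#' Vectorised over `total_dose`, so it applies per DVH bin dose.
#'
#' @param total_dose total physical dose D, Gy (scalar or vector).
#' @param n_fractions number of fractions the dose is split into.
#' @param alpha_beta tissue alpha/beta ratio, Gy.
#' @return EQD2 in Gy, same shape as `total_dose`.
#' @examples
#' eqd2(50, 25, 4)   # 2 Gy/fraction is its own EQD2: 50
#' eqd2(60, 25, 3)   # 64.8
#' @export
eqd2 <- function(total_dose, n_fractions, alpha_beta) {
  if (!is.numeric(n_fractions) || n_fractions < 1) {
    stop("n_fractions must be >= 1")
  }
  if (alpha_beta <= 0) stop("alpha_beta must be > 0 Gy")
  if (any(total_dose < 0)) stop("total_dose must be >= 0")
  d <- total_dose / n_fractions
  total_dose * (d + alpha_beta) / (2 + alpha_beta)
}

#' Convert a physical-dose DVH to the EQD2 domain
#'
#' Applies [eqd2()] to every bin edge; the conversion is strictly monotone
#' in dose, so cumulative volumes are unchanged.
#'
#' @param dvh a `dvh` of physical dose.
#' @inheritParams eqd2
#' @return A `dvh` with EQD2 bin edges (no longer uniformly spaced).
#' @export
dvh_eqd2 <- function(dvh, n_fractions, alpha_beta) {
  stopifnot(inherits(dvh, "dvh"))
  out <- dvh
  out$edges <- eqd2(dvh$edges, n_fractions, alpha_beta)
  out
}

#' TCP parameter set
#'
#' @param tcd50 dose giving 50% tumour control probability, Gy.
#' @param gamma normalised dose-response slope (dimensionless).
#' @param alpha_beta tumour alpha/beta ratio, Gy (used for EQD2 conversion).
#' @return An object of class `tcp_params`.
#' @export
tcp_params <- function(tcd50, gamma, alpha_beta) {
  stopifnot(tcd50 > 0, gamma > 0, alpha_beta > 0)
  structure(list(tcd50 = tcd50, gamma = gamma, alpha_beta = alpha_beta),
            class = "tcp_params")
}

#' NTCP (LKB) parameter set
#'
#' @param td50 uniform dose giving 50% complication probability, Gy.
#' @param m slope parameter (dimensionless).
#' @param n volume-effect exponent, in (0, 1].
#' @param alpha_beta organ alpha/beta ratio, Gy.
#' @param endpoint clinical endpoint label.
#' @return An object of class `ntcp_params`.
#' @export
ntcp_params <- function(td50, m, n, alpha_beta, endpoint = NA_character_) {
  stopifnot(td50 > 0, m > 0, n > 0, n <= 1, alpha_beta > 0)
  structure(list(td50 = td50, m = m, n = n, alpha_beta = alpha_beta,
                 endpoint = endpoint),
            class = "ntcp_params")
}

#' Default radiobiological parameter registry
#'
#' Ships the parameter set used for the reference scenario: PTV tumour
#' control from a multi-centre adjuvant-radiotherapy dose-response model
#' (TCD50 = 39.3 Gy, gamma = 1.7, alpha/beta = 4 Gy, applied to both PTVsc
#' and PTVcw); heart pericarditis (TD50 = 48 Gy, m = 0.1, n = 0.35,
#' alpha/beta = 3 Gy); ipsilateral lung pneumonitis (TD50 = 30.8 Gy,
#' m = 0.18, n = 0.87, alpha/beta = 3 Gy).
#'
#' @return Named list with elements `tcp` (per target) and `ntcp` (per OAR).
#' @export
default_radiobio_params <- function() {
  ptv <- tcp_params(tcd50 = 39.3, gamma = 1.7, alpha_beta = 4)
  list(
    tcp = list(PTVsc = ptv, PTVcw = ptv),
    ntcp = list(
      heart = ntcp_params(td50 = 48, m = 0.1, n = 0.35, alpha_beta = 3,
                          endpoint = "pericarditis"),
      lung_ipsi = ntcp_params(td50 = 30.8, m = 0.18, n = 0.87, alpha_beta = 3,
                              endpoint = "pneumonitis")
    )
  )
}

# normalise (dose, volume) input: either a dvh (differential bins) or a
# numeric dose vector with optional volume weights summing to 1
as_dose_bins <- function(x, volume = NULL) {
  if (inherits(x, "dvh")) {
    dvh_differential(x)
  } else {
    dose <- as.numeric(x)
    if (is.null(volume)) volume <- rep(1 / length(dose), length(dose))
    if (length(volume) != length(dose)) stop("dose and volume lengths differ")
    if (any(volume < 0) || abs(sum(volume) - 1) > 1e-6) {
      stop("volumes must be nonnegative and sum to 1")
    }
    list(dose = dose, volume = volume)
  }
}

#' Poisson linear-quadratic tumour control probability
#'
#' Per-bin response in the Kallman (TCD50, gamma) parameterisation,
#' `P(D) = 2^(-exp(e * gamma * (1 - D/TCD50)))` with `e` Euler's number,
#' combined over a heterogeneous dose distribution as the volume-weighted
#' product `TCP = prod_i P(D_i)^(v_i)` (uniform clonogen density). Doses are
#' expected in the EQD2 domain.
#'
#' @param x a `dvh` in the EQD2 domain, or a numeric vector of EQD2 doses.
#' @param params a [tcp_params()].
#' @param volume optional fractional volumes for numeric `x` (sum to 1);
#'   defaults to equal weights.
#' @return TCP in \[0, 1\].
#' @examples
#' poisson_tcp(39.3, tcp_params(39.3, 1.7, 4))  # 0.5 at TCD50 by definition
#' @export
poisson_tcp <- function(x, params, volume = NULL) {
  stopifnot(inherits(params, "tcp_params"))
  bins <- as_dose_bins(x, volume)
  # log2 P(D) = -exp(e*gamma*(1 - D/TCD50)); cap the exponent so doses far
  # below TCD50 underflow to TCP = 0 instead of overflowing
  z <- pmin(exp(1) * params$gamma * (1 - bins$dose / params$tcd50), 700)
  log_tcp <- -log(2) * sum(bins$volume * exp(z))
  exp(log_tcp)
}

#' Generalised equivalent uniform dose (gEUD)
#'
#' Power mean `gEUD = (sum_i v_i D_i^(1/n))^n` over differential DVH bins;
#' `n = 1` gives the arithmetic mean, `n -> 0` approaches the maximum dose.
#'
#' @param x a `dvh` (typically in the EQD2 domain) or numeric dose vector.
#' @param n volume-effect exponent in (0, 1].
#' @param volume optional fractional volumes for numeric `x`.
#' @return gEUD in Gy.
#' @export
geud <- function(x, n, volume = NULL) {
  if (!is.numeric(n) || n <= 0 || n > 1) stop("n must be in (0, 1]")
  bins <- as_dose_bins(x, volume)
  m <- max(bins$dose)
  if (m == 0) return(0)
  # scale by the max dose so D^(1/n) cannot overflow for small n
  m * sum(bins$volume * (bins$dose / m)^(1 / n))^n
}

#' Lyman-Kutcher-Burman NTCP
#'
#' Probit dose-response on the gEUD: `t = (gEUD - TD50) / (m * TD50)`,
#' `NTCP = pnorm(t)`. Doses are expected in the EQD2 domain.
#'
#' @param x a `dvh` in the EQD2 domain, or numeric EQD2 dose vector.
#' @param params an [ntcp_params()].
#' @param volume optional fractional volumes for numeric `x`.
#' @return NTCP in \[0, 1\].
#' @examples
#' lkb_ntcp(48, ntcp_params(48, 0.1, 0.35, 3))  # 0.5 at TD50
#' @export
lkb_ntcp <- function(x, params, volume = NULL) {
  stopifnot(inherits(params, "ntcp_params"))
  g <- geud(x, params$n, volume)
  stats::pnorm((g - params$td50) / (params$m * params$td50))
}
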