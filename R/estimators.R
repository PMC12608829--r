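#' Convert the normalized maximum rate to an absolute V_max
#'
#' The normalized rate kbar_V = V_max / k_S becomes an absolute maximum
#' reaction rate once the substrate transport rate constant is known. With
#' layer geometry, `k_S = D / (l * t)`; for the urea presets
#' (D = 9.3e-5 cm^2/s, l = 1 cm, t = 1e-7 cm) k_S = 930 1/s, so the PBS fit
#' kbar_V = 2.2e-4 M gives V_max ~= 0.20 M/(L s).
#'
#' @param kbar_V Normalized maximum rate, mol/L (>= 0).
#' @param transport A [transport_model()] carrying `k_S` or the geometry to
#'   derive it.
#'
#' @return V_max in mol/(L s).
#' @export
#' @examples
#' tr <- transport_model(D = 9.3e-5, l = 1, t = 1e-7)
#' vmax_from_normalized(2.2e-4, tr)  # ~0.20
vmax_from_normalized <- function(kbar_V, transport) {
  stopifnot(inherits(transport, "transport_model"),
            is.numeric(kbar_V), kbar_V >= 0)
  k_S <- transport$k_S
  if (is.null(k_S)) {
    stop("transport model has no k_S and no geometry to derive it from")
  }
  kbar_V * k_S
}

.check_rate_points <- function(S, v) {
  if (!is.numeric(S) || !is.numeric(v) || length(S) != length(v)) {
    stop("S and v must be numeric vectors of equal length")
  }
  if (any(!is.finite(S)) || any(!is.finite(v)) || any(S <= 0) || any(v <= 0)) {
    stop("linearization needs strictly positive, finite S and v")
  }
  if (length(unique(S)) < 2L) stop("need at least 2 distinct S values")
}

#' Classical linearization estimators of (V_max, K_M)
#'
#' Straight-line transforms of the Michaelis-Menten law
#' `v = V_max S / (K_M + S)` fitted by unweighted ordinary least squares:
#' \describe{
#'   \item{Lineweaver-Burk}{`1/v` on `1/S`; intercept `1/V_max`, slope
#'     `K_M/V_max`.}
#'   \item{Eadie-Hofstee}{`v` on `v/S`; intercept `V_max`, slope `-K_M`.}
#'   \item{Hanes-Woolf}{`S/v` on `S`; slope `1/V_max`, intercept
#'     `K_M/V_max`.}
#' }
#' All three are exact on noise-free rate-law data and are intended as
#' qualitative cross-checks of the nonlinear fit, not as headline estimators.
#'
#' @param S Substrate concentrations, mol/L (> 0).
#' @param v Reaction rates, mol/(L s) (> 0).
#'
#' @return List with `V_max`, `K_M` and `method`.
#' @export
#' @examples
#' S <- c(1, 2, 5, 10, 20) * 1e-3
#' v <- 1e-3 * S / (5e-3 + S)
#' lineweaver_burk(S, v)  # V_max = 1e-3, K_M = 5e-3
lineweaver_burk <- function(S, v) {
  .check_rate_points(S, v)
  co <- stats::coef(stats::lm(I(1 / v) ~ I(1 / S)))
  if (any(!is.finite(co))) stop("singular design in Lineweaver-Burk fit")
  list(V_max = unname(1 / co[1]), K_M = unname(co[2] / co[1]),
       method = "Lineweaver-Burk")
}

#' @rdname lineweaver_burk
#' @export
eadie_hofstee <- function(S, v) {
  .check_rate_points(S, v)
  co <- stats::coef(stats::lm(v ~ I(v / S)))
  if (any(!is.finite(co))) stop("singular design in Eadie-Hofstee fit")
  list(V_max = unname(co[1]), K_M = unname(-co[2]),
       method = "Eadie-Hofstee")
}

#' @rdname lineweaver_burk
#' @export
hanes_woolf <- function(S, v) {
  .check_rate_points(S, v)
  co <- stats::coef(stats::lm(I(S / v) ~ S))
  if (any(!is.finite(co))) stop("singular design in Hanes-Woolf fit")
  list(V_max = unname(1 / co[2]), K_M = unname(co[1] / co[2]),
       method = "Hanes-Woolf")
}

#' Model reaction rates from fitted parameters
#'
#' Bridges the implicit-balance fit to the graphical estimators: for each bulk
#' concentration the layer substrate concentration comes from
#' [steady_state_substrate()], and the rate is
#' `v(S) = V_max S / (K_M + S)` with V_max from [vmax_from_normalized()].
#' Feeding the output into any of the three linearizations returns the
#' generating (V_max, K_M) to machine precision.
#'
#' @param params A [kinetic_parameters()].
#' @param transport A [transport_model()] with `k_S` available.
#' @param S_B_grid Bulk substrate concentrations, mol/L; zero values are
#'   dropped with a message (the linearization transforms divide by S and v).
#'
#' @return Data frame with columns `S` (layer concentration, mol/L) and `v`
#'   (rate, mol/(L s)).
#' @export
rates_from_fit <- function(params, transport, S_B_grid) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(S_B_grid == 0)) {
    message("dropping ", sum(S_B_grid == 0),
            " zero-concentration point(s): linearization transforms are ",
            "undefined at S = 0")
    S_B_grid <- S_B_grid[S_B_grid != 0]
  }
  if (!length(S_B_grid)) stop("no positive grid points left")
  V_max <- vmax_from_normalized(params$kbar_V, transport)
  S <- steady_state_substrate(S_B_grid, params)
  data.frame(S = S, v = V_max * S / (params$K_M + S))
}
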