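#' Steady-state substrate concentration in the enzyme layer
#'
#' Under the steady-state approximation the substrate balance
#' `k_S S_B - k_S S - Vmax S / (K_M + S) = 0` is a quadratic in S whose
#' physical (non-negative) root is
#' `S = (S_B - kbar_V - K_M + sqrt((K_M + kbar_V - S_B)^2 + 4 K_M S_B)) / 2`,
#' with all quantities normalized by k_S so that kbar_V = Vmax / k_S has
#' concentration units.
#'
#' @param S_B Bulk substrate concentration(s), mol/L (>= 0). Vectorized.
#' @param params A [kinetic_parameters()].
#'
#' @return Layer substrate concentration(s) S, mol/L, with 0 <= S <= S_B.
#' @export
#' @examples
#' p <- kinetic_parameters(K_M = 10e-3, kbar_V = 1e-3)
#' steady_state_substrate(10e-3, p)  # ~9.5125e-3
steady_state_substrate <- function(S_B, params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (!is.numeric(S_B) || any(!is.finite(S_B))) {
    stop("S_B must be finite numeric")
  }
  if (any(S_B < 0)) stop("S_B must be non-negative")
  K_M <- params$K_M
  kv <- params$kbar_V
  b <- K_M + kv - S_B
  sq <- sqrt(b^2 + 4 * K_M * S_B)
  # the two algebraically equal branches of the quadratic root; picking by
  # sign(b) avoids the subtractive cancellation that otherwise costs ~6
  # digits when K_M + kbar_V dominates S_B
  S <- ifelse(b <= 0, (sq - b) / 2, 2 * K_M * S_B / (b + sq))
  # guard against roundoff pushing the root infinitesimally below zero
  pmax(S, 0)
}

# Ha-dependence of the balance split into a part independent of the reaction
# rate and the reaction bracket, so grids over Ha reuse one evaluation:
#   F(Ha; S_B) = base(Ha) + R(S_B) * react(Ha)
# with R = kbar_V * S / (K_M + S).
.balance_parts <- function(Ha, chemistry) {
  b <- chemistry$buffer
  p <- chemistry$products
  kbar_H <- chemistry$transport$kbar_H
  H <- Ha * p$Ka_A
  w <- b$Ka_W / p$Ka_A
  bb <- p$Ka_B / p$Ka_A
  c0 <- 1 / (1 + b$Ka_W / b$H_B)
  base <- kbar_H * (b$H_B - H) +
    b$kbar_W * b$c_WB * (c0 - Ha / (Ha + w))
  react <- p$n_A / (1 + Ha) - p$n_B * Ha / (Ha + bb)
  list(base = base, react = react)
}

#' Implicit surface proton balance residual
#'
#' Evaluates the steady-state proton balance of the enzyme layer at a given
#' normalized proton concentration `Ha = H / Ka_A`:
#' `F = kbar_H (H_B - H) + kbar_W c_WB (1/(1 + Ka_W/H_B) - 1/(1 + Ka_W/H))
#'    + kbar_V S/(K_M + S) * (n_A/(1 + H/Ka_A) - n_B/(1 + Ka_B/H))`
#' where S is the steady-state layer substrate concentration for bulk `S_B`.
#' The surface proton concentration is the root F(Ha) = 0; F is strictly
#' decreasing in Ha for any valid chemistry, so that root is unique.
#'
#' @param Ha Normalized proton concentration(s), H / Ka_A (> 0). Vectorized;
#'   recycled against `S_B`.
#' @param S_B Bulk substrate concentration(s), mol/L (>= 0).
#' @param chemistry A [biosensor_chemistry()].
#' @param params A [kinetic_parameters()].
#'
#' @return Balance residual(s), mol/L-scaled.
#' @export
surface_balance_residual <- function(Ha, S_B, chemistry, params) {
  stopifnot(inherits(chemistry, "biosensor_chemistry"),
            inherits(params, "kinetic_parameters"))
  if (!is.numeric(Ha) || any(!is.finite(Ha)) || any(Ha <= 0)) {
    stop("Ha must be finite and strictly positive")
  }
  S <- steady_state_substrate(S_B, params)
  R <- params$kbar_V * S / (params$K_M + S)
  parts <- .balance_parts(Ha, chemistry)
  parts$base + R * parts$react
}

# Vectorized root solve over a vector of bulk concentrations.
# Brackets on a log10(Ha) grid spanning H in [1e-14, 1] mol/L, then refines
# all roots simultaneously by bisection in log10(Ha).
.solve_ha_vec <- function(S_B, chemistry, params, grid_n = 200,
                          tol_log10 = 1e-13) {
  Ka_A <- chemistry$products$Ka_A
  S <- steady_state_substrate(S_B, params)
  R <- params$kbar_V * S / (params$K_M + S)
  u <- seq(log10(1e-14 / Ka_A), log10(1 / Ka_A), length.out = grid_n)
  parts <- .balance_parts(10^u, chemistry)
  # grid_n x n residual matrix: one column per bulk concentration
  Fmat <- matrix(parts$base, nrow = grid_n, ncol = length(S_B)) +
    outer(parts$react, R)
  lo <- hi <- numeric(length(S_B))
  for (j in seq_along(S_B)) {
    fj <- Fmat[, j]
    hit <- which(fj == 0)
    if (length(hit)) {
      lo[j] <- hi[j] <- u[hit[1L]]
      next
    }
    sign_flip <- which(fj[-grid_n] * fj[-1L] < 0)
    if (length(sign_flip) == 0L) {
      stop(sprintf(paste0(
        "no sign change of the surface balance for S_B = %g M over H in ",
        "[1e-14, 1] M (endpoint residuals %.3e, %.3e); check the chemistry"),
        S_B[j], fj[1L], fj[grid_n]))
    }
    if (length(sign_flip) > 1L) {
      stop(sprintf(paste0(
        "multiple sign changes (%d) of the surface balance for S_B = %g M; ",
        "refusing to pick a root silently - check the chemistry"),
        length(sign_flip), S_B[j]))
    }
    lo[j] <- u[sign_flip]
    hi[j] <- u[sign_flip + 1L]
  }
  flo <- .balance_eval(10^lo, R, chemistry)
  while (max(hi - lo) > tol_log10) {
    mid <- (lo + hi) / 2
    fmid <- .balance_eval(10^mid, R, chemistry)
    take_lower <- flo * fmid <= 0
    hi <- ifelse(take_lower, mid, hi)
    lo <- ifelse(take_lower, lo, mid)
    flo <- ifelse(take_lower, flo, fmid)
  }
  Ha <- 10^((lo + hi) / 2)
  list(Ha = Ha, H = Ha * Ka_A, S = S, pH = -log10(Ha * Ka_A))
}

.balance_eval <- function(Ha, R, chemistry) {
  parts <- .balance_parts(Ha, chemistry)
  parts$base + R * parts$react
}

#' Solve the surface proton balance
#'
#' Finds the unique root of [surface_balance_residual()] with the surface
#' proton concentration H constrained to the physical range \[1e-14, 1\] mol/L
#' (pH 0-14). The root is bracketed on a 200-point logarithmic grid - zero or
#' multiple sign changes abort with a diagnostic - and refined by bisection in
#' log10 space to about 2e-13 relative precision.
#'
#' @inheritParams surface_balance_residual
#' @param S_B Bulk substrate concentration, mol/L (scalar, >= 0).
#' @param grid_n Number of bracketing grid points (default 200).
#'
#' @return An object of class `surface_state`: list with `S` (layer substrate,
#'   mol/L), `H` (surface proton concentration, mol/L), `Ha` (= H / Ka_A) and
#'   `pH_surface`.
#' @export
#' @examples
#' chem <- chem_preset("pbs_urea")
#' p <- kinetic_parameters(K_M = 10.88e-3, kbar_V = 2.2e-4)
#' solve_surface_H(10e-3, chem, p)$pH_surface  # alkaline shift above 7.4
solve_surface_H <- function(S_B, chemistry, params, grid_n = 200) {
  stopifnot(inherits(chemistry, "biosensor_chemistry"),
            inherits(params, "kinetic_parameters"),
            is.numeric(S_B), length(S_B) == 1L)
  if (!is.finite(S_B) || S_B < 0) stop("S_B must be finite and non-negative")
  sol <- .solve_ha_vec(S_B, chemistry, params, grid_n = grid_n)
  structure(list(S = sol$S, H = sol$H, Ha = sol$Ha,
                 pH_surface = sol$pH),
            class = "surface_state")
}

#' @export
print.surface_state <- function(x, ...) {
  cat(sprintf("<surface_state> pH = %.4f, H = %.4g M, S_layer = %.4g M\n",
              x$pH_surface, x$H, x$S))
  invisible(x)
}

# ascending-order polynomial product
.polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Quartic polynomial root oracle for the surface balance
#'
#' Clearing the three denominators of the surface balance (the buffer,
#' acid-product and base-product speciation terms) turns it into a
#' fourth-order polynomial in the normalized proton concentration Ha. This
#' function expands that polynomial (with the layer substrate concentration
#' fixed by [steady_state_substrate()]), finds all its roots by the
#' companion-matrix method, and returns the real positive roots that also
#' satisfy the unexpanded balance - multiplying through by the denominators
#' can introduce spurious roots at the pole locations, so each candidate is
#' re-checked against the original residual (accepted when the residual is
#' below 1e-8 times the largest additive term magnitude).
#'
#' Serves as an independent cross-check of [solve_surface_H()]; the bracketed
#' root must appear in the returned set.
#'
#' @inheritParams solve_surface_H
#' @return Sorted numeric vector of validated positive Ha roots.
#' @export
quartic_root_oracle <- function(S_B, chemistry, params) {
  stopifnot(inherits(chemistry, "biosensor_chemistry"),
            inherits(params, "kinetic_parameters"),
            is.numeric(S_B), length(S_B) == 1L)
  if (!is.finite(S_B) || S_B < 0) stop("S_B must be finite and non-negative")
  b <- chemistry$buffer
  p <- chemistry$products
  kbar_H <- chemistry$transport$kbar_H
  S <- steady_state_substrate(S_B, params)
  R <- params$kbar_V * S / (params$K_M + S)
  w <- b$Ka_W / p$Ka_A
  bb <- p$Ka_B / p$Ka_A
  c0 <- 1 / (1 + b$Ka_W / b$H_B)

  # F(Ha) * (Ha + w)(1 + Ha)(Ha + bb) as ascending coefficients
  pw <- c(w, 1); p1 <- c(1, 1); pb <- c(bb, 1)
  term1 <- .polymul(c(kbar_H * b$H_B, -kbar_H * p$Ka_A),
                    .polymul(pw, .polymul(p1, pb)))
  term2 <- .polymul(b$kbar_W * b$c_WB * c(c0 * w, c0 - 1), .polymul(p1, pb))
  pad <- function(x, n) c(x, numeric(n - length(x)))
  term3 <- R * (pad(p$n_A * .polymul(pw, pb), 4L) -
                  pad(p$n_B * .polymul(c(0, 1), .polymul(pw, p1)), 4L))
  coefs <- pad(term1, 5L) + pad(term2, 5L) + pad(term3, 5L)

  roots <- polyroot(coefs)
  re <- Re(roots)
  keep <- abs(Im(roots)) <= 1e-8 * pmax(abs(roots), 1e-300) & re > 0
  cand <- re[keep]
  if (!length(cand)) return(numeric(0))
  # spurious-root guard: validate against the unexpanded residual
  ok <- vapply(cand, function(ha) {
    parts <- .balance_parts(ha, chemistry)
    terms <- c(kbar_H * (b$H_B - ha * p$Ka_A),
               b$kbar_W * b$c_WB * (c0 - ha / (ha + w)),
               R * parts$react)
    scale <- max(abs(terms), kbar_H * b$H_B)
    abs(parts$base + R * parts$react) <= 1e-8 * scale
  }, logical(1))
  sort(unique(cand[ok]))
}

#' Model response curve: surface pH versus bulk substrate concentration
#'
#' Applies [solve_surface_H()] pointwise over a grid of bulk concentrations.
#' For the urea/urease presets (net proton consumption, n_B > n_A near neutral
#' pH) the predicted surface pH is non-decreasing in the bulk concentration.
#'
#' @param S_B_grid Bulk substrate concentrations, mol/L (>= 0, finite);
#'   output rows keep the input order, duplicates included.
#' @inheritParams solve_surface_H
#'
#' @return A data frame of class `response_curve` with columns `s_b`,
#'   `pH_surface`, `S_layer`, `H_surface` (all concentrations in mol/L).
#' @export
#' @examples
#' chem <- chem_preset("pbs_urea")
#' p <- kinetic_parameters(K_M = 10.88e-3, kbar_V = 2.2e-4)
#' response_curve(c(0, 1e-3, 1e-2, 5e-2), chem, p)
response_curve <- function(S_B_grid, chemistry, params, grid_n = 200) {
  if (!is.numeric(S_B_grid) || any(!is.finite(S_B_grid)) ||
      any(S_B_grid < 0)) {
    stop("S_B_grid values must be finite and non-negative")
  }
  sol <- .solve_ha_vec(S_B_grid, chemistry, params, grid_n = grid_n)
  structure(
    data.frame(s_b = S_B_grid, pH_surface = sol$pH,
               S_layer = sol$S, H_surface = sol$H),
    class = c("response_curve", "data.frame")
  )
}

#' Write a model response curve as CSV (mM units for concentrations)
#'
#' Columns: `s_b_mM`, `pH_surface`, `S_layer_mM`, `H_surface_M`.
#'
#' @param curve A [response_curve()] result.
#' @param path Output CSV path.
#' @export
write_response_curve <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  utils::write.csv(
    data.frame(s_b_mM = curve$s_b * 1e3, pH_surface = curve$pH_surface,
               S_layer_mM = curve$S_layer * 1e3,
               H_surface_M = curve$H_surface),
    path, row.names = FALSE)
  invisible(path)
}
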