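#' Bulk buffer system
#'
#' Describes the pH-buffering acid/base couple of the bulk medium: its total
#' concentration, acid dissociation constant, the bulk pH it holds, and the
#' normalized transport constant of the buffer species between bulk and enzyme
#' layer.
#'
#' @param c_WB Total buffer concentration, mol/L (>= 0).
#' @param pKa_W Buffer acid pKa (used unless `Ka_W` is given). Default 7.21,
#'   the dihydrogen/monohydrogen phosphate couple at 25 degrees C.
#' @param pH_B Bulk pH, in (0, 14).
#' @param kbar_W Normalized buffer transport constant (dimensionless, > 0).
#'   Default 1: buffer species are exchanged at the same rate as the substrate.
#' @param Ka_W Buffer acid dissociation constant, mol/L; overrides `pKa_W`.
#'
#' @return An object of class `buffer_system` with fields `c_WB`, `Ka_W`,
#'   `pH_B`, `kbar_W` and the derived bulk proton concentration `H_B`.
#' @export
#' @examples
#' buffer_system(c_WB = 3.3e-4, pH_B = 7.4)
buffer_system <- function(c_WB, pKa_W = 7.21, pH_B, kbar_W = 1, Ka_W = NULL) {
  if (is.null(Ka_W)) Ka_W <- 10^(-pKa_W)
  stopifnot(
    is.numeric(c_WB), length(c_WB) == 1L, is.finite(c_WB), c_WB >= 0,
    is.numeric(Ka_W), length(Ka_W) == 1L, is.finite(Ka_W), Ka_W > 0,
    is.numeric(pH_B), length(pH_B) == 1L, pH_B > 0, pH_B < 14,
    is.numeric(kbar_W), length(kbar_W) == 1L, kbar_W > 0
  )
  structure(
    list(c_WB = c_WB, Ka_W = Ka_W, pH_B = pH_B, kbar_W = kbar_W,
         H_B = 10^(-pH_B)),
    class = "buffer_system"
  )
}

#' Protolytic reaction products
#'
#' Stoichiometry and dissociation constants of the acid and base products of
#' the enzymatic reaction. For urea hydrolysis by urease the defaults describe
#' one carbonic acid/bicarbonate equivalent (n_A = 1, pKa 6.35) and two
#' ammonium/ammonia equivalents (n_B = 2, pKa 9.25) per urea converted.
#' Non-protolytic products and co-substrates carry no term in the proton
#' balance and are kept as documentation fields only.
#'
#' @param n_A Stoichiometric coefficient of the protolytic acid product (>= 0).
#' @param pKa_A Acid-product pKa; default 6.35 (H2CO3/HCO3-).
#' @param n_B Stoichiometric coefficient of the protolytic base product (>= 0).
#' @param pKa_B Base-product pKa; default 9.25 (NH4+/NH3).
#' @param Ka_A,Ka_B Dissociation constants in mol/L; override the pKa values.
#' @param n_Z,n_X Stoichiometry of the non-protolytic product and co-substrate
#'   (documentation only; urea hydrolysis consumes 3 H2O).
#'
#' @return An object of class `product_system`.
#' @export
product_system <- function(n_A = 1, pKa_A = 6.35, n_B = 2, pKa_B = 9.25,
                           Ka_A = NULL, Ka_B = NULL, n_Z = 0, n_X = 3) {
  if (is.null(Ka_A)) Ka_A <- 10^(-pKa_A)
  if (is.null(Ka_B)) Ka_B <- 10^(-pKa_B)
  stopifnot(
    is.numeric(n_A), n_A >= 0, is.numeric(n_B), n_B >= 0,
    n_A + n_B > 0,
    is.numeric(Ka_A), Ka_A > 0, is.numeric(Ka_B), Ka_B > 0
  )
  structure(
    list(n_A = n_A, Ka_A = Ka_A, n_B = n_B, Ka_B = Ka_B,
         n_Z = n_Z, n_X = n_X),
    class = "product_system"
  )
}

#' Transport model
#'
#' Normalized proton transport constant and, optionally, the absolute substrate
#' transport rate constant `k_S`, needed only to convert the normalized maximum
#' rate into an absolute V_max. When layer geometry is supplied, `k_S` is
#' derived as `D / (l * t)`.
#'
#' @param kbar_H Normalized proton transport constant (> 0, default 1).
#' @param k_S Substrate transport rate constant, 1/s (optional).
#' @param D Substrate diffusion constant, cm^2/s (optional).
#' @param l Active layer length, cm (optional).
#' @param t Active layer thickness, cm (optional).
#'
#' @return An object of class `transport_model`.
#' @export
#' @examples
#' transport_model(D = 9.3e-5, l = 1, t = 1e-7)  # k_S = 930 1/s
transport_model <- function(kbar_H = 1, k_S = NULL, D = NULL, l = NULL,
                            t = NULL) {
  stopifnot(is.numeric(kbar_H), length(kbar_H) == 1L, kbar_H > 0)
  if (is.null(k_S) && !is.null(D) && !is.null(l) && !is.null(t)) {
    if (!all(c(D, l, t) > 0)) {
      stop("layer dimensions and diffusion constant must be positive")
    }
    k_S <- D / (l * t)
  }
  if (!is.null(k_S) && !(is.finite(k_S) && k_S > 0)) {
    stop("k_S must be positive and finite")
  }
  structure(list(kbar_H = kbar_H, k_S = k_S, D = D, l = l, t = t),
            class = "transport_model")
}

#' Kinetic parameters
#'
#' The two quantities recovered by fitting: the apparent Michaelis-Menten
#' constant K_M and the normalized maximum rate kbar_V = V_max / k_S. Both are
#' concentrations in mol/L; fitted values always lie inside the optimizer box
#' \[1e-14, 1\] mol/L.
#'
#' @param K_M Michaelis-Menten constant, mol/L (> 0).
#' @param kbar_V Normalized maximum rate, mol/L (> 0).
#'
#' @return An object of class `kinetic_parameters`.
#' @export
#' @examples
#' kinetic_parameters(K_M = 10.88e-3, kbar_V = 2.2e-4)
kinetic_parameters <- function(K_M, kbar_V) {
  stopifnot(
    is.numeric(K_M), length(K_M) == 1L, is.finite(K_M), K_M > 0,
    is.numeric(kbar_V), length(kbar_V) == 1L, is.finite(kbar_V), kbar_V > 0
  )
  structure(list(K_M = K_M, kbar_V = kbar_V), class = "kinetic_parameters")
}

#' Assemble a full chemistry configuration
#'
#' @param buffer A [buffer_system()].
#' @param products A [product_system()].
#' @param transport A [transport_model()].
#'
#' @return An object of class `biosensor_chemistry`.
#' @export
biosensor_chemistry <- function(buffer, products,
                                transport = transport_model()) {
  stopifnot(inherits(buffer, "buffer_system"),
            inherits(products, "product_system"),
            inherits(transport, "transport_model"))
  structure(list(buffer = buffer, products = products, transport = transport),
            class = "biosensor_chemistry")
}

#' Built-in chemistry presets
#'
#' `pbs_urea`: urea/urease in 0.33 mM phosphate buffer at bulk pH 7.4, with
#' layer geometry l = 1 cm, t = 1e-7 cm and urea diffusion constant
#' D = 9.3e-5 cm^2/s (so k_S = 930 1/s). `au_urea`: the same reaction in an
#' artificial-urine-like matrix, modelled as an effective single-buffer medium
#' (c_WB = 2 mM, pH 7.4); the matrix effect on the enzyme is carried by the
#' fitted kbar_V, not by the buffer description.
#'
#' @param name One of `"pbs_urea"`, `"au_urea"`.
#' @return A [biosensor_chemistry()].
#' @export
#' @examples
#' chem_preset("pbs_urea")
chem_preset <- function(name = c("pbs_urea", "au_urea")) {
  name <- match.arg(name)
  c_WB <- switch(name, pbs_urea = 0.33e-3, au_urea = 2e-3)
  biosensor_chemistry(
    buffer = buffer_system(c_WB = c_WB, pKa_W = 7.21, pH_B = 7.4, kbar_W = 1),
    products = product_system(),
    transport = transport_model(kbar_H = 1, D = 9.3e-5, l = 1, t = 1e-7)
  )
}

#' Read / write a chemistry configuration (YAML)
#'
#' The file uses mM for the buffer concentration and pKa values for all
#' dissociation constants; everything is converted to mol/L on ingest.
#' Expected keys: `buffer{c_wb_mM, pKa_w, pH_bulk, kbar_w}`,
#' `products{n_a, pKa_a, n_b, pKa_b}`,
#' `transport{kbar_h, D_cm2_s, l_cm, t_cm}`.
#'
#' @param path Path to a YAML file.
#' @return A [biosensor_chemistry()].
#' @export
read_chemistry <- function(path) {
  cfg <- yaml::read_yaml(path)
  b <- cfg$buffer
  p <- cfg$products
  tr <- cfg$transport
  if (is.null(b) || is.null(p)) {
    stop("chemistry file must contain 'buffer' and 'products' sections")
  }
  biosensor_chemistry(
    buffer = buffer_system(
      c_WB = b$c_wb_mM * 1e-3, pKa_W = b$pKa_w, pH_B = b$pH_bulk,
      kbar_W = if (is.null(b$kbar_w)) 1 else b$kbar_w
    ),
    products = product_system(
      n_A = p$n_a, pKa_A = p$pKa_a, n_B = p$n_b, pKa_B = p$pKa_b
    ),
    transport = transport_model(
      kbar_H = if (is.null(tr$kbar_h)) 1 else tr$kbar_h,
      D = tr$D_cm2_s, l = tr$l_cm, t = tr$t_cm
    )
  )
}

#' @rdname read_chemistry
#' @param chemistry A [biosensor_chemistry()] to serialize.
#' @export
write_chemistry <- function(chemistry, path) {
  stopifnot(inherits(chemistry, "biosensor_chemistry"))
  b <- chemistry$buffer; p <- chemistry$products; tr <- chemistry$transport
  yaml::write_yaml(list(
    buffer = list(c_wb_mM = b$c_WB * 1e3, pKa_w = -log10(b$Ka_W),
                  pH_bulk = b$pH_B, kbar_w = b$kbar_W),
    products = list(n_a = p$n_A, pKa_a = -log10(p$Ka_A),
                    n_b = p$n_B, pKa_b = -log10(p$Ka_B)),
    transport = list(kbar_h = tr$kbar_H, D_cm2_s = tr$D, l_cm = tr$l,
                     t_cm = tr$t)
  ), path)
  invisible(path)
}

#' @export
print.biosensor_chemistry <- function(x, ...) {
  b <- x$buffer; p <- x$products
  cat("<biosensor_chemistry>\n")
  cat(sprintf("  buffer:   c_WB = %.4g mM, pKa_W = %.2f, pH_B = %.2f, kbar_W = %g\n",
              b$c_WB * 1e3, -log10(b$Ka_W), b$pH_B, b$kbar_W))
  cat(sprintf("  products: n_A = %g (pKa %.2f), n_B = %g (pKa %.2f)\n",
              p$n_A, -log10(p$Ka_A), p$n_B, -log10(p$Ka_B)))
  cat(sprintf("  transport: kbar_H = %g, k_S = %s 1/s\n",
              x$transport$kbar_H,
              if (is.null(x$transport$k_S)) "unset" else
                format(x$transport$k_S)))
  invisible(x)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf("<kinetic_parameters> K_M = %.4g mM, kbar_V = %.4g M\n",
              x$K_M * 1e3, x$kbar_V))
  invisible(x)
}
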