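# Two-pore transcapillary exchange (Rippe-Haraldsson formalism).
#
# The capillary wall is modelled as a membrane with two cylindrical pore
# populations.  A solute of hydrodynamic radius r sees, in a pore of radius
# r_p, the ratio lambda = r/r_p; its equilibrium partition coefficient is
# Phi = (1-lambda)^2.  Convection is hindered by the reflection coefficient
# sigma(lambda), diffusion by the Renkin hindrance F(lambda).  Solute flux
# per pore class follows the Patlak convection-diffusion expression with
# Peclet number Pe = J_v(1-sigma)/PS.

#' Two-pore membrane parameters
#'
#' @param small_pore_radius,large_pore_radius Pore radii in nm (defaults
#'   4.44 and 22.85 nm, standard two-pore literature values).
#' @param alpha_large Fraction of the hydraulic conductivity carried by the
#'   large pores (default 0.042).
#' @param iso_fraction Isogravimetric circular fluid flow through the large
#'   pores (balanced by reabsorption through the small pores), expressed as a
#'   fraction of the organ's net filtration (default 0.2).
#' @param ps_scale Dimensionless permeability-surface-area scale `kappa`:
#'   `PS_j = kappa * J_net * w_j * F_j(lambda) / r_nm` where `w_j` are the
#'   pore-area/length weights implied by `alpha_large` and the pore radii and
#'   `r_nm` the solute hydrodynamic radius (Stokes-Einstein free diffusion
#'   scales as 1/r).  Default 2000.
#' @return An object of class `two_pore_parameters`.
#' @export
two_pore_parameters <- function(small_pore_radius = 4.44,
                                large_pore_radius = 22.85,
                                alpha_large = 0.042,
                                iso_fraction = 0.2,
                                ps_scale = 2000) {
  stopifnot(small_pore_radius > 0, large_pore_radius > small_pore_radius,
            alpha_large > 0, alpha_large < 1, iso_fraction >= 0, ps_scale >= 0)
  structure(list(small_pore_radius = small_pore_radius,
                 large_pore_radius = large_pore_radius,
                 alpha_large = alpha_large,
                 iso_fraction = iso_fraction,
                 ps_scale = ps_scale),
            class = "two_pore_parameters")
}

#' Pore hindrance factors for a solute
#'
#' @param lambda Ratio of solute hydrodynamic radius to pore radius
#'   (vectorized).  Values >= 1 mean complete exclusion.
#' @return A list with `sigma` (osmotic reflection coefficient, in \[0,1\],
#'   increasing in lambda) and `diffusive` (Renkin diffusive hindrance, in
#'   (0,1\], decreasing in lambda); both include the partition coefficient
#'   `(1-lambda)^2`.
#' @examples
#' hindrance_factors(0)      # point solute: sigma 0, hindrance 1
#' hindrance_factors(0.99)
#' @export
hindrance_factors <- function(lambda) {
  stopifnot(all(lambda >= 0))
  lam <- pmin(lambda, 1)
  phi <- (1 - lam)^2
  sigma <- 1 - phi * (2 - phi) * (1 - lam^2 / 3)
  diffusive <- phi * (1 - 2.104 * lam + 2.09 * lam^3 - 0.95 * lam^5)
  sigma[lambda >= 1] <- 1
  diffusive[lambda >= 1] <- 0
  list(sigma = sigma, diffusive = pmax(diffusive, 0))
}

# Per-unit-net-filtration flux coefficients (a_hat, b_hat) such that the
# solute flux for an organ with net filtration J_net is
#   J_s = J_net * (a_hat * C_p - b_hat * C_i).
# Both the pore fluid flows and PS scale with J_net, so the Peclet numbers,
# and hence a_hat/b_hat, are independent of the organ and of age.
.two_pore_unit_coefs <- function(pores, r_nm) {
  stopifnot(inherits(pores, "two_pore_parameters"), r_nm > 0)
  lam <- c(small = r_nm / pores$small_pore_radius,
           large = r_nm / pores$large_pore_radius)
  h <- hindrance_factors(lam)
  # fluid split: J_small + J_large = J_net, plus circular flow J_iso through
  # the large pores balanced by the small pores
  jv <- c(small = (1 - pores$alpha_large) - pores$iso_fraction,
          large = pores$alpha_large + pores$iso_fraction)
  # pore area/length weights from the hydraulic conductivity split
  aw <- c(small = (1 - pores$alpha_large) / pores$small_pore_radius^2,
          large = pores$alpha_large / pores$large_pore_radius^2)
  w <- aw / sum(aw)
  ps <- pores$ps_scale * w * h$diffusive / r_nm
  a <- b <- numeric(2)
  for (j in 1:2) {
    x <- jv[j] * (1 - h$sigma[j])
    if (ps[j] <= 0) {                 # solute excluded from diffusion
      a[j] <- max(x, 0); b[j] <- max(-x, 0)
    } else {
      pe <- x / ps[j]
      if (abs(pe) < 1e-8) {           # Pe -> 0: pure diffusion limit
        a[j] <- ps[j] + x / 2
        b[j] <- ps[j] - x / 2
      } else if (pe > 0) {
        e <- exp(-pe)
        a[j] <- x / (1 - e); b[j] <- x * e / (1 - e)
      } else {
        e <- exp(pe)
        a[j] <- -x * e / (1 - e); b[j] <- -x / (1 - e)
      }
    }
  }
  c(a = sum(a), b = sum(b))
}

#' Two-pore solute flux across one organ's capillary wall
#'
#' Total (small + large pore) convective-diffusive solute flux from plasma to
#' interstitial space, for an organ whose net transcapillary filtration
#' equals `net_filtration` (at steady state the lymph plus recirculation
#' flow).
#'
#' @param c_plasma,c_interstitial Concentrations (any common unit/ml).
#' @param net_filtration Net filtration fluid flow (ml/day).
#' @param pores A [two_pore_parameters()] object.
#' @param drug A [drug_properties()] object (its hydrodynamic radius sets the
#'   hindrances and, via Stokes-Einstein, the free diffusivity).
#' @return Solute flux in concentration-unit x ml / day; positive from plasma
#'   to interstitial.
#' @export
two_pore_solute_flux <- function(c_plasma, c_interstitial, net_filtration,
                                 pores, drug) {
  stopifnot(all(c_plasma >= 0), all(c_interstitial >= 0))
  ab <- .two_pore_unit_coefs(pores, drug$hydrodynamic_radius)
  unname(net_filtration * (ab[["a"]] * c_plasma - ab[["b"]] * c_interstitial))
}
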