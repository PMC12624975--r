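# Constitutive models: one-term Ogden hyperelasticity for cortical tissue,
# St. Venant-Kirchhoff elasticity for the silicon array and for the
# small-strain verification oracle.

#' One-term Ogden hyperelastic material
#'
#' Strain-energy density
#' \deqn{\Psi = \frac{\mu_1}{\alpha_1}(\lambda_1^{-\alpha_1} +
#'   \lambda_2^{-\alpha_1} + \lambda_3^{-\alpha_1} - 3) +
#'   \frac{1}{d_1}(J-1)^2,}
#' with principal stretches \eqn{\lambda_i} and volume ratio
#' \eqn{J = \lambda_1\lambda_2\lambda_3}.  Defaults are the Budday et al.
#' human cortical parameters \eqn{\mu_1 = 150.5} Pa,
#' \eqn{\alpha_1 = 19}, \eqn{d_1 = 6.65\times 10^{-5}} Pa\eqn{^{-1}}.
#'
#' Two stretch conventions are implemented.  `"isochoric"` (the default,
#' matching the one-term Ogden of commercial large-deformation solvers)
#' applies the power terms to \eqn{\bar\lambda_i = J^{-1/3}\lambda_i},
#' which makes the reference state stress free and gives the small-strain
#' moduli \eqn{\mu_0 = \mu_1\alpha_1/2} and \eqn{\kappa = 2/d_1}.  `"raw"`
#' evaluates the power terms on the raw stretches exactly as the formula
#' is written; note this variant carries a hydrostatic reference stress of
#' \eqn{-\mu_1} because the power term is not volumetrically projected.
#'
#' @param mu1 Shear-like modulus, Pa.
#' @param alpha1 Dimensionless exponent.
#' @param d1 Compressibility parameter, 1/Pa.
#' @param convention Stretch convention, `"isochoric"` or `"raw"`.
#' @export
ogden_material <- function(mu1 = 150.5, alpha1 = 19, d1 = 6.65e-5,
                           convention = c("isochoric", "raw")) {
  convention <- match.arg(convention)
  stopifnot(mu1 > 0, d1 > 0)
  structure(list(mu1 = mu1, alpha1 = alpha1, d1 = d1,
                 convention = convention), class = "ogden_material")
}

#' Linear isotropic material (geometrically nonlinear St. Venant-Kirchhoff)
#'
#' Used for the silicon array (default: Young's modulus 200 GPa, Poisson
#' ratio 0.278) and, via [linear_material()], as the small-strain tissue
#' oracle.
#'
#' @param youngs_modulus Pa.
#' @param poisson_ratio Dimensionless, in \[0, 0.5).
#' @export
elastic_material <- function(youngs_modulus = 2e11, poisson_ratio = 0.278) {
  stopifnot(youngs_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5)
  structure(list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio),
            class = "elastic_material")
}

#' @rdname elastic_material
#' @param shear,bulk Shear and bulk moduli, Pa (alternative parametrization).
#' @export
linear_material <- function(shear, bulk) {
  E <- 9 * bulk * shear / (3 * bulk + shear)
  nu <- (3 * bulk - 2 * shear) / (2 * (3 * bulk + shear))
  elastic_material(E, nu)
}

# encode a material as a row of the C-side parameter table
mat_row <- function(m) {
  if (inherits(m, "ogden_material")) {
    type <- if (m$convention == "raw") 1 else 2
    c(type, m$mu1, m$alpha1, m$d1)
  } else if (inherits(m, "elastic_material")) {
    E <- m$youngs_modulus; nu <- m$poisson_ratio
    mu <- E / (2 * (1 + nu))
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    c(3, lam, mu, 0)
  } else stop("unknown material class")
}

#' Ogden strain-energy density
#'
#' Evaluates the strain-energy density at given principal stretches and
#' volume ratio, under the material's stretch convention.  Exactly zero at
#' the reference state \eqn{\lambda = (1,1,1)}, \eqn{J = 1}.
#'
#' @param stretches Numeric triple of principal stretches (all positive).
#' @param J Volume ratio (positive).  Supplied separately so the
#'   volumetric and deviatoric contributions can be probed independently;
#'   for a deformation gradient, `J = prod(stretches)`.
#' @param material An [ogden_material()].
#' @return Energy density, Pa.
#' @export
ogden_energy <- function(stretches, J = prod(stretches), material = ogden_material()) {
  stopifnot(length(stretches) == 3)
  if (any(stretches <= 0) || J <= 0)
    stop("principal stretches and J must be positive")
  lam <- if (material$convention == "isochoric") J^(-1 / 3) * stretches else stretches
  material$mu1 / material$alpha1 * (sum(lam^(-material$alpha1)) - 3) +
    (1 / material$d1) * (J - 1)^2
}

#' First Piola-Kirchhoff stress
#'
#' Analytic stress \eqn{P = \partial\Psi/\partial F} of the configured
#' strain energy, evaluated through the principal-stretch decomposition.
#'
#' @param F Deformation gradient (3 x 3, `det(F) > 0`).
#' @param material An [ogden_material()] or [elastic_material()].
#' @return List with `P` (3 x 3 first Piola-Kirchhoff stress, Pa),
#'   `cauchy` (symmetrized push-forward \eqn{J^{-1} P F^T}) and `psi`
#'   (energy density, Pa).
#' @export
pk1_stress <- function(F, material) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  if (det(F) <= 0) stop("element inversion: det(F) <= 0")
  r <- mat_row(material)
  out <- .pk1_stress_cpp(F, as.integer(r[1]), r[2], r[3], r[4])
  sig <- out$P %*% t(F) / det(F)
  list(P = out$P, cauchy = (sig + t(sig)) / 2, psi = out$psi)
}

#' Von Mises equivalent strain
#'
#' Scalar equivalent of a (Hencky) strain tensor,
#' \deqn{\varepsilon_{vM} = \frac{1}{1+\nu'}\sqrt{\tfrac12\left[
#'  (\varepsilon_1-\varepsilon_2)^2 + (\varepsilon_2-\varepsilon_3)^2 +
#'  (\varepsilon_3-\varepsilon_1)^2\right]},}
#' with effective Poisson ratio \eqn{\nu' = 0.5} by default (the
#' large-deformation post-processing convention).
#'
#' @param eps A symmetric 3 x 3 strain tensor or a length-3 vector of
#'   principal strains.
#' @param nu_eff Effective Poisson ratio.
#' @export
von_mises_strain <- function(eps, nu_eff = 0.5) {
  p <- if (is.matrix(eps)) eigen(eps, symmetric = TRUE)$values else sort(eps)
  stopifnot(length(p) == 3)
  sqrt(0.5 * ((p[1] - p[2])^2 + (p[2] - p[3])^2 + (p[3] - p[1])^2)) / (1 + nu_eff)
}
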