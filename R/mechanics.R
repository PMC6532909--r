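#' Elastic material of a PDMS micropillar
#'
#' Bundles the linear-elastic constants of the pillar material. Defaults are
#' the measured properties of the cured PDMS used for the microdevices:
#' Young's modulus 2.6 MPa (from macroscopic compression testing, see
#' [youngs_modulus_from_compression()]), near-incompressible Poisson ratio
#' 0.499 and density 927 kg/m^3. The density is carried for completeness but
#' unused by the static beam model; the Poisson ratio enters only the
#' optional shear-corrected (Timoshenko) finite-element variant.
#'
#' @param E Young's modulus in Pa. Must be positive.
#' @param nu Poisson's ratio, dimensionless, in `[0, 0.5)`.
#' @param rho density in kg/m^3. Must be positive.
#' @return An object of class `beam_material`.
#' @examples
#' pdms <- beam_material()         # 2.6 MPa PDMS
#' soft <- beam_material(E = 1e6)  # softer elastomer
#' @export
beam_material <- function(E = 2.6e6, nu = 0.499, rho = 927) {
  stopifnot(is.numeric(E), length(E) == 1L, is.finite(E),
            is.numeric(nu), length(nu) == 1L, is.finite(nu),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (E <= 0) stop("Young's modulus E must be positive (Pa)", call. = FALSE)
  if (nu < 0 || nu >= 0.5) stop("Poisson's ratio nu must lie in [0, 0.5)", call. = FALSE)
  if (rho <= 0) stop("density rho must be positive (kg/m^3)", call. = FALSE)
  structure(list(E = E, nu = nu, rho = rho), class = "beam_material")
}

#' Geometry of one cylindrical micropillar
#'
#' A pillar is a clamped circular cylinder described by its diameter `d`,
#' height `h` and base-centre position in the device plane. All lengths are
#' SI metres; micrometre inputs from image metadata are converted at the
#' I/O boundary (see [read_pillar_config()]). The beam model requires a
#' slender pillar, so the aspect ratio `h/d` must exceed 1 (the devices use
#' 300 um tall pillars of 28 or 36 um diameter, aspect ratio 8-11).
#'
#' @param d pillar diameter (m).
#' @param h pillar height (m).
#' @param base base-centre coordinates `c(x, y)` in the device plane (m).
#' @return An object of class `pillar_geometry` with the derived second
#'   moment of area `I = pi d^4 / 64` attached.
#' @examples
#' pillar_geometry(d = 28e-6, h = 300e-6)
#' @export
pillar_geometry <- function(d, h, base = c(0, 0)) {
  stopifnot(is.numeric(d), length(d) == 1L, is.numeric(h), length(h) == 1L,
            is.numeric(base), length(base) == 2L, all(is.finite(c(d, h, base))))
  if (d <= 0 || h <= 0) stop("pillar diameter and height must be positive", call. = FALSE)
  if (h / d <= 1) stop("pillar aspect ratio h/d must exceed 1 for the beam model", call. = FALSE)
  structure(list(d = d, h = h, base = as.numeric(base), I = pi * d^4 / 64),
            class = "pillar_geometry")
}

#' Horizontal load applied by the spheroid to a pillar
#'
#' The spheroid contacts the upper part of each pillar; its push is modelled
#' as a horizontal force `F` distributed uniformly over the loaded span `s`
#' measured down from the pillar top (175 um in the devices, determined from
#' the imprints the pillars leave on the spheroid). The load is idealized as
#' a line load along the pillar axis with line density `q = F/s`.
#'
#' @param F total horizontal force (N), non-negative.
#' @param s loaded span from the pillar top (m), `0 < s <= h` is checked at
#'   use sites against the actual geometry.
#' @param direction unit vector in the device plane; normalized here.
#' @return An object of class `load_spec`.
#' @examples
#' load_spec(F = 230e-9, s = 175e-6)
#' @export
load_spec <- function(F, s = 175e-6, direction = c(1, 0)) {
  stopifnot(is.numeric(F), length(F) == 1L, is.numeric(s), length(s) == 1L,
            is.numeric(direction), length(direction) == 2L,
            all(is.finite(c(F, s, direction))))
  if (F < 0) stop("force F must be non-negative", call. = FALSE)
  if (s <= 0) stop("loaded span s must be positive", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("load direction must be a non-zero vector", call. = FALSE)
  structure(list(F = F, s = s, direction = direction / nrm), class = "load_spec")
}

check_span <- function(geom, load) {
  if (load$s > geom$h)
    stop("loaded span s exceeds pillar height h", call. = FALSE)
  invisible(TRUE)
}

#' Tip spring constant of a clamped pillar
#'
#' Returns the cantilever stiffness `K = 3 E I / h^3` (tip point-load
#' convention) with `I = pi d^4 / 64`, in N/m. [spring_constant_nN_per_um()]
#' converts to the nN/um figure customarily printed for micropillar devices,
#' truncated to an integer: the 28 um and 36 um pillars give 8 and
#' 23 nN/um.
#'
#' @param geom a [pillar_geometry()].
#' @param mat a [beam_material()].
#' @return Stiffness in N/m.
#' @examples
#' K <- spring_constant(pillar_geometry(28e-6, 300e-6), beam_material())
#' spring_constant_nN_per_um(pillar_geometry(28e-6, 300e-6), beam_material())  # 8
#' @export
spring_constant <- function(geom, mat) {
  stopifnot(inherits(geom, "pillar_geometry"), inherits(mat, "beam_material"))
  3 * mat$E * geom$I / geom$h^3
}

#' @rdname spring_constant
#' @export
spring_constant_nN_per_um <- function(geom, mat) {
  trunc(spring_constant(geom, mat) * 1e3)  # 1 N/m = 1000 nN/um
}

#' Deflection profile of a pillar under a partial uniform horizontal load
#'
#' Closed-form Euler-Bernoulli solution of `EI w'''' = q(z)` for a cantilever
#' clamped at the base (`w(0) = w'(0) = 0`) and free at the top
#' (`w''(h) = w'''(h) = 0`), with a uniform line load `q = F/s` acting on the
#' upper span `[h - s, h]` and zero below. The deflection is non-negative,
#' non-decreasing in height and exactly linear in `F`; the largest
#' displacement is at the pillar top.
#'
#' With `a = h - s` the solution is
#' \deqn{w(z) = \frac{q z^2}{6EI}\Big(\tfrac{3}{2}(h^2-a^2) - z(h-a)\Big), \quad z \le a}
#' \deqn{w(z) = \frac{q}{6EI}\Big(\tfrac{z^4}{4} - h z^3 + \tfrac{3}{2}h^2z^2 - a^3 z + \tfrac{a^4}{4}\Big), \quad z > a}
#' which reduces to the classical `q h^4 / 8EI` tip deflection when the whole
#' pillar is loaded (`s = h`) and to the point-load `F h^3 / 3EI` limit as
#' `s -> 0`.
#'
#' @param geom a [pillar_geometry()].
#' @param mat a [beam_material()].
#' @param load a [load_spec()]; `load$s` must not exceed `geom$h`.
#' @param z heights at which to evaluate the deflection (m), all in `[0, h]`.
#' @return Numeric vector of lateral displacements (m), same length as `z`.
#' @examples
#' geom <- pillar_geometry(28e-6, 300e-6)
#' w <- deflection_profile(geom, beam_material(), load_spec(100e-9),
#'                         z = seq(0, 300e-6, length.out = 75))
#' max(w) * 1e6  # tip deflection, about 6.7 um
#' @export
deflection_profile <- function(geom, mat, load, z) {
  stopifnot(inherits(geom, "pillar_geometry"), inherits(mat, "beam_material"),
            inherits(load, "load_spec"), is.numeric(z))
  check_span(geom, load)
  h <- geom$h
  if (any(z < -1e-12 * h | z > h * (1 + 1e-12)))
    stop("evaluation heights z must lie within [0, h]", call. = FALSE)
  z <- pmin(pmax(z, 0), h)
  a <- h - load$s
  q <- load$F / load$s
  EI <- mat$E * geom$I
  ifelse(z <= a,
         q * z^2 / (6 * EI) * (1.5 * (h^2 - a^2) - z * (h - a)),
         q / (6 * EI) * (z^4 / 4 - h * z^3 + 1.5 * h^2 * z^2 - a^3 * z + a^4 / 4))
}

# Antiderivatives of the four cubic Hermite shape functions on [0, L],
# used for exact consistent nodal loads of a partially loaded element.
hermite_load_integral <- function(L, x0, x1) {
  P <- function(x) c(
    x - x^3 / L^2 + x^4 / (2 * L^3),
    x^2 / 2 - 2 * x^3 / (3 * L) + x^4 / (4 * L^2),
    x^3 / L^2 - x^4 / (2 * L^3),
    -x^3 / (3 * L) + x^4 / (4 * L^2))
  P(x1) - P(x0)
}

#' Finite-element beam solution of the pillar deflection
#'
#' Discretizes the pillar into two-node cubic-Hermite beam elements
#' (transverse displacement and rotation at each node), assembles the
#' standard element stiffness with exact consistent nodal loads for the
#' partial uniform load, clamps the base node (the Dirichlet condition at
#' the pillar foot) and solves the linear system. With
#' `shear_corrected = TRUE` the stiffness uses the Timoshenko
#' shear-flexible form with shear modulus `G = E / (2(1+nu))` and the
#' circular-section shear factor `kappa = 6(1+nu)/(7+6nu)`; for the slender
#' pillars here the correction is a sub-percent effect.
#'
#' The Euler-Bernoulli variant reproduces the closed-form
#' [deflection_profile()] at the nodes to machine precision, and is used as
#' a mutual cross-check in the test-suite.
#'
#' @param geom,mat,load as in [deflection_profile()].
#' @param n_elements number of beam elements (>= 2).
#' @param shear_corrected logical; include Timoshenko shear flexibility.
#' @return A list with `z` (node heights, m), `w` (nodal lateral
#'   displacements, m) and `theta` (nodal rotations, rad).
#' @export
fe_beam_profile <- function(geom, mat, load, n_elements = 64, shear_corrected = FALSE) {
  stopifnot(inherits(geom, "pillar_geometry"), inherits(mat, "beam_material"),
            inherits(load, "load_spec"))
  check_span(geom, load)
  if (n_elements < 2) stop("n_elements must be at least 2", call. = FALSE)
  h <- geom$h
  L <- h / n_elements
  EI <- mat$E * geom$I
  phi <- 0
  if (shear_corrected) {
    G <- mat$E / (2 * (1 + mat$nu))
    kappa <- 6 * (1 + mat$nu) / (7 + 6 * mat$nu)
    A <- pi * (geom$d / 2)^2
    phi <- 12 * EI / (kappa * G * A * L^2)
  }
  ke <- EI / ((1 + phi) * L^3) * matrix(c(
    12,          6 * L,            -12,          6 * L,
    6 * L,  (4 + phi) * L^2,  -6 * L,  (2 - phi) * L^2,
    -12,        -6 * L,             12,         -6 * L,
    6 * L,  (2 - phi) * L^2,  -6 * L,  (4 + phi) * L^2), 4, 4, byrow = TRUE)

  ndof <- 2 * (n_elements + 1)
  K <- matrix(0, ndof, ndof)
  f <- numeric(ndof)
  a <- h - load$s
  q <- load$F / load$s
  for (e in seq_len(n_elements)) {
    z1 <- (e - 1) * L
    z2 <- e * L
    idx <- (2 * e - 1):(2 * e + 2)
    K[idx, idx] <- K[idx, idx] + ke
    lo <- max(z1, a)
    if (lo < z2) f[idx] <- f[idx] + q * hermite_load_integral(L, lo - z1, z2 - z1)
  }
  free <- 3:ndof  # clamp w and theta at the base node
  # equilibrate: rotations carry a factor L relative to displacements, which
  # otherwise drives the condition number ~ L^-2 beyond double precision at
  # fine meshes
  sc <- rep(c(1, 1 / L), n_elements + 1)
  Ks <- K[free, free] * tcrossprod(sc[free])
  u <- numeric(ndof)
  sol <- tryCatch(solve(Ks, f[free] * sc[free]) * sc[free],
                  error = function(e) stop("finite-element system is singular", call. = FALSE))
  u[free] <- sol
  list(z = seq(0, h, length.out = n_elements + 1),
       w = u[seq(1, ndof, by = 2)],
       theta = u[seq(2, ndof, by = 2)])
}

#' Maximum bending stress in the pillar
#'
#' The bending moment of the partial uniform load about the clamped base is
#' `M = F (h - s/2)`, so the maximal fibre stress, attained at the base on
#' the outer surface, is `sigma = M (d/2) / I`. This mirrors the observation
#' that the equivalent (von Mises) stress of the bent pillar peaks at the
#' fixed bottom.
#'
#' @param geom,mat,load as in [deflection_profile()].
#' @return Stress in Pa.
#' @examples
#' max_bending_stress(pillar_geometry(28e-6, 300e-6), beam_material(),
#'                    load_spec(100e-9, 175e-6))  # about 9.9 kPa
#' @export
max_bending_stress <- function(geom, mat, load) {
  stopifnot(inherits(geom, "pillar_geometry"), inherits(load, "load_spec"))
  check_span(geom, load)
  M_base <- load$F * (geom$h - load$s / 2)
  M_base * (geom$d / 2) / geom$I
}

#' Uniaxial compression test of a macroscopic elastomer post
#'
#' Records a calibration compression experiment on a macroscopic post cast
#' from the same elastomer as the micropillars: a post of height `H` and
#' radius `r` is compressed and the slope of force versus axial deformation
#' `F / dL` is measured.
#'
#' @param H post height (m).
#' @param r post radius (m).
#' @param slope measured force per unit compression `F/dL` (N/m),
#'   non-negative.
#' @return An object of class `compression_test`.
#' @export
compression_test <- function(H, r, slope) {
  stopifnot(is.numeric(H), is.numeric(r), is.numeric(slope),
            all(is.finite(c(H, r, slope))))
  if (H <= 0) stop("post height H must be positive", call. = FALSE)
  if (r <= 0) stop("post radius r must be positive", call. = FALSE)
  if (slope < 0) stop("compression slope must be non-negative", call. = FALSE)
  structure(list(H = H, r = r, slope = slope, S = pi * r^2),
            class = "compression_test")
}

#' Young's modulus from a uniaxial compression test
#'
#' Under uniaxial stress the linear-elastic relation `F/S = E dL/H` holds,
#' so `E = slope * H / (pi r^2)` with `slope = F/dL`. This is how the
#' 2.6 MPa modulus of the pillar PDMS is obtained from compression of a
#' 10 mm tall, 9 mm diameter calibration post.
#'
#' @param test a [compression_test()].
#' @return Young's modulus in Pa.
#' @examples
#' youngs_modulus_from_compression(
#'   compression_test(H = 10e-3, r = 4.5e-3, slope = 16540))  # ~2.6 MPa
#' @export
youngs_modulus_from_compression <- function(test) {
  stopifnot(inherits(test, "compression_test"))
  test$slope * test$H / test$S
}

#' Read pillar material/geometry configuration from JSON
#'
#' The configuration file is a flat key-value JSON with the keys
#' `E_MPa`, `nu`, `rho_kg_m3`, `diameter_um`, `height_um`,
#' `loaded_span_um`; missing keys take the device defaults
#' (2.6, 0.499, 927, 28, 300, 175). Values are converted to SI here, so all
#' downstream computation is in metres, newtons and pascals.
#'
#' @param path path to the JSON file, or `NULL` for pure defaults.
#' @return A list with `geom` ([pillar_geometry()]), `mat`
#'   ([beam_material()]) and `loaded_span` (m).
#' @export
read_pillar_config <- function(path = NULL) {
  cfg <- list(E_MPa = 2.6, nu = 0.499, rho_kg_m3 = 927,
              diameter_um = 28, height_um = 300, loaded_span_um = 175)
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(user)] <- user
  }
  list(geom = pillar_geometry(d = cfg$diameter_um * 1e-6, h = cfg$height_um * 1e-6),
       mat = beam_material(E = cfg$E_MPa * 1e6, nu = cfg$nu, rho = cfg$rho_kg_m3),
       loaded_span = cfg$loaded_span_um * 1e-6)
}
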