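#' Ogden hyperelastic material parameters
#'
#' An N-term Ogden strain-energy model. The default one-term parameter set
#' (`mu = -5.8` kPa, `alpha = -1.3`, `d = 0`) describes oxidised
#' alginate-gelatin (ADA-GEL) hydrogel under the assumption of full
#' incompressibility; `d = 0` is the sentinel for an incompressible term
#' whose volumetric contribution is omitted.
#'
#' @param mu shear-like moduli, kPa (one per term).
#' @param alpha dimensionless exponents (non-zero, one per term).
#' @param d volumetric compliances, 1/kPa (`0` encodes incompressibility).
#' @return An object of class `ogden_params`.
#' @export
ogden_params <- function(mu = -5.8, alpha = -1.3, d = 0) {
  if (length(mu) < 1 || length(alpha) != length(mu))
    stop("'mu' and 'alpha' must have equal length >= 1", call. = FALSE)
  if (length(d) == 1) d <- rep(d, length(mu))
  if (length(d) != length(mu))
    stop("'d' must have length 1 or length(mu)", call. = FALSE)
  if (any(!is.finite(mu)) || any(!is.finite(alpha)) || any(!is.finite(d)))
    stop("Ogden parameters must be finite", call. = FALSE)
  if (any(alpha == 0)) stop("'alpha' terms must be non-zero", call. = FALSE)
  if (any(d < 0)) stop("'d' terms must be >= 0", call. = FALSE)
  structure(list(mu = mu, alpha = alpha, d = d, N = length(mu)),
            class = "ogden_params")
}

#' @export
print.ogden_params <- function(x, ...) {
  cat(sprintf("%d-term Ogden material\n", x$N))
  for (i in seq_len(x$N))
    cat(sprintf("  term %d: mu = %g kPa, alpha = %g, d = %g%s\n", i,
                x$mu[i], x$alpha[i], x$d[i],
                if (x$d[i] == 0) " (incompressible)" else ""))
  invisible(x)
}

#' Principal stretch state
#'
#' @param lambda1,lambda2,lambda3 principal stretch ratios (> 0).
#' @param J volume ratio; defaults to `lambda1 * lambda2 * lambda3`.
#' @return An object of class `stretch_state`.
#' @export
stretch_state <- function(lambda1, lambda2, lambda3,
                          J = lambda1 * lambda2 * lambda3) {
  lam <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("principal stretches must be finite and > 0", call. = FALSE)
  structure(list(lambda = lam, J = J), class = "stretch_state")
}

#' Ogden strain-energy density
#'
#' `W = sum_i mu_i/alpha_i (lb1^alpha_i + lb2^alpha_i + lb3^alpha_i - 3)
#'      + sum_i (1/d_i) (J - 1)^(2i)`,
#' where `lb_k = J^(-1/3) lambda_k` are the deviatoric principal stretches
#' (equal to `lambda_k` for incompressible deformation, `J = 1`). Volumetric
#' terms with `d_i = 0` are skipped.
#'
#' @param params an [ogden_params()] object.
#' @param state a [stretch_state()], or a numeric vector of three principal
#'   stretches (then `J` is their product).
#' @return Strain-energy density, kPa.
#' @examples
#' p <- ogden_params()
#' strain_energy(p, stretch_state(0.95, 0.95^-0.5, 0.95^-0.5))
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "ogden_params"))
  if (is.numeric(state) && length(state) == 3)
    state <- stretch_state(state[1], state[2], state[3])
  stopifnot(inherits(state, "stretch_state"))
  lb <- state$J^(-1 / 3) * state$lambda
  W <- 0
  for (i in seq_len(params$N)) {
    W <- W + params$mu[i] / params$alpha[i] * (sum(lb^params$alpha[i]) - 3)
    if (params$d[i] > 0)
      W <- W + (state$J - 1)^(2 * i) / params$d[i]
  }
  W
}

#' Nominal stress under incompressible uniaxial loading
#'
#' Closed-form specialisation of the Ogden model to the incompressible
#' uniaxial path `(lambda, lambda^-1/2, lambda^-1/2)`:
#' `P(lambda) = sum_i mu_i (lambda^(alpha_i - 1) -
#' lambda^(-alpha_i/2 - 1))`. Compression (`lambda < 1`) yields negative
#' stress for the default parameters.
#'
#' @param params an [ogden_params()] object with all `d = 0`.
#' @param lambda stretch ratio(s), > 0.
#' @return Nominal (first Piola-Kirchhoff) stress, kPa; vectorised over
#'   `lambda`.
#' @export
uniaxial_nominal_stress <- function(params, lambda) {
  stopifnot(inherits(params, "ogden_params"))
  if (any(params$d != 0))
    stop("unsupported mode: closed form requires a fully incompressible ",
         "parameter set (all d = 0)", call. = FALSE)
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("'lambda' must be finite and > 0", call. = FALSE)
  P <- 0
  for (i in seq_len(params$N))
    P <- P + params$mu[i] *
      (lambda^(params$alpha[i] - 1) - lambda^(-params$alpha[i] / 2 - 1))
  P
}

#' Octahedral shear strain
#'
#' `OSS = 2/3 sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)` from the elastic
#' principal strains. Invariant under permutation of the strains and under
#' adding a constant to all three.
#'
#' @param e1,e2,e3 principal strains; vectorised. Alternatively `e1` may be
#'   an n x 3 matrix of principal strains.
#' @return Octahedral shear strain (dimensionless).
#' @examples
#' octahedral_shear_strain(0.05, 0, 0)  # ~0.0471
#' @export
octahedral_shear_strain <- function(e1, e2 = NULL, e3 = NULL) {
  if (is.matrix(e1)) {
    stopifnot(ncol(e1) == 3)
    e3 <- e1[, 3]; e2 <- e1[, 2]; e1 <- e1[, 1]
  }
  if (any(!is.finite(c(e1, e2, e3))))
    stop("principal strains must be finite", call. = FALSE)
  2 / 3 * sqrt((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2)
}
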