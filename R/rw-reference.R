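#' Random-walk reference-state parameters
#'
#' The reference state of the distance potential is a freely-jointed chain
#' (FJC): an ideal polymer whose nodes map to protein residues and whose
#' end-to-end distance over `n` links is Maxwell-distributed with
#' mean-square `n * lam`, where `lam = b^2` is the squared effective Kuhn
#' length.  `rw_params()` bundles the three tunables of the method:
#'
#' * `lam` — squared Kuhn length in squared Angstrom (default 460,
#'   i.e. b = 21.4 A),
#' * `R0` — interaction cutoff in Angstrom (default 15.5),
#' * `dR` — distance-bin width in Angstrom (default 0.5, giving 31 bins).
#'
#' @param lam Squared Kuhn length (A^2), > 0.
#' @param R0 Distance cutoff (A), > 0 and an integer multiple of `dR`.
#' @param dR Bin width (A), > 0.
#' @return An object of class `rw_params`: a list with `lam`, `R0`, `dR`,
#'   the derived Kuhn length `b = sqrt(lam)` and bin count `n_bins`.
#' @export
#' @examples
#' p <- rw_params()
#' p$b       # 21.44761...
#' p$n_bins  # 31
rw_params <- function(lam = 460, R0 = 15.5, dR = 0.5) {
  if (!is.numeric(lam) || lam <= 0) abort("`lam` must be > 0")
  if (!is.numeric(R0) || R0 <= 0) abort("`R0` must be > 0")
  if (!is.numeric(dR) || dR <= 0) abort("`dR` must be > 0")
  k <- R0 / dR
  if (abs(k - round(k)) > 1e-8) abort("`R0` must be an integer multiple of `dR`")
  structure(list(lam = lam, R0 = R0, dR = dR, b = sqrt(lam),
                 n_bins = as.integer(round(k))),
            class = "rw_params")
}

#' @export
print.rw_params <- function(x, ...) {
  cat(sprintf("<rw_params> lam = %g A^2 (b = %.4g A), R0 = %g A, dR = %g A (%d bins)\n",
              x$lam, x$b, x$R0, x$dR, x$n_bins))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "rw_params")) abort("`params` must come from rw_params()")
  params
}

#' Radial end-to-end density of the freely-jointed chain
#'
#' The probability density of the end-to-end distance `R` of an ideal chain
#' of `n` links in the Gaussian (random-walk) limit:
#' \deqn{P(R \mid n) = 4 \pi R^2 \left(\frac{3}{2 \pi n \lambda}\right)^{3/2}
#'   e^{-3R^2 / (2 n \lambda)}.}
#' It integrates to 1 over `R >= 0` and has mean-square distance
#' `n * lam`.
#'
#' @param R Distance(s), A, >= 0 (vectorised).
#' @param n Integer sequence separation, >= 1.
#' @param params An [rw_params()] object.
#' @return Density values (1/A), same length as `R`.
#' @export
fjc_density <- function(R, n, params = rw_params()) {
  .check_params(params)
  if (any(R < 0)) abort("`R` must be >= 0")
  if (length(n) != 1L || n < 1 || n != floor(n)) abort("`n` must be an integer >= 1")
  4 * pi * R^2 * (3 / (2 * pi * n * params$lam))^1.5 *
    exp(-3 * R^2 / (2 * n * params$lam))
}

#' Aggregate random-walk distance probability for a chain of N residues
#'
#' Sums the FJC radial density over the sequence separations realisable in a
#' protein of `N` residues; separations `n >= N` contribute exactly zero.
#' Two aggregation shapes are available: `"uniform"` sums the per-separation
#' densities with equal weight, `"multiplicity"` weights separation `n` by
#' the number of residue pairs `N - n` that realise it (the marginal
#' distance density of an actual random-walk chain).  Only the shape in `R`
#' matters downstream — the potential uses ratios to the value at the
#' cutoff — so the sum is left unnormalised.
#'
#' @inheritParams fjc_density
#' @param N Protein length in residues, >= 2.
#' @param n_min Smallest separation included in the sum (default 1).
#' @param weighting `"uniform"` (default) or `"multiplicity"`.
#' @return Relative density values, same length as `R`.
#' @export
rw_probability <- function(R, N, params = rw_params(), n_min = 1L,
                           weighting = c("uniform", "multiplicity")) {
  .check_params(params)
  weighting <- match.arg(weighting)
  if (length(N) != 1L || N < 2 || N != floor(N)) abort("`N` must be an integer >= 2")
  if (n_min < 1) abort("`n_min` must be >= 1")
  if (n_min > N - 1L) return(rep(0, length(R)))
  ns <- seq.int(n_min, N - 1L)
  w <- if (weighting == "multiplicity") N - ns else rep(1, length(ns))
  out <- rep(0, length(R))
  for (i in seq_along(ns)) out <- out + w[i] * fjc_density(R, ns[i], params)
  out
}

# 16-point Gauss-Legendre nodes/weights on [0, 1], computed once
.gl_env <- new.env(parent = emptyenv())
.gl16 <- function() {
  if (is.null(.gl_env$gl)) .gl_env$gl <- pracma::gaussLegendre(16L, 0, 1)
  .gl_env$gl
}

#' Per-bin integral of the random-walk reference density
#'
#' Integrates [rw_probability()] over each half-open distance shell
#' `[(k-1) dR, k dR)` up to the cutoff, by 16-point Gauss-Legendre
#' quadrature per shell.  These weights give the shape over bins of the
#' expected pair counts under the reference state.
#'
#' @inheritParams rw_probability
#' @param normalise If `TRUE` (default) the weights are scaled to sum to 1
#'   over the bins inside the cutoff.
#' @return Numeric vector of length `params$n_bins`.
#' @export
shell_weights <- function(N, params = rw_params(), n_min = 1L,
                          weighting = c("uniform", "multiplicity"),
                          normalise = TRUE) {
  .check_params(params)
  weighting <- match.arg(weighting)
  gl <- .gl16()
  lo <- (seq_len(params$n_bins) - 1) * params$dR
  # nodes for all shells at once: n_bins x 16
  nodes <- outer(lo, gl$x * params$dR, `+`)
  vals <- rw_probability(as.numeric(nodes), N, params, n_min, weighting)
  w <- params$dR * as.numeric(matrix(vals, nrow = length(lo)) %*% gl$w)
  if (normalise) w <- w / sum(w)
  w
}

#' @rdname shell_weights
#' @param bin 1-based bin index in `1..params$n_bins`.
#' @export
expected_shell_weight <- function(bin, N, params = rw_params(), n_min = 1L,
                                  weighting = c("uniform", "multiplicity")) {
  if (any(bin < 1 | bin > params$n_bins)) abort("`bin` out of range")
  shell_weights(N, params, n_min, weighting, normalise = FALSE)[bin]
}

#' Ideal-gas (DFIRE-style) reference shell ratio
#'
#' The ratio of expected pair counts in the shell at `R` to the shell at the
#' cutoff under the finite-ideal-gas reference, `(R / R0)^gamma` with
#' `gamma = 1.61`.  Provided as a baseline against which the random-walk
#' reference can be compared; the random-walk ratio falls below it at short
#' distances, which is what makes the resulting potential steeper there.
#'
#' @param R Distance(s), A, 0 < R <= R0.
#' @param R0 Cutoff distance, A.
#' @param gamma Exponent (default 1.61).
#' @return Ratio values in (0, 1].
#' @export
dfire_shell_ratio <- function(R, R0 = 15.5, gamma = 1.61) {
  if (any(R <= 0)) abort("`R` must be > 0")
  if (any(R > R0 + 1e-9)) abort("`R` must be <= R0")
  (R / R0)^gamma
}

#' Reference-state ratio curve of the random-walk model
#'
#' Tidy evaluation of `P_RW(R; N) / P_RW(R_ref; N)` together with the
#' ideal-gas baseline, for plotting and comparison.
#'
#' @inheritParams rw_probability
#' @param R Distances at which to evaluate (A).
#' @param R_ref Normalisation distance (default 15 A).
#' @param gamma Ideal-gas exponent (default 1.61).
#' @return A tibble with columns `R`, `reference` ("RW"/"ideal gas"),
#'   `ratio`.
#' @export
reference_ratio_curve <- function(R, N = 100L, params = rw_params(),
                                  R_ref = 15, gamma = 1.61) {
  rw <- rw_probability(R, N, params) / rw_probability(R_ref, N, params)
  ig <- (R / R_ref)^gamma
  r2 <- rep(R, 2L)
  lab <- rep(c("RW", "ideal gas"), each = length(R))
  tibble::tibble(R = r2, reference = lab, ratio = c(rw, ig))
}
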