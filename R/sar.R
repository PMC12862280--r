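#' Simulate a spatially autocorrelated field (SAR)
#'
#' Draws one realization of the simultaneous-autoregressive model
#' \eqn{u = (I - \rho W)^{-1} \varepsilon}, \eqn{\varepsilon \sim N(0, 1)}
#' iid, with `W` the row-standardized contiguity matrix. At `rho = 0` the
#' field is the raw noise draw; as `rho` approaches 1 like values cluster
#' ever more strongly. The same weights object that parameterizes the
#' generator is the one the Moran statistics use downstream, which keeps
#' simulated autocorrelation directly interpretable.
#'
#' @param w a row-standardized (`style = "W"`) `spatial_weights`.
#' @param rho autocorrelation strength in `[0, 0.99]`; must stay strictly
#'   below 1 so the SAR inverse exists.
#' @param seed optional integer seed; with a seed the draw is deterministic
#'   and the caller's RNG stream is left untouched.
#' @return numeric vector with one finite value per tract.
#' @examples
#' w <- queen_weights(make_lattice(5, 5))
#' u <- sar_field(w, rho = 0.8, seed = 1)
#' @export
sar_field <- function(w, rho, seed = NULL) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style != "W") stop("`w` must be row-standardized (style \"W\")")
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho > 0.99)
    stop("`rho` must lie in [0, 0.99]")
  n <- w$n
  eps <- with_seed(seed, stats::rnorm(n))
  if (rho == 0) return(eps)
  A <- diag(n) - rho * weights_matrix(w)
  if (rcond(A) < .Machine$double.eps * 100)
    stop("(I - rho * W) is numerically singular")
  u <- solve(A, eps)
  if (any(!is.finite(u))) stop("SAR solve produced non-finite values")
  u
}
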