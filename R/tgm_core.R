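#' Truncated-Gaussian graphical model parameters
#'
#' Bundle a symmetric interaction matrix `Theta` and a linear vector `eta`
#' parameterizing the non-negative truncated-Gaussian density
#' \deqn{p(y) \propto \exp\{-\tfrac12 y^\top \Theta y + \eta^\top (y - 1_p)\}
#'       \, I(y \in \mathbb{R}_+^p).}
#' When `Theta` is positive definite this is the multivariate normal
#' \eqn{N(\Theta^{-1}\eta, \Theta^{-1})} restricted to the non-negative
#' orthant; nonzero off-diagonal entries of `Theta` encode conditional
#' dependence between coordinates.
#'
#' @param Theta symmetric numeric p x p matrix.
#' @param eta numeric vector of length p.
#' @return An object of class `tgm_params` with elements `Theta`, `eta`, `p`.
#' @export
tgm_params <- function(Theta, eta) {
  Theta <- as.matrix(Theta)
  p <- nrow(Theta)
  if (ncol(Theta) != p)
    stop("Theta must be square")
  if (length(eta) != p)
    stop("eta must have length nrow(Theta)")
  if (max(abs(Theta - t(Theta))) > 1e-10)
    stop("Theta must be symmetric (tolerance 1e-10)")
  structure(list(Theta = (Theta + t(Theta)) / 2, eta = as.numeric(eta), p = p),
            class = "tgm_params")
}

#' @export
print.tgm_params <- function(x, ...) {
  cat(sprintf("tgm_params: p = %d, %d nonzero off-diagonal entries\n",
              x$p, sum(x$Theta[upper.tri(x$Theta)] != 0) * 2L))
  invisible(x)
}

#' Unnormalized log-density of the truncated-Gaussian model
#'
#' Evaluates \eqn{-\tfrac12 y^\top \Theta y + \eta^\top(y - 1_p)} for
#' non-negative `y`, and `-Inf` for any `y` with a negative component
#' (the orthant indicator).
#'
#' @param y numeric vector of length p.
#' @param params a [tgm_params()] object.
#' @return A scalar, defined up to the additive log normalizing constant.
#' @export
log_density_unnorm <- function(y, params) {
  stopifnot(inherits(params, "tgm_params"))
  if (length(y) != params$p)
    stop("dimension mismatch: length(y) != p")
  if (any(y < 0)) return(-Inf)
  -0.5 * drop(crossprod(y, params$Theta %*% y)) + sum(params$eta * (y - 1))
}

#' Truncation weight for the score-matching loss
#'
#' The weight function is \eqn{h(y) = \min(y, C)} applied componentwise,
#' with derivative \eqn{h'(y) = 1} for \eqn{y < C} and 0 beyond the cap.
#' `h(0) = 0` makes the boundary term of the integration-by-parts identity
#' vanish on the non-negative orthant, and the cap `C` bounds the weight
#' for heavy right tails. `C = Inf` gives the uncapped weight `h(y) = y`.
#'
#' @param cap truncation constant C > 0 (may be `Inf`). Default 3, intended
#'   for data standardized to unit scale.
#' @return An object of class `h_weight`.
#' @export
h_weight <- function(cap = 3) {
  if (!is.numeric(cap) || length(cap) != 1 || is.na(cap) || cap <= 0)
    stop("cap must be a positive scalar (possibly Inf)")
  structure(list(cap = cap), class = "h_weight")
}

#' Evaluate the truncation weight and its derivative
#'
#' @param y non-negative numeric vector (or matrix).
#' @param hweight an [h_weight()] object.
#' @return List with components `h` and `hprime`, the same shape as `y`.
#' @export
h_eval <- function(y, hweight = h_weight()) {
  stopifnot(inherits(hweight, "h_weight"))
  if (any(y < 0)) stop("h_eval requires non-negative input")
  C <- hweight$cap
  list(h = pmin(y, C), hprime = (y < C) * 1)
}

.check_data_matrix <- function(Y, p = NULL) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y) || anyNA(Y) || any(!is.finite(Y)))
    stop("data matrix must be finite numeric without NA")
  if (any(Y < 0))
    stop("data matrix must be non-negative")
  if (!is.null(p) && ncol(Y) != p)
    stop("data matrix has ", ncol(Y), " columns but parameters have p = ", p)
  Y
}

#' Empirical generalized h-score matching loss
#'
#' The estimation loss for the truncated-Gaussian model: with residuals
#' \eqn{r_{ij} = (\Theta y_i)_j - \eta_j} and weights \eqn{h_{ij} = h(y_{ij})},
#' \deqn{\hat J = \frac1n \sum_i \sum_j \Big[ \tfrac12 h_{ij} r_{ij}^2
#'   - h'_{ij} r_{ij} - h_{ij}\,\theta_{jj} \Big].}
#' This is the integration-by-parts form of the h-weighted Hyvarinen score
#' objective, which avoids the intractable orthant normalizing constant and
#' is jointly quadratic (hence convex) in `(Theta, eta)`.
#'
#' @param Y n x p non-negative data matrix (rows are observations).
#' @param params a [tgm_params()] object.
#' @param hweight an [h_weight()] object.
#' @return Scalar loss value.
#' @export
sm_loss <- function(Y, params, hweight = h_weight()) {
  stopifnot(inherits(params, "tgm_params"))
  Y <- .check_data_matrix(Y, params$p)
  hw <- h_eval(Y, hweight)
  R <- Y %*% params$Theta - matrix(params$eta, nrow(Y), params$p, byrow = TRUE)
  bracket <- 0.5 * hw$h * R^2 - hw$hprime * R -
    hw$h * matrix(diag(params$Theta), nrow(Y), params$p, byrow = TRUE)
  sum(bracket) / nrow(Y)
}

#' Gradient of the score-matching loss
#'
#' Exact gradient of [sm_loss()] in the symmetric parameterization of
#' `Theta`: the partial with respect to an off-diagonal entry accumulates
#' both the (l,j) and (j,l) contributions, so `grad_Theta` is symmetric.
#'
#' @inheritParams sm_loss
#' @return List with `grad_Theta` (symmetric p x p) and `grad_eta` (length p).
#' @export
sm_loss_grad <- function(Y, params, hweight = h_weight()) {
  stopifnot(inherits(params, "tgm_params"))
  Y <- .check_data_matrix(Y, params$p)
  n <- nrow(Y)
  hw <- h_eval(Y, hweight)
  R <- Y %*% params$Theta - matrix(params$eta, n, params$p, byrow = TRUE)
  U <- hw$h * R - hw$hprime            # dJ/dr_{ij}
  G <- crossprod(U, Y) / n             # G[j, l] = dJ/dtheta[j, l], rows free
  diag(G) <- diag(G) - colMeans(hw$h)
  grad_Theta <- G + t(G)
  diag(grad_Theta) <- diag(G)          # diagonal entries appear once
  list(grad_Theta = grad_Theta, grad_eta = -colMeans(U))
}

#' Standardize a panel by pooled column standard deviations
#'
#' Each keyword column is divided by its standard deviation pooled over all
#' periods; no centering is applied, so non-negativity is preserved.
#' Constant columns (zero pooled SD) are left unscaled.
#'
#' @param panel a [panel_data()] object.
#' @return List with `panel` (rescaled) and `scale` (length-p divisors).
#' @export
standardize_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  pooled <- do.call(rbind, panel$matrices)
  s <- apply(pooled, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  out <- panel
  out$matrices <- lapply(panel$matrices, function(m) sweep(m, 2, s, "/"))
  list(panel = out, scale = s)
}
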