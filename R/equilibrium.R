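#' Closed-form coexistence equilibrium
#'
#' The untreated model has two equilibria: extinction (all zeros, unstable)
#' and a coexistence state in which phenotype transitions balance. The
#' coexistence abundances are
#' \deqn{x_i^* = K \frac{(1-\lambda)^{N-i} (1+\lambda)^{i-1}}
#'   {\sum_{j=1}^N (1-\lambda)^{N-j} (1+\lambda)^{j-1}},}
#' a (truncated) geometric profile with ratio \eqn{(1+\lambda)/(1-\lambda)}.
#' The components sum to K, and the distribution depends only on lambda and N
#' — not on the growth rates or the transition speed, as long as c > 0.
#'
#' For c = 0 there are no transitions and the long-run phenotype composition
#' depends on the initial condition, so the closed form does not apply and an
#' error is raised. The closed form assumes the reference model (all-ones
#' competition, epithelial-rate transition scaling).
#'
#' @param model a \code{\link{plasticity_model}} with transition_speed > 0.
#' @return Numeric vector of N equilibrium abundances summing to K.
#' @examples
#' coexistence_equilibrium(plasticity_model())                        # uniform
#' coexistence_equilibrium(plasticity_model(transition_bias = 0.5))   # (1,3,9)/13
#' @export
coexistence_equilibrium <- function(model) {
  stopifnot(inherits(model, "plasticity_model"))
  if (model$transition_speed <= 0) {
    stop("the coexistence equilibrium distribution is undefined for c = 0 ",
         "(no transitions: the composition depends on the initial condition)")
  }
  n <- model$n_phenotypes
  lam <- model$transition_bias
  i <- seq_len(n)
  w <- (1 - lam)^(n - i) * (1 + lam)^(i - 1)
  model$carrying_capacity * w / sum(w)
}

#' Summary moments of a phenotype distribution
#'
#' Summarizes an abundance vector on the E-M axis via trait scores
#' \eqn{s_i = (i-1)/(N-1)} (0 = most epithelial, 1 = most mesenchymal; for
#' N = 1, s = 0): the total abundance X, the frequencies \eqn{p_i = x_i / X},
#' and the mean, variance and third central moment of s under p. The [0, 1]
#' trait axis makes moments comparable across different N.
#'
#' @param abundances numeric vector of nonnegative abundances with positive sum.
#' @return An object of class \code{"distribution_summary"}: list with
#'   \code{total}, \code{frequencies}, \code{mean_trait}, \code{variance},
#'   \code{third_central_moment}.
#' @examples
#' distribution_moments(c(1, 1, 1) / 3)  # mean 0.5, variance 1/6, skewless
#' @export
distribution_moments <- function(abundances) {
  x <- as.numeric(abundances)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("abundances must be finite and nonnegative")
  }
  total <- sum(x)
  if (total <= 0) {
    stop("degenerate distribution: total abundance is zero")
  }
  n <- length(x)
  p <- x / total
  s <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  m <- sum(p * s)
  structure(
    list(
      total = total,
      frequencies = p,
      mean_trait = m,
      variance = sum(p * (s - m)^2),
      third_central_moment = sum(p * (s - m)^3)
    ),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("Phenotype distribution: X = %g over %d phenotypes\n",
              x$total, length(x$frequencies)))
  cat("  frequencies (E -> M):", format(x$frequencies, digits = 4), "\n")
  cat(sprintf("  mean trait %.4f | variance %.4f | third central moment %.4g\n",
              x$mean_trait, x$variance, x$third_central_moment))
  invisible(x)
}

#' Linear stability of an equilibrium point
#'
#' Evaluates the analytic Jacobian of the untreated model at a point and
#' reports its eigenvalues. The verdict is \code{"stable"} when the largest
#' real part is below \code{-tol}, \code{"unstable"} when above \code{+tol},
#' and \code{"marginal"} inside the band. For the reference model the
#' coexistence equilibrium is stable and the extinction state (origin) is
#' unstable, so an untreated tumor always progresses.
#'
#' @param model a \code{\link{plasticity_model}}.
#' @param point numeric vector of N abundances; defaults to the coexistence
#'   equilibrium.
#' @param tol verdict tolerance on the spectral abscissa (default 1e-9).
#' @return An object of class \code{"stability_report"}: list with
#'   \code{equilibrium_point}, \code{eigenvalues} (complex),
#'   \code{max_real_part}, \code{verdict}.
#' @examples
#' stability_report(plasticity_model())                    # stable
#' stability_report(plasticity_model(), point = c(0, 0, 0)) # unstable
#' @export
stability_report <- function(model, point = NULL, tol = 1e-9) {
  stopifnot(inherits(model, "plasticity_model"))
  if (is.null(point)) point <- coexistence_equilibrium(model)
  stopifnot(length(point) == model$n_phenotypes)
  J <- phenotype_jacobian(point, model, treatment = "none")
  ev <- eigen(J, only.values = TRUE)$values
  mx <- max(Re(ev))
  verdict <- if (mx < -tol) "stable" else if (mx > tol) "unstable" else "marginal"
  structure(
    list(equilibrium_point = point, eigenvalues = ev,
         max_real_part = mx, verdict = verdict),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Linear stability report\n")
  cat("  point:", format(x$equilibrium_point, digits = 6), "\n")
  cat("  eigenvalue real parts:", format(Re(x$eigenvalues), digits = 4), "\n")
  cat(sprintf("  max real part: %.6g -> %s\n", x$max_real_part, x$verdict))
  invisible(x)
}

#' Treatment decision boundary in the transition bias
#'
#' At the coexistence equilibrium \eqn{x^*(\lambda)}, growth-dependent
#' treatment kills at total rate \eqn{\sum_i m_D r_i x_i^*} and
#' growth-independent treatment at \eqn{\sum_i m_I x_i^*}. The boundary
#' \eqn{\tilde\lambda} is the root in [-1, 1] of
#' \deqn{f(\lambda) = \sum_i (m_D r_i - m_I)\, x_i^*(\lambda),}
#' a low-degree polynomial in lambda: for more epithelial tumors
#' (\eqn{\lambda < \tilde\lambda}) growth-dependent treatment exerts the
#' higher instantaneous mortality, for more mesenchymal tumors
#' (\eqn{\lambda > \tilde\lambda}) growth-independent does.
#'
#' The root is located by sign-change bracketing on a lambda grid and polished
#' by bisection until \eqn{|f| < 10^{-12}}. If f has no sign change on
#' [-1, 1], one treatment dominates for every bias and \code{NA} is returned.
#' Multiple sign changes (not expected: f is a monotone weighted mean of the
#' growth ladder minus a constant) raise an error listing all roots.
#'
#' @param model a \code{\link{plasticity_model}} with c > 0 and a set (or
#'   calibratable) mI. If \code{model$mI} is \code{NULL} it is calibrated
#'   first via \code{\link{calibrate_mI}} with a message.
#' @param grid_size number of lambda grid points for bracketing (default 1001).
#' @return The root lambda-tilde in [-1, 1], or \code{NA_real_} when one
#'   treatment dominates throughout.
#' @examples
#' m <- plasticity_model(mI = 0.6475)
#' decision_boundary(m)  # about -0.089
#' @export
decision_boundary <- function(model, grid_size = 1001L) {
  stopifnot(inherits(model, "plasticity_model"))
  if (model$transition_speed <= 0) {
    stop("decision boundary requires c > 0 (equilibrium distribution defined)")
  }
  if (is.null(model$mI)) {
    message("model$mI not set; calibrating against growth-dependent treatment")
    model$mI <- calibrate_mI(model)
  }
  if (model$mD <= 0 && model$mI <= 0) {
    stop("decision boundary requires mD > 0 or mI > 0")
  }
  r <- growth_rates(model)
  f <- function(lam) {
    eq <- coexistence_equilibrium(update_model(model, transition_bias = lam))
    sum((model$mD * r - model$mI) * eq)
  }
  grid <- seq(-1, 1, length.out = grid_size)
  fv <- vapply(grid, f, numeric(1))
  # exact zeros on the grid count as roots; otherwise bracket sign changes
  roots <- grid[fv == 0]
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (k in idx) {
    lo <- grid[k]; hi <- grid[k + 1L]
    flo <- fv[k]
    # bisection to |f| < 1e-12 (f is smooth and low-degree)
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < 1e-12) break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, mid)
  }
  roots <- unique(roots)
  if (length(roots) == 0L) return(NA_real_)
  if (length(roots) > 1L) {
    stop("ambiguous decision boundary: multiple roots found at lambda = ",
         paste(format(roots, digits = 8), collapse = ", "))
  }
  roots
}
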