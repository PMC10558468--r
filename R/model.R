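#' Construct a phenotypic-plasticity population model
#'
#' Builds the parameter object for an N-compartment model of a tumor cell
#' population distributed along the epithelial-mesenchymal (E-M) axis.
#' Compartment 1 is the most epithelial phenotype (fastest growth), compartment
#' N the most mesenchymal (slowest growth). All compartments grow logistically
#' under a shared carrying capacity and exchange cells with their nearest
#' neighbours on the axis at rates set by the transition speed \code{c} and the
#' transition bias \code{lambda}.
#'
#' The per-phenotype growth rates decrease linearly from \code{r1} to
#' \code{rN}; see \code{\link{growth_rates}}. Mesenchymal-ward transitions
#' (i to i+1) occur at rate \eqn{c (1+\lambda) r_1} and epithelial-ward
#' transitions (i to i-1) at rate \eqn{c (1-\lambda) r_1}; see
#' \code{\link{transition_rates}}.
#'
#' Two optional variant hooks generalize the reference model. A
#' \code{competition_matrix} \eqn{\alpha} replaces the shared competition load
#' \eqn{X = \sum_j x_j} on phenotype i by \eqn{\sum_j \alpha_{ij} x_j}; the
#' all-ones default recovers the shared-K model exactly.
#' \code{transition_scaling = "own_rate"} replaces the \eqn{r_1} prefactor of a
#' phenotype's outgoing transitions by its own growth rate \eqn{r_i}. The
#' closed-form equilibrium and decision boundary assume the reference model
#' (all-ones competition, epithelial-rate scaling).
#'
#' @param n_phenotypes integer, number of phenotype compartments N (>= 1).
#' @param r1 growth rate of the epithelial phenotype (per unit time; the model
#'   time unit). Must satisfy 0 < rN <= r1.
#' @param rN growth rate of the mesenchymal phenotype (per unit time).
#' @param carrying_capacity shared carrying capacity K (abundance units, > 0).
#' @param transition_speed transition speed c >= 0, the scale of phenotype
#'   transitions relative to epithelial growth; c > 1 means transitions outpace
#'   proliferation.
#' @param transition_bias transition bias lambda in [-1, 1]; positive favors
#'   mesenchymal-ward transitions, negative epithelial-ward.
#' @param mD growth-dependent (chemotherapy-like) treatment intensity,
#'   a dimensionless multiplier on each phenotype's growth rate (>= 0).
#' @param mI growth-independent (immunotherapy-like) treatment intensity
#'   (per unit time, >= 0), or \code{NULL} if not yet calibrated; see
#'   \code{\link{calibrate_mI}}.
#' @param competition_matrix optional N x N matrix of nonnegative competition
#'   coefficients; \code{NULL} (default) means all ones.
#' @param transition_scaling \code{"epithelial_rate"} (default) or
#'   \code{"own_rate"}; see Details.
#'
#' @return An object of class \code{"plasticity_model"}: a list with the
#'   validated parameters.
#' @examples
#' m <- plasticity_model()
#' growth_rates(m)
#' coexistence_equilibrium(m)
#' @export
plasticity_model <- function(n_phenotypes = 3L,
                             r1 = 1,
                             rN = 1 / 5,
                             carrying_capacity = 1,
                             transition_speed = 1,
                             transition_bias = 0,
                             mD = 1,
                             mI = NULL,
                             competition_matrix = NULL,
                             transition_scaling = c("epithelial_rate", "own_rate")) {
  transition_scaling <- match.arg(transition_scaling)
  n_phenotypes <- as.integer(n_phenotypes)
  stopifnot(
    length(n_phenotypes) == 1L, n_phenotypes >= 1L,
    length(r1) == 1L, length(rN) == 1L, is.finite(r1), is.finite(rN)
  )
  if (!(rN > 0 && rN <= r1)) {
    stop("growth rates must satisfy 0 < rN <= r1 (got rN = ", rN,
         ", r1 = ", r1, ")")
  }
  if (!(is.finite(carrying_capacity) && carrying_capacity > 0)) {
    stop("carrying_capacity must be > 0")
  }
  if (!(is.finite(transition_speed) && transition_speed >= 0)) {
    stop("transition_speed must be >= 0")
  }
  if (!(is.finite(transition_bias) &&
        transition_bias >= -1 && transition_bias <= 1)) {
    stop("transition_bias must lie in [-1, 1] (got ", transition_bias, ")")
  }
  if (!(is.finite(mD) && mD >= 0)) stop("mD must be >= 0")
  if (!is.null(mI) && !(is.finite(mI) && mI >= 0)) {
    stop("mI must be >= 0 (or NULL before calibration)")
  }
  if (!is.null(competition_matrix)) {
    competition_matrix <- as.matrix(competition_matrix)
    if (!all(dim(competition_matrix) == n_phenotypes)) {
      stop("competition_matrix must be ", n_phenotypes, " x ", n_phenotypes)
    }
    if (any(!is.finite(competition_matrix)) || any(competition_matrix < 0)) {
      stop("competition_matrix entries must be finite and >= 0")
    }
  }
  structure(
    list(
      n_phenotypes = n_phenotypes,
      r1 = r1,
      rN = rN,
      carrying_capacity = carrying_capacity,
      transition_speed = transition_speed,
      transition_bias = transition_bias,
      mD = mD,
      mI = mI,
      competition_matrix = competition_matrix,
      transition_scaling = transition_scaling
    ),
    class = "plasticity_model"
  )
}

#' Modify parameters of a plasticity model
#'
#' Returns a copy of the model with the named parameters replaced and all
#' invariants re-validated.
#'
#' @param model a \code{\link{plasticity_model}}.
#' @param ... named arguments accepted by \code{\link{plasticity_model}}.
#' @return A new \code{plasticity_model}.
#' @examples
#' m <- plasticity_model()
#' update_model(m, transition_bias = 0.5)
#' @export
update_model <- function(model, ...) {
  stopifnot(inherits(model, "plasticity_model"))
  args <- utils::modifyList(unclass(model), list(...), keep.null = TRUE)
  do.call(plasticity_model, args)
}

#' Per-phenotype growth rates
#'
#' The growth-rate ladder decreases linearly from the epithelial rate
#' \eqn{r_1} to the mesenchymal rate \eqn{r_N}:
#' \eqn{r_i = r_1 - (r_1 - r_N)(i-1)/(N-1)}. For N = 1 the single rate is
#' \eqn{r_1}.
#'
#' @param model a \code{\link{plasticity_model}}.
#' @return Numeric vector of N non-increasing rates (per unit time).
#' @examples
#' growth_rates(plasticity_model())  # 1, 0.6, 0.2
#' @export
growth_rates <- function(model) {
  stopifnot(inherits(model, "plasticity_model"))
  n <- model$n_phenotypes
  if (n == 1L) return(model$r1)
  model$r1 - (model$r1 - model$rN) * (seq_len(n) - 1) / (n - 1)
}

#' Phenotype transition rates
#'
#' The mesenchymal-ward rate \eqn{T_{EM} = c (1+\lambda) r_1} and the
#' epithelial-ward rate \eqn{T_{ME} = c (1-\lambda) r_1}.
#'
#' @param model a \code{\link{plasticity_model}}.
#' @return Named numeric vector \code{c(T_EM = , T_ME = )} (per unit time).
#' @examples
#' transition_rates(plasticity_model(transition_speed = 2, transition_bias = 0.5))
#' @export
transition_rates <- function(model) {
  stopifnot(inherits(model, "plasticity_model"))
  cc <- model$transition_speed
  lam <- model$transition_bias
  c(T_EM = cc * (1 + lam) * model$r1, T_ME = cc * (1 - lam) * model$r1)
}

# Effective (mD, mI) intensities for a treatment kind.
treatment_intensities <- function(model, kind) {
  switch(kind,
    none = c(mD = 0, mI = 0),
    growth_dependent = c(mD = model$mD, mI = 0),
    growth_independent = {
      if (is.null(model$mI)) {
        stop("model$mI is not set; calibrate it first (see calibrate_mI)")
      }
      c(mD = 0, mI = model$mI)
    },
    stop("unknown treatment kind: ", kind)
  )
}

# Per-phenotype transition prefactors: the rate scale of a phenotype's
# outgoing transitions (r1 for the reference model, r_i for the variant).
transition_prefactors <- function(model) {
  if (model$transition_scaling == "own_rate") {
    growth_rates(model)
  } else {
    rep(model$r1, model$n_phenotypes)
  }
}

#' Right-hand side of the plasticity model ODE
#'
#' Time derivative of the phenotype abundances: logistic growth under the
#' shared carrying capacity, nearest-neighbour phenotype transitions, and
#' treatment mortality,
#' \deqn{\dot x_i = r_i x_i (1 - X/K)
#'   + c r_1 [(1+\lambda) x_{i-1} + (1-\lambda) x_{i+1} - 2 x_i]
#'   - (m_D r_i + m_I) x_i,}
#' with one-sided transition terms in the terminal compartments (i = 1 and
#' i = N have a single neighbour each). Transitions conserve total abundance.
#'
#' @param x numeric vector of N nonnegative abundances.
#' @param model a \code{\link{plasticity_model}}.
#' @param treatment one of \code{"none"}, \code{"growth_dependent"},
#'   \code{"growth_independent"}: which treatment is active, selecting the
#'   effective intensities (0, 0), (mD, 0) or (0, mI).
#' @return Numeric vector of N time derivatives.
#' @examples
#' m <- plasticity_model()
#' phenotype_rhs(c(1, 0, 0), m)         # growth term vanishes at X = K
#' phenotype_rhs(coexistence_equilibrium(m), m)  # ~ zero at the fixed point
#' @export
phenotype_rhs <- function(x, model, treatment = "none") {
  stopifnot(inherits(model, "plasticity_model"))
  n <- model$n_phenotypes
  if (length(x) != n) {
    stop("state has length ", length(x), " but the model has ", n,
         " phenotypes")
  }
  r <- growth_rates(model)
  K <- model$carrying_capacity
  load <- if (is.null(model$competition_matrix)) {
    rep(sum(x), n)
  } else {
    as.numeric(model$competition_matrix %*% x)
  }
  dx <- r * x * (1 - load / K)
  if (n > 1L && model$transition_speed > 0) {
    cc <- model$transition_speed
    lam <- model$transition_bias
    rho <- transition_prefactors(model)
    i <- seq_len(n - 1L)
    f_up <- cc * (1 + lam) * rho[i] * x[i]          # flux i -> i + 1
    f_dn <- cc * (1 - lam) * rho[i + 1L] * x[i + 1L] # flux i + 1 -> i
    dx[i] <- dx[i] - f_up + f_dn
    dx[i + 1L] <- dx[i + 1L] + f_up - f_dn
  }
  mm <- treatment_intensities(model, treatment)
  dx - (mm[["mD"]] * r + mm[["mI"]]) * x
}

#' Analytic Jacobian of the plasticity model ODE
#'
#' Entries \eqn{\partial \dot x_i / \partial x_j} at a state: the growth and
#' competition derivatives
#' \eqn{\delta_{ij} r_i (1 - L_i/K) - r_i x_i \alpha_{ij} / K}
#' (with \eqn{L_i} the competition load on phenotype i), the constant linear
#' transition operator, and the diagonal treatment mortality.
#'
#' @inheritParams phenotype_rhs
#' @return N x N numeric matrix.
#' @export
phenotype_jacobian <- function(x, model, treatment = "none") {
  stopifnot(inherits(model, "plasticity_model"))
  n <- model$n_phenotypes
  stopifnot(length(x) == n)
  r <- growth_rates(model)
  K <- model$carrying_capacity
  alpha <- if (is.null(model$competition_matrix)) {
    matrix(1, n, n)
  } else {
    model$competition_matrix
  }
  load <- as.numeric(alpha %*% x)
  J <- -(r * x / K) * alpha            # row i scaled by r_i x_i / K
  diag(J) <- diag(J) + r * (1 - load / K)
  if (n > 1L && model$transition_speed > 0) {
    cc <- model$transition_speed
    lam <- model$transition_bias
    rho <- transition_prefactors(model)
    up <- cc * (1 + lam) * rho   # outgoing i -> i+1 rate per unit x_i
    dn <- cc * (1 - lam) * rho   # outgoing i -> i-1 rate per unit x_i
    Tm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      if (i < n) {
        Tm[i, i] <- Tm[i, i] - up[i]
        Tm[i + 1L, i] <- Tm[i + 1L, i] + up[i]
      }
      if (i > 1L) {
        Tm[i, i] <- Tm[i, i] - dn[i]
        Tm[i - 1L, i] <- Tm[i - 1L, i] + dn[i]
      }
    }
    J <- J + Tm
  }
  mm <- treatment_intensities(model, treatment)
  diag(J) <- diag(J) - (mm[["mD"]] * r + mm[["mI"]])
  J
}

#' @export
print.plasticity_model <- function(x, ...) {
  cat("Phenotypic-plasticity population model\n")
  cat(sprintf("  phenotypes (E -> M):  N = %d\n", x$n_phenotypes))
  cat(sprintf("  growth rates:         r1 = %g, rN = %g (linear ladder)\n",
              x$r1, x$rN))
  cat(sprintf("  carrying capacity:    K = %g\n", x$carrying_capacity))
  cat(sprintf("  transitions:          c = %g, lambda = %g  (T_EM = %g, T_ME = %g)\n",
              x$transition_speed, x$transition_bias,
              transition_rates(x)[["T_EM"]], transition_rates(x)[["T_ME"]]))
  cat(sprintf("  treatment intensity:  mD = %g, mI = %s\n", x$mD,
              if (is.null(x$mI)) "<uncalibrated>" else format(x$mI)))
  if (!is.null(x$competition_matrix)) {
    cat("  variant: custom competition matrix\n")
  }
  if (x$transition_scaling == "own_rate") {
    cat("  variant: transitions scaled by each phenotype's own growth rate\n")
  }
  invisible(x)
}

#' @export
coef.plasticity_model <- function(object, ...) {
  c(N = object$n_phenotypes, r1 = object$r1, rN = object$rN,
    K = object$carrying_capacity, c = object$transition_speed,
    lambda = object$transition_bias, mD = object$mD,
    mI = if (is.null(object$mI)) NA_real_ else object$mI)
}

#' @export
summary.plasticity_model <- function(object, ...) {
  print(object)
  if (object$transition_speed > 0) {
    eq <- coexistence_equilibrium(object)
    mom <- distribution_moments(eq)
    cat("\nCoexistence equilibrium (abundances, E -> M):\n  ")
    cat(format(eq, digits = 6), sep = "  ")
    cat(sprintf("\n  mean trait %.4f, variance %.4f, third central moment %.4g\n",
                mom$mean_trait, mom$variance, mom$third_central_moment))
  } else {
    cat("\nc = 0: no phenotype transitions; equilibrium distribution depends",
        "on the initial condition.\n")
  }
  invisible(object)
}
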