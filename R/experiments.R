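#' Scenario initial conditions
#'
#' Standard initial conditions for the study scenarios:
#' \describe{
#'   \item{primary_site}{a tumor founded by epithelial cells only:
#'     (K/10, 0, ..., 0).}
#'   \item{secondary_site}{a metastasis founded by mesenchymal cells that
#'     disseminated from the primary site: (0, ..., 0, K/10).}
#'   \item{ablate_E / ablate_H / ablate_M}{the coexistence equilibrium with
#'     the epithelial / hybrid / mesenchymal compartment emptied, emulating a
#'     phenotype-targeted ablation (hybrid ablation requires N = 3; pass
#'     \code{index} for other N).}
#'   \item{equilibrium}{the coexistence equilibrium itself.}
#' }
#'
#' @param kind scenario name (see Description).
#' @param model a \code{\link{plasticity_model}}.
#' @param index phenotype index to ablate (defaults to 1, (N+1)/2, N for
#'   ablate_E, ablate_H, ablate_M).
#' @return Numeric vector of N initial abundances.
#' @examples
#' scenario_initial_condition("primary_site", plasticity_model())  # (0.1, 0, 0)
#' @export
scenario_initial_condition <- function(kind = c("primary_site",
                                                "secondary_site",
                                                "ablate_E", "ablate_H",
                                                "ablate_M", "equilibrium"),
                                       model, index = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "plasticity_model"))
  n <- model$n_phenotypes
  K <- model$carrying_capacity
  if (kind == "primary_site") {
    x0 <- numeric(n); x0[1L] <- K / 10
    return(x0)
  }
  if (kind == "secondary_site") {
    x0 <- numeric(n); x0[n] <- K / 10
    return(x0)
  }
  eq <- coexistence_equilibrium(model)
  if (kind == "equilibrium") return(eq)
  if (is.null(index)) {
    index <- switch(kind, ablate_E = 1L, ablate_M = n,
                    ablate_H = {
                      if (n != 3L) {
                        stop("ablate_H needs N = 3 or an explicit index")
                      }
                      2L
                    })
  }
  if (index < 1L || index > n) stop("ablation index out of range")
  eq[index] <- 0
  eq
}

#' Burden-reduction sweep over transition bias and speed
#'
#' For every cell of a (lambda, c) grid: sets the model's transition
#' parameters, starts from the coexistence equilibrium at those parameters
#' (the tumor's phenotype distribution is assumed equilibrated before
#' treatment), applies the scheme's schedule, and records the burden
#' reduction \eqn{(K - X)/K} at the end of the treatment duration. For
#' adaptive schemes the resolved per-block treatment sequence is recorded
#' per cell.
#'
#' Default grids: 41 evenly spaced biases in [-1, 1] and 25 logarithmically
#' spaced speeds in [1e-2, 1e2], spanning the slow- and fast-transition
#' regimes; both fully configurable.
#'
#' @param model a \code{\link{plasticity_model}} (with mI set for schemes
#'   using growth-independent treatment).
#' @param scheme scheme name for \code{\link{build_schedule}}.
#' @param n_blocks number of blocks.
#' @param lambda_grid vector of transition biases in [-1, 1].
#' @param c_grid vector of positive transition speeds.
#' @param duration treatment duration (default 10).
#' @param dt output resolution passed to the simulator.
#' @return An object of class \code{"sweep_result"}: list with
#'   \code{lambda_grid}, \code{c_grid}, \code{scheme}, \code{n_blocks},
#'   \code{reduction} (c-by-lambda matrix), \code{resolved_sequences}
#'   (character matrix, adaptive schemes only).
#' @export
sweep_burden_reduction <- function(model, scheme, n_blocks = 1L,
                                   lambda_grid = seq(-1, 1,
                                                     length.out = 41L),
                                   c_grid = 10^seq(-2, 2,
                                                   length.out = 25L),
                                   duration = 10, dt = 0.5) {
  stopifnot(inherits(model, "plasticity_model"), all(c_grid > 0),
            all(lambda_grid >= -1 & lambda_grid <= 1))
  sched <- build_schedule(scheme, n_blocks = n_blocks, duration = duration)
  red <- matrix(NA_real_, length(c_grid), length(lambda_grid),
                dimnames = list(format(c_grid, digits = 4),
                                format(lambda_grid, digits = 4)))
  seqs <- if (scheme == "adaptive") {
    matrix(NA_character_, length(c_grid), length(lambda_grid),
           dimnames = dimnames(red))
  } else {
    NULL
  }
  for (i in seq_along(c_grid)) {
    for (j in seq_along(lambda_grid)) {
      mm <- update_model(model, transition_speed = c_grid[i],
                         transition_bias = lambda_grid[j])
      traj <- tryCatch(
        simulate(mm, x0 = coexistence_equilibrium(mm), schedule = sched,
                 horizon = duration, dt = dt),
        error = function(e) {
          stop("sweep cell (c = ", c_grid[i], ", lambda = ",
               lambda_grid[j], ") failed: ", conditionMessage(e))
        }
      )
      red[i, j] <- burden_reduction(traj, at_time = duration)
      if (!is.null(seqs)) {
        seqs[i, j] <- paste(traj$schedule_applied$kind_resolved,
                            collapse = ">")
      }
    }
  }
  structure(
    list(lambda_grid = lambda_grid, c_grid = c_grid, scheme = scheme,
         n_blocks = n_blocks, reduction = red, resolved_sequences = seqs),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Burden-reduction sweep: scheme %s (%d block(s)), %d x %d grid\n",
              x$scheme, x$n_blocks, length(x$c_grid), length(x$lambda_grid)))
  cat(sprintf("  reduction range: [%.4f, %.4f]\n",
              min(x$reduction), max(x$reduction)))
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  grid <- expand.grid(c = x$c_grid, lambda = x$lambda_grid,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(lambda = grid$lambda, c = grid$c, scheme = x$scheme,
                    n_blocks = x$n_blocks,
                    reduction = as.vector(x$reduction),
                    sequence = if (is.null(x$resolved_sequences)) {
                      NA_character_
                    } else {
                      as.vector(x$resolved_sequences)
                    },
                    stringsAsFactors = FALSE)
  out[order(out$lambda, out$c), , drop = FALSE]
}

#' Effect of an adjuvant transition-modulating shift
#'
#' An adjuvant (transition-modulating) intervention is represented as a shift
#' of the transition bias and/or speed applied before and during treatment:
#' the shifted run re-equilibrates its initial condition at the shifted
#' parameters and then receives the same treatment scheme. Compares burden
#' reductions with and without the shift.
#'
#' @param model baseline \code{\link{plasticity_model}}.
#' @param delta_lambda shift of the transition bias (shifted value must stay
#'   in [-1, 1]).
#' @param delta_c shift of the transition speed (shifted value must stay
#'   positive).
#' @param scheme,n_blocks,duration treatment scheme as in
#'   \code{\link{sweep_burden_reduction}}.
#' @param dt output resolution.
#' @return List with \code{baseline_reduction}, \code{shifted_reduction},
#'   \code{improvement} (shifted minus baseline).
#' @export
adjuvant_shift <- function(model, delta_lambda = 0, delta_c = 0,
                           scheme = "single_GD", n_blocks = 1L,
                           duration = 10, dt = 0.5) {
  stopifnot(inherits(model, "plasticity_model"))
  lam2 <- model$transition_bias + delta_lambda
  c2 <- model$transition_speed + delta_c
  if (lam2 < -1 || lam2 > 1) {
    stop("shifted transition bias ", lam2, " is outside [-1, 1]")
  }
  if (c2 <= 0) stop("shifted transition speed ", c2, " must be positive")
  sched <- build_schedule(scheme, n_blocks = n_blocks, duration = duration)
  one <- function(m) {
    traj <- simulate(m, x0 = coexistence_equilibrium(m), schedule = sched,
                     horizon = duration, dt = dt)
    burden_reduction(traj, at_time = duration)
  }
  base <- one(model)
  shifted <- one(update_model(model, transition_bias = lam2,
                              transition_speed = c2))
  list(baseline_reduction = base, shifted_reduction = shifted,
       improvement = shifted - base)
}
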