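#' Construct a treatment schedule
#'
#' A schedule is an ordered set of contiguous, non-overlapping treatment
#' blocks tiling [0, duration]. Each block carries one treatment kind:
#' \code{"growth_dependent"}, \code{"growth_independent"}, \code{"adaptive"}
#' (kind resolved at block start during simulation) or \code{"none"}.
#'
#' @param blocks data frame with columns \code{start}, \code{end},
#'   \code{kind}.
#' @return An object of class \code{"treatment_schedule"}.
#' @seealso \code{\link{build_schedule}} for the standard schemes.
#' @export
treatment_schedule <- function(blocks) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("start", "end", "kind") %in% names(blocks)),
            nrow(blocks) >= 1L)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  kinds <- c("growth_dependent", "growth_independent", "adaptive", "none")
  if (!all(blocks$kind %in% kinds)) {
    stop("block kinds must be one of: ", paste(kinds, collapse = ", "))
  }
  if (any(blocks$start >= blocks$end)) stop("each block needs start < end")
  if (nrow(blocks) > 1L) {
    gaps <- blocks$start[-1L] - blocks$end[-nrow(blocks)]
    if (any(abs(gaps) > 1e-12)) {
      stop("blocks must be contiguous and non-overlapping")
    }
  }
  if (abs(blocks$start[1L]) > 1e-12) stop("the first block must start at 0")
  structure(list(blocks = blocks, duration = blocks$end[nrow(blocks)]),
            class = "treatment_schedule")
}

#' Build a standard treatment schedule
#'
#' The schemes studied here split a fixed treatment duration (default 10 time
#' units) into \code{n_blocks} equal blocks:
#' \describe{
#'   \item{single_GD / single_GI}{one block of growth-dependent /
#'     growth-independent treatment (requires \code{n_blocks = 1}).}
#'   \item{alternating_GD_first / alternating_GI_first}{blocks alternate
#'     between the two types, starting with the named one.}
#'   \item{adaptive}{every block's type is chosen at its start, picking the
#'     type with the higher instantaneous mortality on the current state
#'     (\code{\link{adaptive_choice}}).}
#'   \item{none}{no treatment (convenience for untreated runs).}
#' }
#'
#' @param scheme scheme name (see Description).
#' @param n_blocks integer >= 1, number of equal-length blocks.
#' @param duration total treatment duration (time units, default 10).
#' @return A \code{\link{treatment_schedule}}.
#' @examples
#' build_schedule("alternating_GD_first", n_blocks = 2)
#' @export
build_schedule <- function(scheme = c("single_GD", "single_GI",
                                      "alternating_GD_first",
                                      "alternating_GI_first",
                                      "adaptive", "none"),
                           n_blocks = 1L, duration = 10) {
  scheme <- match.arg(scheme)
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1L, duration > 0)
  if (scheme %in% c("single_GD", "single_GI") && n_blocks > 1L) {
    stop("single-block schemes require n_blocks = 1 (got ", n_blocks, ")")
  }
  edges <- seq(0, duration, length.out = n_blocks + 1L)
  kind <- switch(scheme,
    single_GD = "growth_dependent",
    single_GI = "growth_independent",
    alternating_GD_first = rep_len(c("growth_dependent", "growth_independent"),
                                   n_blocks),
    alternating_GI_first = rep_len(c("growth_independent", "growth_dependent"),
                                   n_blocks),
    adaptive = "adaptive",
    none = "none"
  )
  treatment_schedule(data.frame(
    start = edges[-length(edges)],
    end = edges[-1L],
    kind = rep_len(kind, n_blocks),
    stringsAsFactors = FALSE
  ))
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("Treatment schedule: %d block(s) over [0, %g]\n",
              nrow(x$blocks), x$duration))
  print(x$blocks)
  invisible(x)
}

#' Instantaneous treatment mortality
#'
#' The total death flux a treatment type exerts on a state: growth-dependent
#' treatment kills at \eqn{\sum_i m_D r_i x_i} (faster-growing, more
#' epithelial phenotypes suffer more), growth-independent treatment at
#' \eqn{\sum_i m_I x_i} (all phenotypes equally).
#'
#' @param x numeric vector of nonnegative abundances.
#' @param model a \code{\link{plasticity_model}}.
#' @param kind \code{"growth_dependent"}, \code{"growth_independent"} or
#'   \code{"none"}.
#' @return Total death flux (abundance per unit time).
#' @examples
#' m <- plasticity_model(mI = 0.64)
#' instantaneous_mortality(rep(1 / 3, 3), m, "growth_dependent")  # 0.6
#' @export
instantaneous_mortality <- function(x, model,
                                    kind = c("growth_dependent",
                                             "growth_independent", "none")) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "plasticity_model"),
            length(x) == model$n_phenotypes, all(x >= 0))
  if (kind == "none") return(0)
  mm <- treatment_intensities(model, kind)
  sum((mm[["mD"]] * growth_rates(model) + mm[["mI"]]) * x)
}

#' Adaptive treatment-type choice
#'
#' Picks the treatment type with the higher instantaneous mortality on the
#' given phenotype distribution. Growth-dependent treatment is favored for
#' epithelial-dominated states, growth-independent for mesenchymal-dominated
#' ones. Exact ties resolve to growth-dependent (deterministic tie-break for
#' a measure-zero case).
#'
#' @inheritParams instantaneous_mortality
#' @return \code{"growth_dependent"} or \code{"growth_independent"}.
#' @export
adaptive_choice <- function(x, model) {
  stopifnot(inherits(model, "plasticity_model"))
  if (sum(x) <= 0) stop("adaptive choice undefined for an all-zero state")
  gd <- instantaneous_mortality(x, model, "growth_dependent")
  gi <- instantaneous_mortality(x, model, "growth_independent")
  if (gd >= gi) "growth_dependent" else "growth_independent"
}

#' Calibrate the growth-independent treatment intensity
#'
#' Finds the intensity \eqn{m_I} at which a single block of
#' growth-independent treatment reduces the tumor exactly as much as a single
#' block of growth-dependent treatment at the model's \eqn{m_D}: both runs
#' start from the coexistence equilibrium of the calibration model
#' (c = 1, lambda = 0, other parameters as given) and are integrated over the
#' treatment duration; the endpoint totals X(duration) are matched by root
#' finding on the monotone gap \eqn{X_{GI}(m_I) - X_{GD}}, bracketed on
#' \eqn{[0, 10\, m_D r_1]} and solved by bisection to a residual below
#' \code{match_tol}.
#'
#' Calibration makes the two treatment types comparable: differences in
#' outcome across transition bias and speed then reflect phenotype matching,
#' not raw dose.
#'
#' @param model a \code{\link{plasticity_model}}; its mD, growth ladder and K
#'   are used. Transition parameters are forced to the calibration point
#'   c = 1, lambda = 0.
#' @param duration treatment duration (default 10 time units).
#' @param match_tol required endpoint-abundance match (default 1e-8).
#' @return The calibrated intensity mI (per unit time).
#' @examples
#' \donttest{calibrate_mI(plasticity_model())  # about 0.647}
#' @export
calibrate_mI <- function(model, duration = 10, match_tol = 1e-8) {
  stopifnot(inherits(model, "plasticity_model"), duration > 0)
  if (model$mD == 0) return(0)
  cal <- update_model(model, transition_speed = 1, transition_bias = 0,
                      mI = NULL)
  x0 <- coexistence_equilibrium(cal)
  end_total <- function(kind, mI) {
    m <- update_model(cal, mI = mI)
    sched <- treatment_schedule(data.frame(start = 0, end = duration,
                                           kind = kind))
    traj <- simulate(m, x0 = x0, schedule = sched, horizon = duration,
                     dt = duration, rtol = 1e-10, atol = 1e-12)
    sum(traj$states[nrow(traj$states), ])
  }
  target <- end_total("growth_dependent", mI = 0)
  gap <- function(mI) end_total("growth_independent", mI) - target
  hi <- 10 * model$mD * model$r1
  g0 <- gap(0)
  ghi <- gap(hi)
  if (g0 < 0 || ghi > 0) {
    stop("calibration failed: no sign change of the endpoint gap on [0, ",
         hi, "]")
  }
  root <- stats::uniroot(gap, c(0, hi), f.lower = g0, f.upper = ghi,
                         tol = 1e-12)$root
  if (abs(gap(root)) > match_tol) {
    stop("calibration did not reach the required endpoint match (residual ",
         format(abs(gap(root))), ")")
  }
  root
}
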