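#' Simulate the plasticity model over a treatment schedule
#'
#' Integrates the model ODE piecewise over the blocks of a treatment
#' schedule, restarting the integrator at every block boundary so intensity
#' switches are exact, and continues untreated from the end of the schedule
#' to the horizon. Blocks of kind \code{"adaptive"} resolve their treatment
#' type at block start from the current state via
#' \code{\link{adaptive_choice}}.
#'
#' Integration uses a stiff-capable adaptive-step solver (\code{deSolve}'s
#' \code{lsoda}) with tight default tolerances; the system is small and
#' smooth, so tight tolerances are cheap and make results reproducible.
#' Round-off can push abundances marginally negative: values in
#' [-1e-12, 0) are clamped to zero and counted in the trajectory's
#' \code{clamped} field; anything below -1e-12 is treated as a solver
#' failure.
#'
#' The model is deterministic, so \code{nsim} and \code{seed} are accepted
#' for compatibility with the \code{\link[stats]{simulate}} generic but must
#' be left at their defaults.
#'
#' @param object a \code{\link{plasticity_model}}.
#' @param nsim,seed ignored (deterministic model).
#' @param x0 numeric vector of N nonnegative initial abundances (default: the
#'   coexistence equilibrium).
#' @param schedule a \code{\link{treatment_schedule}}, or \code{NULL} for an
#'   untreated run.
#' @param horizon end time of the run (>= schedule duration); defaults to the
#'   schedule duration, or 10 for untreated runs.
#' @param dt output resolution (time units between stored points, default 0.1).
#' @param rtol,atol solver relative/absolute tolerances.
#' @param ... unused.
#' @return An object of class \code{"trajectory"}: list with \code{times},
#'   \code{states} (time-by-phenotype matrix), \code{summaries} (per-time
#'   totals and trait moments), \code{active} (treatment kind per stored
#'   time), \code{schedule_applied} (blocks with adaptive kinds resolved),
#'   \code{model}, \code{clamped}.
#' @examples
#' m <- plasticity_model()
#' traj <- simulate(m, x0 = c(0.1, 0, 0), horizon = 50)
#' tail(traj$states, 1)  # near the uniform equilibrium
#' @export
simulate.plasticity_model <- function(object, nsim = 1, seed = NULL,
                                      x0 = NULL, schedule = NULL,
                                      horizon = NULL, dt = 0.1,
                                      rtol = 1e-8, atol = 1e-10, ...) {
  if (!identical(nsim, 1) && !identical(nsim, 1L)) {
    stop("the model is deterministic; nsim must be 1")
  }
  if (!is.null(seed)) stop("the model is deterministic; seed is not used")
  model <- object
  n <- model$n_phenotypes
  if (is.null(x0)) x0 <- coexistence_equilibrium(model)
  x0 <- as.numeric(x0)
  if (length(x0) != n) stop("x0 must have length ", n)
  if (any(x0 < 0)) stop("x0 must be nonnegative")
  if (is.null(horizon)) {
    horizon <- if (is.null(schedule)) 10 else schedule$duration
  }
  pieces <- schedule_pieces(schedule, horizon)

  times_all <- numeric(0)
  states_all <- NULL
  active_all <- character(0)
  resolved <- character(nrow(pieces))
  clamped <- 0L
  x <- x0
  for (b in seq_len(nrow(pieces))) {
    kind <- pieces$kind[b]
    if (kind == "adaptive") kind <- adaptive_choice(x, model)
    resolved[b] <- kind
    tt <- piece_times(pieces$start[b], pieces$end[b], dt)
    sol <- deSolve::ode(
      y = x, times = tt,
      func = function(t, y, p) list(phenotype_rhs(y, model, kind)),
      parms = NULL, method = "lsoda", rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1L] < 0) {
      stop("ODE solver failed in block [", pieces$start[b], ", ",
           pieces$end[b], "] (last valid state: ",
           paste(format(x), collapse = ", "), ")")
    }
    st <- unname(sol[, -1L, drop = FALSE])
    if (min(st) < -1e-12) {
      stop("integration produced a negative abundance beyond tolerance (",
           format(min(st)), ") in block [", pieces$start[b], ", ",
           pieces$end[b], "]")
    }
    neg <- st < 0
    if (any(neg)) {
      clamped <- clamped + sum(neg)
      st[neg] <- 0
    }
    keep <- if (b == 1L) seq_len(nrow(st)) else -1L  # drop shared boundary
    times_all <- c(times_all, sol[keep, 1L])
    states_all <- rbind(states_all, st[keep, , drop = FALSE])
    active_all <- c(active_all, rep(kind, length(sol[keep, 1L])))
    x <- st[nrow(st), ]
  }
  colnames(states_all) <- paste0("x_", seq_len(n))
  applied <- pieces
  applied$kind_resolved <- resolved
  structure(
    list(
      times = times_all,
      states = states_all,
      summaries = state_summaries(times_all, states_all),
      active = active_all,
      schedule_applied = applied,
      model = model,
      clamped = clamped
    ),
    class = "trajectory"
  )
}

# Blocks of the schedule clipped to [0, horizon], plus a trailing untreated
# piece; an untreated run is one "none" piece.
schedule_pieces <- function(schedule, horizon) {
  if (is.null(schedule)) {
    return(data.frame(start = 0, end = horizon, kind = "none",
                      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (horizon < schedule$duration - 1e-12) {
    stop("horizon (", horizon, ") is shorter than the schedule duration (",
         schedule$duration, ")")
  }
  pieces <- schedule$blocks
  if (horizon > schedule$duration + 1e-12) {
    pieces <- rbind(pieces, data.frame(start = schedule$duration,
                                       end = horizon, kind = "none",
                                       stringsAsFactors = FALSE))
  }
  pieces
}

piece_times <- function(start, end, dt) {
  tt <- seq(start, end, by = dt)
  if (tt[length(tt)] < end - 1e-12) tt <- c(tt, end)
  tt
}

# Per-time totals and trait moments; moments are NA where the population is
# extinct (zero total).
state_summaries <- function(times, states) {
  out <- data.frame(time = times, X = rowSums(states),
                    mean_trait = NA_real_, variance = NA_real_,
                    third_central_moment = NA_real_)
  alive <- out$X > 0
  if (any(alive)) {
    mom <- t(vapply(which(alive), function(i) {
      s <- distribution_moments(states[i, ])
      c(s$mean_trait, s$variance, s$third_central_moment)
    }, numeric(3)))
    out$mean_trait[alive] <- mom[, 1L]
    out$variance[alive] <- mom[, 2L]
    out$third_central_moment[alive] <- mom[, 3L]
  }
  out
}

#' Tumor burden reduction at a time point
#'
#' The reduction in tumor burden relative to the carrying capacity,
#' \eqn{(K - X(t))/K}, where X(t) is the total abundance at the evaluation
#' time (by convention the end of the treatment duration). Values marginally
#' outside [0, 1] from numerical noise are clipped.
#'
#' @param traj a \code{\link[=simulate.plasticity_model]{trajectory}}.
#' @param at_time evaluation time within the trajectory range; defaults to
#'   the end of the applied treatment schedule.
#' @return Burden reduction in [0, 1].
#' @export
burden_reduction <- function(traj, at_time = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(at_time)) {
    blocks <- traj$schedule_applied
    treated <- blocks$kind != "none"
    at_time <- if (any(treated)) max(blocks$end[treated]) else
      max(traj$times)
  }
  rng <- range(traj$times)
  if (at_time < rng[1L] - 1e-12 || at_time > rng[2L] + 1e-12) {
    stop("at_time = ", at_time, " lies outside the trajectory range [",
         rng[1L], ", ", rng[2L], "]")
  }
  X <- stats::approx(traj$times, traj$summaries$X, xout = at_time,
                     ties = "ordered")$y
  K <- traj$model$carrying_capacity
  red <- (K - X) / K
  if (red < -1e-9 || red > 1 + 1e-9) {
    stop("burden reduction ", format(red), " is outside [0, 1] beyond ",
         "numerical noise")
  }
  min(max(red, 0), 1)
}

#' Run the untreated model to its steady state
#'
#' Integrates without treatment in chunks until both the right-hand side and
#' the change of the phenotype frequencies are negligible
#' (max-norm below \code{tol} per unit time), or the horizon cap is reached.
#'
#' @param model a \code{\link{plasticity_model}}.
#' @param x0 initial abundances.
#' @param max_horizon cap on integration time (default 1000).
#' @param chunk chunk length between convergence checks (default 25).
#' @param tol convergence tolerance (default 1e-10).
#' @param rtol,atol solver tolerances.
#' @return List with \code{state} (abundances), \code{time},
#'   \code{converged} (logical).
#' @export
steady_state <- function(model, x0, max_horizon = 1000, chunk = 25,
                         tol = 1e-10, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(model, "plasticity_model"))
  x <- as.numeric(x0)
  t_now <- 0
  repeat {
    t_next <- min(t_now + chunk, max_horizon)
    sol <- deSolve::ode(
      y = x, times = c(t_now, t_next),
      func = function(t, y, p) list(phenotype_rhs(y, model, "none")),
      parms = NULL, method = "lsoda", rtol = rtol, atol = atol
    )
    x_new <- pmax(unname(sol[nrow(sol), -1L]), 0)
    drift <- max(abs(phenotype_rhs(x_new, model, "none")))
    freq_change <- if (sum(x_new) > 0 && sum(x) > 0) {
      max(abs(x_new / sum(x_new) - x / sum(x))) / (t_next - t_now)
    } else {
      0
    }
    x <- x_new
    t_now <- t_next
    if ((drift < tol && freq_change < tol) || t_now >= max_horizon) break
  }
  list(state = x, time = t_now,
       converged = max(abs(phenotype_rhs(x, model, "none"))) < tol)
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Trajectory: %d time points over [%g, %g], %d phenotypes\n",
              n, x$times[1L], x$times[n], ncol(x$states)))
  cat("  blocks applied:\n")
  print(x$schedule_applied)
  cat(sprintf("  final state: X = %.6g, mean trait = %.4f\n",
              x$summaries$X[n], x$summaries$mean_trait[n]))
  if (x$clamped > 0L) {
    cat(sprintf("  note: %d state entries clamped from round-off negatives\n",
                x$clamped))
  }
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  cbind(data.frame(time = x$times), as.data.frame(x$states),
        x$summaries[, c("X", "mean_trait", "variance",
                        "third_central_moment")],
        data.frame(active_treatment = x$active))
}

#' Plot a trajectory
#'
#' Phenotype abundances and the total over time (base graphics). Treated
#' periods are shaded.
#'
#' @param x a trajectory.
#' @param ... passed to \code{matplot}.
#' @export
plot.trajectory <- function(x, ...) {
  n <- ncol(x$states)
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time", ylab = "abundance", ...)
  graphics::lines(x$times, x$summaries$X, lty = 2, col = "grey30")
  blocks <- x$schedule_applied
  for (b in seq_len(nrow(blocks))) {
    if (blocks$kind_resolved[b] != "none") {
      graphics::rect(blocks$start[b], graphics::par("usr")[3L],
                     blocks$end[b], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("grey", 0.2), border = NA)
    }
  }
  graphics::legend("topright", bty = "n", lty = c(rep(1, n), 2),
                   col = c(seq_len(n), "grey30"),
                   legend = c(paste0("x_", seq_len(n)), "total X"))
  invisible(x)
}
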