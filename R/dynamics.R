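# Time integration of total species concentrations with a quasi-steady-state
# complex solve at every step (differential-algebraic scheme).

#' Habitat restriction factor
#'
#' Logistic-style resource limitation multiplying all catalytic production:
#' \deqn{\Pi = 1 - \frac{1}{K} \sum_i \frac{R_i}{q_i},}
#' where K is the habitat capacity and q_i the per-species capacity weight
#' (1 for host species; larger for parasitic species, whose smaller molecules
#' consume fewer resources each). The factor is not clamped: transient
#' overshoot produces a negative value, which downstream integration handles
#' by clamping negative totals.
#'
#' @param totals length-n vector of total concentrations.
#' @param capacity habitat capacity K > 0.
#' @param weights length-n vector of positive capacity weights q_i.
#' @return scalar habitat restriction factor.
#' @examples
#' habitat_restriction(c(5, 5, 5, 10), 20, c(1, 1, 5, 10))  # 0.4
#' @export
habitat_restriction <- function(totals, capacity, weights) {
  if (!(capacity > 0)) stop("capacity must be > 0")
  if (any(weights <= 0)) stop("capacity weights must be > 0")
  1 - sum(totals / weights) / capacity
}

.rule_arrays <- function(spec) {
  r <- spec$rules
  n <- spec$n
  list(
    l = (r$enzyme - 1L) * n + r$template,
    kcat = spec$kcat[cbind(r$enzyme, r$template)],
    yield = r$yield,
    # aggregation matrix: production of species p = row p of P %*% per-rule flux
    P = {
      P <- matrix(0, n, nrow(r))
      P[cbind(r$product, seq_len(nrow(r)))] <- 1
      P
    }
  )
}

#' Right-hand side of the population ODEs
#'
#' For each species p,
#' \deqn{\frac{dR_p}{dt} = \sum_{rules \to p} y \, k_{cat}[e,t] \,
#'   c_{e,t} \, \Pi + \alpha_p - d_p R_p,}
#' summing over the production rules targeting p (yield y, source complex
#' concentration c from the converged quasi-steady-state solve), with the
#' habitat restriction applied to all catalytic production, constant inflow
#' alpha applied outside the restriction (inflow is not resource-limited),
#' and first-order decay.
#'
#' @param spec a `model_spec`.
#' @param totals length-n vector of current total concentrations.
#' @param complexes optional converged complex state: a `solve_report` from
#'   [newton_solve()] or a raw length-n^2 vector. When omitted it is solved
#'   here (cold start). An unconverged report, or a raw vector whose residual
#'   is not small, is refused: the scheme is only valid on the
#'   quasi-steady-state manifold.
#' @return length-n named vector of time derivatives.
#' @export
model_rhs <- function(spec, totals, complexes = NULL) {
  if (is.null(complexes)) {
    complexes <- newton_solve(totals, spec$km)
  }
  if (inherits(complexes, "solve_report")) {
    if (!complexes$converged) {
      stop("refusing to evaluate the rhs with an unconverged complex solve")
    }
    x <- complexes$solution
  } else {
    x <- as.numeric(complexes)
    resid <- max(abs(qssa_residual(totals, x, spec$km)))
    if (resid > 1e-6 * max(1, max(totals))^2) {
      stop(sprintf("supplied complexes are not in quasi-steady state (residual %.3e)", resid))
    }
  }
  ra <- .rule_arrays(spec)
  Pi <- habitat_restriction(totals, spec$capacity, spec$species$capacity_weight)
  production <- as.numeric(ra$P %*% (ra$yield * ra$kcat * x[ra$l])) * Pi
  setNames(production + spec$alpha - spec$decay * totals, spec$species$name)
}

#' Integrate a model forward in time
#'
#' Explicit Euler scheme on the total concentrations; at every step the full
#' n^2 complex system is brought to quasi-steady state by a Newton solve
#' (warm-started from the previous step, with a cold-start retry on failure)
#' before the derivative is assembled. Negative totals produced by an Euler
#' step are clamped to zero; clamping events and negative habitat-restriction
#' events are counted and reported once as a warning.
#'
#' @param spec a `model_spec`; must pass [validate_spec()] without errors.
#' @param record_every record the state every this many steps (the initial
#'   and final states are always recorded).
#' @param record_complexes also record complex and free concentrations at the
#'   recorded times.
#' @param tol absolute Newton tolerance passed to the complex solver.
#' @return object of class `trajectory`: list with `times`, `totals` (matrix,
#'   one row per recorded time, columns named by species), optional
#'   `complexes` and `free` matrices, `species` (roles/weights table),
#'   `initials`, `spec_name`, `spec_fingerprint` and a `stats` list
#'   (max Newton iterations per step, clamping and negative-restriction
#'   event counts).
#' @examples
#' \donttest{
#' traj <- integrate_model(build_preset("1"))
#' tail(as.data.frame(traj))
#' }
#' @export
integrate_model <- function(spec, record_every = 10L, record_complexes = FALSE,
                            tol = 1e-12) {
  findings <- validate_spec(spec)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop("invalid model spec: ", paste(errs$message, collapse = "; "))
  }
  n <- spec$n
  n2 <- n * n
  maps <- .index_maps(n)
  km_vec <- .km_vec(spec$km)
  ra <- .rule_arrays(spec)
  weights <- spec$species$capacity_weight
  K <- spec$capacity
  alpha <- spec$alpha
  decay <- spec$decay
  dt <- spec$dt
  steps <- if (spec$t_end <= 0) 0L else as.integer(round(spec$t_end / dt))
  record_every <- max(1L, as.integer(record_every))

  rec_mid <- if (steps >= record_every) {
    seq.int(record_every, steps, by = record_every)
  } else integer()
  rec_steps <- unique(c(0L, rec_mid, steps))
  n_rec <- length(rec_steps)
  rec_pos <- integer(steps + 1L)        # step index (0-based) -> record row or 0
  rec_pos[rec_steps + 1L] <- seq_len(n_rec)

  totals_out <- matrix(NA_real_, n_rec, n,
                       dimnames = list(NULL, spec$species$name))
  cplx_out <- if (record_complexes) {
    pair <- index_to_pair(seq_len(n2), n)
    matrix(NA_real_, n_rec, n2,
           dimnames = list(NULL, paste0(spec$species$name[pair$i], "_",
                                        spec$species$name[pair$j])))
  } else NULL
  free_out <- if (record_complexes) {
    matrix(NA_real_, n_rec, n,
           dimnames = list(NULL, paste0(spec$species$name, "_free")))
  } else NULL

  totals <- spec$initials
  x <- rep(0, n2)
  max_newton <- 0L
  clamp_events <- 0L
  pi_neg_events <- 0L

  solve_step <- function(totals, x, t_now) {
    sol <- .newton_core(totals, km_vec, maps, tol, 200L, x)
    if (!sol$converged) {
      sol <- .newton_core(totals, km_vec, maps, tol, 200L, rep(0, n2))
    }
    if (!sol$converged) {
      stop(sprintf("complex solver failed at t = %g (residual %.3e); state: %s",
                   t_now, sol$residual_norm, paste(signif(totals, 6), collapse = ", ")))
    }
    sol
  }

  record <- function(row, sol) {
    totals_out[row, ] <<- totals
    if (record_complexes) {
      cplx_out[row, ] <<- sol$x
      free_out[row, ] <<- free_concentrations(totals, sol$x)
    }
  }

  sol <- solve_step(totals, x, 0)
  x <- sol$x
  max_newton <- sol$iterations
  record(1L, sol)

  if (steps > 0L) {
    for (s in seq_len(steps)) {
      # x currently holds the converged complexes for the current totals
      Pi <- 1 - sum(totals / weights) / K
      if (Pi < 0) pi_neg_events <- pi_neg_events + 1L
      production <- as.numeric(ra$P %*% (ra$yield * ra$kcat * x[ra$l])) * Pi
      totals <- totals + dt * (production + alpha - decay * totals)
      neg <- totals < 0
      if (any(neg)) {
        clamp_events <- clamp_events + sum(neg)
        totals[neg] <- 0
      }
      sol <- solve_step(totals, x, s * dt)
      x <- sol$x
      if (sol$iterations > max_newton) max_newton <- sol$iterations
      row <- rec_pos[s + 1L]
      if (row > 0L) record(row, sol)
    }
  }

  if (clamp_events > 0L || pi_neg_events > 0L) {
    warning(sprintf("integration of '%s': %d negative-total clamping event(s), %d step(s) with negative habitat restriction",
                    spec$name, clamp_events, pi_neg_events))
  }

  structure(list(
    times = rec_steps * dt,
    totals = totals_out,
    complexes = cplx_out,
    free = free_out,
    species = spec$species,
    initials = spec$initials,
    spec_name = spec$name,
    spec_fingerprint = rlang::hash(spec),
    stats = list(newton_max_iter = max_newton,
                 clamp_events = clamp_events,
                 pi_negative_events = pi_neg_events,
                 dt = dt, steps = steps)
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  m <- nrow(x$totals)
  cat(sprintf("<trajectory '%s'> %d samples over t = [%g, %g], species: %s\n",
              x$spec_name, m, x$times[1], x$times[m],
              paste(colnames(x$totals), collapse = ", ")))
  cat("  final totals:", paste(sprintf("%s = %.4g", colnames(x$totals),
                                       x$totals[m, ]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(t = x$times, x$totals, check.names = FALSE)
  if (!is.null(x$complexes)) df <- cbind(df, as.data.frame(x$complexes))
  if (!is.null(x$free)) df <- cbind(df, as.data.frame(x$free))
  df
}

#' Export a trajectory to CSV
#'
#' Header `t,<species names...>` plus optional complex and free-concentration
#' columns; values are written with 10 significant digits, so repeated runs
#' of the same deterministic model produce byte-identical files.
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, function(col) formatC(col, digits = 10, format = "g"),
                character(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(num, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Check Euler step-size convergence by dt halving
#'
#' Reruns the model at `dt_coarse` and `dt_coarse / 2` and returns the
#' maximum relative deviation of the final totals, a self-convergence
#' estimate of the first-order Euler discretization error.
#'
#' @param spec a `model_spec`.
#' @param dt_coarse coarse step size (defaults to the spec's dt).
#' @return scalar maximum relative deviation of final totals.
#' @export
step_refinement_check <- function(spec, dt_coarse = spec$dt) {
  spec_c <- spec; spec_c$dt <- dt_coarse
  spec_f <- spec; spec_f$dt <- dt_coarse / 2
  a <- integrate_model(spec_c, record_every = 1e9)
  b <- integrate_model(spec_f, record_every = 1e9)
  fa <- a$totals[nrow(a$totals), ]
  fb <- b$totals[nrow(b$totals), ]
  max(abs(fa - fb) / pmax(abs(fb), 1e-9))
}
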