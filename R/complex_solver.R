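# Quasi-steady-state solver for the n^2 ribozyme-template complex system.
#
# Complex vectors use the row-major layout [R1_R1, R1_R2, ..., Rn_Rn]:
# element l holds the complex with enzyme i(l) and template j(l).

.maps_cache <- new.env(parent = emptyenv())

# Precompute, per n, the l -> (i, j) index vectors and the two constant 0/1
# masks that carry the Kronecker-delta structure of the analytic Jacobian.
.index_maps <- function(n) {
  key <- as.character(n)
  cached <- .maps_cache[[key]]
  if (!is.null(cached)) return(cached)
  l <- seq_len(n * n)
  j <- ((l - 1L) %% n) + 1L
  i <- ((l - j) %/% n) + 1L
  d_ii <- outer(i, i, "==") # [l,m]: i(m) == i(l)
  d_ij <- outer(i, j, "==") # [l,m]: j(m) == i(l)
  d_ji <- outer(j, i, "==") # [l,m]: i(m) == j(l)
  d_jj <- outer(j, j, "==") # [l,m]: j(m) == j(l)
  maps <- list(
    n = n, iL = i, jL = j,
    M1 = (d_ii + d_ij - d_ii * d_ij) * 1.0,
    M2 = (d_ji + d_jj - d_ji * d_jj) * 1.0
  )
  .maps_cache[[key]] <- maps
  maps
}

#' Map a flat complex index to its (enzyme, template) pair
#'
#' The n^2 complexes are stored row-major, so index l corresponds to enzyme
#' `i = (l - j)/n + 1` and template `j = l mod n` (with the zero remainder
#' mapped to n). All indices are 1-based.
#'
#' @param l flat index (vectorized), in 1..n^2.
#' @param n number of species.
#' @return list with integer vectors `i` (enzyme) and `j` (template).
#' @examples
#' index_to_pair(4, n = 3)  # enzyme 2, template 1
#' @export
index_to_pair <- function(l, n) {
  l <- as.integer(l)
  if (any(l < 1L | l > n * n)) {
    stop(sprintf("complex index out of range 1..%d", n * n))
  }
  j <- ((l - 1L) %% n) + 1L
  i <- ((l - j) %/% n) + 1L
  list(i = i, j = j)
}

#' Map an (enzyme, template) pair to its flat complex index
#'
#' Inverse of [index_to_pair()].
#'
#' @param i enzyme index, 1..n.
#' @param j template index, 1..n.
#' @param n number of species.
#' @return integer flat index in 1..n^2.
#' @export
pair_to_index <- function(i, j, n) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1L | i > n) || any(j < 1L | j > n)) {
    stop(sprintf("species index out of range 1..%d", n))
  }
  (i - 1L) * n + j
}

.complex_matrix <- function(complexes, n) {
  matrix(as.numeric(complexes), n, n, byrow = TRUE)
}

.km_vec <- function(km) as.numeric(t(km))

#' Free concentrations implied by totals and complex concentrations
#'
#' Each molecule bound in a complex is unavailable, whether it sits in the
#' enzyme or the template slot; the self-complex R_i_R_i consumes two
#' molecules of species i but appears in both the row and the column sum, so
#' it is added back once:
#' \deqn{R_i^{free} = R_i - \sum_k (R_i\_R_k + R_k\_R_i) + R_i\_R_i.}
#' The result may be negative for an infeasible complex vector; callers that
#' require feasibility must check.
#'
#' @param totals length-n vector of total concentrations.
#' @param complexes length-n^2 complex vector (row-major) or n x n matrix.
#' @return length-n vector of free concentrations.
#' @export
free_concentrations <- function(totals, complexes) {
  n <- length(totals)
  if (length(complexes) != n * n) {
    stop(sprintf("expected %d complex concentrations, got %d", n * n, length(complexes)))
  }
  C <- if (is.matrix(complexes)) complexes else .complex_matrix(complexes, n)
  as.numeric(totals) - (rowSums(C) + colSums(C)) + diag(C)
}

#' Steady-state residual of the complex mass-balance system
#'
#' Component l of the residual is
#' \deqn{F_l = K_M[i(l), j(l)] \cdot c_l - R^{free}_{i(l)} R^{free}_{j(l)},}
#' which vanishes exactly when every complex satisfies its quasi-steady-state
#' balance between formation from free partners and loss by dissociation plus
#' turnover.
#'
#' @param totals length-n vector of total concentrations.
#' @param complexes length-n^2 complex vector (row-major) or n x n matrix.
#' @param km n x n Michaelis-constant matrix.
#' @return length-n^2 residual vector.
#' @export
qssa_residual <- function(totals, complexes, km) {
  n <- length(totals)
  maps <- .index_maps(n)
  x <- if (is.matrix(complexes)) .km_vec(complexes) else as.numeric(complexes)
  free <- free_concentrations(totals, x)
  .km_vec(km) * x - free[maps$iL] * free[maps$jL]
}

#' Analytic Jacobian of the steady-state residual
#'
#' Closed-form derivative of [qssa_residual()] with respect to the complex
#' vector, built from Kronecker-delta masks over the index maps: entry (l, m)
#' is \eqn{K_M \delta(l,m)} plus the sensitivities of the two free
#' concentrations entering residual l to complex m.
#'
#' @inheritParams qssa_residual
#' @return n^2 x n^2 Jacobian matrix.
#' @export
qssa_jacobian <- function(totals, complexes, km) {
  n <- length(totals)
  maps <- .index_maps(n)
  x <- if (is.matrix(complexes)) .km_vec(complexes) else as.numeric(complexes)
  free <- free_concentrations(totals, x)
  J <- free[maps$jL] * maps$M1 + free[maps$iL] * maps$M2
  diag(J) <- diag(J) + .km_vec(km)
  J
}

# Core damped Newton iteration shared by newton_solve() and the integrator.
# Returns the raw solution state; wrapping into a report happens above.
.newton_core <- function(totals, km_vec, maps, tol, max_iter, start) {
  n <- maps$n; iL <- maps$iL; jL <- maps$jL
  free_of <- function(x) {
    C <- matrix(x, n, n, byrow = TRUE)
    totals - (rowSums(C) + colSums(C)) + diag(C)
  }
  # absolute tolerance with a floating-point floor: residual entries are
  # differences of terms of order max(totals)^2, which bounds the attainable
  # absolute accuracy
  tol_eff <- max(tol, 64 * .Machine$double.eps * max(1, max(totals))^2)

  x <- start
  free <- free_of(x)
  f <- km_vec * x - free[iL] * free[jL]
  fn <- max(abs(f))
  damped <- 0L
  if (fn <= tol_eff) {
    return(list(x = x, iterations = 0L, residual_norm = fn, converged = TRUE,
                damped_steps = 0L, tol_effective = tol_eff))
  }
  for (k in seq_len(max_iter)) {
    J <- free[jL] * maps$M1 + free[iL] * maps$M2
    diag(J) <- diag(J) + km_vec
    delta <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(delta)) {
      return(list(x = x, iterations = k - 1L, residual_norm = fn, converged = FALSE,
                  damped_steps = damped, tol_effective = tol_eff,
                  message = "singular Jacobian"))
    }
    lam <- 1
    accepted <- FALSE
    for (h in 0:30) {
      x_try <- x - lam * delta
      free_try <- free_of(x_try)
      f_try <- km_vec * x_try - free_try[iL] * free_try[jL]
      fn_try <- max(abs(f_try))
      # accept only feasible states (free >= 0) that reduce the residual;
      # overshoot is handled by step halving
      if (all(free_try >= -tol_eff) && (fn_try < fn || fn_try <= tol_eff)) {
        x <- x_try; free <- free_try; f <- f_try; fn <- fn_try
        accepted <- TRUE
        if (h > 0) damped <- damped + h
        break
      }
      lam <- lam / 2
    }
    if (!accepted) {
      return(list(x = x, iterations = k, residual_norm = fn, converged = FALSE,
                  damped_steps = damped, tol_effective = tol_eff,
                  message = "step halving exhausted without residual decrease"))
    }
    if (fn <= tol_eff) {
      x[x < 0 & x > -tol_eff] <- 0 # snap roundoff negatives of suppressed complexes
      return(list(x = x, iterations = k, residual_norm = fn, converged = TRUE,
                  damped_steps = damped, tol_effective = tol_eff))
    }
  }
  list(x = x, iterations = max_iter, residual_norm = fn, converged = FALSE,
       damped_steps = damped, tol_effective = tol_eff,
       message = "maximum iterations reached")
}

#' Solve the quasi-steady-state complex system by damped Newton iteration
#'
#' Finds the complex vector annihilating [qssa_residual()], i.e. the
#' concentrations of all n^2 enzyme--template complexes in quasi-steady state
#' with the given totals. The iteration starts from the zero vector (no
#' complexes formed) unless a warm start is supplied, updates with the
#' analytic Jacobian through a direct linear solve, and halves the step
#' whenever a full step would increase the residual norm or drive a free
#' concentration negative. Convergence is declared on the maximum absolute
#' residual; the reported effective tolerance includes a floating-point floor
#' proportional to `max(totals)^2`, the scale of the products being balanced.
#'
#' The converged solution is the physically relevant root: all complex and
#' all free concentrations are nonnegative.
#'
#' @param totals length-n vector of total concentrations, nonnegative.
#' @param km n x n Michaelis-constant matrix, strictly positive.
#' @param tol absolute tolerance on `max(abs(residual))`.
#' @param max_iter maximum Newton iterations.
#' @param warm_start optional length-n^2 complex vector used as the starting
#'   point (e.g. the previous time step's solution).
#' @return object of class `solve_report`: list with `solution` (length-n^2
#'   complex vector), `n`, `iterations`, `residual_norm`, `converged`,
#'   `damped_steps`, `tol`, `tol_effective` and (on failure) `message`. A
#'   non-converged report is returned, never silently treated as converged.
#' @examples
#' rep <- newton_solve(c(1, 1), km = matrix(c(1, 1, 1e4, 1e4), 2, byrow = TRUE))
#' rep$solution
#' @export
newton_solve <- function(totals, km, tol = 1e-12, max_iter = 200,
                         warm_start = NULL) {
  totals <- as.numeric(totals)
  n <- length(totals)
  if (any(totals < 0)) stop("totals must be nonnegative")
  km <- as.matrix(km)
  if (!all(dim(km) == c(n, n))) stop(sprintf("km must be %d x %d", n, n))
  if (any(km <= 0)) stop("km entries must be strictly positive")
  maps <- .index_maps(n)
  start <- if (is.null(warm_start)) rep(0, n * n) else as.numeric(warm_start)
  if (length(start) != n * n) stop(sprintf("warm_start must have length %d", n * n))
  res <- .newton_core(totals, .km_vec(km), maps, tol, max_iter, start)
  structure(list(solution = res$x, n = n, iterations = res$iterations,
                 residual_norm = res$residual_norm, converged = res$converged,
                 damped_steps = res$damped_steps, tol = tol,
                 tol_effective = res$tol_effective,
                 message = res$message %||% "converged"),
            class = "solve_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("<solve_report> n = %d, %s in %d iterations (residual %.3e, %d damped steps)\n",
              x$n, if (x$converged) "converged" else paste0("FAILED: ", x$message),
              x$iterations, x$residual_norm, x$damped_steps))
  invisible(x)
}

#' Tight-binding (Morrison) closed form for a single complex
#'
#' When only one enzyme--template pair can form a complex, the
#' quasi-steady-state balance \eqn{(E - c)(S - c) = K_M c} is a quadratic in
#' c; the physically relevant root keeps both free concentrations
#' nonnegative:
#' \deqn{c = \tfrac12 (E + S + K_M) - \sqrt{\tfrac14 (E + S + K_M)^2 - E S}.}
#' Unlike the classical Michaelis-Menten expression, this form stays valid
#' when enzyme and substrate totals are comparable (tight binding).
#'
#' @param total_e total enzyme concentration, >= 0.
#' @param total_s total substrate (template) concentration, >= 0.
#' @param km Michaelis constant, > 0.
#' @return complex concentration in `[0, min(total_e, total_s)]`.
#' @examples
#' morrison_complex(1, 1, 1)  # (3 - sqrt(5))/2
#' @export
morrison_complex <- function(total_e, total_s, km) {
  if (any(total_e < 0) || any(total_s < 0)) stop("totals must be nonnegative")
  if (any(km <= 0)) stop("km must be strictly positive")
  s <- total_e + total_s + km
  disc <- 0.25 * s^2 - total_e * total_s
  0.5 * s - sqrt(pmax(disc, 0))
}

#' Damped fixed-point solver for the complex system (verification oracle)
#'
#' Newton-independent solver used for cross-checking: iterates the natural
#' fixed-point map \eqn{c_l \leftarrow R^{free}_{i} R^{free}_{j} / K_M[i,j]}
#' (free concentrations clamped at zero inside the map, which leaves the
#' feasible fixed point unchanged) with relaxation
#' `x <- (1 - omega) x + omega g(x)`. If the iteration diverges or stalls for
#' a relaxation factor, the run restarts with omega halved; tight-binding
#' instances need small omega and converge linearly, which is acceptable for
#' a test oracle.
#'
#' The starting relaxation factor is scaled to the stiffness of the map
#' (roughly `1 / (1 + 4 max(totals) / min(KM))`, the tight-binding regime
#' needing the most damping); a run that diverges or stalls restarts with
#' omega halved.
#'
#' @inheritParams newton_solve
#' @param tol convergence tolerance on the undamped update
#'   `max(abs(g(x) - x))`.
#' @param max_iter iteration budget per relaxation factor.
#' @return length-n^2 complex vector.
#' @export
fixed_point_oracle <- function(totals, km, tol = 1e-11, max_iter = 100000) {
  totals <- as.numeric(totals)
  n <- length(totals)
  if (any(totals < 0)) stop("totals must be nonnegative")
  km_vec <- .km_vec(as.matrix(km))
  maps <- .index_maps(n)
  iL <- maps$iL; jL <- maps$jL
  if (all(totals == 0)) return(rep(0, n * n))

  omega0 <- min(0.5, 1 / (1 + 4 * max(totals) / min(km_vec)))
  for (omega in omega0 / 2^(0:8)) {
    x <- rep(0, n * n)
    last_check <- Inf
    failed <- FALSE
    for (k in seq_len(max_iter)) {
      C <- matrix(x, n, n, byrow = TRUE)
      free <- pmax(totals - (rowSums(C) + colSums(C)) + diag(C), 0)
      g <- free[iL] * free[jL] / km_vec
      change <- max(abs(g - x))
      if (!is.finite(change) || change > 1e8) { failed <- TRUE; break }
      if (change <= tol) return(pmax(x, 0))
      x <- (1 - omega) * x + omega * g
      if (k %% 2000L == 0L) {
        # linear convergence should shrink the update decisively between
        # checkpoints; a bounded oscillation means omega is too large
        if (change > 0.5 * last_check) { failed <- TRUE; break }
        last_check <- change
      }
    }
  }
  stop("fixed-point oracle failed to converge; last max change above tolerance")
}
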