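#' Discretisation for the reaction-diffusion oracle
#'
#' Node-centred grid on `[-L/2, L/2]` with `n_cells` nodes (both ends
#' included), reflecting (no-flux) boundaries via mirrored ghost nodes, and
#' a fixed time step. The explicit scheme requires
#' `dt <= dx^2 / (2 max(D))`; Crank-Nicolson is unconditionally stable.
#'
#' @param L Domain length (um).
#' @param n_cells Number of grid nodes, `>= 3`.
#' @param dt Time step (s). Default `NULL`: chosen from the decay rates
#'   (Crank-Nicolson) or the stability bound (explicit) at integration time.
#' @param T Time horizon (s). Default `NULL`: `60 / min(k)`.
#' @return An object of class `"rd_grid"`.
#' @export
rd_grid <- function(L = 10, n_cells = 401, dt = NULL, T = NULL) {
  if (!is.numeric(L) || L <= 0) stop("L must be > 0", call. = FALSE)
  if (!is.numeric(n_cells) || n_cells < 3) stop("n_cells must be >= 3", call. = FALSE)
  n_cells <- as.integer(n_cells)
  structure(list(L = L, n_cells = n_cells, dx = L / (n_cells - 1L),
                 dt = dt, T = T),
            class = "rd_grid")
}

# No-flux Laplacian action on z (node-centred, mirrored ghost nodes).
laplacian_noflux <- function(z, dx) {
  n <- length(z)
  out <- numeric(n)
  out[1] <- 2 * (z[2] - z[1])
  out[n] <- 2 * (z[n - 1] - z[n])
  out[2:(n - 1)] <- z[1:(n - 2)] - 2 * z[2:(n - 1)] + z[3:n]
  out / dx^2
}

# Tridiagonal no-flux operator M = D * Lap - k * I as a dense matrix.
rd_operator <- function(n, dx, D, k) {
  M <- matrix(0, n, n)
  idx <- seq_len(n - 2) + 1L
  M[cbind(idx, idx - 1L)] <- D / dx^2
  M[cbind(idx, idx + 1L)] <- D / dx^2
  M[cbind(idx, idx)] <- -2 * D / dx^2 - k
  M[1, 1] <- -2 * D / dx^2 - k; M[1, 2] <- 2 * D / dx^2
  M[n, n] <- -2 * D / dx^2 - k; M[n, n - 1] <- 2 * D / dx^2
  M
}

integrate_species <- function(p, src, grid, scheme, steady_tol = 1e-8) {
  n <- grid$n_cells; dx <- grid$dx
  k <- p$k; D <- p$D
  z_scale <- max(mean(src) / k, .Machine$double.eps)  # ~ baseline activity
  if (scheme == "explicit") {
    dt_stab <- if (D > 0) dx^2 / (2 * D) else Inf
    dt <- if (is.null(grid$dt)) min(0.9 * dt_stab, 0.1 / k) else grid$dt
    if (dt > dt_stab)
      stop(sprintf("explicit scheme unstable: dt = %g exceeds dx^2/(2D) = %g",
                   dt, dt_stab), call. = FALSE)
  } else {
    dt <- if (is.null(grid$dt)) 0.05 / k else grid$dt
  }
  Tmax <- if (is.null(grid$T)) 60 / k else grid$T
  max_steps <- max(1L, ceiling(Tmax / dt))
  z <- numeric(n)
  n_startup <- 0L
  if (scheme == "crank_nicolson") {
    M <- rd_operator(n, dx, D, k)
    A1 <- diag(n) - (dt / 2) * M
    A0 <- diag(n) + (dt / 2) * M
    A1_inv <- solve(A1)
    P <- A1_inv %*% A0
    q <- as.numeric(A1_inv %*% (dt * src))
    # Rannacher startup: a few implicit-Euler steps damp the stiff-mode
    # ringing that plain Crank-Nicolson keeps alive when D dt >> dx^2.
    n_startup <- 4L
    BE_inv <- solve(diag(n) - dt * M)
    P_be <- BE_inv
    q_be <- as.numeric(BE_inv %*% (dt * src))
  }
  converged <- FALSE; resid <- NA_real_; step <- 0L
  for (step in seq_len(max_steps)) {
    z_new <- if (scheme == "explicit") {
      z + dt * (D * laplacian_noflux(z, dx) - k * z + src)
    } else if (step <= n_startup) {
      as.numeric(P_be %*% z) + q_be
    } else {
      as.numeric(P %*% z) + q
    }
    resid <- max(abs(z_new - z)) / dt / z_scale
    z <- z_new
    if (resid < steady_tol) { converged <- TRUE; break }
  }
  list(values = z, converged = converged, steps = step, residual = resid,
       dt = dt)
}

#' Brute-force reaction-diffusion oracle
#'
#' Integrates the two uncoupled linear reaction-diffusion equations
#' `dZ/dt = D Z'' - k Z + c + alpha f(x)` for the activator and the
#' inhibitor from zero initial conditions with reflecting boundaries,
#' until `max |dZ/dt| / Z* < steady_tol` or the horizon is reached. This
#' is the numerical ground truth against which the analytic series
#' solution is checked; the physical steady state always carries the
#' efficacy `alpha` on the stimulus.
#'
#' @param pA,pI [species_params()] for the two species.
#' @param stimulus Either a function of position `x` (um, cone-centred)
#'   returning the transduced signal f(x) `>= 0`, or a
#'   [growth_cone_context()] whose linearised stimulus
#'   `f* + g_eff x` is used.
#' @param L Domain length (um); ignored when `stimulus` is a context.
#' @param grid An [rd_grid()].
#' @param scheme `"crank_nicolson"` (default; unconditionally stable) or
#'   `"explicit"` (forward Euler; errors before integrating when
#'   `dt > dx^2 / (2 D)`).
#' @param steady_tol Steady-state criterion on `max|dZ/dt|/Z*`.
#' @return An object of class `"rd_solution"`: `positions`, `A_values`,
#'   `I_values`, `E_values`, per-species convergence reports, and the
#'   stimulus evaluated on the grid.
#' @examples
#' pre <- table1_preset("fig2C")
#' ctx <- growth_cone_context(L = 10, f_star = 10, g_eff = 0.75)
#' sol <- integrate_rd(pre$pA, pre$pI, ctx, grid = rd_grid(n_cells = 101))
#' @export
integrate_rd <- function(pA, pI, stimulus, L = 10, grid = rd_grid(L = L),
                         scheme = c("crank_nicolson", "explicit"),
                         steady_tol = 1e-8) {
  assert_species(pA, "pA"); assert_species(pI, "pI")
  scheme <- match.arg(scheme)
  if (inherits(stimulus, "growth_cone_context")) {
    ctx <- stimulus
    L <- ctx$L
    if (!isTRUE(all.equal(grid$L, L))) grid <- rd_grid(L = L, n_cells = grid$n_cells,
                                                       dt = grid$dt, T = grid$T)
    stim_fun <- function(x) ctx$f_star + ctx$g_eff * x
  } else if (is.function(stimulus)) {
    stim_fun <- stimulus
  } else stop("stimulus must be a function of x or a growth_cone_context",
              call. = FALSE)
  x <- seq(-grid$L / 2, grid$L / 2, length.out = grid$n_cells)
  f <- stim_fun(x)
  if (any(!is.finite(f)) || any(f < 0))
    stop("stimulus must be non-negative and finite on the domain", call. = FALSE)
  resA <- integrate_species(pA, pA$c + pA$alpha * f, grid, scheme, steady_tol)
  resI <- integrate_species(pI, pI$c + pI$alpha * f, grid, scheme, steady_tol)
  if (!resA$converged || !resI$converged)
    warning("reaction-diffusion integration did not reach steady state within the horizon",
            call. = FALSE)
  A <- resA$values; I <- resI$values
  E <- ifelse(I > 0, A / I, NA_real_)
  structure(list(positions = x, A_values = A, I_values = I, E_values = E,
                 stimulus = f, L = grid$L, dx = grid$dx, scheme = scheme,
                 convergence = list(
                   A = resA[c("converged", "steps", "residual", "dt")],
                   I = resI[c("converged", "steps", "residual", "dt")])),
            class = "rd_solution")
}

#' @export
print.rd_solution <- function(x, ...) {
  cat(sprintf("rd_solution (%s): %d nodes, dx = %.4g um\n", x$scheme,
              length(x$positions), x$dx))
  for (sp in c("A", "I")) {
    cv <- x$convergence[[sp]]
    cat(sprintf("  %s: %s in %d steps (dt = %.3g s, residual %.2g)\n", sp,
                if (cv$converged) "steady" else "NOT steady", cv$steps, cv$dt,
                cv$residual))
  }
  cat(sprintf("  dE/E* (profile) = %.6g\n", polarity_from_profile(x)))
  invisible(x)
}

#' Steady-state mass balance of an oracle solution
#'
#' With no-flux boundaries, decay must balance input at steady state:
#' `k * integral(Z) = integral(c + alpha f)` for each species. Returns the
#' relative imbalance (trapezoidal quadrature); a diagnostic for the
#' integrator.
#'
#' @param sol An `"rd_solution"`.
#' @param pA,pI The [species_params()] that produced it.
#' @return Named numeric: relative imbalance for A and I.
#' @export
rd_mass_balance <- function(sol, pA, pI) {
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * sol$dx
  out <- c(A = NA_real_, I = NA_real_)
  for (sp in c("A", "I")) {
    p <- if (sp == "A") pA else pI
    decay <- p$k * trap(sol[[paste0(sp, "_values")]])
    input <- trap(p$c + p$alpha * sol$stimulus)
    out[sp] <- abs(decay - input) / input
  }
  out
}
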