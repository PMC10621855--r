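# Nonlinear axisymmetric Laplace solver: div(sigma(|E|) grad phi) = 0 with
# phi = V on the electrode surface, phi = 0 on the outer (grounded)
# boundaries, natural (zero-flux) conditions on the symmetry axis and the
# insulated shaft. Linear triangular elements with the 2*pi*r axisymmetric
# weight; the field-dependent conductivity is resolved by damped Picard
# (fixed-point) iteration; the applied voltage is matched to a target
# delivered current by secant iteration on the linearized I(V) curve.

#' Solver settings
#'
#' @param picard_tol relative conductivity-change threshold for convergence
#' @param picard_max_iter maximum Picard iterations
#' @param damping Picard damping factor in (0, 1]
#' @param current_tol relative tolerance on the delivered current
#' @param current_max_iter maximum voltage (secant) iterations
#' @return object of class `solver_settings`
#' @export
solver_settings <- function(picard_tol = 1e-4, picard_max_iter = 50,
                            damping = 0.5, current_tol = 1e-3,
                            current_max_iter = 25) {
  stopifnot(picard_tol > 0, current_tol > 0,
            damping > 0, damping <= 1,
            picard_max_iter >= 1, current_max_iter >= 1)
  structure(list(picard_tol = picard_tol, picard_max_iter = picard_max_iter,
                 damping = damping, current_tol = current_tol,
                 current_max_iter = current_max_iter),
            class = "solver_settings")
}

assemble_stiffness <- function(mesh, sigma_e) {
  Matrix::sparseMatrix(i = mesh$asm_i, j = mesh$asm_j,
                       x = as.vector(t(mesh$geo * sigma_e)),
                       dims = c(mesh$n_nodes, mesh$n_nodes))
}

element_field <- function(mesh, phi) {
  p1 <- phi[mesh$tri[, 1]]
  p2 <- phi[mesh$tri[, 2]]
  p3 <- phi[mesh$tri[, 3]]
  Er <- -(mesh$grad_b[, 1] * p1 + mesh$grad_b[, 2] * p2 +
            mesh$grad_b[, 3] * p3)
  Ez <- -(mesh$grad_c[, 1] * p1 + mesh$grad_c[, 2] * p2 +
            mesh$grad_c[, 3] * p3)
  list(Er = Er, Ez = Ez, E_mag = sqrt(Er^2 + Ez^2))
}

#' Solve the field at a fixed electrode voltage
#'
#' Runs the damped Picard loop until the element conductivities are
#' self-consistent with the field they produce. The delivered current is
#' computed from the assembled stiffness action on the solution (the
#' volume-consistent discrete flux), summed over the electrode nodes; the
#' same sum over the ground nodes gives an independent balance check.
#'
#' @param mesh a [generate_mesh()] mesh
#' @param props a [tissue_properties()]
#' @param V_applied electrode voltage (V), > 0
#' @param settings a [solver_settings()]
#' @param sigma_init optional per-element conductivity warm start (S/m)
#' @param cache internal environment reusing the symbolic factorization
#' @return object of class `field_solution`
#' @export
solve_at_voltage <- function(mesh, props, V_applied,
                             settings = solver_settings(),
                             sigma_init = NULL, cache = NULL) {
  stopifnot(V_applied > 0)
  n <- mesh$n_nodes
  fixed <- c(mesh$idx_electrode, mesh$idx_ground)
  fixed_vals <- c(rep(V_applied, length(mesh$idx_electrode)),
                  rep(0, length(mesh$idx_ground)))
  free <- setdiff(seq_len(n), fixed)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  i <- match(mesh$label, props$table$label)
  linear_only <- all(props$table$sigma1[i] <= props$table$sigma0[i])
  sigma <- if (!is.null(sigma_init)) sigma_init else
    sigma_of_E(mesh$label, 0, props)

  phi <- numeric(n)
  phi[fixed] <- fixed_vals
  K <- NULL
  residual <- NA_real_
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(settings$picard_max_iter)) {
    iters <- it
    K <- assemble_stiffness(mesh, sigma)
    Kff <- Matrix::forceSymmetric(K[free, free])
    rhs <- as.numeric(-K[free, fixed] %*% fixed_vals)
    if (is.null(cache$chol)) {
      cache$chol <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE)
    } else {
      cache$chol <- Matrix::.updateCHMfactor(cache$chol, Kff, mult = 0)
    }
    phi[free] <- as.numeric(Matrix::solve(cache$chol, rhs))
    ef <- element_field(mesh, phi)
    sigma_prop <- sigma_of_E(mesh$label, ef$E_mag, props)
    residual <- max(abs(sigma_prop - sigma) / pmax(sigma, 1e-12))
    if (residual < settings$picard_tol || linear_only) {
      sigma <- sigma_prop
      converged <- TRUE
      break
    }
    sigma <- sigma + settings$damping * (sigma_prop - sigma)
  }
  if (!converged)
    warning(sprintf(
      "Picard iteration did not converge in %d iterations (residual %.2e)",
      settings$picard_max_iter, residual))

  flux <- as.numeric(K %*% phi)
  I_el <- sum(flux[mesh$idx_electrode])
  I_gnd <- -sum(flux[mesh$idx_ground])
  ef <- element_field(mesh, phi)

  structure(list(phi = phi, Er = ef$Er, Ez = ef$Ez, E_mag = ef$E_mag,
                 sigma_eff = sigma, J_mag = sigma * ef$E_mag,
                 V_applied = V_applied, I_delivered = I_el,
                 I_ground = I_gnd, picard_iters = iters,
                 residual = residual, converged = converged,
                 mesh = mesh),
            class = "field_solution")
}

#' Solve with the voltage matched to a target delivered current
#'
#' Secant iteration on V; each voltage step warm-starts the Picard loop
#' from the previous converged conductivity field, so the nested iteration
#' typically costs only a few extra linear solves.
#'
#' @param mesh a [generate_mesh()] mesh
#' @param props a [tissue_properties()]
#' @param I_target target delivered current (A), > 0
#' @param settings a [solver_settings()]
#' @param V_init starting voltage guess (V)
#' @return a `field_solution` whose `I_delivered` matches `I_target` to
#'   `settings$current_tol`; `current_iters` records the voltage solves
#' @export
solve_at_current <- function(mesh, props, I_target,
                             settings = solver_settings(), V_init = 2000) {
  stopifnot(I_target > 0)
  cache <- new.env(parent = emptyenv())
  Vh <- numeric(0)
  Ih <- numeric(0)
  sol <- NULL
  V <- V_init
  for (k in seq_len(settings$current_max_iter)) {
    sol <- solve_at_voltage(mesh, props, V, settings,
                            sigma_init = sol$sigma_eff, cache = cache)
    Vh <- c(Vh, V)
    Ih <- c(Ih, sol$I_delivered)
    if (abs(sol$I_delivered - I_target) / I_target < settings$current_tol) {
      sol$current_iters <- k
      sol$V_history <- Vh
      sol$I_history <- Ih
      return(sol)
    }
    if (k == 1) {
      V <- V * I_target / sol$I_delivered
    } else {
      dI <- Ih[k] - Ih[k - 1]
      dV <- Vh[k] - Vh[k - 1]
      if (dI / dV <= 0)
        stop("non-monotone I(V) detected during current matching")
      V <- Vh[k] + (I_target - Ih[k]) * dV / dI
    }
    if (V <= 0) stop("current matching produced a non-positive voltage")
  }
  stop(sprintf("current not matched in %d voltage iterations (last I = %.3f A)",
               settings$current_max_iter, sol$I_delivered))
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("Field solution: V = %.1f V, I = %.3f A (ground %.3f A)\n",
              x$V_applied, x$I_delivered, x$I_ground))
  cat(sprintf("  Picard iterations: %d (residual %.2e)\n",
              x$picard_iters, x$residual))
  cat(sprintf("  max |E| = %.0f V/cm on %d elements\n",
              max(x$E_mag) / 100, x$mesh$n_elements))
  invisible(x)
}

#' Relative mismatch between electrode and ground current
#'
#' Discrete charge conservation diagnostic; equals the solver's algebraic
#' round-off for a converged solution.
#'
#' @param sol a `field_solution`
#' @return |I_electrode - I_ground| / I_electrode
#' @export
charge_imbalance <- function(sol) {
  abs(sol$I_delivered - sol$I_ground) / abs(sol$I_delivered)
}
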