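# Static nonlinear solver: total-Lagrangian Newton iteration with load
# stepping, sparse symmetric tangent (CHOLMOD factorization, symbolic
# analysis reused across iterations) and backtracking line search.
# Degenerate load steps are bisected on Newton failure.

#' Micromotion boundary conditions
#'
#' The bottom face of the tissue block is held fixed (zero displacement)
#' and the top face of the array (rigid mode: the whole array) is
#' prescribed an in-plane displacement of `magnitude` um at `angle`
#' degrees from the Y axis: \eqn{d = m(\sin\theta, \cos\theta, 0)}.
#'
#' @param magnitude Displacement magnitude, um (study values 1, 5, 10, 20,
#'   50; default 10).
#' @param angle In-plane angle from the Y axis, degrees (0, 22.5, 45).
#' @export
boundary_conditions <- function(magnitude = 10, angle = 0) {
  th <- angle * pi / 180
  structure(list(magnitude = magnitude, angle = angle,
                 displacement = magnitude * c(sin(th), cos(th), 0)),
            class = "boundary_conditions")
}

#' Newton solver controls
#'
#' @param n_load_steps Number of equal load increments; `NULL` picks
#'   `ceiling(magnitude / 8)` (one step per ~8 um of driven displacement).
#' @param tol_rel,tol_abs Residual convergence: `||R|| <= tol_rel *
#'   ||R_initial|| + tol_abs` (consistent Pa-um units).
#' @param max_iter Newton iterations per load step.
#' @param max_backtrack Line-search halvings before a step is declared
#'   failed and bisected.
#' @param max_bisect Maximum load-step bisection depth.
#' @param lag_tangent Initial-stiffness iteration: factorize the tangent
#'   once per load step (at the converged previous state) and reuse it
#'   for all corrections.  Trades quadratic for linear convergence but
#'   avoids repeated large sparse factorizations; recommended for
#'   full-array meshes.
#' @param linear_solver `"direct"` (sparse Cholesky), `"pcg"` (conjugate
#'   gradients preconditioned by a two-level V-cycle: Jacobi smoothing on
#'   the quadratic system plus an exact factorization of its Galerkin
#'   restriction to the linear-element vertex space), or `"auto"` (direct
#'   up to `direct_limit` free dofs, PCG beyond).
#' @param direct_limit Free-dof count above which `"auto"` switches to
#'   PCG.
#' @param pcg_tol,pcg_maxit Relative residual tolerance and iteration cap
#'   of the inner PCG solver.
#' @param verbose Print per-iteration residuals.
#' @export
solver_control <- function(n_load_steps = NULL, tol_rel = 1e-7, tol_abs = 1e-8,
                           max_iter = 25, max_backtrack = 8, max_bisect = 6,
                           lag_tangent = FALSE, linear_solver = "auto",
                           direct_limit = 100000, pcg_tol = 1e-7,
                           pcg_maxit = 800, verbose = FALSE) {
  list(n_load_steps = n_load_steps, tol_rel = tol_rel, tol_abs = tol_abs,
       max_iter = max_iter, max_backtrack = max_backtrack,
       max_bisect = max_bisect, lag_tangent = lag_tangent,
       linear_solver = linear_solver, direct_limit = direct_limit,
       pcg_tol = pcg_tol, pcg_maxit = pcg_maxit, verbose = verbose)
}

# Core Newton solve.  `dirichlet` is a list of constraints, each
# list(nodes = ids, value = length-3 vector or nnodes x 3 matrix); values
# are ramped linearly with the load factor.  `hierarchy` (list with
# n_vertex and midside_parents) enables the two-level PCG backend.
fem_solve <- function(nodes, tets, region, materials, dirichlet,
                      control = solver_control(), hierarchy = NULL,
                      schedule = NULL) {
  nn <- nrow(nodes)
  matpar <- do.call(rbind, lapply(materials, mat_row))
  # each constraint may restrict a subset of components (comps, default
  # all three); later constraints override earlier ones on overlap
  presc <- rep(FALSE, 3L * nn)
  uhat <- numeric(3L * nn)
  for (d in dirichlet) {
    comps <- if (is.null(d$comps)) c(TRUE, TRUE, TRUE) else d$comps
    v <- d$value
    vm <- if (is.matrix(v)) v else matrix(v, length(d$nodes), 3, byrow = TRUE)
    for (i in which(comps)) {
      ii <- 3L * (d$nodes - 1L) + i
      presc[ii] <- TRUE
      uhat[ii] <- vm[, i]
    }
  }
  nfree <- sum(!presc)
  # free dofs numbered in geometric nested-dissection order (node-blocked),
  # so the Cholesky factorization runs on the natural ordering
  ndo <- .nd_order_cpp(nodes, tets)
  dof_order <- rep(3L * (ndo - 1L), each = 3L) + rep(1:3, length(ndo))
  dof_order <- dof_order[!presc[dof_order]]
  dofmap <- rep(-1L, 3L * nn)
  dofmap[dof_order] <- seq_len(nfree) - 1L
  free_idx <- dof_order

  pat <- .fem_pattern_cpp(tets, dofmap, nfree)
  Kx <- numeric(pat$nnz)
  assemble <- function(u, tangent) {
    .fem_assemble_cpp(nodes, tets, region, matpar, u, dofmap, nfree,
                      if (tangent) pat$slot else integer(0),
                      if (tangent) Kx else numeric(0), tangent)
  }
  Kmat <- function() {
    # Kx + 0 forces a genuine copy: the assembly kernel overwrites Kx in
    # place, and matrices built from it must not alias the live buffer
    Matrix::sparseMatrix(i = pat$i, p = pat$p, x = Kx + 0,
                         symmetric = TRUE, index1 = FALSE,
                         dims = c(nfree, nfree))
  }

  use_pcg <- switch(control$linear_solver,
                    direct = FALSE, pcg = TRUE,
                    auto = nfree > control$direct_limit,
                    stop("unknown linear_solver"))
  if (use_pcg && is.null(hierarchy))
    stop("PCG backend requires the quadratic->linear node hierarchy")

  chol_fac <- NULL
  Kx_good <- NULL
  if (use_pcg) {
    # prolongation from the linear (vertex) space: vertex dofs injected,
    # midside dofs averaged from their parent vertices
    nv <- hierarchy$n_vertex
    mp <- hierarchy$midside_parents
    p1free <- !presc[1:(3 * nv)]
    p1map <- rep(NA_integer_, 3 * nv)
    p1map[p1free] <- seq_len(sum(p1free))
    rows <- cols <- vals <- vector("list", 3)
    g2 <- dofmap[1:(3 * nv)] + 1L
    selv <- which(g2 > 0 & p1free)
    rows[[1]] <- g2[selv]; cols[[1]] <- p1map[selv]; vals[[1]] <- rep(1, length(selv))
    for (s in 2:3) {
      pa <- mp[, s - 1]
      dofm <- rep(3L * (as.integer(nv + seq_len(nrow(mp))) - 1L), each = 3L) + rep(1:3, nrow(mp))
      dofp <- rep(3L * (pa - 1L), each = 3L) + rep(1:3, nrow(mp))
      sel <- which(dofmap[dofm] >= 0 & !presc[dofp])
      rows[[s]] <- dofmap[dofm][sel] + 1L
      cols[[s]] <- p1map[dofp][sel]
      vals[[s]] <- rep(0.5, length(sel))
    }
    P <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                              x = unlist(vals),
                              dims = c(nfree, sum(p1free)))
    pcg_env <- new.env()
  }

  refactor <- function() {
    # returns TRUE if the current K was (re)processed, FALSE if the
    # previous (lagged) operator is retained.  In PCG mode this rebuilds
    # the two-level preconditioner (once per load step); the operator
    # itself is refreshed cheaply via update_operator().
    K <- Kmat()
    if (use_pcg) {
      ok <- tryCatch({
        dA <- Matrix::diag(K)
        A1 <- Matrix::forceSymmetric(Matrix::crossprod(P, K %*% P))
        ch1 <- Matrix::Cholesky(A1, LDL = FALSE, super = TRUE)
        # spectral bound of the Jacobi-preconditioned operator for the
        # smoother damping, by a few power iterations
        set.seed(0)
        v <- stats::rnorm(nfree)
        lam <- 1
        for (i in 1:8) {
          w <- as.numeric(K %*% (v / dA))
          lam <- sqrt(sum(w^2)) / sqrt(sum(v^2))
          v <- w / sqrt(sum(w^2))
        }
        assign("A", K, pcg_env)
        assign("dA", dA, pcg_env)
        assign("ch1", ch1, pcg_env)
        assign("omega", 0.9 / lam, pcg_env)
        TRUE
      }, error = function(e) FALSE)
      return(ok)
    }
    if (is.null(chol_fac)) {
      chol_fac <<- tryCatch(Matrix::Cholesky(K, LDL = FALSE, super = TRUE),
                            error = function(e) NULL)
      if (is.null(chol_fac)) {
        chol_fac <<- Matrix::Cholesky(K, LDL = FALSE, super = TRUE,
                                      Imult = mean(abs(Kx)))
        return(FALSE)
      }
      Kx_good <<- Kx + 0
      return(TRUE)
    }
    # When the deformed tangent is indefinite the numeric update fails --
    # and it also leaves the factor object numerically corrupted (the
    # update works in place).  Restore the last successfully factorized
    # matrix so the lagged-factor fallback stays valid, and rely on the
    # line search / load-step bisection for globalization.
    ok <- tryCatch({ chol_fac <<- Matrix::update(chol_fac, K); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (ok) {
      Kx_good <<- Kx + 0
    } else if (!is.null(Kx_good)) {
      # a failed in-place update corrupts the factor beyond what a second
      # update can repair; rebuild a fresh factorization of the last
      # successfully factorized matrix
      Kg <- Matrix::sparseMatrix(i = pat$i, p = pat$p, x = Kx_good,
                                 symmetric = TRUE, index1 = FALSE,
                                 dims = c(nfree, nfree))
      chol_fac <<- Matrix::Cholesky(Kg, LDL = FALSE, super = TRUE)
    }
    ok
  }

  update_operator <- function() {
    if (use_pcg) assign("A", Kmat(), pcg_env)
  }

  vcycle <- function(r) {
    A <- pcg_env$A; dA <- pcg_env$dA; om <- pcg_env$omega
    z <- om * r / dA
    rr <- r - as.numeric(A %*% z)
    z <- z + as.numeric(P %*% Matrix::solve(pcg_env$ch1, Matrix::crossprod(P, rr)))
    rr <- r - as.numeric(A %*% z)
    z + om * rr / dA
  }

  fsolve <- function(b, rtol = control$pcg_tol) {
    if (!use_pcg) return(as.numeric(Matrix::solve(chol_fac, b)))
    A <- pcg_env$A
    x <- numeric(nfree)
    r <- b
    z <- vcycle(r)
    p <- z
    rz <- sum(r * z)
    bnorm <- sqrt(sum(b^2))
    for (it in seq_len(control$pcg_maxit)) {
      Ap <- as.numeric(A %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) <= rtol * bnorm) break
      z <- vcycle(r)
      rz2 <- sum(r * z)
      beta <- rz2 / rz
      rz <- rz2
      p <- z + beta * p
    }
    if (control$verbose)
      message(sprintf("    pcg: %d iterations, rel res %.2e", it,
                      sqrt(sum(r^2)) / bnorm))
    x
  }

  mag <- sqrt(max(rowSums(matrix(uhat, ncol = 3, byrow = TRUE)^2)))
  if (is.null(schedule)) {
    nstep <- control$n_load_steps
    if (is.null(nstep)) nstep <- max(1L, ceiling(mag / 8))
    schedule <- seq_len(nstep) / nstep
  }
  stopifnot(!is.unsorted(schedule), all(schedule > 0), max(schedule) <= 1)
  record <- list()
  snapshots <- vector("list", length(schedule))

  u <- numeric(3L * nn)

  # Consistent linear predictor for a Dirichlet increment: with K and R at
  # the converged previous state, solve K_ff du_f = -(R_f + K_fp du_p),
  # where K_fp du_p is obtained by a directional finite difference of the
  # residual.  This moves the free nodes smoothly with the boundary instead
  # of imposing the full boundary jump across one element layer.
  predict <- function(u, t_from, t_to) {
    a0 <- assemble(u, TRUE)
    if (!a0$ok) stop("inadmissible state at start of load step")
    refactor()
    dup <- (t_to - t_from) * uhat
    eps <- 1e-4
    ue <- u
    ue[presc] <- u[presc] + eps * dup[presc]
    a1 <- assemble(ue, FALSE)
    if (!a1$ok) stop("inadmissible state in predictor difference")
    rhs <- a0$res + (a1$res - a0$res) / eps
    du <- fsolve(-rhs, rtol = 1e-3)
    u[presc] <- t_to * uhat[presc]
    u[free_idx] <- u[free_idx] + du
    u
  }

  newton <- function(u, t_target) {
    a <- assemble(u, FALSE)
    if (!a$ok) return(list(ok = FALSE, u = u, residual = Inf))
    rn <- sqrt(sum(a$res^2))
    tol <- control$tol_rel * max(rn, 1) + control$tol_abs
    if (control$verbose)
      message(sprintf("  t=%.3f predictor |R|=%.3e tol=%.3e", t_target, rn, tol))
    rn0 <- rn
    for (it in seq_len(control$max_iter)) {
      if (rn <= tol) break
      if (control$lag_tangent && !use_pcg) {
        # initial-stiffness iteration: reuse the factorization from the
        # start of the step, assemble residual only
        at <- assemble(u, FALSE)
        if (!at$ok) return(list(ok = FALSE, u = u, residual = rn))
      } else {
        t_a <- Sys.time()
        at <- assemble(u, TRUE)
        if (!at$ok) return(list(ok = FALSE, u = u, residual = rn))
        t_b <- Sys.time()
        if (use_pcg) update_operator() else refactor()
        if (control$verbose)
          message(sprintf("    [asm %.1fs fact %.1fs]",
                          as.numeric(t_b - t_a, units = "secs"),
                          as.numeric(Sys.time() - t_b, units = "secs")))
      }
      # inexact Newton forcing: loose inner solves far from the root and
      # once the outer residual approaches its tolerance
      eta <- min(0.3, max(control$pcg_tol, 0.5 * tol / rn,
                          min(1e-3, 0.1 * (rn / rn0))))
      du <- fsolve(-at$res, rtol = eta)
      s <- 1
      ok_ls <- FALSE
      for (bt in seq_len(control$max_backtrack)) {
        ut <- u
        ut[free_idx] <- u[free_idx] + s * du
        al <- assemble(ut, FALSE)
        if (al$ok && sqrt(sum(al$res^2)) < rn) { ok_ls <- TRUE; break }
        s <- s / 2
      }
      if (!ok_ls) return(list(ok = rn <= 10 * tol, u = u, residual = rn))
      u <- ut
      rn <- sqrt(sum(al$res^2))
      # fail fast into load-step bisection rather than grinding out the
      # full iteration budget on a hopeless step
      if (!control$lag_tangent && it >= 6 && rn > 0.3 * rn0)
        return(list(ok = FALSE, u = u, residual = rn))
      record[[length(record) + 1]] <<- data.frame(t = t_target, iter = it,
                                                  residual = rn, step_size = s)
      if (control$verbose)
        message(sprintf("  t=%.3f iter %d |R|=%.3e (s=%.3f)", t_target, it, rn, s))
    }
    list(ok = rn <= tol, u = u, residual = rn)
  }

  advance <- function(u, t_from, t_to, depth) {
    up <- predict(u, t_from, t_to)
    res <- newton(up, t_to)
    if (res$ok) return(res$u)
    if (depth >= control$max_bisect)
      stop(sprintf("Newton failed to converge at load factor %.3f (last residual %.3e)",
                   t_to, res$residual))
    tm <- (t_from + t_to) / 2
    u <- advance(u, t_from, tm, depth + 1)
    advance(u, tm, t_to, depth + 1)
  }

  tprev <- 0
  for (k in seq_along(schedule)) {
    u <- advance(u, tprev, schedule[k], 0)
    tprev <- schedule[k]
    snapshots[[k]] <- matrix(u, ncol = 3, byrow = TRUE)
  }

  structure(list(
    u = matrix(u, ncol = 3, byrow = TRUE),
    convergence = do.call(rbind, record),
    n_free = nfree, n_steps = length(schedule),
    schedule = schedule, snapshots = snapshots
  ), class = "displacement_field")
}

#' Solve the static micromotion problem
#'
#' Rigid mode (default) exploits the ~8 orders of magnitude stiffness
#' mismatch between silicon and brain: array degrees of freedom are
#' eliminated and every node of the array region (including the bonded
#' interface) carries the full prescribed displacement, while only the
#' tissue region is assembled.  Elastic mode retains the silicon region
#' with its linear material and drives the top face of the array base.
#'
#' @param mesh A [generate_mesh()] result.
#' @param bc A [boundary_conditions()].
#' @param tissue_material An [ogden_material()] (or [elastic_material()]
#'   for linearized verification runs).
#' @param array_material Silicon material for elastic mode.
#' @param mode `"rigid"` or `"elastic"`.
#' @param control A [solver_control()].
#' @param dirichlet Optional explicit constraint list overriding `bc`
#'   (each element `list(nodes=, value=)`), for verification problems.
#' @return A `displacement_field`: nodal displacements (`u`, n x 3 um) and
#'   the Newton convergence record.
#' @export
solve_static <- function(mesh, bc = boundary_conditions(),
                         tissue_material = ogden_material(),
                         array_material = elastic_material(),
                         mode = c("rigid", "elastic"),
                         control = solver_control(), dirichlet = NULL) {
  mode <- match.arg(mode)
  if (is.null(dirichlet)) {
    d <- bc$displacement
    sym <- list()
    if (isTRUE(mesh$half_x)) {
      if (abs(d[1]) > 1e-12)
        stop("half-domain mesh requires a load with no x component (angle 0)")
      sym <- list(list(nodes = mesh$sets$sym_x, value = c(0, 0, 0),
                       comps = c(TRUE, FALSE, FALSE)))
    }
    if (mode == "rigid") {
      dirichlet <- c(sym,
                     list(list(nodes = setdiff(mesh$sets$tissue_bottom, mesh$sets$array_nodes),
                               value = c(0, 0, 0)),
                          list(nodes = mesh$sets$array_nodes, value = d)))
    } else {
      dirichlet <- c(sym,
                     list(list(nodes = mesh$sets$tissue_bottom, value = c(0, 0, 0)),
                          list(nodes = mesh$sets$array_top, value = d)))
    }
  }
  hier <- list(n_vertex = mesh$n_vertex, midside_parents = mesh$midside_parents)
  if (mode == "rigid") {
    keep <- mesh$region == 1L
    out <- fem_solve(mesh$nodes, mesh$tets[keep, , drop = FALSE],
                     rep(1L, sum(keep)), list(tissue_material),
                     dirichlet, control, hierarchy = hier)
  } else {
    check_array_connectivity(mesh)
    out <- fem_solve(mesh$nodes, mesh$tets, mesh$region,
                     list(tissue_material, array_material),
                     dirichlet, control, hierarchy = hier)
  }
  out$bc <- bc
  out$mode <- mode
  out
}

#' Nodal Hencky strain and von Mises equivalent strain
#'
#' The deformation gradient is evaluated at every node of each tissue
#' element from the quadratic shape functions, the logarithmic (Hencky)
#' strain tensor is formed via the spectral decomposition of
#' \eqn{C = F^T F}, tensors are averaged over adjacent elements, and the
#' von Mises equivalent strain is computed from the principal values of
#' the averaged tensor with effective Poisson ratio `nu_eff`.
#'
#' @param mesh A `tet_mesh`.
#' @param displacement A `displacement_field` from [solve_static()].
#' @param nu_eff Effective Poisson ratio of the equivalent-strain formula.
#' @param regions Element regions over which strain is recovered
#'   (default: tissue only).
#' @return A `strain_field`: `eps` (n x 6 Hencky components xx, yy, zz,
#'   xy, yz, xz), `von_mises` (length n), `n_contrib` (elements averaged
#'   per node; 0 for nodes outside the requested regions).
#' @export
strain_from_displacement <- function(mesh, displacement, nu_eff = 0.5,
                                     regions = 1L) {
  u <- as.vector(t(displacement$u))
  out <- .strain_recover_cpp(mesh$nodes, mesh$tets, mesh$region,
                             as.integer(regions), u, nu_eff)
  structure(list(eps = out$eps, von_mises = as.numeric(out$von_mises),
                 n_contrib = as.integer(out$n_contrib),
                 nu_eff = nu_eff, mesh = mesh,
                 displacement = displacement), class = "strain_field")
}

#' Run one micromotion case end to end
#'
#' Builds (or reuses) the geometry and mesh, solves the static problem,
#' recovers strain, and summarizes the 50 um tip regions of interest into
#' a per-electrode strain table.
#'
#' @param array,tissue,mspec Specs ([array_spec()], [tissue_spec()],
#'   [mesh_spec()]).
#' @param bc A [boundary_conditions()].
#' @param mode `"rigid"` or `"elastic"`.
#' @param control A [solver_control()].
#' @param mesh Optional pre-built mesh (reused across boundary-condition
#'   sweeps).
#' @param roi_radius,bin_width ROI summarization parameters, um.
#' @return List of class `micromotion_case` with `mesh`, `displacement`,
#'   `strain` and `table` (an [electrode_strain_table()]).
#' @export
run_micromotion_case <- function(array, tissue = tissue_spec(),
                                 mspec = mesh_spec(), bc = boundary_conditions(),
                                 mode = "rigid", control = solver_control(),
                                 mesh = NULL, roi_radius = 50, bin_width = 2.5) {
  if (is.null(mesh)) mesh <- generate_mesh(build_geometry(array, tissue), mspec)
  disp <- solve_static(mesh, bc, mode = mode, control = control)
  sf <- strain_from_displacement(mesh, disp)
  tab <- electrode_strain_table(sf, radius = roi_radius, bin_width = bin_width)
  structure(list(mesh = mesh, displacement = disp, strain = sf, table = tab,
                 bc = bc), class = "micromotion_case")
}

#' Mesh convergence study on a single-shank model
#'
#' Solves the same single-shank micromotion problem on a sequence of
#' meshes with decreasing tip edge length and reports the volume-weighted
#' ROI-average von Mises strain of each, with relative errors against the
#' finest mesh.
#'
#' @param tip_edges Maximum tip-sphere edge lengths, um, sorted
#'   descending (e.g. `c(3, 2, 1, 0.5)`).
#' @param array,tissue Specs; defaults to a single-shank array.
#' @param mspec Base [mesh_spec()]; `tip_max_edge` is overridden per run.
#' @param bc,control Solver setup.
#' @return data.frame: `tip_edge`, `avg_strain`, `max_strain`,
#'   `n_elements`, `n_nodes`, `rel_error` (vs the finest mesh).
#' @export
mesh_convergence_study <- function(tip_edges = c(3, 2, 1, 0.5),
                                   array = array_spec(1, 1),
                                   tissue = tissue_spec(),
                                   mspec = mesh_spec(),
                                   bc = boundary_conditions(),
                                   control = solver_control()) {
  stopifnot(length(tip_edges) >= 2, !is.unsorted(rev(tip_edges)))
  geom <- build_geometry(array, tissue)
  rows <- lapply(tip_edges, function(h) {
    ms <- mspec
    ms$tip_max_edge <- h
    mesh <- generate_mesh(geom, ms)
    disp <- solve_static(mesh, bc, control = control)
    sf <- strain_from_displacement(mesh, disp)
    tab <- electrode_strain_table(sf)
    data.frame(tip_edge = h, avg_strain = tab$avg_strain[1],
               max_strain = tab$max_strain[1],
               n_elements = mesh$n_elements, n_nodes = mesh$n_nodes)
  })
  out <- do.call(rbind, rows)
  out$rel_error <- abs(out$avg_strain - out$avg_strain[nrow(out)]) /
    abs(out$avg_strain[nrow(out)])
  out
}

#' Solve a displacement-magnitude sweep by load continuation
#'
#' Solves the rigid-mode micromotion problem for several displacement
#' magnitudes at a fixed angle in one continuation run: the load is
#' ramped to the largest magnitude with every requested magnitude as an
#' intermediate equilibrium, reusing the assembled pattern and
#' preconditioner throughout.
#'
#' @param mesh A `tet_mesh`.
#' @param magnitudes Displacement magnitudes, um (ascending).
#' @param angle In-plane angle from the Y axis, degrees.
#' @param tissue_material,control See [solve_static()].
#' @return Named list of `micromotion_case`-like results: for each
#'   magnitude, `displacement`, `strain` and `table`.
#' @export
solve_magnitude_sweep <- function(mesh, magnitudes = c(1, 5, 10, 20, 50),
                                  angle = 0,
                                  tissue_material = ogden_material(),
                                  control = solver_control()) {
  stopifnot(!is.unsorted(magnitudes), all(magnitudes > 0))
  bc <- boundary_conditions(max(magnitudes), angle)
  d <- bc$displacement
  sym <- list()
  if (isTRUE(mesh$half_x)) {
    if (abs(d[1]) > 1e-12)
      stop("half-domain mesh requires a load with no x component (angle 0)")
    sym <- list(list(nodes = mesh$sets$sym_x, value = c(0, 0, 0),
                     comps = c(TRUE, FALSE, FALSE)))
  }
  dirichlet <- c(sym, list(
    list(nodes = setdiff(mesh$sets$tissue_bottom, mesh$sets$array_nodes),
         value = c(0, 0, 0)),
    list(nodes = mesh$sets$array_nodes, value = d)))
  keep <- mesh$region == 1L
  sched <- magnitudes / max(magnitudes)
  sol <- fem_solve(mesh$nodes, mesh$tets[keep, , drop = FALSE],
                   rep(1L, sum(keep)), list(tissue_material), dirichlet,
                   control,
                   hierarchy = list(n_vertex = mesh$n_vertex,
                                    midside_parents = mesh$midside_parents),
                   schedule = sched)
  out <- lapply(seq_along(magnitudes), function(k) {
    disp <- structure(list(u = sol$snapshots[[k]],
                           convergence = sol$convergence,
                           bc = boundary_conditions(magnitudes[k], angle)),
                      class = "displacement_field")
    sf <- strain_from_displacement(mesh, disp)
    list(displacement = disp, strain = sf,
         table = electrode_strain_table(sf))
  })
  names(out) <- paste0("mag", magnitudes)
  out
}

# Elastic mode transmits the drive through the meshed silicon, so the
# array region must form one connected solid from the driven top face to
# the tips.  The voxelized array representation only achieves that when
# the background cells are smaller than the shank cross-section; warn
# when the region falls apart at the meshed resolution.
check_array_connectivity <- function(mesh) {
  arr <- which(mesh$region == 2L)
  if (length(arr) < 2) {
    warning("array region is nearly empty at this resolution; ",
            "elastic mode results are not meaningful")
    return(invisible(FALSE))
  }
  Tarr <- mesh$tets[arr, 1:4, drop = FALSE]
  verts <- sort(unique(as.vector(Tarr)))
  vid <- match(Tarr, verts)
  dim(vid) <- dim(Tarr)
  # union-find over array vertices through shared elements
  parent <- seq_along(verts)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(nrow(vid))) {
    r <- find(vid[e, 1])
    for (j in 2:4) { rj <- find(vid[e, j]); if (rj != r) parent[rj] <- r }
  }
  roots <- vapply(seq_along(verts), find, 1L)
  top <- unique(roots[verts %in% mesh$sets$array_top])
  if (length(unique(roots)) > length(top) || length(top) == 0) {
    warning("array region is not contiguous from the driven face to the ",
            "tips at this mesh resolution (background cells exceed the ",
            "shank width); elastic mode will underestimate tip motion -- ",
            "use rigid mode or refine the mesh")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
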