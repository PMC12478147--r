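# Branch enumeration and the (d, A) phase diagram of the planar ring.

#' Enumerate stationary branches of the constrained planar ring
#'
#' Solves the half-ring boundary-value problem from a catalog of seeds
#' (curvature Fourier perturbations of the circle, lobe numbers 2--4, both
#' signs and phases), deduplicates converged solutions into distinct
#' curvature profiles, and assembles full-ring solution branches.
#'
#' The marked points act as clamps (both position and tangent direction are
#' imposed by the germ band), so the ring's curvature may jump there and the
#' upper and lower half-rings decouple once the multipliers are shared.  An
#' AP-asymmetric half-profile `P` therefore generates a four-fold degenerate
#' family: the pairings (P, P), (P', P'), (P, P'), (P', P) of `P` with its AP
#' reflection `P'` as upper/lower halves -- two bilaterally symmetric
#' keyholes (apex at either marked point) and two skew variants, all of
#' exactly equal bending energy.  These are labeled `asymmetric-1..4`.
#'
#' @param d,A Constraints as in [solve_half_ring_bvp()].
#' @param modes Integer vector of perturbation lobe numbers for the seed
#'   catalog.
#' @param amplitude Seed perturbation amplitude(s).
#' @param n_mesh,tol,refine Passed to [solve_half_ring_bvp()].
#' @param dedup_tol Normalized root-mean-square curvature distance under
#'   which two converged profiles count as the same branch.
#' @return An object of class `elastica_branches`: a list of `elastica_ring`
#'   solutions sorted by energy, with a `summary` tibble attribute
#'   (see [tidy.elastica_branches()]).
#' @export
#' @examples
#' \donttest{
#' br <- enumerate_branches(2 / pi, 0.9 / pi, n_mesh = 151)
#' tidy(br)
#' }
enumerate_branches <- function(d, A, modes = 2:4, amplitude = 0.1,
                               n_mesh = 201L, tol = 1e-10, refine = TRUE,
                               dedup_tol = 1e-4) {
  check_feasible(d, A)
  d0 <- d0_circle(); A0 <- A0_circle()
  if (abs(d - d0) < 1e-12 && abs(A - A0) < 1e-12) {
    sol <- circle_solution()
    return(new_elastica_branches(list(sol)))
  }
  seeds <- list()
  for (m in modes) for (ph in c("cos", "sin")) for (sg in c(1, -1))
    for (am in amplitude) {
      seeds[[length(seeds) + 1L]] <- ring_seed(m, sg, ph, am)
    }
  sols <- list()
  n_failed <- 0L
  for (sd in seeds) {
    s <- tryCatch(
      solve_half_ring_bvp(d, A, seed = sd, n_mesh = n_mesh, tol = tol,
                          refine = refine),
      morphoring_no_convergence = function(e) NULL)
    if (is.null(s)) n_failed <- n_failed + 1L else sols[[length(sols) + 1L]] <- s
  }
  if (n_failed > 0L) {
    rlang::warn(sprintf("%d of %d branch seeds failed to converge and were dropped",
                        n_failed, length(seeds)))
  }
  if (length(sols) == 0L) {
    rlang::abort("no branch seed converged", class = "morphoring_no_convergence")
  }
  # deduplicate into distinct shapes (profiles modulo AP reflection)
  shapes <- list()
  for (s in sols) {
    dup <- FALSE
    for (sh in shapes) {
      if (profile_distance(s, sh, reflect = TRUE) < dedup_tol) {
        dup <- TRUE; break
      }
    }
    if (!dup) shapes[[length(shapes) + 1L]] <- s
  }
  # assemble members: symmetric shapes singly, asymmetric shapes as quartets
  members <- list()
  for (sh in shapes) {
    if (is_ap_symmetric(sh)) {
      members[[length(members) + 1L]] <- sh
    } else {
      shr <- reflect_solution(sh)
      quartet <- list(
        pair_solution(sh, sh), pair_solution(shr, shr),
        pair_solution(sh, shr), pair_solution(shr, sh))
      members <- c(members, quartet)
    }
  }
  members <- members[order(vapply(members, function(x) x$energy, numeric(1)))]
  # label the lowest asymmetric family asymmetric-1..4
  is_asym <- vapply(members, function(x) !is_ap_symmetric(x), logical(1))
  if (any(is_asym)) {
    fam_energy <- members[[which(is_asym)[1L]]]$energy
    k <- 0L
    for (i in seq_along(members)) {
      if (is_asym[i] && abs(members[[i]]$energy - fam_energy) <
            1e-9 * (1 + fam_energy)) {
        k <- k + 1L
        members[[i]]$branch <- sprintf("asymmetric-%d", min(k, 4L))
      } else if (is_asym[i]) {
        members[[i]]$branch <- "higher-mode"
      }
    }
  }
  new_elastica_branches(members)
}

# upper/lower pairing of two half-ring solutions sharing (d, A_half, lambda0, p)
pair_solution <- function(upper, lower) {
  out <- upper
  out$lower <- lower$profile
  out$energy <- (trapz_energy(upper$profile) + trapz_energy(lower$profile)) / 2
  out$branch <- upper$branch
  out
}

trapz_energy <- function(prof) {
  simpson_uniform(prof$s[2L] - prof$s[1L], prof$kappa^2)
}

is_ap_symmetric <- function(sol, tol = 1e-3) {
  k <- sol$profile$kappa
  sqrt(mean((k - rev(k))^2)) / sqrt(mean(k^2)) < tol
}

profile_distance <- function(a, b, reflect = FALSE) {
  ka <- a$profile$kappa; kb <- b$profile$kappa
  if (length(ka) != length(kb)) {
    kb <- stats::spline(b$profile$s, kb, xout = a$profile$s)$y
  }
  d1 <- sqrt(mean((ka - kb)^2))
  d2 <- if (reflect) sqrt(mean((ka - rev(kb))^2)) else Inf
  min(d1, d2) / (1 + sqrt(mean(ka^2)))
}

new_elastica_branches <- function(members) {
  structure(members, class = "elastica_branches")
}

#' @export
print.elastica_branches <- function(x, ...) {
  cat(sprintf("<elastica_branches> %d members\n", length(x)))
  for (m in x) {
    cat(sprintf("  %-16s E = %.8f\n", m$branch, m$energy))
  }
  invisible(x)
}

#' Full-ring curve of a planar solution
#'
#' Stitches the upper half-profile and the (possibly different) lower
#' half-profile into the closed ring: the lower half is the reflection of
#' its half-ring solution in the AP axis, traversed from `(d, 0)` back to
#' the origin.
#'
#' @param sol An `elastica_ring`.
#' @return A tibble with columns `s` (full-ring arclength in `[0, 2]`),
#'   `x`, `y`, `kappa`.
#' @export
full_ring_curve <- function(sol) {
  stopifnot(inherits(sol, "elastica_ring"))
  up <- sol$profile
  lo <- if (!is.null(sol$lower)) sol$lower else up
  n <- nrow(lo)
  idx <- rev(seq_len(n))[-1L]
  tibble::tibble(
    s = c(up$s, 2 - lo$s[idx]),
    x = c(up$x, lo$x[idx]),
    y = c(up$y, -lo$y[idx]),
    kappa = c(up$kappa, lo$kappa[idx]))
}

#' Scan the (d, A) plane and classify the lowest-energy branch
#'
#' For every accessible grid cell (`A <= max_area_for_diameter(d)`) the
#' asymmetric keyhole branch and the two leading AP-symmetric branches are
#' tracked by warm-started continuation down each grid column, and the cell
#' is classified by the symmetry of its minimum-energy branch.  Cells where
#' a branch fails to converge are marked `unresolved`, never silently filled.
#'
#' @param d_grid,A_grid Numeric grids (dimensionless); defaults span
#'   `d/d0` in `[0.7, 1.4]` and `A/A0` in `[0.5, 1.0]` with 21 points each.
#' @param n_mesh Collocation mesh for the scan (speed/accuracy trade-off).
#' @param tol Newton tolerance.
#' @return A tibble of class `ring_phase_diagram` with one row per cell:
#'   `d`, `A`, `d_rel` (`d/d0`), `A_rel` (`A/A0`), `accessible`,
#'   `E_asymmetric`, `E_symmetric`, `lowest_class`
#'   (`"circle"`, `"asymmetric"`, `"symmetric"`, `"inaccessible"`,
#'   `"unresolved"`).
#' @export
scan_phase_diagram <- function(d_grid = seq(0.7, 1.4, length.out = 21) * 2 / pi,
                               A_grid = seq(0.5, 1.0, length.out = 21) / pi,
                               n_mesh = 121L, tol = 1e-9) {
  stopifnot(all(d_grid > 0), all(d_grid <= 1), all(A_grid > 0),
            all(A_grid <= 1 / pi + 1e-12))
  d0 <- d0_circle(); A0 <- A0_circle()
  d_grid <- sort(d_grid); A_grid <- sort(A_grid, decreasing = TRUE)
  amax <- max_area_for_diameter(d_grid)
  s <- seq(0, 1, length.out = n_mesh)
  h <- s[2L] - s[1L]

  branch_seeds <- list(
    asym = ring_seed(3L, 1, "cos"),
    sym_a = ring_seed(2L, -1, "cos"),
    sym_b = ring_seed(2L, 1, "cos"))

  # track branch states per column, seeded from the previous column
  cells <- vector("list", length(d_grid) * length(A_grid))
  ci <- 0L
  # order columns from the one nearest d0 outward
  col_order <- order(abs(d_grid - d0))
  col_states <- vector("list", length(d_grid))

  for (jj in col_order) {
    dj <- d_grid[jj]
    # find a neighboring solved column to warm-start from
    nb <- NULL
    solved <- which(!vapply(col_states, is.null, logical(1)))
    if (length(solved)) nb <- solved[which.min(abs(d_grid[solved] - dj))]
    cold_fails <- list(asym = 0L, sym_a = 0L, sym_b = 0L)
    col_cells <- vector("list", length(A_grid))
    col_states[[jj]] <- list(asym = vector("list", length(A_grid)),
                             sym_a = vector("list", length(A_grid)),
                             sym_b = vector("list", length(A_grid)))
    accessible_rows <- which(A_grid <= amax[jj] + 1e-12)
    for (ii in setdiff(seq_along(A_grid), accessible_rows)) {
      col_cells[[ii]] <- cell_row(dj, A_grid[ii], d0, A0, FALSE, NA, NA,
                                  "inaccessible")
    }
    if (length(accessible_rows) == 0L) {
      for (ii in seq_along(A_grid)) {
        ci <- ci + 1L
        cells[[ci]] <- col_cells[[ii]]
      }
      next
    }
    # anchor the column at an easy mid-range area, then sweep up and down
    anchor <- accessible_rows[which.min(abs(A_grid[accessible_rows] -
                                              0.7 * A0))]
    upward <- rev(accessible_rows[accessible_rows < anchor])
    downward <- accessible_rows[accessible_rows >= anchor]
    anchor_states <- NULL
    for (sweep in list(downward, upward)) {
      states <- anchor_states
      if (is.null(states)) states <- list()
      dead <- list(asym = 0L, sym_a = 0L, sym_b = 0L)
      for (ii in sweep) {
        Ai <- A_grid[ii]
        if (abs(dj - d0) < 1e-12 && abs(Ai - A0) < 1e-12) {
          col_cells[[ii]] <- cell_row(dj, Ai, d0, A0, TRUE, pi^2, pi^2,
                                      "circle")
          next
        }
        # energies by symmetry class of the converged state (a tracked
        # branch that merges into the other class is counted there)
        e_asym <- NA_real_; e_sym <- NA_real_
        for (bn in names(branch_seeds)) {
          if (dead[[bn]] >= 2L) next        # branch folded away up-sweep
          st <- states[[bn]]
          if (is.null(st) && !is.null(nb)) st <- col_states[[nb]][[bn]][[ii]]
          z <- branch_step(st, bn, branch_seeds[[bn]], dj, Ai, s, h,
                           n_mesh, tol,
                           allow_cold = cold_fails[[bn]] < 3L)
          if (is.null(z) && ii == anchor) {
            z <- rescue_branch(dj, Ai, bn == "asym", s, h, n_mesh, tol)
          }
          if (!is.null(z)) {
            Y <- matrix(z[seq_len(6L * n_mesh)], n_mesh, 6L, byrow = TRUE)
            E_b <- simpson_uniform(h, Y[, 1L]^2)
            k <- Y[, 1L]
            is_asym <- sqrt(mean((k - rev(k))^2)) / sqrt(mean(k^2)) > 1e-3
            if (is_asym) e_asym <- min(e_asym, E_b, na.rm = TRUE)
            else e_sym <- min(e_sym, E_b, na.rm = TRUE)
            states[[bn]] <- z
            col_states[[jj]][[bn]][ii] <- list(z)
            dead[[bn]] <- 0L
          } else {
            # keep the previous state for warm-starting the next row;
            # give up on cold starts after a few failures in this column
            cold_fails[[bn]] <- cold_fails[[bn]] + 1L
            dead[[bn]] <- dead[[bn]] + 1L
            col_states[[jj]][[bn]][ii] <- list(NULL)
          }
        }
        if (ii == anchor) anchor_states <- states
        cls <- if (is.na(e_asym) && is.na(e_sym)) "unresolved"
               else if (is.na(e_sym)) "asymmetric"
               else if (is.na(e_asym)) "symmetric"
               else if (e_asym < e_sym) "asymmetric" else "symmetric"
        col_cells[[ii]] <- cell_row(dj, Ai, d0, A0, TRUE, e_asym, e_sym, cls)
      }
    }
    for (ii in seq_along(A_grid)) {
      ci <- ci + 1L
      cells[[ci]] <- col_cells[[ii]]
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(cells), .data$d, dplyr::desc(.data$A))
  class(out) <- c("ring_phase_diagram", class(out))
  out
}

cell_row <- function(d, A, d0, A0, acc, e_asym, e_sym, cls) {
  tibble::tibble(d = d, A = A, d_rel = d / d0, A_rel = A / A0,
                 accessible = acc,
                 E_asymmetric = as.numeric(e_asym),
                 E_symmetric = as.numeric(e_sym),
                 lowest_class = cls)
}

# last-resort seed sweep at a column's anchor cell: look for the lowest
# branch of the wanted symmetry class among large-amplitude seeds
rescue_branch <- function(d, A, want_asym, s, h, n_mesh, tol) {
  best <- NULL; best_E <- Inf
  for (m in 2:3) for (ph in c("cos", "sin")) for (sg in c(1, -1)) {
    sol <- tryCatch(
      solve_half_ring_bvp(d, A, seed = ring_seed(m, sg, ph, 0.4),
                          n_mesh = n_mesh, tol = tol, refine = FALSE),
      error = function(e) NULL)
    if (is.null(sol)) next
    k <- sol$profile$kappa
    is_asym <- sqrt(mean((k - rev(k))^2)) / sqrt(mean(k^2)) > 1e-3
    if (is_asym != want_asym || sol$energy >= best_E) next
    kap <- stats::spline(sol$profile$s, k, xout = s)$y
    z <- colloc_init_from_kappa(kap, s, sol$lambda0, sol$p)
    nw <- colloc_newton(z, n_mesh, h, d, A, tol = tol)
    if (nw$converged) { best <- nw$z; best_E <- sol$energy }
  }
  best
}

# advance one tracked branch to (d, A): warm start from a previous state or
# (once per column) freshly continue from the circle; substep in A on
# failure.
branch_step <- function(state, name, seed, d, A, s, h, n_mesh, tol,
                        allow_cold = TRUE) {
  if (!is.null(state)) {
    nw <- colloc_newton(state, n_mesh, h, d, A, tol = tol, max_iter = 14L,
                        stall_limit = 12L)
    if (nw$converged) return(nw$z)
    # if the direct attempt got nowhere near, the branch has likely folded
    # away; otherwise retry through joint intermediate (d, A) steps
    if (nw$res < 1e-2) {
      Yold <- matrix(state[seq_len(6L * n_mesh)], n_mesh, 6L, byrow = TRUE)
      old_A <- Yold[n_mesh, 6L]
      old_d <- Yold[n_mesh, 4L]
      z <- state
      ok <- TRUE
      for (f in c(1 / 3, 2 / 3, 1)) {
        nw <- colloc_newton(z, n_mesh, h, old_d + f * (d - old_d),
                            old_A + f * (A - old_A), tol = tol,
                            max_iter = 10L, stall_limit = 10L)
        if (!nw$converged) { ok <- FALSE; break }
        z <- nw$z
      }
      if (ok) return(z)
    }
  }
  if (!allow_cold) return(NULL)
  # cold start: full continuation from the circle
  sol <- tryCatch(
    solve_half_ring_bvp(d, A, seed = seed, n_mesh = n_mesh, tol = tol,
                        refine = FALSE),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  kap <- stats::spline(sol$profile$s, sol$profile$kappa, xout = s)$y
  z <- colloc_init_from_kappa(kap, s, sol$lambda0, sol$p)
  nw <- colloc_newton(z, n_mesh, h, d, A, tol = tol)
  if (nw$converged) nw$z else NULL
}
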