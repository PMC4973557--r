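#' Solve a bounded linear program
#'
#' Thin R interface to the package's dense bounded-variable simplex. Solves
#' `max/min c'v` subject to `A v = b` and `lb <= v <= ub` (entries of the
#' bounds may be `-Inf`/`Inf`).
#'
#' @param obj numeric objective coefficients (length `ncol(A)`).
#' @param A dense constraint matrix (equality rows).
#' @param b right-hand side vector.
#' @param lb,ub per-variable bounds.
#' @param sense `"max"` or `"min"`.
#' @param tol optimality/feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x` (solution), `objective`.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, sense = "max", tol = 1e-9) {
  stopifnot(length(obj) == ncol(A), length(b) == nrow(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  if (any(lb > ub)) {
    abort("lp_solve: lower bound exceeds upper bound for some variable")
  }
  res <- .simplex_cpp(A, b, obj, lb, ub, maximize = identical(sense, "max"),
                      tol = tol)
  status <- c("optimal", "infeasible", "unbounded", "maxiter")[res$status + 1L]
  list(status = status, x = res$x, objective = res$objective,
       iterations = res$iterations)
}

# ---------------------------------------------------------------------------
# Lexicographic / phase-I machinery.
#
# All levels are solved on one augmented LP whose constraint matrix is fixed:
#
#   structural fluxes v (n)                user bounds
#   elastic slacks p, n (one pair          [0, Inf)
#     per balanced metabolite):  S v + p - n = 0
#   elastic relaxations (r_j, s_j) for each designated regulatory lower
#     bound:                     v_j + r_j - s_j = 0,  r_j >= 0, s_j >= lb_j
#     (v_j's own lower bound is dropped so the violation is measured by r_j)
#   fix slacks s_k, one per lexicographic level except the last:
#     c_k' z - s_k = 0; the slack's bounds pin earlier optima.
#
# The phase-I penalty Theta = min sum(p) + sum(n) + sum(r) is always the
# first level; when the problem is feasible it is 0 and the elastic columns
# are inert.
# ---------------------------------------------------------------------------

#' Precompute the augmented lexicographic LP for a network
#'
#' @param network a [stoich_network()].
#' @param priorities a priority list, see [default_priorities()].
#' @param elastic reaction ids whose *lower* bounds are elastic in the
#'   phase-I relaxation; defaults to the chlorophyll and carotene
#'   accumulation reactions (the only bounds the regulatory models can make
#'   conflicting).
#' @keywords internal
lex_setup <- function(network, priorities = default_priorities(network),
                      elastic = NULL) {
  S <- network$S
  bal <- network$metabolites$balanced
  Sb <- S[bal, , drop = FALSE]
  m <- nrow(Sb)
  n <- ncol(Sb)
  rxn <- network$reactions$id

  if (is.null(elastic)) {
    elastic <- rxn[network$reactions$role %in% c("chl_acc", "car_acc")]
  }
  e_idx <- match(elastic, rxn)
  ne <- length(e_idx)

  k_obj <- nrow(priorities)
  # objective rows in full column space (penalty first, then user levels)
  n_fix <- k_obj            # fix slacks for penalty + all levels but the last
  ncol_tot <- n + 2L * m + 2L * ne + n_fix

  A <- matrix(0, m + ne + n_fix, ncol_tot)
  A[seq_len(m), seq_len(n)] <- Sb
  A[seq_len(m), n + seq_len(m)] <- diag(m)                # +p
  A[seq_len(m), n + m + seq_len(m)] <- -diag(m)           # -n
  if (ne > 0) {
    for (k in seq_len(ne)) {
      A[m + k, e_idx[k]] <- 1                              # v_j
      A[m + k, n + 2L * m + k] <- 1                        # + r_j
      A[m + k, n + 2L * m + ne + k] <- -1                  # - s_j
    }
  }
  # objective coefficient rows (in full column space)
  C <- matrix(0, k_obj + 1L, ncol_tot)
  C[1L, n + seq_len(2L * m)] <- 1                          # penalty: p, n
  if (ne > 0) C[1L, n + 2L * m + seq_len(ne)] <- 1         # ... and r
  for (k in seq_len(k_obj)) {
    C[k + 1L, seq_len(n)] <- priority_coef(priorities, k, rxn)
  }
  senses <- c("min", priorities$sense)
  # fix rows: c_k' z - s_k = 0 for the first k_obj objectives
  fix_col <- n + 2L * m + 2L * ne + seq_len(n_fix)
  for (k in seq_len(n_fix)) {
    A[m + ne + k, ] <- C[k, ]
    A[m + ne + k, fix_col[k]] <- -1
  }
  b <- rep(0, nrow(A))

  list(A = A, b = b, C = C, senses = senses, n = n, m = m,
       e_idx = e_idx, ne = ne, fix_col = fix_col, rxn = rxn)
}

#' Run the lexicographic solve for given bounds
#'
#' @param setup result of [lex_setup()].
#' @param lb,ub per-reaction bounds (full vectors in network reaction order).
#' @param tol LP tolerance.
#' @param fix_abs,fix_rel tolerances used to pin earlier objective optima.
#' @return list with `flux`, `objective_values` (user levels), `penalty`,
#'   `status` (worst over levels).
#' @keywords internal
lex_run <- function(setup, lb, ub, tol = 1e-9,
                    fix_abs = 1e-9, fix_rel = 1e-7) {
  n <- setup$n; m <- setup$m; ne <- setup$ne
  ntot <- ncol(setup$A)
  LO <- rep(0, ntot)
  HI <- rep(Inf, ntot)
  LO[seq_len(n)] <- lb
  HI[seq_len(n)] <- ub
  if (ne > 0) {
    # violation of the elastic lower bounds is carried by r_j >= 0
    s_col <- n + 2L * m + ne + seq_len(ne)
    LO[s_col] <- lb[setup$e_idx]
    HI[s_col] <- Inf
    LO[setup$e_idx] <- -Inf
  }
  LO[setup$fix_col] <- -Inf                 # fix slacks inert until pinned

  res <- .lex_cpp(setup$A, setup$b, setup$C,
                  setup$senses == "max", LO, HI,
                  as.integer(setup$fix_col), fix_abs, fix_rel, tol)
  st <- c("optimal", "infeasible", "unbounded", "maxiter")[res$status + 1L]
  if (st != "optimal") {
    return(list(flux = res$x[seq_len(n)], objective_values = res$objectives,
                penalty = NA_real_, status = st, level = res$level))
  }
  list(flux = res$x[seq_len(n)], objective_values = res$objectives[-1L],
       penalty = res$objectives[1L], status = st, level = res$level)
}

priority_coef <- function(priorities, k, rxn) {
  tgt <- priorities$objective[[k]]
  co <- numeric(length(rxn))
  if (is.character(tgt) && length(tgt) == 1L) {
    j <- match(tgt, rxn)
    if (is.na(j)) abort(paste0("priority objective '", tgt, "' is not a reaction"))
    co[j] <- 1
  } else if (is.numeric(tgt) && !is.null(names(tgt))) {
    j <- match(names(tgt), rxn)
    if (anyNA(j)) abort("priority objective names must be reaction ids")
    co[j] <- tgt
  } else {
    abort("each priority objective must be a reaction id or a named coefficient vector")
  }
  co
}

#' Default lexicographic priority list
#'
#' Growth first, then pigments, then nutrient uptake: (1) maximize biomass,
#' (2) minimize chlorophyll accumulation, (3) minimize beta-carotene
#' accumulation, (4) minimize the magnitude of the (non-positive) nitrate
#' metabolization flux, i.e. maximize its signed value towards zero.
#'
#' @param network a [stoich_network()].
#' @return a `priority_list` tibble with columns `objective` (list of
#'   reaction ids or named coefficient vectors) and `sense`.
#' @export
default_priorities <- function(network) {
  roles <- network_roles(network)
  priority_list(
    list(roles[["biomass"]], "max"),
    list(roles[["chl_acc"]], "min"),
    list(roles[["car_acc"]], "min"),
    list(roles[["nitrate_met"]], "max")
  )
}

#' Build a priority list
#'
#' @param ... each argument is `list(objective, sense)` where `objective` is
#'   a reaction id or a named coefficient vector and `sense` is `"max"` or
#'   `"min"`.
#' @export
priority_list <- function(...) {
  items <- list(...)
  if (length(items) == 0L) abort("priority list must be non-empty")
  out <- tibble(
    objective = purrr::map(items, 1L),
    sense = purrr::map_chr(items, 2L)
  )
  if (!all(out$sense %in% c("max", "min"))) {
    abort("priority senses must be 'max' or 'min'")
  }
  class(out) <- c("priority_list", class(out))
  out
}

resolve_bounds <- function(network, bounds = NULL) {
  lb <- network$reactions$lb
  ub <- network$reactions$ub
  names(lb) <- names(ub) <- network$reactions$id
  if (!is.null(bounds)) {
    if (is.data.frame(bounds)) {
      bl <- setNames(purrr::map2(bounds$lb, bounds$ub, c), bounds$reaction)
    } else {
      bl <- bounds
    }
    for (id in names(bl)) {
      j <- match(id, network$reactions$id)
      if (is.na(j)) abort(paste0("bound override for unknown reaction '", id, "'"))
      lb[j] <- bl[[id]][1L]
      ub[j] <- bl[[id]][2L]
    }
  }
  if (any(lb > ub)) abort("bound overrides yield lb > ub")
  list(lb = unname(lb), ub = unname(ub))
}

#' Flux balance analysis with a single objective
#'
#' Solves `max/min c'v` subject to steady-state mass balance `S v = 0` on the
#' balanced metabolites and flux bounds. Infeasible problems are relaxed by
#' the phase-I elastic program and reported with a positive penalty.
#'
#' @param network a [stoich_network()].
#' @param bounds optional per-reaction bound overrides: a named list of
#'   `c(lb, ub)` or a tibble with columns `reaction`, `lb`, `ub`.
#' @param objective reaction id (or named coefficient vector); defaults to
#'   the biomass reaction.
#' @param sense `"max"` (default) or `"min"`.
#' @return an `fba_solution`: list with `flux` tibble, `objective_values`,
#'   `penalty`, `feasible`, `status`.
#' @examples
#' net <- toy_network()
#' sol <- solve_fba(net, bounds = list(EX_photon = c(-10, -10)))
#' sol$objective_values
#' @export
solve_fba <- function(network, bounds = NULL, objective = NULL, sense = "max") {
  if (is.null(objective)) objective <- network_roles(network)[["biomass"]]
  pri <- priority_list(list(objective, sense))
  solve_lexicographic(network, bounds, pri)
}

#' Lexicographic flux balance analysis
#'
#' Solves a priority-ordered sequence of LPs: level 1 is solved first, then
#' each subsequent level is solved with all earlier objectives constrained to
#' their optimal values (absolute fixing tolerance 1e-9, relative 1e-7 for
#' values above 1). The phase-I penalty is always minimized first, so an
#' infeasible instance falls back to the elastic relaxation and records a
#' positive penalty instead of failing.
#'
#' @inheritParams solve_fba
#' @param priorities a [priority_list()]; defaults to
#'   [default_priorities()] (biomass, chlorophyll, carotene, nitrate).
#' @return an `fba_solution` (see [solve_fba()]); `objective_values` has one
#'   entry per priority level.
#' @export
solve_lexicographic <- function(network, bounds = NULL,
                                priorities = default_priorities(network)) {
  bb <- resolve_bounds(network, bounds)
  setup <- lex_setup(network, priorities)
  res <- lex_run(setup, bb$lb, bb$ub)
  if (res$status == "unbounded") {
    abort(paste0("LP unbounded at priority level ", res$level,
                 " (a missing flux bound?)"))
  }
  if (res$status == "maxiter") abort("LP iteration limit reached")
  new_fba_solution(network, res)
}

new_fba_solution <- function(network, res) {
  structure(
    list(
      flux = tibble(reaction = network$reactions$id, flux = res$flux),
      objective_values = res$objective_values,
      penalty = res$penalty,
      feasible = is.finite(res$penalty) && res$penalty <= 1e-6,
      status = res$status
    ),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution>  penalty:", format(x$penalty),
      " feasible:", x$feasible, "\n")
  cat("objective values:", paste(format(x$objective_values, digits = 6),
                                 collapse = ", "), "\n")
  print(x$flux, n = nrow(x$flux))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fba_solution <- function(x, ...) x$flux

#' @exportS3Method generics::glance
glance.fba_solution <- function(x, ...) {
  tibble(penalty = x$penalty, feasible = x$feasible,
         levels = length(x$objective_values),
         objective_1 = x$objective_values[1L])
}

#' Phase-I elastic relaxation
#'
#' Minimizes the total constraint violation of the steady-state system:
#' non-negative elastic slacks on every balanced-metabolite mass balance and
#' on the regulatory lower bounds (chlorophyll and carotene accumulation),
#' each with weight one. The optimum `Theta` is zero if and only if the
#' original problem is feasible; when positive, the returned relaxed lower
#' bounds make the lexicographic sequence solvable.
#'
#' @inheritParams solve_fba
#' @return list with `penalty` (Theta), `bounds` (tibble of relaxed bounds)
#'   and `slacks` (mass-balance violations by metabolite).
#' @export
phase1_relax <- function(network, bounds = NULL) {
  bb <- resolve_bounds(network, bounds)
  # a single-level setup: penalty, then nothing else matters
  pri <- priority_list(list(network_roles(network)[["biomass"]], "max"))
  setup <- lex_setup(network, pri)
  n <- setup$n; m <- setup$m; ne <- setup$ne
  ntot <- ncol(setup$A)
  LO <- rep(0, ntot); HI <- rep(Inf, ntot)
  LO[seq_len(n)] <- bb$lb; HI[seq_len(n)] <- bb$ub
  if (ne > 0) {
    s_col <- n + 2L * m + ne + seq_len(ne)
    LO[s_col] <- bb$lb[setup$e_idx]
    LO[setup$e_idx] <- -Inf
  }
  LO[setup$fix_col] <- -Inf
  res <- .simplex_cpp(setup$A, setup$b, setup$C[1L, ], LO, HI,
                      maximize = FALSE, tol = 1e-9)
  if (res$status != 0L) abort("phase-I LP did not solve (unexpected)")
  theta <- res$objective
  r <- if (ne > 0) res$x[n + 2L * m + seq_len(ne)] else numeric(0)
  lb_rel <- bb$lb
  if (ne > 0) lb_rel[setup$e_idx] <- bb$lb[setup$e_idx] - r
  slack_p <- res$x[n + seq_len(m)]
  slack_n <- res$x[n + m + seq_len(m)]
  list(
    penalty = max(0, theta),
    bounds = tibble(reaction = network$reactions$id,
                    lb = lb_rel, ub = bb$ub),
    slacks = tibble(
      metabolite = network$metabolites$id[network$metabolites$balanced],
      violation = slack_p - slack_n
    )
  )
}
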