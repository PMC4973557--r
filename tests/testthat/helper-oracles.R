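# Shared fixtures and independent oracles.

toy <- toy_network()
PSET1 <- algal_parameters("set_I")
PSET2 <- algal_parameters("set_II")

# Enumerate every vertex of {S_bal v = 0, lb <= v <= ub} (finite bounds) by
# fixing n - m variables at a bound and solving the square system for the
# rest.  Exponential, usable only for desk-scale networks.
enumerate_vertices <- function(network, lb, ub, tol = 1e-8) {
  Sb <- network$S[network$metabolites$balanced, , drop = FALSE]
  m <- nrow(Sb); n <- ncol(Sb)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  nb_count <- n - m
  combs <- utils::combn(n, nb_count)
  verts <- list()
  for (ci in seq_len(ncol(combs))) {
    nb <- combs[, ci]
    basic <- setdiff(seq_len(n), nb)
    B <- Sb[, basic, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    # every lower/upper assignment of the nonbasic set
    for (mask in 0:(2^nb_count - 1L)) {
      at_ub <- as.logical(bitwAnd(bitwShiftR(mask, seq_len(nb_count) - 1L), 1L))
      v <- numeric(n)
      v[nb] <- ifelse(at_ub, ub[nb], lb[nb])
      rhs <- -Sb[, nb, drop = FALSE] %*% v[nb]
      v[basic] <- solve(B, rhs)
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
      }
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  unique(do.call(rbind, verts))
}

# Lexicographic optimum by exhaustive filtering of the vertex list: at each
# level keep the vertices optimal for that objective, then optimize the next
# among them.
oracle_lexicographic <- function(network, lb, ub, priorities, tol = 1e-7) {
  V <- enumerate_vertices(network, lb, ub)
  stopifnot(nrow(V) > 0)
  rxn <- network$reactions$id
  objs <- numeric(nrow(priorities))
  for (k in seq_len(nrow(priorities))) {
    co <- phycoflux:::priority_coef(priorities, k, rxn)
    vals <- as.numeric(V %*% co)
    best <- if (priorities$sense[k] == "max") max(vals) else min(vals)
    objs[k] <- best
    keep <- abs(vals - best) <= tol * max(1, abs(best))
    V <- V[keep, , drop = FALSE]
  }
  list(objective_values = objs, vertices = V)
}

# finite-bound override set for oracle comparisons on the toy network
finite_toy_bounds <- function(photon = 50, chl = c(-0.05, 5), car = c(0, 5),
                              ngam = c(0.1, 5)) {
  list(EX_photon = c(-photon, -photon), EX_no3 = c(-0.19, 0),
       PSY = c(0, 50), CEF = c(0, 50), ASM = c(0, 50),
       ACC_chl = chl, ACC_car = car, NGAM = ngam, BIO = c(0, 5))
}

toy_bounds_vectors <- function(bounds) {
  bb <- phycoflux:::resolve_bounds(toy, bounds)
  list(lb = bb$lb, ub = bb$ub)
}

quick_scenario <- function(c_no3 = 0.5, light = 178, horizon = 24,
                           x0 = 0.1, w_n0 = 0.08) {
  list(name = "quick",
       initial = reactor_state(x = x0, c_no3 = c_no3, w_n = w_n0),
       light = light, horizon = horizon)
}
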