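# Core of the method: ray samples -> node costs -> signed terminal weights ->
# s-t flow network with infinity-weighted intra-/inter-edges -> min cut.
#
# Cost of a node is the absolute deviation of its sampled gray value from the
# seed-region average; the terminal weight of an interior node is the
# difference of two radially adjacent costs (a large positive jump marks the
# lesion-to-tissue transition), while the innermost/outermost node of each ray
# is bound to the source/sink with its plain cost.

#' Node costs from ray samples
#'
#' `c[r, i] = |seed_avg - gray[r, i]|`: how much each sampled intensity
#' deviates from the average gray value around the seed. Inside a homogeneous
#' lesion the costs are near zero; they jump when a ray crosses into tissue
#' of different echogenicity.
#'
#' @param samples a [sample_rays()] object.
#' @return An object of class `cost_profile`: list with `costs`
#'   (`R x L` non-negative matrix) and `seed_avg`.
#' @examples
#' # seed average 100, sampled gray values 131 and 160 -> costs 31 and 60
#' abs(100 - c(131, 160))
#' @export
compute_costs <- function(samples) {
  stopifnot(inherits(samples, "ray_samples"))
  structure(list(costs = abs(samples$seed_avg - samples$gray),
                 seed_avg = samples$seed_avg),
            class = "cost_profile")
}

#' Coerce a cost matrix to a cost profile
#'
#' Convenience for constructing small instances directly from a matrix of
#' non-negative costs (rows = rays in cyclic order, columns = nodes from
#' innermost to outermost).
#'
#' @param x `cost_profile` object or numeric matrix of non-negative costs.
#' @return a `cost_profile`.
#' @export
as_cost_profile <- function(x) {
  if (inherits(x, "cost_profile")) return(x)
  if (is.matrix(x) && is.numeric(x)) {
    if (any(!is.finite(x)) || any(x < 0))
      stop("costs must be finite and non-negative")
    if (ncol(x) < 2L) stop("a cost profile needs at least 2 nodes per ray")
    return(structure(list(costs = x, seed_avg = NA_real_),
                     class = "cost_profile"))
  }
  stop("cannot coerce to cost_profile")
}

#' Signed terminal weights along one ray (or all rays)
#'
#' Implements the terminal-edge weighting rule: the innermost node of a ray is
#' bound to the source with capacity `c[1]` (reported as a negative value),
#' the outermost node to the sink with capacity `c[L]` (positive), and every
#' interior node `i` carries the difference `c[i] - c[i-1]` of adjacent
#' costs -- bound to the sink when the difference is non-negative, otherwise
#' to the source with its absolute value. The sign of the returned value
#' encodes the side (negative = source, non-negative = sink); its magnitude
#' is the edge capacity. Boundary nodes carry only this single binding, no
#' additional difference edge.
#'
#' @param costs numeric vector of one ray's costs (length >= 2, innermost
#'   first) or an `R x L` matrix / `cost_profile` (rule applied per ray).
#' @return signed weights, same shape as `costs`.
#' @examples
#' compute_terminal_weights(c(9, 10, 6, 55, 60, 31))
#' # -> -9  1 -4 49  5 31  (transition weight 55 - 6 = 49)
#' @export
compute_terminal_weights <- function(costs) {
  if (inherits(costs, "cost_profile")) costs <- costs$costs
  if (is.matrix(costs))
    return(t(apply(costs, 1L, compute_terminal_weights)))
  if (!is.numeric(costs) || length(costs) < 2L)
    stop("'costs' must be a numeric vector of length >= 2")
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("'costs' must be finite and non-negative")
  L <- length(costs)
  w <- c(-costs[1L], diff(costs))
  w[L] <- costs[L]
  w
}

# Source/sink capacities implied by the signed weights.
terminal_capacities <- function(profile) {
  w <- compute_terminal_weights(profile$costs)
  list(src = pmax(-w, 0), snk = pmax(w, 0))
}

#' Build the s-t cut graph from a cost profile
#'
#' Nodes are indexed ray-major, innermost to outermost (`(r, i) ->
#' (r - 1) * L + i` for 1-based `r`, `i`), followed by the virtual source and
#' sink. Three edge families are created:
#' \itemize{
#'   \item intra-edges: for each ray a directed "infinite" edge from node `i`
#'     to node `i - 1`, forcing the cut to sever exactly one terminal level
#'     per ray (the star-shape guarantee); `R * (L - 1)` edges.
#'   \item inter-edges: from every node `(r, i)` to both cyclically adjacent
#'     rays at level `max(i - delta_r, 1)`, limiting the cut-level difference
#'     between neighbouring rays to `delta_r` (contour smoothness);
#'     `2 * R * L` edges.
#'   \item terminal edges: source/sink bindings from
#'     [compute_terminal_weights()].
#' }
#' "Infinity" is represented by the finite capacity
#' `1 + sum(all terminal capacities)`, which provably exceeds the cost of any
#' cut that severs terminal edges only, so no intra-/inter-edge is ever cut.
#'
#' @param profile a `cost_profile` (or cost matrix, see [as_cost_profile()]).
#' @param delta_r non-negative integer smoothness parameter; `delta_r = 0`
#'   forces a concyclic (template-shaped) contour, larger values let the
#'   contour adapt to irregular boundaries.
#' @return An object of class `cut_graph`: list with `R`, `L`, `delta_r`,
#'   `INF`, `src_cap`/`snk_cap` (`R x L` matrices), and the edge list
#'   `from`, `to`, `cap`, `type` over node ids `1..R*L`, source `R*L + 1`,
#'   sink `R*L + 2`.
#' @export
build_graph <- function(profile, delta_r = 2L) {
  profile <- as_cost_profile(profile)
  if (!is.numeric(delta_r) || length(delta_r) != 1L || is.na(delta_r) ||
      delta_r < 0)
    stop("'delta_r' must be a single integer >= 0")
  delta_r <- as.integer(delta_r)
  R <- nrow(profile$costs); L <- ncol(profile$costs)
  caps <- terminal_capacities(profile)
  src_cap <- matrix(caps$src, R, L)
  snk_cap <- matrix(caps$snk, R, L)
  INF <- 1 + sum(src_cap) + sum(snk_cap)

  nid <- function(r, i) (r - 1L) * L + i
  s <- R * L + 1L
  t <- R * L + 2L

  rr <- rep(seq_len(R), each = L - 1L)
  ii <- rep(2:L, times = R)
  intra_from <- nid(rr, ii)
  intra_to <- nid(rr, ii - 1L)

  rr2 <- rep(seq_len(R), each = L)
  ii2 <- rep(seq_len(L), times = R)
  tgt_lvl <- pmax(ii2 - delta_r, 1L)
  nxt <- rr2 %% R + 1L
  prv <- (rr2 - 2L) %% R + 1L
  inter_from <- c(nid(rr2, ii2), nid(rr2, ii2))
  inter_to <- c(nid(nxt, tgt_lvl), nid(prv, tgt_lvl))

  src_pos <- which(as.vector(t(src_cap)) > 0)  # node-id order is ray-major
  snk_pos <- which(as.vector(t(snk_cap)) > 0)

  from <- c(intra_from, inter_from, rep(s, length(src_pos)), snk_pos)
  to <- c(intra_to, inter_to, src_pos, rep(t, length(snk_pos)))
  cap <- c(rep(INF, length(intra_from) + length(inter_from)),
           as.vector(t(src_cap))[src_pos], as.vector(t(snk_cap))[snk_pos])
  type <- c(rep("intra", length(intra_from)),
            rep("inter", length(inter_from)),
            rep("source", length(src_pos)),
            rep("sink", length(snk_pos)))

  structure(list(R = R, L = L, delta_r = delta_r, INF = INF,
                 src_cap = src_cap, snk_cap = snk_cap,
                 n_nodes = R * L + 2L, s = s, t = t,
                 from = from, to = to, cap = cap, type = type),
            class = "cut_graph")
}

#' @export
print.cut_graph <- function(x, ...) {
  cat("s-t cut graph\n")
  cat(sprintf("  rays R = %d, nodes L = %d, delta_r = %d\n",
              x$R, x$L, x$delta_r))
  cat(sprintf("  %d nodes (+s, +t); %d intra, %d inter, %d terminal edges\n",
              x$R * x$L, sum(x$type == "intra"), sum(x$type == "inter"),
              sum(x$type %in% c("source", "sink"))))
  cat(sprintf("  'infinite' capacity: %.6g\n", x$INF))
  invisible(x)
}

# Terminal cost of cutting ray r at level k (0..L): sink capacities of the
# k source-side nodes plus source capacities of the remaining sink-side
# nodes. Returns an R x (L + 1) table, column k + 1 <-> level k.
ray_level_costs <- function(src_cap, snk_cap) {
  R <- nrow(src_cap); L <- ncol(src_cap)
  snk_cum <- cbind(0, t(apply(snk_cap, 1L, cumsum)))
  src_tot <- rowSums(src_cap)
  src_cum <- cbind(0, t(apply(src_cap, 1L, cumsum)))
  snk_cum + (src_tot - src_cum)
}

cut_vector_cost <- function(k, level_costs) {
  sum(level_costs[cbind(seq_along(k), k + 1L)])
}

#' Solve the minimum s-t cut of a template graph
#'
#' Computes the maximum flow / minimum cut of the graph and converts the cut
#' into a per-ray cut vector `k` (`k[r]` = number of lesion-side nodes on ray
#' `r`, counted from the innermost node). Because no infinite edge can be
#' severed, the source side of every min cut is a per-ray prefix and adjacent
#' rays differ by at most `delta_r` levels.
#'
#' When several minimum cuts exist, the canonical *maximal* source side is
#' returned: the complement of the set of nodes that can still reach the sink
#' in the residual network. This is the unique largest minimum cut (the
#' pointwise maximum of all minimum cut vectors), making the output
#' deterministic and, on noiseless images, placing the contour at the
#' outermost zero-cost position rather than letting it fall back to the seed.
#'
#' @param graph a [build_graph()] object.
#' @return An object of class `cut_vector`: list with `k` (length `R`,
#'   values in `0..L`), `cut_cost` (total severed terminal capacity, equal to
#'   the max-flow value), `R`, `L`, `delta_r`.
#' @export
solve_min_cut <- function(graph) {
  stopifnot(inherits(graph, "cut_graph"))
  g <- igraph::make_graph(c(rbind(graph$from, graph$to)), n = graph$n_nodes,
                          directed = TRUE)
  mf <- igraph::max_flow(g, source = graph$s, target = graph$t,
                         capacity = graph$cap)
  flow <- as.numeric(mf$flow)
  tol <- 1e-9 * max(1, max(graph$cap))

  # residual network: forward where capacity remains, backward where flow > 0
  fwd <- flow < graph$cap - tol
  bwd <- flow > tol
  rf <- c(graph$from[fwd], graph$to[bwd])
  rt <- c(graph$to[fwd], graph$from[bwd])
  gres <- igraph::make_graph(c(rbind(rf, rt)), n = graph$n_nodes,
                             directed = TRUE)
  reach_t <- as.integer(igraph::subcomponent(gres, graph$t, mode = "in"))

  R <- graph$R; L <- graph$L
  sink_side <- matrix(FALSE, R, L)
  nodes_t <- setdiff(reach_t, c(graph$s, graph$t))
  if (length(nodes_t)) {
    r_idx <- (nodes_t - 1L) %/% L + 1L
    i_idx <- (nodes_t - 1L) %% L + 1L
    sink_side[cbind(r_idx, i_idx)] <- TRUE
  }
  src_side <- !sink_side
  k <- rowSums(src_side)

  # star-shape prefix property: source side of each ray is a contiguous run
  # from the innermost node; guaranteed because no infinite edge is severed
  prefix_ok <- all(src_side == (col(src_side) <= k[row(src_side)]))
  if (!prefix_ok)
    stop("internal error: min cut violates the star-shape prefix property")
  dk <- abs(diff(c(k, k[1L])))
  if (any(dk > graph$delta_r))
    stop("internal error: min cut violates the delta_r smoothness constraint")

  lc <- ray_level_costs(graph$src_cap, graph$snk_cap)
  cost_k <- cut_vector_cost(k, lc)
  if (abs(cost_k - mf$value) > 1e-6 * max(1, mf$value))
    stop("internal error: cut cost does not match the max-flow value")

  structure(list(k = as.integer(k), cut_cost = as.numeric(mf$value),
                 R = R, L = L, delta_r = graph$delta_r),
            class = "cut_vector")
}

#' @export
print.cut_vector <- function(x, ...) {
  cat(sprintf("Cut vector over %d rays (L = %d, delta_r = %d), cost %.6g\n",
              x$R, x$L, x$delta_r, x$cut_cost))
  cat("  k:", x$k, "\n")
  invisible(x)
}

#' Exhaustive-enumeration minimum-cut oracle
#'
#' Independent reference for [solve_min_cut()] on small instances: enumerates
#' every cut vector `k` in `{0..L}^R` satisfying the cyclic smoothness
#' constraint `|k[r] - k[r+1]| <= delta_r`, sums the severed terminal
#' capacities for each, and returns the minimum. Ties are resolved exactly as
#' in [solve_min_cut()]: the pointwise maximum of all minimising vectors
#' (which is itself a minimising vector, by the lattice structure of min
#' cuts).
#'
#' @inheritParams build_graph
#' @param max_states guard on the enumeration size `(L + 1)^R`.
#' @return a `cut_vector` object.
#' @export
brute_force_min_cut <- function(profile, delta_r = 2L, max_states = 1e7) {
  profile <- as_cost_profile(profile)
  delta_r <- as.integer(delta_r)
  if (is.na(delta_r) || delta_r < 0)
    stop("'delta_r' must be a single integer >= 0")
  R <- nrow(profile$costs); L <- ncol(profile$costs)
  if ((L + 1)^R > max_states)
    stop("instance too large for exhaustive enumeration")
  caps <- terminal_capacities(profile)
  src_cap <- matrix(caps$src, R, L)
  snk_cap <- matrix(caps$snk, R, L)
  lc <- ray_level_costs(src_cap, snk_cap)
  tol <- 1e-9 * max(1, max(lc))

  best_cost <- Inf
  best_kmax <- NULL

  recurse <- function(r, k, cost) {
    if (cost > best_cost + tol) return(invisible())
    if (r > R) {
      if (abs(k[R] - k[1L]) > delta_r) return(invisible())
      if (cost < best_cost - tol) {
        best_cost <<- cost
        best_kmax <<- k
      } else if (cost <= best_cost + tol) {
        best_cost <<- min(best_cost, cost)
        best_kmax <<- pmax(best_kmax, k)
      }
      return(invisible())
    }
    lv <- if (r == 1L) 0:L else
      max(0L, k[r - 1L] - delta_r):min(L, k[r - 1L] + delta_r)
    for (v in lv) {
      k[r] <- v
      recurse(r + 1L, k, cost + lc[r, v + 1L])
    }
    invisible()
  }
  recurse(1L, integer(R), 0)

  k <- as.integer(best_kmax)
  stopifnot(all(abs(diff(c(k, k[1L]))) <= delta_r),
            abs(cut_vector_cost(k, lc) - best_cost) <= tol)
  structure(list(k = k, cut_cost = as.numeric(cut_vector_cost(k, lc)),
                 R = R, L = L, delta_r = delta_r),
            class = "cut_vector")
}
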