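#' Genealogy objects
#'
#' A `genealogy` is a rooted, ultrametric, bifurcating coalescent tree over
#' `n_tips` sampled lineages, stored in a flat form convenient for MCMC:
#' tips are nodes `1..n_tips` at time 0, internal nodes are
#' `n_tips+1 .. 2*n_tips-1` with strictly positive times measured backwards
#' in coalescent units (one unit = 2N generations). Row `r` of `children`
#' holds the two children of internal node `n_tips + r`.
#'
#' @param n_tips Number of sampled lineages.
#' @param children Integer matrix `(n_tips-1) x 2` of child node ids.
#' @param node_time Numeric vector of length `2*n_tips-1`; tips must be 0.
#' @return An object of class `genealogy`.
#' @seealso [simulate_genealogy()]
#' @export
new_genealogy <- function(n_tips, children, node_time) {
  g <- structure(
    list(n_tips = as.integer(n_tips),
         children = matrix(as.integer(children), ncol = 2),
         node_time = as.numeric(node_time)),
    class = "genealogy")
  validate_genealogy(g)
  g
}

#' Validate genealogy invariants
#'
#' Checks the class invariants: `n_tips - 1` internal nodes, tips at time 0
#' (ultrametricity), every parent strictly older than its children, and every
#' non-root node appearing exactly once as a child.
#'
#' @param g A `genealogy`.
#' @return `g`, invisibly; errors if an invariant is violated.
#' @export
validate_genealogy <- function(g) {
  n <- g$n_tips
  if (n < 2) stop("a genealogy needs at least 2 tips")
  if (nrow(g$children) != n - 1)
    stop("a genealogy of ", n, " tips must have exactly ", n - 1, " internal nodes")
  if (length(g$node_time) != 2 * n - 1)
    stop("node_time must have length 2*n_tips - 1")
  if (any(g$node_time[seq_len(n)] != 0))
    stop("tips must sit at time 0 (ultrametric tree)")
  kids <- as.vector(g$children)
  if (!setequal(kids, setdiff(seq_len(2 * n - 1), root_node(g))) ||
      anyDuplicated(kids))
    stop("every non-root node must appear exactly once as a child")
  par <- genealogy_parent(g)
  nonroot <- which(par > 0)
  if (any(g$node_time[par[nonroot]] <= g$node_time[nonroot]))
    stop("every parent must be strictly older than its children")
  invisible(g)
}

# Parent vector (0 for the root), recomputed from the children matrix.
genealogy_parent <- function(g) {
  par <- integer(2 * g$n_tips - 1)
  for (r in seq_len(nrow(g$children)))
    par[g$children[r, ]] <- g$n_tips + r
  par
}

root_node <- function(g) {
  # the root is the internal node with the maximal time; by construction
  # (and preserved by all MCMC moves) every other node has a parent
  n <- g$n_tips
  internal <- (n + 1L):(2L * n - 1L)
  internal[which.max(g$node_time[internal])]
}

#' Simulate a Kingman coalescent genealogy
#'
#' While `k` lineages remain, the waiting time to the next coalescence is
#' exponential with rate `k(k-1)/2` (time in coalescent units of 2N
#' generations) and two uniformly chosen lineages merge.
#'
#' @param n_tips Number of sampled lineages (>= 2).
#' @param seed Optional integer seed; identical seeds give identical trees.
#' @return A [new_genealogy()] object.
#' @examples
#' g <- simulate_genealogy(10, seed = 1)
#' max(g$node_time)  # time to the most recent common ancestor
#' @export
simulate_genealogy <- function(n_tips, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2) stop("n_tips must be an integer >= 2")
  with_seed_opt(seed, {
    n <- n_tips
    children <- matrix(0L, n - 1, 2)
    node_time <- numeric(2 * n - 1)
    active <- seq_len(n)
    t <- 0
    for (k in n:2) {
      t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
      pick <- sample(length(active), 2)
      node <- 2L * n - k + 1L  # n+1, n+2, ..., 2n-1
      children[node - n, ] <- active[pick]
      node_time[node] <- t
      active <- c(active[-pick], node)
    }
    new_genealogy(n, children, node_time)
  })
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Convert a genealogy to an ape \code{phylo} tree
#'
#' Branch lengths are time differences in coalescent units; tip labels are
#' `t1..tn`. Useful for plotting and for checking ultrametricity with ape.
#'
#' @param x A `genealogy`.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.genealogy <- function(x, ...) {
  n <- x$n_tips
  par <- genealogy_parent(x)
  nonroot <- which(par > 0)
  edge <- cbind(par[nonroot], nonroot)
  edge_length <- x$node_time[edge[, 1]] - x$node_time[edge[, 2]]
  # ape convention: root must be node n+1; swap ids with our root if needed
  rt <- root_node(x)
  if (rt != n + 1) {
    swap <- function(v) { v[v == rt] <- 0L; v[v == n + 1L] <- rt; v[v == 0L] <- n + 1L; v }
    edge <- apply(edge, 2, swap)
  }
  structure(list(edge = edge, edge.length = edge_length,
                 tip.label = paste0("t", seq_len(n)), Nnode = n - 1L),
            class = "phylo", order = NULL)
}

# Log-density of the node times under the Kingman coalescent: with k lineages
# an interval of length dt contributes -choose(k,2)*dt. The labelled topology
# factor is a constant shared by all states visited by the sampler.
coalescent_log_density <- function(g) {
  n <- g$n_tips
  times <- sort(g$node_time[(n + 1):(2 * n - 1)])
  k <- n:2
  dt <- diff(c(0, times))
  -sum(choose(k, 2) * dt)
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d tips, TMRCA = %.4f coalescent units\n",
              x$n_tips, max(x$node_time)))
  invisible(x)
}
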