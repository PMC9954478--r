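#' Spreading-activation parameters
#'
#' Parameters of the diffusion rule used in the retrieval simulations:
#' each time step, a node keeps proportion `retention` (r) of its
#' activation and splits the remaining (1 - r) equally among its
#' neighbors; a degree-0 node's outgoing share is lost. The result is
#' then reduced by proportion `decay` (d), and any node whose activation
#' falls below `suppress` (s) is set to 0. Defaults follow the standard
#' simulation settings: initial activation 20 units on the target word,
#' r = 0.5, d = 0, s = 0, t = 5 steps (activation is near asymptote by
#' five steps).
#'
#' @param a0 Initial activation placed on the target word (units > 0).
#' @param retention r in \[0, 1\].
#' @param decay d in \[0, 1\].
#' @param suppress s >= 0; activations below s are forced to 0.
#' @param t Positive integer number of time steps.
#' @return A `spread_params` object.
#' @export
spread_params <- function(a0 = 20, retention = 0.5, decay = 0,
                          suppress = 0, t = 5L) {
  stopifnot(a0 > 0,
            retention >= 0, retention <= 1,
            decay >= 0, decay <= 1,
            suppress >= 0,
            t == as.integer(t), t >= 1)
  structure(list(a0 = a0, retention = retention, decay = decay,
                 suppress = suppress, t = as.integer(t)),
            class = "spread_params")
}

#' @export
print.spread_params <- function(x, ...) {
  cat(sprintf("spread_params: a0=%g r=%g d=%g s=%g t=%d\n",
              x$a0, x$retention, x$decay, x$suppress, x$t))
  invisible(x)
}

# Column-stochastic-like spread operator P with P[i, j] = 1/deg(j) for
# each edge (i, j); columns of degree-0 nodes are zero (their outgoing
# share is discarded). One step is a' = (1-d) * (r*a + (1-r) * P %*% a),
# followed by suppress thresholding.
spread_operator <- function(network) {
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- Matrix::colSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  A %*% Matrix::Diagonal(x = inv)
}

#' One synchronous spreading-activation step
#'
#' @param activation Numeric vector of per-node activations (in network
#'   vertex order).
#' @param network An igraph, or a pre-built operator from the internal
#'   representation (recomputed per call when an igraph is given).
#' @param params A [spread_params()].
#' @return Updated activation vector.
#' @export
spread_step <- function(activation, network, params = spread_params()) {
  P <- if (igraph::is_igraph(network)) spread_operator(network) else network
  if (length(activation) != nrow(P)) {
    stop("activation vector length does not match the network")
  }
  a <- (1 - params$decay) *
    (params$retention * activation +
       (1 - params$retention) * as.numeric(P %*% activation))
  if (params$suppress > 0) a[a < params$suppress] <- 0
  a
}

# Run t steps on a matrix of initial states (one column per run).
run_spread <- function(P, states, params) {
  for (step in seq_len(params$t)) {
    states <- (1 - params$decay) *
      (params$retention * states +
         (1 - params$retention) * (P %*% states))
    if (params$suppress > 0) states[states < params$suppress] <- 0
  }
  as.matrix(states)
}

#' Simulate retrieval of a single word
#'
#' Places the full initial activation on the target node, runs `t`
#' synchronous steps, and reports the target's absolute final activation
#' (the dynamics keep the target relatively more active than competitors,
#' so its absolute activation is the retrieval metric).
#'
#' @param network An igraph with named vertices.
#' @param target A vertex name present in the network.
#' @param params A [spread_params()].
#' @param trajectory Logical; also return the per-step activation of the
#'   target.
#' @return List with `target`, `final` (activation after t steps), and —
#'   when `trajectory = TRUE` — `steps` (vector of length t + 1 starting
#'   at a0).
#' @examples
#' g <- igraph::make_graph(~ a - b) + igraph::vertices("hermit")
#' simulate_word(g, "hermit")$final # 20 * 0.5^5 = 0.625
#' simulate_word(g, "a")$final      # settles at a0/2 = 10
#' @export
simulate_word <- function(network, target, params = spread_params(),
                          trajectory = FALSE) {
  nm <- igraph::V(network)$name
  idx <- match(target, nm)
  if (is.na(idx)) stop(sprintf("target word not in network: %s", target))
  P <- spread_operator(network)
  a <- numeric(igraph::vcount(network))
  a[idx] <- params$a0
  steps <- if (trajectory) numeric(params$t + 1L) else NULL
  if (trajectory) steps[1L] <- params$a0
  for (k in seq_len(params$t)) {
    a <- spread_step(a, P, params)
    if (trajectory) steps[k + 1L] <- a[idx]
  }
  out <- list(target = target, final = a[idx])
  if (trajectory) out$steps <- steps
  out
}

#' Batch retrieval simulations across a damage trajectory
#'
#' Runs one independent simulation per (target word, damage stage): each
#' run starts from activation `a0` on that word alone. Returns the long
#' table behind the activation-by-damage analyses.
#'
#' @param trajectory A `damage_trajectory` (node set is identical across
#'   stages) or a list of igraphs with a parallel `labels` argument.
#' @param words Character vector of target word names, or a `target_list`.
#' @param params A [spread_params()].
#' @param joint Logical. The default (`FALSE`) runs each word separately,
#'   which is how per-word retrieval is scored; `TRUE` activates all
#'   targets at `a0` simultaneously in one co-activation run per stage,
#'   so activation from different targets can mix.
#' @return Data frame with columns `word`, `fraction_removed`,
#'   `activation`.
#' @export
batch_spread <- function(trajectory, words, params = spread_params(),
                         joint = FALSE) {
  stopifnot(inherits(trajectory, "damage_trajectory"))
  if (inherits(words, "target_list")) words <- words$items
  words <- as.character(words)
  if (length(words) == 0L) {
    return(data.frame(word = character(0), fraction_removed = numeric(0),
                      activation = numeric(0)))
  }
  nm <- igraph::V(trajectory$stages[[1L]])$name
  idx <- match(words, nm)
  if (anyNA(idx)) {
    stop(sprintf("target word(s) not in network: %s",
                 paste(words[is.na(idx)], collapse = ", ")))
  }
  n <- length(nm)
  init <- if (joint) {
    Matrix::sparseMatrix(i = idx, j = rep(1L, length(words)),
                         x = params$a0, dims = c(n, 1L))
  } else {
    Matrix::sparseMatrix(i = idx, j = seq_along(words),
                         x = params$a0, dims = c(n, length(words)))
  }
  rows <- lapply(seq_along(trajectory$stages), function(k) {
    P <- spread_operator(trajectory$stages[[k]])
    finals <- run_spread(P, init, params)
    act <- if (joint) finals[idx, 1L] else finals[cbind(idx, seq_along(words))]
    data.frame(word = words,
               fraction_removed = trajectory$fractions[k],
               activation = act)
  })
  do.call(rbind, rows)
}

#' Decay-parameter sweep on a single network
#'
#' Re-runs the batch simulation on one (intact) network at each decay
#' value, holding all other parameters fixed. Because the update rule is
#' linear and decay multiplies every node uniformly, the final-activation
#' vector at decay d equals the d = 0 vector scaled by (1-d)^t — so
#' activation values across decay settings stay perfectly rank-ordered.
#'
#' @param network An igraph with named vertices.
#' @param words Character vector of target names, or a `target_list`.
#' @param d_values Numeric vector of decay settings in \[0, 1).
#' @param params Base [spread_params()]; its `decay` is overridden.
#' @return Data frame with columns `word`, `decay`, `activation`.
#' @export
decay_sweep <- function(network, words,
                        d_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        params = spread_params()) {
  if (length(d_values) == 0L) stop("'d_values' must be non-empty")
  if (any(d_values < 0) || any(d_values >= 1)) {
    stop("'d_values' must lie in [0, 1)")
  }
  if (inherits(words, "target_list")) words <- words$items
  traj <- structure(list(stages = list(network), fractions = 0,
                         removed = list(), seed = NA_integer_),
                    class = "damage_trajectory")
  rows <- lapply(d_values, function(d) {
    p <- params
    p$decay <- d
    out <- batch_spread(traj, words, p)
    data.frame(word = out$word, decay = d, activation = out$activation)
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlations across decay settings
#'
#' @param sweep Output of [decay_sweep()].
#' @return Data frame with columns `d1`, `d2`, `r` for every unordered
#'   pair of decay settings (empty when only one setting was swept).
#' @export
sweep_correlations <- function(sweep) {
  ds <- sort(unique(sweep$decay))
  if (length(ds) < 2L) {
    return(data.frame(d1 = numeric(0), d2 = numeric(0), r = numeric(0)))
  }
  wide <- do.call(cbind, lapply(ds, function(d) {
    s <- sweep[sweep$decay == d, ]
    s$activation[order(s$word)]
  }))
  pairs <- utils::combn(seq_along(ds), 2L)
  data.frame(
    d1 = ds[pairs[1L, ]],
    d2 = ds[pairs[2L, ]],
    r = apply(pairs, 2L, function(pr) cor(wide[, pr[1L]], wide[, pr[2L]]))
  )
}
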