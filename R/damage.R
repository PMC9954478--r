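#' Define a cumulative edge-removal schedule
#'
#' The schedule lists cumulative fractions of the *intact* edge count to
#' be removed, strictly increasing in (0, 1]. The default reproduces the
#' five damage levels used throughout the package: 10%, 30%, 50%, 70%,
#' and 90% of connections removed.
#'
#' @param fractions Numeric vector, strictly increasing, each in (0, 1].
#' @param seed Integer RNG seed controlling which edges are sampled.
#' @return A `damage_schedule` object.
#' @export
damage_schedule <- function(fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            seed = 1L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) == 0L) stop("schedule needs at least one fraction")
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  if (any(diff(fractions) <= 0)) stop("fractions must be strictly increasing")
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "damage_schedule")
}

#' Plan per-stage removal counts
#'
#' Converts cumulative removal fractions into per-stage edge counts. Each
#' stage removes its *increment* of the intact edge count — the fraction
#' newly removed at that stage times `n_edges` — rounded up to a whole
#' edge. This per-stage ceiling rule reproduces the canonical published
#' removal ladder for a 31,267-edge network (remaining edges 28,140 /
#' 21,886 / 15,632 / 9,378 / 3,124) exactly, which no rounding of the
#' cumulative targets does.
#'
#' @param n_edges Intact edge count (positive integer).
#' @param schedule A `damage_schedule` or numeric vector of fractions.
#' @return Data frame with columns `fraction`, `cumulative_removed`,
#'   `stage_removed`, `remaining`.
#' @examples
#' plan_removals(100, damage_schedule(0.5))
#' @export
plan_removals <- function(n_edges, schedule) {
  if (inherits(schedule, "damage_schedule")) {
    fractions <- schedule$fractions
  } else {
    fractions <- damage_schedule(schedule)$fractions
  }
  n_edges <- as.integer(n_edges)
  if (n_edges <= 0L) stop("'n_edges' must be positive")
  # 1e-9 guards against 50.000000000000007-style float noise under ceiling
  stage <- as.integer(ceiling(diff(c(0, fractions)) * n_edges - 1e-9))
  cum <- cumsum(stage)
  if (any(cum > n_edges)) stop("cumulative removal exceeds the edge count")
  data.frame(
    fraction = fractions,
    cumulative_removed = cum,
    stage_removed = stage,
    remaining = n_edges - cum
  )
}

#' Apply cumulative random edge removal
#'
#' Damages a network longitudinally: at each stage, edges are sampled
#' uniformly at random *from the edges surviving the previous stage* (not
#' from the intact edge list) and deleted, so stage k+1's edge set is
#' nested inside stage k's. Nodes are never removed — words are not
#' unlearned, only harder to reach — so every stage has the identical
#' node set. The same `(network, schedule)` pair with the same seed
#' reproduces the trajectory exactly.
#'
#' @param network An igraph (the intact network).
#' @param schedule A `damage_schedule`.
#' @return A `damage_trajectory`: list with `stages` (list of igraphs,
#'   first entry the intact network), `fractions` (0 for the intact
#'   stage), `removed` (per-stage lists of removed edges as a 2-column
#'   name matrix), and `seed`.
#' @export
apply_damage <- function(network, schedule) {
  stopifnot(igraph::is_igraph(network))
  if (!inherits(schedule, "damage_schedule")) {
    stop("'schedule' must be a damage_schedule")
  }
  plan <- plan_removals(igraph::ecount(network), schedule)
  stages <- vector("list", nrow(plan) + 1L)
  removed <- vector("list", nrow(plan) + 1L)
  stages[[1L]] <- network
  removed[[1L]] <- matrix(character(0), ncol = 2L)
  current <- network
  with_rng_seed(schedule$seed, {
    for (k in seq_len(nrow(plan))) {
      n_remove <- plan$stage_removed[k]
      m <- igraph::ecount(current)
      if (n_remove > m) stop("schedule demands more edges than remain")
      drop_ids <- sample.int(m, n_remove)
      removed[[k + 1L]] <- igraph::as_edgelist(current, names = TRUE)[drop_ids, ,
                                                                      drop = FALSE]
      current <- igraph::delete_edges(current, drop_ids)
      stages[[k + 1L]] <- current
    }
  })
  structure(
    list(stages = stages, fractions = c(0, plan$fraction),
         removed = removed, seed = schedule$seed),
    class = "damage_trajectory"
  )
}

#' @export
print.damage_trajectory <- function(x, ...) {
  cat(sprintf("damage_trajectory: %d stages (seed %d)\n",
              length(x$stages), x$seed))
  for (k in seq_along(x$stages)) {
    cat(sprintf("  %4.0f%% removed: %d nodes, %d edges\n",
                100 * x$fractions[k],
                as.integer(igraph::vcount(x$stages[[k]])),
                as.integer(igraph::ecount(x$stages[[k]]))))
  }
  invisible(x)
}

#' Write a damage trajectory's stages and manifest
#'
#' Exports each stage via [write_network()] plus a stage manifest CSV
#' (fraction, edges remaining, seed). The manifest starts with a `# seed:`
#' metadata comment line so stochastic outputs carry their seed.
#'
#' @param trajectory A `damage_trajectory`.
#' @param dir Output directory (created if needed).
#' @param format Network serialization format, see [write_network()].
#' @return The manifest path, invisibly.
#' @export
write_trajectory <- function(trajectory, dir, format = "graphml") {
  stopifnot(inherits(trajectory, "damage_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(format, graphml = "graphml", gml = "gml",
                pajek = "net", edgelist = "edges")
  files <- character(length(trajectory$stages))
  for (k in seq_along(trajectory$stages)) {
    files[k] <- file.path(dir, sprintf("stage_%03.0f.%s",
                                       100 * trajectory$fractions[k], ext))
    write_network(trajectory$stages[[k]], files[k], format = format)
  }
  manifest <- file.path(dir, "stages.csv")
  tab <- data.frame(
    fraction = trajectory$fractions,
    edges = vapply(trajectory$stages, function(g) as.integer(igraph::ecount(g)),
                   integer(1)),
    nodes = vapply(trajectory$stages, function(g) as.integer(igraph::vcount(g)),
                   integer(1)),
    file = basename(files)
  )
  writeLines(c(sprintf("# seed: %d", trajectory$seed),
               paste(names(tab), collapse = ","),
               do.call(paste, c(tab, sep = ","))), manifest)
  invisible(manifest)
}
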