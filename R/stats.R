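#' Pearson correlation with p-value
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#' Errors on constant input, for which the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate simulated activation with naming accuracy per group
#'
#' Inner-joins an activation table with an accuracy table on `word` and
#' computes one Pearson correlation per accuracy group (e.g. aphasia
#' type). The number of joined words is reported per group; groups with
#' fewer than 3 common words raise an error naming the group.
#'
#' @param activations Data frame with columns `word` and `activation`
#'   (e.g. one stage of [batch_spread()] output).
#' @param accuracy Data frame with columns `word`, `group`, `accuracy`
#'   (proportion correct in \[0, 1\]).
#' @return Data frame with columns `group`, `r`, `p`, `n`.
#' @export
correlate_activation_accuracy <- function(activations, accuracy) {
  stopifnot(all(c("word", "activation") %in% names(activations)),
            all(c("word", "group", "accuracy") %in% names(accuracy)))
  if (any(accuracy$accuracy < 0 | accuracy$accuracy > 1)) {
    stop("accuracy values must lie in [0, 1]")
  }
  groups <- unique(accuracy$group)
  rows <- lapply(groups, function(g) {
    acc <- accuracy[accuracy$group == g, ]
    if (anyDuplicated(acc$word)) {
      stop(sprintf("duplicate (word, group) rows in group '%s'", g))
    }
    joined <- merge(activations[, c("word", "activation")],
                    acc[, c("word", "accuracy")], by = "word")
    if (nrow(joined) < 3L) {
      stop(sprintf("fewer than 3 words overlap for group '%s'", g))
    }
    ct <- pearson_test(joined$activation, joined$accuracy)
    data.frame(group = g, r = ct$r, p = ct$p, n = ct$n)
  })
  do.call(rbind, rows)
}

#' Classify a word's location in the network
#'
#' @param network An igraph with named vertices.
#' @param word A vertex name.
#' @param census Optional pre-computed [component_census()] of the
#'   network (recomputed when absent).
#' @return `"isolate"` (degree 0), `"giant_component"`, or `"island"`.
#' @export
classify_location <- function(network, word, census = NULL) {
  nm <- igraph::V(network)$name
  idx <- match(word, nm)
  if (anyNA(idx)) {
    stop(sprintf("word(s) not in network: %s",
                 paste(word[is.na(idx)], collapse = ", ")))
  }
  if (is.null(census)) census <- component_census(network)
  deg <- igraph::degree(network)[idx]
  out <- ifelse(deg == 0L, "isolate",
                ifelse(nm[idx] %in% census$gc_nodes,
                       "giant_component", "island"))
  unname(out)
}

#' Goodness-of-fit chi-square for error locations
#'
#' Tests whether naming errors fall on giant-component words more often
#' than random selection from the network predicts. Observed counts are
#' errors whose *target* word lies in vs. outside the GC of the supplied
#' (damaged) network; expected proportions are the network's node
#' fractions in vs. outside the GC.
#'
#' @param errors Data frame with a `word` column (error target words), or
#'   a character vector of target words.
#' @param network The (damaged) igraph whose structure defines the
#'   expected proportions.
#' @return List of class `location_chisq` with `observed` (named counts
#'   in/out of the GC), `expected_prop`, `statistic`, `df` (= 1), `p`.
#' @export
location_chisq <- function(errors, network) {
  words <- if (is.data.frame(errors)) errors$word else as.character(errors)
  if (length(words) == 0L) stop("no error records supplied")
  census <- component_census(network)
  loc <- classify_location(network, words, census)
  observed <- c(in_gc = sum(loc == "giant_component"),
                outside_gc = sum(loc != "giant_component"))
  p_gc <- census$gc_size / census$n_nodes
  expected_prop <- c(in_gc = p_gc, outside_gc = 1 - p_gc)
  if (any(expected_prop == 0)) {
    stop("an expected proportion is zero; chi-square undefined")
  }
  ct <- suppressWarnings(chisq.test(observed, p = expected_prop))
  structure(
    list(observed = observed, expected_prop = expected_prop,
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value),
    class = "location_chisq"
  )
}

#' @export
print.location_chisq <- function(x, ...) {
  cat(sprintf(
    "location chi-square: observed %d in GC / %d outside (expected %.1f%% / %.1f%%)\n",
    x$observed[["in_gc"]], x$observed[["outside_gc"]],
    100 * x$expected_prop[["in_gc"]], 100 * x$expected_prop[["outside_gc"]]))
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g\n", x$statistic, x$df, x$p))
  invisible(x)
}

#' Classify a word's activation trajectory across damage stages
#'
#' Labels the patterns seen when following one word's final activation
#' across increasing damage. Sentinel values are derived from the
#' parameters rather than hard-coded: an isolate's final activation is
#' `a0 * r^t` (0.625 at defaults) and a two-node island settles at
#' `a0 / 2` (10 at defaults). Checks are applied in order:
#' \describe{
#'   \item{`always_isolate`}{at the isolate sentinel at every stage (the
#'     word started as a lexical hermit and, since only edges are
#'     removed, stays one);}
#'   \item{`became_isolate`}{at the sentinel in the final stage but not
#'     the first (damage stripped its last connection);}
#'   \item{`became_size2_island`}{at the two-node-island sentinel in the
#'     final stage but not the first;}
#'   \item{`activation_increased`}{final-stage activation above the
#'     first-stage value (neighborhood pruning left more activation with
#'     the target);}
#'   \item{`other_decreasing`}{everything else.}
#' }
#'
#' @param activations Numeric vector of final activations, ordered by
#'   increasing damage; length >= 2.
#' @param params The [spread_params()] the activations were produced
#'   with (defaults assumed d = 0).
#' @param tol Absolute tolerance for the sentinel comparisons.
#' @return Character scalar, one of the five labels above.
#' @export
classify_trajectory <- function(activations, params = spread_params(),
                                tol = 1e-9) {
  if (length(activations) < 2L) stop("need activations at >= 2 stages")
  iso <- params$a0 * params$retention^params$t * (1 - params$decay)^params$t
  dyad <- params$a0 / 2 * (1 - params$decay)^params$t
  at_iso <- abs(activations - iso) <= tol
  at_dyad <- abs(activations - dyad) <= tol
  last <- length(activations)
  if (all(at_iso)) return("always_isolate")
  if (at_iso[last] && !at_iso[1L]) return("became_isolate")
  if (at_dyad[last] && !at_dyad[1L]) return("became_size2_island")
  if (activations[last] > activations[1L]) return("activation_increased")
  "other_decreasing"
}
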