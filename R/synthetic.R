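#' Specification for a synthetic lexicon
#'
#' The generator samples abstract phoneme strings: word lengths are drawn
#' from a short-skewed distribution, and unique transcriptions are drawn
#' without replacement over the inventory. Short words over a small
#' inventory land in a dense neighborhood core while long words tend to
#' be isolates, qualitatively reproducing the giant-component / island /
#' hermit mixture characteristic of real phonological lexicons (roughly a
#' third of words in the giant component and half as isolates). The
#' defaults are calibrated so a 2000-word lexicon's network has a GC
#' fraction in \[0.20, 0.50\] and an isolate fraction in \[0.35, 0.70\].
#'
#' @param n_words Number of words (>= 2).
#' @param inventory_size Number of distinct phoneme symbols (>= 2).
#' @param length_support Integer word lengths the distribution can take.
#' @param length_probs Probabilities for `length_support` (must sum to 1).
#' @param seed Integer RNG seed.
#' @return A `synth_lexicon_spec` object.
#' @export
synth_lexicon_spec <- function(n_words = 2000L,
                               inventory_size = 16L,
                               length_support = 2:8,
                               length_probs = c(0.12, 0.18, 0.20, 0.18,
                                                0.12, 0.10, 0.10),
                               seed = 1L) {
  stopifnot(n_words >= 2L, inventory_size >= 2L,
            length(length_support) == length(length_probs),
            all(length_support >= 1L), all(length_probs >= 0))
  if (abs(sum(length_probs) - 1) > 1e-8) {
    stop("'length_probs' must sum to 1")
  }
  structure(list(n_words = as.integer(n_words),
                 inventory_size = as.integer(inventory_size),
                 length_support = as.integer(length_support),
                 length_probs = length_probs,
                 seed = as.integer(seed)),
            class = "synth_lexicon_spec")
}

#' Generate a synthetic lexicon
#'
#' @param spec A [synth_lexicon_spec()].
#' @return A `phon_lexicon` with `n_words` unique transcriptions,
#'   bit-reproducible from the spec (including its seed).
#' @export
generate_lexicon <- function(spec = synth_lexicon_spec()) {
  stopifnot(inherits(spec, "synth_lexicon_spec"))
  inv <- letters[seq_len(min(26L, spec$inventory_size))]
  if (spec$inventory_size > 26L) {
    inv <- c(inv, paste0("z", seq_len(spec$inventory_size - 26L)))
    scheme <- "delim"
  } else {
    scheme <- "chars"
  }
  support <- spec$length_support[spec$length_probs > 0]
  capacity <- sum(spec$inventory_size^support)
  if (spec$n_words > capacity) {
    stop(sprintf(
      "requested %d words but only %.0f distinct transcriptions exist",
      spec$n_words, capacity))
  }
  sep <- if (scheme == "chars") "" else " "
  with_rng_seed(spec$seed, {
    transcriptions <- character(0)
    tries <- 0L
    while (length(transcriptions) < spec$n_words) {
      tries <- tries + 1L
      if (tries > 1000L) stop("could not draw enough unique transcriptions")
      need <- spec$n_words - length(transcriptions)
      lens <- sample(spec$length_support, need, replace = TRUE,
                     prob = spec$length_probs)
      fresh <- vapply(lens, function(L) {
        paste(sample(inv, L, replace = TRUE), collapse = sep)
      }, "")
      transcriptions <- unique(c(transcriptions, fresh))
    }
    transcriptions <- transcriptions[seq_len(spec$n_words)]
  })
  phon_lexicon(word = sprintf("w%04d", seq_len(spec$n_words)),
               transcription = transcriptions,
               scheme = scheme, delim = " ", inventory = inv)
}

#' Specification for synthetic behavioural data
#'
#' Parameters for the stand-in behavioural generators used where real
#' naming-accuracy and error databases are not distributable: a planted
#' activation-accuracy correlation and a planted giant-component error
#' enrichment.
#'
#' @param rho Planted Pearson correlation between activation and
#'   accuracy, in \[-1, 1\].
#' @param noise Noise scale; 1 gives expected correlation `rho`, 0 gives
#'   a perfectly linear relation.
#' @param enrichment Multiplier (>= 0) on the selection probability of
#'   giant-component words when sampling error targets.
#' @param n_errors Number of error records to draw.
#' @param seed Integer RNG seed.
#' @return A `synth_behavior_spec` object.
#' @export
synth_behavior_spec <- function(rho = 0.18, noise = 1, enrichment = 1.7,
                                n_errors = 1500L, seed = 1L) {
  if (rho < -1 || rho > 1) stop("'rho' must lie in [-1, 1]")
  stopifnot(noise >= 0, enrichment >= 0, n_errors >= 0)
  structure(list(rho = rho, noise = noise, enrichment = enrichment,
                 n_errors = as.integer(n_errors), seed = as.integer(seed)),
            class = "synth_behavior_spec")
}

#' Generate a synthetic accuracy table with a planted correlation
#'
#' Plants an expected Pearson correlation `rho` between activation and
#' accuracy: accuracy is built as `rho * scale(activation) +
#' noise * sqrt(1 - rho^2) * N(0, 1)`, then mapped into \[0.05, 0.95\] by a
#' monotone linear (min-max) transform, which preserves the correlation
#' exactly and avoids clipping. With `noise = 0` and `rho = 1` the
#' accuracy is an exact linear transform of activation (r = 1).
#'
#' @param activations Data frame with columns `word` and `activation`
#'   (>= 3 rows, non-constant).
#' @param spec A [synth_behavior_spec()].
#' @param groups Character vector of group labels; one independent noise
#'   draw per group.
#' @return Data frame with columns `word`, `group`, `accuracy`,
#'   `n_respondents`.
#' @export
generate_accuracy <- function(activations, spec = synth_behavior_spec(),
                              groups = c("anomic", "broca", "conduction",
                                         "wernicke")) {
  stopifnot(inherits(spec, "synth_behavior_spec"),
            all(c("word", "activation") %in% names(activations)))
  if (nrow(activations) < 3L) stop("need at least 3 activation rows")
  x <- activations$activation
  if (sd(x) == 0) stop("activation values are constant")
  xs <- as.numeric(scale(x))
  with_rng_seed(spec$seed, {
    rows <- lapply(groups, function(g) {
      eps <- rnorm(length(xs))
      y <- spec$rho * xs + spec$noise * sqrt(1 - spec$rho^2) * eps
      rng <- range(y)
      acc <- if (rng[1L] == rng[2L]) rep(0.5, length(y)) else {
        0.05 + 0.9 * (y - rng[1L]) / (rng[2L] - rng[1L])
      }
      data.frame(word = activations$word, group = g, accuracy = acc,
                 n_respondents = length(xs))
    })
    do.call(rbind, rows)
  })
}

#' Generate synthetic error records with planted GC enrichment
#'
#' Samples error target words from the network's nodes with probability
#' proportional to `enrichment` for giant-component words and 1 for all
#' other words, emulating the over-representation of giant-component
#' targets among phonologically related naming errors.
#'
#' @param network An igraph with named vertices.
#' @param spec A [synth_behavior_spec()].
#' @param severity Label attached to every record (e.g. `"mild"`).
#' @return Data frame with columns `word`, `error_class` (formal or
#'   nonword), `severity`.
#' @export
generate_errors <- function(network, spec = synth_behavior_spec(),
                            severity = "mild") {
  stopifnot(inherits(spec, "synth_behavior_spec"))
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty network")
  if (spec$n_errors == 0L) stop("'n_errors' must be positive")
  census <- component_census(network)
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  w <- ifelse(nm %in% census$gc_nodes, spec$enrichment, 1)
  with_rng_seed(spec$seed, {
    targets <- sample(nm, spec$n_errors, replace = TRUE, prob = w)
    classes <- sample(c("formal", "nonword"), spec$n_errors, replace = TRUE)
  })
  data.frame(word = targets, error_class = classes, severity = severity)
}
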