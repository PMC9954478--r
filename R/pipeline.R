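#' Assemble a pipeline configuration
#'
#' A single configuration drives all three study drivers. It can be given
#' as a YAML file path or a named list; missing entries fall back to the
#' defaults below. Each stochastic stage (lexicon, targets, damage,
#' behaviour) has its own seed namespace, so changing one stage's seed
#' leaves the others untouched.
#'
#' \preformatted{
#' out_dir: phonet-out
#' lexicon:  {source: synthetic, n_words: 2000, inventory_size: 12, seed: 101}
#'           # or {source: file, path: lexicon.tsv, scheme: chars}
#' targets:  {source: sample, n: 60, seed: 202}
#'           # or {source: file, path: targets.txt}
#' damage:   {fractions: [0.1, 0.3, 0.5, 0.7, 0.9], seed: 303}
#' spread:   {a0: 20, retention: 0.5, decay: 0, suppress: 0, t: 5}
#' sweep:    [0.1, 0.3, 0.5, 0.7, 0.9]
#' behavior: {rho: 0.18, noise: 1, enrichment: 1.7, n_errors: 1500, seed: 404}
#' severity_stage: {mild: 0.1, very_severe: 0.9}
#' }
#'
#' @param config Path to a YAML file, or a named list of overrides.
#' @return A validated `phonet_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  defaults <- list(
    out_dir = "phonet-out",
    lexicon = list(source = "synthetic", n_words = 2000L,
                   inventory_size = 16L, seed = 101L,
                   path = NULL, scheme = "chars"),
    targets = list(source = "sample", n = 60L, seed = 202L, path = NULL),
    damage = list(fractions = c(0.1, 0.3, 0.5, 0.7, 0.9), seed = 303L),
    spread = list(a0 = 20, retention = 0.5, decay = 0, suppress = 0, t = 5L),
    sweep = c(0.1, 0.3, 0.5, 0.7, 0.9),
    behavior = list(rho = 0.18, noise = 1, enrichment = 1.7,
                    n_errors = 1500L, seed = 404L),
    severity_stage = list(mild = 0.1, very_severe = 0.9)
  )
  merged <- modifyList(defaults, config)
  if (identical(merged$lexicon$source, "file") &&
      (is.null(merged$lexicon$path) || !file.exists(merged$lexicon$path))) {
    stop("config error: lexicon source is 'file' but 'path' is missing")
  }
  if (identical(merged$targets$source, "file") &&
      (is.null(merged$targets$path) || !file.exists(merged$targets$path))) {
    stop("config error: targets source is 'file' but 'path' is missing")
  }
  if (length(merged$sweep) == 0L) stop("config error: empty decay sweep")
  structure(merged, class = "phonet_config")
}

config_lexicon <- function(config) {
  lx <- config$lexicon
  if (identical(lx$source, "file")) {
    read_lexicon(lx$path, scheme = lx$scheme %||% "chars")
  } else {
    generate_lexicon(synth_lexicon_spec(
      n_words = lx$n_words, inventory_size = lx$inventory_size,
      seed = lx$seed))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_spread <- function(config) {
  sp <- config$spread
  spread_params(a0 = sp$a0, retention = sp$retention, decay = sp$decay,
                suppress = sp$suppress, t = sp$t)
}

#' Sample target words spanning network locations
#'
#' Draws targets stratified over the three location classes (giant
#' component, island, isolate) proportionally to class size, with at
#' least one word from every non-empty class, so retrieval simulations
#' exercise all trajectory patterns.
#'
#' @param network An igraph with named vertices.
#' @param n Number of targets.
#' @param seed Integer seed.
#' @return Character vector of vertex names.
#' @export
sample_targets <- function(network, n, seed = 1L) {
  nm <- igraph::V(network)$name
  census <- component_census(network)
  loc <- classify_location(network, nm, census)
  classes <- split(nm, loc)
  with_rng_seed(seed, {
    quota <- pmax(1L, round(n * lengths(classes) / length(nm)))
    picked <- unlist(lapply(seq_along(classes), function(i) {
      sample(classes[[i]], min(quota[i], length(classes[[i]])))
    }), use.names = FALSE)
    if (length(picked) > n) picked <- sample(picked, n)
    picked
  })
}

config_targets <- function(config, lexicon, network) {
  tg <- config$targets
  if (identical(tg$source, "file")) {
    read_target_list(tg$path, lexicon)$items
  } else {
    sample_targets(network, tg$n, tg$seed)
  }
}

write_manifest <- function(config, out_dir, extra = list()) {
  manifest <- c(list(package = "phonet",
                     version = as.character(utils::packageVersion("phonet")),
                     config = unclass(config)),
                extra)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_nulls)
  x[!vapply(x, is.null, logical(1))]
}

manifest_matches <- function(config, out_dir) {
  path <- file.path(out_dir, "manifest.yaml")
  if (!file.exists(path)) return(FALSE)
  m <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (is.null(m)) return(FALSE)
  identical(yaml::as.yaml(drop_nulls(m$config)),
            yaml::as.yaml(drop_nulls(unclass(pipeline_config(config)))))
}

#' Study 1 driver: damage the network and summarise its structure
#'
#' Builds (or reads) the lexicon, constructs the phonological network,
#' applies the cumulative random edge-removal schedule, and writes the
#' structural metric panel (one row per stage, intact first), per-stage
#' network exports, and a manifest to `out_dir`.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with `lexicon`, `network`, `trajectory`,
#'   and `panel`.
#' @export
run_study1 <- function(config = list()) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lexicon <- config_lexicon(config)
  network <- build_phon_network(lexicon)
  message(sprintf("study1: network with %d nodes, %d edges",
                  igraph::vcount(network), igraph::ecount(network)))
  schedule <- damage_schedule(config$damage$fractions, config$damage$seed)
  trajectory <- apply_damage(network, schedule)
  panel <- summarize_trajectory(trajectory)
  write.csv(panel, file.path(config$out_dir, "metrics.csv"),
            row.names = FALSE)
  write_trajectory(trajectory, file.path(config$out_dir, "stages"))
  write_lexicon(lexicon, file.path(config$out_dir, "lexicon.tsv"))
  write_manifest(config, config$out_dir)
  invisible(list(lexicon = lexicon, network = network,
                 trajectory = trajectory, panel = panel))
}

load_study1 <- function(config) {
  stage_dir <- file.path(config$out_dir, "stages")
  if (manifest_matches(config, config$out_dir) && dir.exists(stage_dir)) {
    lexicon <- read_lexicon(file.path(config$out_dir, "lexicon.tsv"),
                            scheme = config$lexicon$scheme %||% "chars")
    stage_files <- sort(list.files(stage_dir, pattern = "^stage_.*\\.graphml$",
                                   full.names = TRUE))
    stages <- lapply(stage_files, read_network, format = "graphml")
    fractions <- as.numeric(sub("^stage_([0-9]+)\\.graphml$", "\\1",
                                basename(stage_files))) / 100
    trajectory <- structure(
      list(stages = stages, fractions = fractions,
           removed = NULL, seed = config$damage$seed),
      class = "damage_trajectory")
    panel <- read.csv(file.path(config$out_dir, "metrics.csv"))
    message("study2: reusing study 1 outputs from ", config$out_dir)
    list(lexicon = lexicon, network = stages[[1L]],
         trajectory = trajectory, panel = panel)
  } else {
    run_study1(config)
  }
}

#' Study 2 driver: retrieval simulations on the damaged networks
#'
#' Reuses study 1 outputs when present in `out_dir` with a matching
#' manifest (recomputing otherwise), then runs one spreading-activation
#' simulation per (target word, damage stage), classifies each word's
#' activation trajectory, correlates final activation on the most-damaged
#' network with a naming-accuracy table (synthetic, with a planted
#' correlation, unless a real table is supplied via
#' `config$behavior$accuracy_path`), and runs the location chi-square per
#' severity group against the damage stage configured for that severity.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with `activations` (long table),
#'   `classes` (per-word trajectory labels), `correlations`, and
#'   `chisq` (per-severity results).
#' @export
run_study2 <- function(config = list()) {
  config <- pipeline_config(config)
  s1 <- load_study1(config)
  params <- config_spread(config)
  targets <- config_targets(config, s1$lexicon, s1$network)
  act <- batch_spread(s1$trajectory, targets, params)
  write.csv(act, file.path(config$out_dir, "activations.csv"),
            row.names = FALSE)
  # per-word trajectory classification over the damaged stages
  damaged <- act[act$fraction_removed > 0, ]
  classes <- vapply(split(damaged, damaged$word), function(d) {
    classify_trajectory(d$activation[order(d$fraction_removed)], params)
  }, "")
  class_table <- data.frame(word = names(classes), pattern = unname(classes))
  write.csv(class_table, file.path(config$out_dir, "trajectory_classes.csv"),
            row.names = FALSE)
  # activation on the most damaged network vs naming accuracy
  last_frac <- max(act$fraction_removed)
  final_act <- act[act$fraction_removed == last_frac, ]
  bh <- config$behavior
  accuracy <- if (!is.null(bh$accuracy_path)) {
    read.csv(bh$accuracy_path)
  } else {
    generate_accuracy(final_act, synth_behavior_spec(
      rho = bh$rho, noise = bh$noise, enrichment = bh$enrichment,
      n_errors = bh$n_errors, seed = bh$seed))
  }
  correlations <- correlate_activation_accuracy(final_act, accuracy)
  write.csv(correlations, file.path(config$out_dir, "correlations.csv"),
            row.names = FALSE)
  # location chi-square per severity group, on that severity's stage
  chisq <- lapply(names(config$severity_stage), function(sev) {
    frac <- config$severity_stage[[sev]]
    k <- which(abs(s1$trajectory$fractions - frac) < 1e-9)
    if (length(k) != 1L) {
      stop(sprintf("severity '%s' maps to fraction %g not in the schedule",
                   sev, frac))
    }
    net <- s1$trajectory$stages[[k]]
    errs <- generate_errors(net, synth_behavior_spec(
      rho = bh$rho, noise = bh$noise, enrichment = bh$enrichment,
      n_errors = bh$n_errors, seed = bh$seed), severity = sev)
    location_chisq(errs, net)
  })
  names(chisq) <- names(config$severity_stage)
  report <- file.path(config$out_dir, "location_chisq.txt")
  sink(report); on.exit(sink(), add = TRUE)
  for (sev in names(chisq)) {
    cat(sprintf("severity: %s (stage %g)\n", sev,
                config$severity_stage[[sev]]))
    print(chisq[[sev]])
    cat("\n")
  }
  sink(); on.exit()
  invisible(list(activations = act, classes = class_table,
                 correlations = correlations, chisq = chisq))
}

#' Study 3 driver: decay sweep on the intact network
#'
#' Sweeps the decay parameter over the configured values on the intact
#' network, writes the long activation table and all pairwise Pearson
#' correlations between decay settings, and logs whether the
#' final-activation vectors obey the analytic `(1-d)^t` scaling of the
#' d = 0 run.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with `sweep` (long table), `correlations`
#'   (pairwise r), and `scaling_ok` (logical).
#' @export
run_study3 <- function(config = list()) {
  config <- pipeline_config(config)
  s1 <- load_study1(config)
  params <- config_spread(config)
  targets <- config_targets(config, s1$lexicon, s1$network)
  sweep <- decay_sweep(s1$network, targets, config$sweep, params)
  write.csv(sweep, file.path(config$out_dir, "decay_sweep.csv"),
            row.names = FALSE)
  correlations <- sweep_correlations(sweep)
  write.csv(correlations, file.path(config$out_dir,
                                    "decay_correlations.csv"),
            row.names = FALSE)
  # analytic check: activation at decay d = (1-d)^t * activation at d=0
  p0 <- params; p0$decay <- 0
  base <- decay_sweep(s1$network, targets, 0, p0)
  scaling_ok <- all(vapply(unique(sweep$decay), function(d) {
    lhs <- sweep$activation[sweep$decay == d]
    rhs <- (1 - d)^params$t * base$activation
    max(abs(lhs - rhs)) < 1e-9
  }, logical(1)))
  message(sprintf("study3: (1-d)^t scaling check %s",
                  if (scaling_ok) "passed" else "FAILED"))
  invisible(list(sweep = sweep, correlations = correlations,
                 scaling_ok = scaling_ok))
}
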