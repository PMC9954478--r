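test_that("pearson_test matches the closed-form estimator and its t p-value", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  got <- pearson_test(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((length(x) - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = length(x) - 2)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, p, tolerance = 1e-12)
  expect_equal(pearson_test(x, 2 * x)$r, 1)
  expect_equal(pearson_test(x, -x)$r, -1)
  expect_error(pearson_test(x, rep(1, 10)), "constant")
  expect_error(pearson_test(1:2, 1:2), "at least 3")
})

test_that("activation-accuracy correlation joins per group and checks overlap", {
  act <- data.frame(word = paste0("w", 1:20), activation = (1:20)^2)
  acc <- rbind(
    data.frame(word = paste0("w", 1:20), group = "anomic",
               accuracy = seq(0.05, 0.95, length.out = 20)),
    data.frame(word = paste0("w", 1:2), group = "tiny", accuracy = 0.5)
  )
  expect_error(correlate_activation_accuracy(act, acc), "tiny")
  acc <- acc[acc$group == "anomic", ]
  out <- correlate_activation_accuracy(act, acc)
  expect_equal(out$n, 20L)
  # a linear transform of activation correlates perfectly
  acc$accuracy <- (act$activation / max(act$activation)) * 0.9
  expect_equal(correlate_activation_accuracy(act, acc)$r, 1)
  # out-of-range accuracy rejected
  acc$accuracy[1] <- 1.2
  expect_error(correlate_activation_accuracy(act, acc), "\\[0, 1\\]")
})

test_that("word locations are classified exactly and partition the network", {
  g <- igraph::make_graph(~ a - b, b - c, c - d, p - q) +
    igraph::vertices("solo")
  expect_equal(classify_location(g, "solo"), "isolate")
  expect_equal(classify_location(g, "a"), "giant_component")
  expect_equal(classify_location(g, "p"), "island")
  expect_error(classify_location(g, "nope"), "not in network")
  loc <- classify_location(g, igraph::V(g)$name)
  expect_equal(sum(loc == "giant_component"), 4L)
  expect_equal(sum(loc == "island"), 2L)
  expect_equal(sum(loc == "isolate"), 1L)
})

test_that("location chi-square equals the textbook goodness-of-fit formula", {
  # network with 1/3 of nodes in the GC
  g <- igraph::make_graph(~ a - b, b - c, c - a) +
    igraph::vertices(paste0("x", 1:6))
  # observed proportions equal to expected -> statistic 0
  errs <- c("a", "b", "c", paste0("x", 1:6))
  res <- location_chisq(errs, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_error(location_chisq(character(0), g), "no error records")

  # hand-computed example: observed (60, 40) of 100 errors on a network
  # with exactly 33% of nodes in the GC -> X^2 = 27^2/33 + 27^2/67 = 32.97
  ring <- igraph::make_ring(33)
  igraph::V(ring)$name <- paste0("g", 1:33)
  h <- ring + igraph::vertices(paste0("x", 1:67))
  errs <- c(rep("g1", 60), rep("x1", 40))
  res <- location_chisq(errs, h)
  oracle <- sum((c(60, 40) - c(33, 67))^2 / c(33, 67))
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 32.97, tolerance = 1e-2)
  expect_lt(res$p, 0.001)
})

test_that("chi-square matches direct arithmetic on random 2-cell inputs", {
  g <- igraph::make_graph(~ a - b, b - c, c - a) +
    igraph::vertices(paste0("x", 1:6))
  set.seed(42)
  for (rep in 1:20) {
    n_in <- sample(1:50, 1); n_out <- sample(1:50, 1)
    errs <- c(rep("a", n_in), rep("x1", n_out))
    res <- location_chisq(errs, g)
    n <- n_in + n_out
    exp_counts <- n * c(1 / 3, 2 / 3)
    expect_equal(res$statistic,
                 sum((c(n_in, n_out) - exp_counts)^2 / exp_counts),
                 tolerance = 1e-9)
  }
})

test_that("planted GC enrichment is detected with high power", {
  lex <- generate_lexicon(synth_lexicon_spec(n_words = 800, seed = 19))
  g <- build_phon_network(lex)
  n_reject <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    errs <- generate_errors(g, synth_behavior_spec(enrichment = 1.7,
                                                   n_errors = 1500L,
                                                   seed = s))
    res <- location_chisq(errs, g)
    if (res$p < 0.01) n_reject <- n_reject + 1L
  }
  expect_gte(n_reject / n_rep, 0.95)
})

test_that("null errors stay within the binomial band", {
  lex <- generate_lexicon(synth_lexicon_spec(n_words = 800, seed = 19))
  g <- build_phon_network(lex)
  cen <- component_census(g)
  p_gc <- cen$gc_size / cen$n_nodes
  errs <- generate_errors(g, synth_behavior_spec(enrichment = 1,
                                                 n_errors = 2000L, seed = 5))
  frac <- mean(classify_location(g, errs$word, cen) == "giant_component")
  expect_lt(abs(frac - p_gc), 3 * sqrt(p_gc * (1 - p_gc) / 2000))
})

test_that("trajectory patterns are classified with parameter-derived sentinels", {
  expect_equal(classify_trajectory(rep(0.625, 5)), "always_isolate")
  expect_equal(classify_trajectory(c(3.1, 2.2, 0.625, 0.625, 0.625)),
               "became_isolate")
  expect_equal(classify_trajectory(c(3.1, 2.2, 2.0, 10, 10)),
               "became_size2_island")
  expect_equal(classify_trajectory(c(1.8, 2.0, 2.9, 4.4, 7.0)),
               "activation_increased")
  expect_equal(classify_trajectory(c(5.2, 4.0, 3.1, 2.8, 2.2)),
               "other_decreasing")
  # sentinels follow the parameters instead of being hard-coded
  p <- spread_params(a0 = 100, retention = 0.4, t = 3L)
  iso_val <- 100 * 0.4^3
  expect_equal(classify_trajectory(rep(iso_val, 4), p), "always_isolate")
  expect_equal(classify_trajectory(c(7, 50, 50), p), "became_size2_island")
  expect_error(classify_trajectory(1), ">= 2 stages")
})

test_that("trajectory classes are mutually exclusive and exhaustive", {
  # every random activation sequence gets exactly one of the five labels
  labels <- c("always_isolate", "became_isolate", "became_size2_island",
              "activation_increased", "other_decreasing")
  set.seed(7)
  for (rep in 1:50) {
    acts <- sample(c(runif(3, 0, 15), 0.625, 10), 5, replace = TRUE)
    got <- classify_trajectory(acts)
    expect_true(got %in% labels)
  }
})

test_that("planted correlation is recovered on average at study scale", {
  # 500 replicate accuracy tables at n = 165 with rho = 0.18
  lex <- generate_lexicon(synth_lexicon_spec(n_words = 1000, seed = 23))
  g <- build_phon_network(lex)
  words <- sample_targets(g, 165, seed = 3)
  act <- decay_sweep(g, words, 0)[, c("word", "activation")]
  rs <- vapply(1:500, function(s) {
    acc <- generate_accuracy(act, synth_behavior_spec(rho = 0.18, seed = s),
                             groups = "anomic")
    correlate_activation_accuracy(act, acc)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.18), 0.03)
})
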