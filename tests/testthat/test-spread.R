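test_that("one step reproduces the hand-computed worked examples", {
  p <- spread_params()
  # isolate keeps r of its activation; the outgoing share is lost
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "x"
  expect_equal(spread_step(20, iso, p), 10)
  # dyad (20, 0) -> (10, 10)
  dyad <- igraph::make_graph(~ a - b)
  expect_equal(spread_step(c(20, 0), dyad, p), c(10, 10))
  # star: center 20, three leaves -> center 10, each leaf 10/3
  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- c("c", "l1", "l2", "l3")
  expect_equal(spread_step(c(20, 0, 0, 0), star, p),
               c(10, 10 / 3, 10 / 3, 10 / 3))
})

test_that("steps agree with the transition-matrix power oracle", {
  for (seed in 1:5) {
    g <- random_named_graph(20, 0.2, seed = seed)
    set.seed(seed + 100)
    init <- runif(20, 0, 20)
    r <- runif(1, 0.1, 0.9)
    d <- runif(1, 0, 0.5)
    p <- spread_params(a0 = 20, retention = r, decay = d, t = 4L)
    a <- init
    for (k in 1:4) a <- spread_step(a, g, p)
    oracle <- spread_by_matrix_power(g, init, r, d, 4L)
    expect_equal(a, oracle, tolerance = 1e-12)
  }
})

test_that("activation is conserved without decay unless isolates leak it", {
  p <- spread_params()
  # no degree-0 node holds activation: total is constant
  g <- random_named_graph(15, 0.35, seed = 3)
  keep <- igraph::degree(g) > 0
  init <- ifelse(keep, 2, 0)
  a <- init
  for (k in 1:6) a <- spread_step(a, g, p)
  expect_equal(sum(a), sum(init), tolerance = 1e-9)
  # an active isolate leaks its outgoing share each step
  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("u", "v")
  totals <- numeric(4)
  a <- c(20, 20)
  for (k in 1:4) { a <- spread_step(a, iso, p); totals[k] <- sum(a) }
  expect_true(all(diff(c(40, totals)) < 0))
})

test_that("activation stays non-negative for all in-range parameters", {
  g <- random_named_graph(12, 0.3, seed = 6)
  for (r in c(0, 0.3, 1)) {
    for (d in c(0, 0.5, 1)) {
      p <- spread_params(retention = r, decay = d, suppress = 0.01, t = 3L)
      a <- runif(12, 0, 5)
      for (k in 1:3) {
        a <- spread_step(a, g, p)
        expect_true(all(a >= 0))
      }
    }
  }
})

test_that("worked final activations: hermit 0.625, two-node island 10", {
  g <- igraph::make_graph(~ a - b) + igraph::vertices("hermit")
  expect_identical(simulate_word(g, "hermit")$final, 20 * 0.5^5)
  expect_equal(simulate_word(g, "hermit")$final, 0.625)
  expect_equal(simulate_word(g, "a")$final, 10)
  expect_error(simulate_word(g, "nope"), "not in network")
  # trajectory starts at a0 and settles monotonically for the dyad
  tr <- simulate_word(g, "a", trajectory = TRUE)$steps
  expect_equal(tr[1], 20)
  expect_equal(tr[-1], rep(10, 5)) # settles after one step, stays there
})

test_that("a two-node island splits activation equally for any retention", {
  dyad <- igraph::make_graph(~ a - b)
  for (r in c(0.2, 0.5, 0.8)) {
    p <- spread_params(retention = r, t = 60L)
    out <- simulate_word(dyad, "a", p, trajectory = TRUE)
    expect_equal(out$final, 10, tolerance = 1e-9)
    # the deviation from the A/2 steady state contracts monotonically
    expect_true(all(diff(abs(out$steps - 10)) <= 1e-12))
  }
})

test_that("decay rescales the whole state by (1-d)^t", {
  g <- random_named_graph(30, 0.15, seed = 9)
  words <- igraph::V(g)$name[1:10]
  p0 <- spread_params()
  base <- decay_sweep(g, words, 0, p0)
  for (d in c(0.1, 0.9)) {
    out <- decay_sweep(g, words, d, p0)
    expect_equal(out$activation, (1 - d)^5 * base$activation,
                 tolerance = 1e-12)
  }
})

test_that("batch simulation tracks stage structure word by word", {
  # empty word list -> empty table
  g <- random_named_graph(10, 0.3, seed = 1)
  traj <- apply_damage(g, damage_schedule(0.5, seed = 1))
  empty <- batch_spread(traj, character(0))
  expect_equal(nrow(empty), 0L)

  # a word stripped of all edges reports the hermit value from then on
  h <- igraph::make_graph(~ a - b) + igraph::vertices("z")
  traj <- apply_damage(h, damage_schedule(1.0, seed = 2))
  out <- batch_spread(traj, c("a", "z"))
  expect_equal(out$activation[out$word == "a" & out$fraction_removed == 1],
               0.625)
  expect_equal(out$activation[out$word == "z" & out$fraction_removed == 0],
               0.625)
})

test_that("activation drains away when neighbors connect deeper", {
  # the retrieval advantage of sparse neighborhoods: the more onward
  # connections a target's neighbors have, the less activation returns
  # to the target. Hub with 3 leaves; each leaf carries p pendant drains.
  finals <- vapply(0:5, function(p) {
    g <- igraph::make_star(4, mode = "undirected")
    if (p > 0) {
      for (leaf in 2:4) {
        n0 <- igraph::vcount(g)
        g <- igraph::add_vertices(g, p)
        g <- igraph::add_edges(g, as.vector(rbind(leaf, (n0 + 1):(n0 + p))))
      }
    }
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    simulate_word(g, "v1")$final
  }, numeric(1))
  expect_equal(finals[1], 10) # pure star: leaves return everything
  expect_true(all(diff(finals) < 0))
  # cross-check the densest case against the matrix-power oracle
  g <- igraph::make_star(4, mode = "undirected")
  for (leaf in 2:4) {
    n0 <- igraph::vcount(g)
    g <- igraph::add_vertices(g, 5)
    g <- igraph::add_edges(g, as.vector(rbind(leaf, (n0 + 1):(n0 + 5))))
  }
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  init <- numeric(igraph::vcount(g)); init[1] <- 20
  expect_equal(finals[6],
               spread_by_matrix_power(g, init, 0.5, 0, 5L)[1],
               tolerance = 1e-12)
})

test_that("sweep correlations are all +1 and consistent with d = 0", {
  lex <- generate_lexicon(synth_lexicon_spec(n_words = 300, seed = 17))
  g <- build_phon_network(lex)
  words <- sample_targets(g, 30, seed = 2)
  sweep <- decay_sweep(g, words)
  cors <- sweep_correlations(sweep)
  expect_equal(nrow(cors), 10L) # choose(5, 2)
  expect_equal(cors$r, rep(1, 10), tolerance = 1e-12)
  # d = 0 column equals plain simulate_word output
  p <- spread_params()
  zero <- decay_sweep(g, words, 0)
  direct <- vapply(words, function(w) simulate_word(g, w, p)$final,
                   numeric(1))
  expect_equal(zero$activation, unname(direct), tolerance = 1e-12)
  # a single d value yields an empty correlation table
  single <- sweep_correlations(decay_sweep(g, words, 0.3))
  expect_equal(nrow(single), 0L)
})

test_that("co-activation mode matches separate runs only when targets cannot mix", {
  # two targets in disjoint components: joint run equals separate runs
  g <- igraph::make_graph(~ a - b, c - d)
  traj <- apply_damage(g, damage_schedule(0.5, seed = 1))
  sep <- batch_spread(traj, c("a", "c"))
  jnt <- batch_spread(traj, c("a", "c"), joint = TRUE)
  expect_equal(jnt$activation, sep$activation, tolerance = 1e-12)
  # adjacent targets exchange activation: joint run ends higher; compare
  # on the intact stage where both targets stay connected
  h <- igraph::make_graph(~ a - b, b - c)
  traj <- apply_damage(h, damage_schedule(0.5, seed = 1))
  sep <- batch_spread(traj, c("a", "b"))
  jnt <- batch_spread(traj, c("a", "b"), joint = TRUE)
  sep0 <- sep$activation[sep$fraction_removed == 0]
  jnt0 <- jnt$activation[jnt$fraction_removed == 0]
  # joint state is the superposition of the separate runs (linearity)
  both <- sapply(c("a", "b"), function(w) {
    init <- numeric(3); init[match(w, igraph::V(h)$name)] <- 20
    spread_by_matrix_power(h, init, 0.5, 0, 5L)
  })
  expect_equal(jnt0, (both[, "a"] + both[, "b"])[1:2], tolerance = 1e-12)
  expect_true(all(jnt0 > sep0))
})
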