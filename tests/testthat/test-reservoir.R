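test_that("the packaged template grid has 1471 neurons", {
  g <- load_grid(system.file("extdata", "talairach_grid_1cm_synthetic.txt",
                             package = "snnmorph"))
  expect_equal(g$n, 1471)
  expect_equal(ncol(g$coords), 3)
})

test_that("load_grid reads toy files and rejects malformed or duplicate rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0", "10, 0, 0", "0 10 0"), path)
  expect_equal(load_grid(path)$n, 3)
  writeLines(c("0 0 0", "1 2"), path)
  expect_error(load_grid(path), "line 2")
  writeLines(c("0 0 0", "0 0 0"), path)
  expect_error(load_grid(path), "[Dd]uplicate")
})

test_that("synthetic lattice grids are deterministic and inside the ellipsoid", {
  g2 <- synthetic_grid(2)
  expect_lte(g2$n, 8)
  g <- synthetic_grid(7)
  memb <- (g$coords[, 1] / 70)^2 + (g$coords[, 2] / 85)^2 +
    (g$coords[, 3] / 65)^2
  expect_true(all(memb <= 1 + 1e-9))
  expect_identical(synthetic_grid(7)$coords, g$coords)
  expect_error(synthetic_grid(1), ">= 2")
})

test_that("input mapping is nearest-neighbour, collision-safe and injective", {
  # channel exactly at a neuron's coordinate
  g <- neuron_grid(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0),
                         c(0, 10, 0), c(0, 0, 10)))
  m1 <- montage("A", matrix(c(10, 0, 0), 1))
  expect_equal(unname(map_inputs(m1, g)), 2L)
  # two channels nearest to the same neuron: second takes next-nearest free
  m2 <- montage(c("A", "B"), rbind(c(10, 0, 0), c(11, 0, 0)))
  im <- map_inputs(m2, g)
  expect_equal(unname(im), c(2L, 3L))
  expect_equal(length(unique(im)), 2)
  # full montage onto the desk grid stays injective
  mont <- make_default_montage()
  im66 <- map_inputs(mont, synthetic_grid(11))
  expect_length(unique(im66), 66)
  # more channels than neurons
  expect_error(map_inputs(mont, synthetic_grid(3)), "more channels")
})

test_that("small-world wiring respects the hard radius and decays with distance", {
  g <- synthetic_grid(7)
  res <- init_small_world(g, swc_params(r_frac = 0.25), seed = 5)
  d <- as.matrix(dist(g$coords))
  radius <- 0.25 * max(d)
  ed <- d[cbind(res$edges$i, res$edges$j)]
  expect_true(all(ed <= radius + 1e-9))
  expect_true(all(res$edges$i != res$edges$j))
  expect_true(all(abs(res$edges$w) <= swc_params()$w_init + 1e-12))
  # empirical connection frequency is non-increasing across distance bins
  bins <- cut(ed, breaks = seq(0, radius, length.out = 4))
  all_bins <- cut(d[d > 0 & d <= radius], breaks = seq(0, radius,
                                                       length.out = 4))
  freq <- as.numeric(table(bins) / table(all_bins))
  freq <- freq[is.finite(freq)]
  expect_true(all(diff(freq) < 0.05))
})

test_that("connection probability at d = lambda matches exp(-1)", {
  # three collinear neurons: the far pair sets d_max, the near pair sits at
  # exactly lambda = (r_frac * d_max) / 2
  r_frac <- 0.5
  d_far <- 100
  lambda <- r_frac * d_far / 2
  g <- neuron_grid(rbind(c(0, 0, 0), c(lambda, 0, 0), c(d_far, 0, 0)))
  hits <- vapply(1:1000, function(s) {
    res <- init_small_world(g, swc_params(r_frac = r_frac, p_inh = 0),
                            seed = s)
    any(res$edges$i == 1 & res$edges$j == 2)
  }, logical(1))
  expect_equal(mean(hits), exp(-1), tolerance = 0.05 / exp(-1))
})

test_that("identical seeds reproduce wiring exactly", {
  g <- synthetic_grid(6)
  a <- init_small_world(g, seed = 9)
  b <- init_small_world(g, seed = 9)
  expect_identical(a$edges, b$edges)
  expect_identical(a$inhibitory, b$inhibitory)
  expect_false(identical(a$edges,
                         init_small_world(g, seed = 10)$edges))
})

test_that("dynamics: silence stays silent, forced input fires, chains propagate", {
  edges <- data.frame(i = c(1L, 2L), j = c(2L, 3L), w = c(1, 1))
  mod <- toy_model(3, edges, imap = c(IN = 1L),
                   lif = lif_params(v_thr = 1, k_in = 1.2, refrac = 2))
  quiet <- raw_raster(matrix(0L, 1, 20))
  expect_equal(nrow(run_dynamics(mod, quiet)$fired), 0)
  sp <- matrix(0L, 1, 10); sp[1, 3] <- 1L
  act <- run_dynamics(mod, raw_raster(sp))
  # input neuron fires at the injection step, then one hop per step
  expect_equal(act$fired$neuron[order(act$fired$step)][1:3], c(1L, 2L, 3L))
  expect_equal(act$fired$step[order(act$fired$step)][1:3], c(3L, 4L, 5L))
})

test_that("dynamics match the brute-force LIF oracle on random toy nets", {
  for (k in 1:10) {
    set.seed(400 + k)
    n <- 5
    pairs <- expand.grid(i = 1:n, j = 1:n)
    pairs <- pairs[pairs$i != pairs$j, ]
    pick <- pairs[sample(nrow(pairs), 8), ]
    edges <- data.frame(i = as.integer(pick$i), j = as.integer(pick$j),
                        w = round(runif(8, -0.8, 0.8), 3))
    edges <- edges[order(edges$i, edges$j), ]
    edges$sign <- ifelse(edges$w < 0, -1L, 1L)
    inhib <- rep(FALSE, n)
    inhib[unique(edges$i[edges$sign < 0])] <- TRUE
    # keep signs consistent with per-neuron inhibitory flags
    edges$w <- ifelse(inhib[edges$i], -abs(edges$w), abs(edges$w))
    edges$sign <- ifelse(inhib[edges$i], -1L, 1L)
    lif <- lif_params(tau_m = 8, refrac = sample(1:3, 1), k_in = 1.3)
    imap <- c(A = 1L, B = 4L)
    raster <- matrix(sample(c(-1L, 0L, 1L), 2 * 60, TRUE,
                            prob = c(0.2, 0.5, 0.3)), 2)
    mod <- toy_model(n, edges[, c("i", "j", "w")], imap, lif,
                     inhibitory = inhib)
    got <- run_dynamics(mod, raw_raster(raster))
    want <- oracle_lif_stdp(n, edges, raster, imap, lif)
    expect_equal(got$fired$step, want$fired$step)
    expect_equal(got$fired$neuron, want$fired$neuron)
  }
})

test_that("refractory period bounds inter-fire intervals on the fixture", {
  fx <- make_study_fixture(seed = 2, duration = 4,
                           conditions = "Sound1")
  mont <- fx$montage
  mod <- init_small_world(synthetic_grid(7), seed = 3, montage = mont)
  act <- run_dynamics(mod, sf_encode(fx$recordings$Sound1,
                                     encoder_params(optimize = TRUE)))
  expect_gt(nrow(act$fired), 0)
  by_neuron <- split(act$fired$step, act$fired$neuron)
  gaps <- unlist(lapply(by_neuron, function(s) diff(sort(s))))
  if (length(gaps)) expect_gte(min(gaps), mod$lif$refrac)
})

test_that("potentials decay monotonically toward zero without input", {
  mod <- toy_model(2, data.frame(i = 1L, j = 2L, w = 0.1),
                   imap = c(A = 1L), lif = lif_params(v_thr = 10))
  act <- run_dynamics(mod, raw_raster(matrix(0L, 1, 30)),
                      record_potentials = TRUE, v0 = c(5, -3))
  v <- act$potentials
  expect_true(all(diff(v[1, ]) < 0))      # positive trace decreasing
  expect_true(all(diff(v[2, ]) > 0))      # negative trace rising toward 0
  expect_lt(abs(v[1, 30]), 0.5)
})

test_that("firing grows with the input gain on a fixed raster", {
  fx <- make_study_fixture(seed = 4, duration = 2, conditions = "Pre")
  raster <- sf_encode(fx$recordings$Pre, encoder_params(optimize = TRUE))
  counts <- vapply(c(0.8, 1.2, 2.0), function(k) {
    mod <- init_small_world(synthetic_grid(7), seed = 6,
                            lif = lif_params(k_in = k),
                            montage = fx$montage)
    nrow(run_dynamics(mod, raster)$fired)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_lt(counts[3], 66 * ncol(raster$spikes))   # finite, sane scale
})
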