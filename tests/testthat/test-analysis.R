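# Hand-built trained models over an explicit grid, for exact arithmetic.
mini_trained <- function(w, coords = cbind(c(0, 10, 20), 0, 0),
                         edges_ij = data.frame(i = c(1L, 2L), j = c(2L, 3L)),
                         condition = "Pre") {
  edges <- cbind(edges_ij, w = w)
  mod <- toy_model(nrow(coords), edges, imap = c(A = 1L), coords = coords)
  structure(list(model = mod, trained_on = condition,
                 activity = list(n_fired = 0L, n_steps = 0L),
                 params = stdp_params()),
            class = "snn_trained_model")
}

test_that("model subtraction is exact, antisymmetric and zero on identity", {
  a <- mini_trained(c(0.2, 0.5))
  b <- mini_trained(c(0.4, 0.1), condition = "Post")
  expect_true(all(subtract_models(a, a)$edges$delta == 0))
  ab <- subtract_models(a, b)$edges$delta
  ba <- subtract_models(b, a)$edges$delta
  expect_equal(ab, c(0.2, -0.4))
  expect_equal(ab, -ba)
})

test_that("subtraction requires identical grids and sparsity patterns", {
  a <- mini_trained(c(0.2, 0.5))
  b <- mini_trained(c(0.2, 0.5))
  b$model$grid <- neuron_grid(cbind(c(0, 10, 30), 0, 0))
  expect_error(subtract_models(a, b), "grids")
  d <- mini_trained(0.2, edges_ij = data.frame(i = 1L, j = 3L))
  expect_error(subtract_models(a, d), "sparsity")
})

test_that("retention keeps ceiling(fraction * nonzero) edges with nesting", {
  mk_delta <- function(M) {
    pre <- mini_trained(rep(0.5, M),
                        edges_ij = data.frame(i = rep(1L, M),
                                              j = seq_len(M) + 1L))
    post <- mini_trained(0.5 + seq_len(M) / (2 * M),
                         edges_ij = data.frame(i = rep(1L, M),
                                               j = seq_len(M) + 1L),
                         condition = "Post")
    pre$model$grid <- post$model$grid <-
      neuron_grid(cbind(seq_len(M + 1) * 5, 0, 0))
    subtract_models(pre, post)
  }
  for (M in c(1, 19, 20, 200)) {
    d <- retain_top(mk_delta(M), 0.05)
    expect_equal(sum(d$edges$retained), ceiling(0.05 * M))
  }
  d <- mk_delta(40)
  expect_equal(sum(retain_top(d, 1.0)$edges$retained), 40)
  r05 <- which(retain_top(d, 0.05)$edges$retained)
  r10 <- which(retain_top(d, 0.10)$edges$retained)
  expect_true(all(r05 %in% r10))
})

test_that("retention ranks by relative change with the documented floor", {
  pre <- mini_trained(c(0.9, 0.01),
                      edges_ij = data.frame(i = c(1L, 1L), j = c(2L, 3L)))
  post <- mini_trained(c(0.5, 0.05),
                       edges_ij = data.frame(i = c(1L, 1L), j = c(2L, 3L)),
                       condition = "Post")
  d <- retain_top(subtract_models(pre, post), 0.5)
  # |delta|/|w_pre|: 0.44 vs 4.0 -> the small-weight edge wins
  expect_equal(which(d$edges$retained), 2L)
  d_abs <- retain_top(subtract_models(pre, post), 0.5, relative = FALSE)
  expect_equal(which(d_abs$edges$retained), 1L)
})

test_that("the ten zones are disjoint and place the printed electrodes", {
  sch <- region_scheme()
  expect_length(sch, 10)
  all_z <- unlist(sch)
  expect_equal(anyDuplicated(all_z), 0)
  expect_equal(electrode_zone("P3"), "left_centroparietal")
  expect_equal(electrode_zone("Fp2"), "right_frontal")
  expect_equal(electrode_zone("TP8"), "right_temporal")
  expect_equal(electrode_zone("Cz"), "unassigned")
  expect_equal(electrode_zone("AUX1"), "unassigned")
  expect_error(electrode_zone("ZZ9"), "unknown")
})

test_that("region summaries lateralize correctly and handle empty retention", {
  mont <- make_default_montage()
  # neurons exactly at electrode positions -> zone assignment is exact
  g <- neuron_grid(mont$positions)
  idx <- function(lab) match(lab, mont$labels)
  mk <- function(w, ij, cond) {
    mod <- toy_model(66, cbind(ij, w = w), imap = c(A = 1L),
                     coords = mont$positions)
    structure(list(model = mod, trained_on = cond,
                   activity = list(n_fired = 0L, n_steps = 0L),
                   params = stdp_params()), class = "snn_trained_model")
  }
  ij <- data.frame(i = c(idx("P3"), idx("CP5")),
                   j = c(idx("O1"), idx("P5")))
  pre <- mk(c(0.3, 0.3), ij, "Pre")
  post <- mk(c(0.6, 0.1), ij, "Sound1")
  s <- summarize_regions(retain_top(subtract_models(pre, post), 1.0),
                         montage = mont)
  expect_equal(s$dominance, -1)
  expect_gt(s$increase["left_centroparietal", "left_occipitoparietal"], 0)
  expect_lt(s$decrease["left_centroparietal", "left_centroparietal"], 0)
  expect_true(all(s$increase >= 0) && all(s$decrease <= 0))
  # empty retained set
  s0 <- summarize_regions(subtract_models(pre, pre), montage = mont)
  expect_equal(s0$dominance, 0)
  expect_true(all(s0$increase == 0) && all(s0$decrease == 0))
})

test_that("recovery score finds planted pairs and rejects empty metadata", {
  mont <- make_default_montage()
  idx <- function(lab) match(lab, mont$labels)
  mk <- function(w, ij, cond) {
    mod <- toy_model(66, cbind(ij, w = w), imap = c(A = 1L),
                     coords = mont$positions)
    structure(list(model = mod, trained_on = cond,
                   activity = list(n_fired = 0L, n_steps = 0L),
                   params = stdp_params()), class = "snn_trained_model")
  }
  ij <- data.frame(i = idx("CP5"), j = idx("P5"))
  pre <- mk(0.3, ij, "Pre"); post <- mk(0.8, ij, "Post")
  s <- summarize_regions(retain_top(subtract_models(pre, post), 1.0),
                         montage = mont)
  planted <- data.frame(source = "CP5", target = "P5",
                        source_zone = "left_centroparietal",
                        target_zone = "left_centroparietal")
  expect_equal(recovery_score(s, planted), 1.0)
  expect_error(recovery_score(s, planted[0, ]), "planted")
})
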