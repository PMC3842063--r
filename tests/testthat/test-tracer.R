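test_that("candidate_points enumerates the punctured disk exactly", {
  cfg <- trace_config(radius = 20)
  cand <- candidate_points(c(100, 100), NULL, c(300, 300), cfg)
  expect_equal(nrow(cand), 1256)
  oracle <- oracle_disk_points(c(100, 100), 20, c(300, 300))
  expect_equal(unname(cand), unname(oracle)) # both row-major
  # corner case at r = 2
  cfg2 <- trace_config(radius = 2)
  cand2 <- candidate_points(c(0, 0), NULL, c(100, 100), cfg2)
  expect_equal(unname(cand2),
               rbind(c(0, 1), c(0, 2), c(1, 0), c(1, 1), c(2, 0)))
})

test_that("revisit exclusion removes zones around accepted points", {
  cfg <- trace_config(radius = 5, revisit_exclusion = 2)
  prev <- rbind(c(50, 48)) # adjacent-ish previous point
  cand <- candidate_points(c(50, 50), prev, c(200, 200), cfg)
  cheb <- pmax(abs(cand[, 1] - 50), abs(cand[, 2] - 48))
  expect_true(all(cheb > 2))
  # without history the zone is present
  cand0 <- candidate_points(c(50, 50), NULL, c(200, 200), cfg)
  expect_gt(nrow(cand0), nrow(cand))
})

test_that("score_candidate multiplies exactly the enabled factors", {
  sm <- fit_smoothness_model(rbind(c(0, 0), c(0.2, 0), c(0, 0.2), c(0.2, 0.2)))
  cfg_t <- trace_config(mode = "T")
  cfg_ts <- trace_config(mode = "TS")
  cfg_tsp <- trace_config(mode = "TSP")
  cand <- c(10, 11); p_k <- c(9, 10); p_k1 <- c(8, 9)
  s_t <- score_candidate(cand, p_k, p_k1, 0.8, sm, cfg_t)
  expect_equal(s_t$joint, 0.8)
  s_ts <- score_candidate(cand, p_k, p_k1, 0.8, sm, cfg_ts)
  expect_equal(s_ts$joint,
               0.8 * smoothness_probability(sm, cand, p_k, p_k1))
  s_tsp <- score_candidate(cand, p_k, p_k1, 0.8, sm, cfg_tsp)
  expect_equal(s_tsp$joint,
               0.8 * smoothness_probability(sm, cand, p_k, p_k1) *
                 laplace_prior(0.8, cfg_tsp$prior))
  # missing history: smoothness dropped, prior kept in TSP
  s2 <- score_candidate(cand, p_k, NULL, 0.8, sm, cfg_tsp)
  expect_equal(s2$joint, 0.8 * laplace_prior(0.8, cfg_tsp$prior))
  expect_equal(score_candidate(cand, p_k, p_k1, 0, sm, cfg_tsp)$joint, 0)
})

test_that("equal-texture candidates are ranked by closeness to the slope mean", {
  # straight history moving down; smoothness prefers continuing straight
  sm <- structure(list(mean = c(0, 0), covariance = diag(0.05, 2),
                       epsilon = 0), class = "smoothness_model")
  cfg <- trace_config(mode = "TS")
  p_k1 <- c(8, 20); p_k <- c(10, 20)
  straight <- c(12, 20) # slope (0, 0)
  bent <- c(12, 24)     # turns sideways
  s1 <- score_candidate(straight, p_k, p_k1, 0.7, sm, cfg)
  s2 <- score_candidate(bent, p_k, p_k1, 0.7, sm, cfg)
  expect_gt(s1$joint, s2$joint)
})

test_that("a shared positive constant never changes the argmax (dropped factors)", {
  set.seed(51)
  texture <- runif(30, 0.5, 1)
  sm <- fit_smoothness_model(cbind(rnorm(20, 0, 0.2), rnorm(20, 0, 0.2)))
  cfg <- trace_config(mode = "TSP")
  p_k <- c(50, 50); p_k1 <- c(48, 49)
  cand <- cbind(51 + sample(0:3, 30, TRUE), 48 + sample(0:5, 30, TRUE))
  ok <- !(cand[, 1] == p_k[1] & cand[, 2] == p_k[2])
  cand <- cand[ok, ]; texture <- texture[ok]
  joints <- sapply(seq_len(nrow(cand)), function(i) {
    score_candidate(cand[i, ], p_k, p_k1, texture[i], sm, cfg)$joint
  })
  for (const in c(0.013, 1, 57)) {
    expect_identical(which.max(joints), which.max(joints * const))
  }
})

test_that("find_start_point picks the topmost boundary row, leftmost max", {
  suite <- small_suite()
  ph <- suite$test
  start <- find_start_point(ph$image, suite$models$texture)
  expect_false(is.null(start))
  # the start row must be at/above wherever the gt curve begins (the curve
  # spans every row, so the first boundary-classified row is near the top)
  expect_lte(start["row"], 25)
  # pure background image: no start point
  set.seed(52)
  bg <- matrix(pmax(0, pmin(255, round(rnorm(64 * 64, 5, 2)))), 64, 64)
  expect_null(find_start_point(bg, suite$models$texture))
})

test_that("tracing a small phantom follows its ground truth", {
  suite <- small_suite()
  ph <- suite$test
  b <- trace_boundary(ph$image, suite$models$texture,
                      suite$models$smoothness, trace_config())
  expect_gt(nrow(b), 5)
  # consecutive points distinct and within the trace radius
  d <- sqrt(rowSums(diff(b)^2))
  expect_true(all(d > 0))
  expect_true(all(d <= 20))
  # no accepted point repeats
  expect_equal(nrow(unique(b)), nrow(b))
  # follows the gt curve reasonably at small scale
  expect_lt(acc_mean(b, ph$gt_boundary), 8)
  # the accepted point at each step attains the maximum joint score:
  # re-check determinism by re-tracing
  b2 <- trace_boundary(ph$image, suite$models$texture,
                       suite$models$smoothness, trace_config())
  expect_identical(b, b2)
})

test_that("tracing a uniform black image returns an empty boundary", {
  suite <- small_suite()
  img <- matrix(0L, 96, 96)
  b <- trace_boundary(img, suite$models$texture, suite$models$smoothness,
                      trace_config())
  expect_equal(nrow(b), 0)
  expect_match(attr(b, "termination"), "no start")
})

test_that("the trace window must match the model's training window", {
  suite <- small_suite()
  expect_error(
    trace_boundary(suite$test$image, suite$models$texture,
                   suite$models$smoothness, trace_config(window = 40)),
    "does not match")
})

test_that("max_steps caps the trace length", {
  suite <- small_suite()
  cfg <- trace_config(max_steps = 4)
  b <- trace_boundary(suite$test$image, suite$models$texture,
                      suite$models$smoothness, cfg)
  expect_lte(nrow(b), 4)
})

test_that("ablate_modes shares texture probabilities across modes", {
  suite <- small_suite()
  traced <- ablate_modes(suite$test$image, suite$models$texture,
                         suite$models$smoothness, trace_config())
  expect_named(traced, c("T", "TS", "TSP"))
  # each mode's trace equals an independent run of that mode
  for (m in names(traced)) {
    cfg <- trace_config(mode = m)
    solo <- trace_boundary(suite$test$image, suite$models$texture,
                           suite$models$smoothness, cfg)
    expect_identical(unname(traced[[m]]), unname(solo), label = m)
  }
})
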