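# Frame-subtraction scoring, tracking classification, response latency.

test_that("binarization handles constant, two-level and noisy frames", {
  expect_false(any(binarize(matrix(5, 10, 10))))
  two <- matrix(1, 16, 16); two[5:8, 5:8] <- 100
  expect_identical(unname(which(binarize(two))),
                   unname(which(two == 100)))
  # seeded noisy Gaussian spot: >= 99% of true spot pixels recovered
  set.seed(41)
  spot <- outer(1:32, 1:32, function(r, c)
    1000 * exp(-((r - 16)^2 + (c - 16)^2) / (2 * 1.5^2)))
  noisy <- matrix(rpois(32 * 32, 10 + spot), 32, 32)
  truth <- spot > 200  # the resolvable core of the blob
  mask <- binarize(noisy)
  expect_gte(sum(mask & truth) / sum(truth), 0.99)
})

test_that("motility score is zero for static movies and scale-invariant", {
  pos <- matrix(c(10, 10, 30, 40), 2, 2, byrow = TRUE)
  static <- toy_movie(list(pos, pos, pos))
  ms <- motility_score(static)
  expect_equal(ms$score, 0)

  moving <- toy_movie(list(pos, pos + 3, pos + 6))
  msm <- motility_score(moving)
  expect_gt(msm$score, ms$score)

  # global intensity scaling leaves the binarized score unchanged
  scaled <- moving
  scaled$frames <- scaled$frames * 7.3
  expect_equal(motility_score(scaled)$per_pair, msm$per_pair)

  dark <- movie_stack(array(0, dim = c(8, 8, 2)), fps = 25)
  expect_true(motility_score(dark)$undefined)
})

test_that("doubling density doubles the raw score but not the normalized", {
  set.seed(42)
  n <- 20
  x <- runif(n, 10, 110); y <- runif(n, 10, 110)
  step <- function(p, k) cbind(p[, 1] + 3 * k, p[, 2])
  base <- lapply(0:4, function(k) step(cbind(x, y), k))
  dup <- lapply(base, function(p) rbind(p, p + 60))  # second shifted copy
  m1 <- motility_score(toy_movie(base, dim = c(220, 220)))
  m2 <- motility_score(toy_movie(dup, dim = c(220, 220)))
  expect_equal(mean(m2$per_pair) / mean(m1$per_pair), 2, tolerance = 0.2)
  expect_lt(abs(m2$score - m1$score) / m1$score, 0.2)
})

test_that("percent motile is exact on noise-free extremes", {
  pos <- cbind(seq(10, 50, by = 10), seq(10, 50, by = 10))
  static <- toy_movie(rep(list(pos), 8))
  expect_equal(percent_motile(static)$percent_motile, 0)

  frames <- lapply(0:7, function(k) pos + 3 * k)
  allmot <- toy_movie(frames, dim = c(96, 96))
  expect_equal(percent_motile(allmot)$percent_motile, 100)

  empty <- movie_stack(array(1, dim = c(16, 16, 3)), 25)
  expect_error(percent_motile(empty), "zero detected cells")
})

test_that("generated movies at extreme motile fractions classify exactly", {
  pre <- fixture_preset("arbacia_asw_motility")
  pre$n_cells <- 40L; pre$n_frames <- 20L; pre$dim <- c(160L, 160L)
  pre$motile_fraction <- 0
  mv0 <- gen_movie(pre, seed = 43)
  expect_equal(percent_motile(mv0$stack)$percent_motile, 0)
  pre$motile_fraction <- 1
  mv1 <- gen_movie(pre, seed = 44)
  expect_equal(percent_motile(mv1$stack)$percent_motile, 100)
})

test_that("a planted motile fraction is recovered within binomial error", {
  pre <- fixture_preset("arbacia_asw_motility")
  pre$n_cells <- 120L; pre$n_frames <- 20L; pre$dim <- c(300L, 300L)
  pre$motile_fraction <- 0.6
  mv <- gen_movie(pre, seed = 45)
  est <- percent_motile(mv$stack)$percent_motile
  expect_equal(est, 60, tolerance = 0.12)
})

test_that("response latency times planted onsets and non-responders", {
  # all cells start moving 4 frames after the flash at 40 Hz -> 0.1 s
  pos <- cbind(c(15, 15, 45, 45), c(15, 45, 15, 45))
  frames <- lapply(1:16, function(f)
    if (f < 9) pos else pos + 3 * (f - 8))
  st <- toy_movie(frames, dim = c(128, 128), fps = 40, flash_frame = 5)
  rl <- response_latency(st)
  expect_equal(unname(rl$latency_s), rep(0.1, 4))
  expect_equal(rl$responder_fraction, 1)

  still <- toy_movie(rep(list(pos), 10), dim = c(128, 128), fps = 40,
                     flash_frame = 3)
  rl0 <- response_latency(still)
  expect_equal(rl0$responder_fraction, 0)
  expect_true(all(is.infinite(rl0$latency_s)))

  expect_error(response_latency(still, flash_frame = 10), "post-flash")
})

test_that("latency is nonincreasing in planted speed", {
  mk <- function(speed) {
    pos <- cbind(c(20, 60), c(20, 60))
    frames <- lapply(1:12, function(f)
      if (f < 6) pos else pos + speed * (f - 5))
    toy_movie(frames, dim = c(160, 160), fps = 40, flash_frame = 2)
  }
  slow <- response_latency(mk(1.2), speed_threshold_px = 1)
  fast <- response_latency(mk(4), speed_threshold_px = 1)
  expect_true(all(fast$latency_s <= slow$latency_s))
})

test_that("tiff round trip preserves the stack geometry", {
  pre <- fixture_preset("arbacia_asw_motility")
  pre$n_cells <- 10L; pre$n_frames <- 3L; pre$dim <- c(64L, 64L)
  mv <- gen_movie(pre, seed = 46)
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(mv$stack, path)
  back <- read_movie_tiff(path, fps = 25)
  expect_equal(dim(back$frames), dim(mv$stack$frames))
  # relative intensities preserved up to the storage scaling
  expect_gt(cor(as.numeric(back$frames), as.numeric(mv$stack$frames)),
            0.999)
})
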