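# independent oracle: SEM at block size B by direct consecutive chunking
# (no pairwise recursion); valid whenever B divides n
chunked_sem <- function(x, B) {
  m <- length(x) %/% B
  bm <- colMeans(matrix(x[seq_len(m * B)], nrow = B))
  stats::sd(bm) / sqrt(m)
}

test_that("reblocking matches direct chunked blocking on power-of-two input", {
  set.seed(41)
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 2^10))
  curve <- reblock(x)
  for (i in seq_len(nrow(curve$levels))) {
    B <- curve$levels$block_size[i]
    expect_equal(curve$levels$sem_estimate[i], chunked_sem(x, B),
                 tolerance = 1e-12)
    expect_equal(curve$levels$n_blocks[i], length(x) %/% B)
    expect_equal(curve$levels$block_mean[i], mean(x), tolerance = 1e-9)
  }
  # sem_of_sem convention: sem / sqrt(2 (m - 1))
  m <- curve$levels$n_blocks
  expect_equal(curve$levels$sem_of_sem,
               curve$levels$sem_estimate / sqrt(2 * (m - 1)))
})

test_that("level structure: doubling block sizes, floor(n / 2^k) blocks, odd discards", {
  set.seed(5)
  x <- rnorm(1000)  # not a power of two
  curve <- reblock(x)
  k <- seq_len(nrow(curve$levels)) - 1L
  expect_equal(curve$levels$block_size, 2^k)
  expect_equal(curve$levels$n_blocks, 1000 %/% 2^k)
  expect_true(all(curve$levels$n_blocks >= 2))
  expect_error(reblock(rnorm(3)), "at least 4")
})

test_that("a constant series has zero SEM at every level", {
  curve <- reblock(rep(3.5, 16))
  expect_equal(curve$levels$sem_estimate, rep(0, nrow(curve$levels)))
  expect_equal(curve$selected_sem, 0)
})

test_that("white noise: level-0 SEM near 1/sqrt(n) and no systematic growth", {
  n <- 2^15
  sem0 <- plateau <- numeric(20)
  for (s in 1:20) {
    tr <- gen_trace(ou_params(0, 1, 0, 0.1), n, seed = 1000 + s)
    curve <- reblock(tr$values)
    sem0[s] <- curve$levels$sem_estimate[1]
    # restrict to well-populated levels where estimates are stable
    lv <- curve$levels[curve$levels$n_blocks >= 64, ]
    plateau[s] <- lv$sem_estimate[nrow(lv)]
  }
  expect_lt(abs(mean(sem0) - 1 / sqrt(n)), 0.1 / sqrt(n))
  # for uncorrelated data blocking should not inflate the estimate
  expect_lt(mean(plateau / sem0), 1.1)
  expect_gt(mean(plateau / sem0), 0.9)
})

test_that("AR(1) phi = 0.9: plateau SEM matches the closed form over 50 seeds", {
  n <- 2^15
  phi <- 0.9
  closed_form <- sqrt((1 + phi) / (1 - phi)) / sqrt(n)
  tau <- -0.1 / log(phi)  # dt = 0.1 => exp(-dt/tau) = phi
  sel <- vapply(1:50, function(s) {
    tr <- gen_trace(ou_params(0, 1, tau, 0.1), n, seed = 2000 + s)
    as.numeric(select_sem(reblock(tr$values), "heuristic"))
  }, numeric(1))
  expect_lt(abs(mean(sel) / closed_form - 1), 0.15)
})

test_that("max strategy picks the largest level and never undercuts level 0", {
  # hand-built curve: sem estimates (0.1, 0.2, 0.3, 0.25) -> max is 0.3
  curve <- structure(list(
    n = 16L,
    levels = data.frame(block_size = c(1L, 2L, 4L, 8L),
                        n_blocks = c(16L, 8L, 4L, 2L),
                        block_mean = rep(0, 4),
                        sem_estimate = c(0.1, 0.2, 0.3, 0.25),
                        sem_of_sem = rep(0.01, 4)),
    n_corr = NA_real_, selected_level = NA_integer_,
    selected_sem = NA_real_, strategy = "max"),
    class = "blocking_curve")
  sel <- select_sem(curve, "max")
  expect_equal(as.numeric(sel), 0.3)
  expect_equal(attr(sel, "level"), 3L)
  # property: max rule >= level-0 sem on random data
  for (s in 1:10) {
    set.seed(s)
    curve <- reblock(rnorm(500))
    expect_gte(curve$selected_sem, curve$levels$sem_estimate[1])
  }
})

test_that("heuristic block size is well past the correlation length for AR(1)", {
  n <- 2^15
  tau <- -0.1 / log(0.9)
  B <- vapply(1:50, function(s) {
    curve <- reblock(gen_trace(ou_params(0, 1, tau, 0.1), n,
                               seed = 3000 + s)$values)
    sel <- select_sem(curve, "heuristic")
    curve$levels$block_size[attr(sel, "level")]
  }, numeric(1))
  expect_gte(mean(B >= 8), 0.9)
})

test_that("positively correlated data: SEM grows from level 0 to the plateau", {
  n <- 2^14
  tau <- -0.1 / log(0.9)
  ratio <- vapply(1:50, function(s) {
    curve <- reblock(gen_trace(ou_params(0, 1, tau, 0.1), n,
                               seed = 4000 + s)$values)
    lv <- curve$levels
    plateau <- as.numeric(select_sem(curve, "heuristic"))
    plateau / lv$sem_estimate[1]
  }, numeric(1))
  # statistical inefficiency ~ (1+phi)/(1-phi) = 19 => ratio ~ sqrt(19)
  expect_gt(mean(ratio), 3)
})

test_that("pooled and per-trajectory ensemble SEMs agree in order of magnitude", {
  spec <- small_synth_spec(seed = 21, N = 4096)
  g <- gen_quadruple(spec)
  pooled <- as.numeric(ensemble_sem(g$quadruple$complex))
  pertraj <- ensemble_sem(g$quadruple$complex, mode = "per-trajectory")
  expect_gt(pooled / pertraj, 0.5)
  expect_lt(pooled / pertraj, 2.5)
})
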