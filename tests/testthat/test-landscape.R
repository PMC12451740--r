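ca_topology <- function(n) {
  new_topology(data.frame(name = rep("CA", n), resid = seq_len(n) - 1L, resname = "ALA"))
}

test_that("C-alpha RMSD removes rigid-body motion and matches a brute-force oracle", {
  set.seed(21)
  top <- ca_topology(4)
  a <- matrix(rnorm(12, sd = 3), 4, 3)
  fa <- new_frame(a)
  expect_equal(rmsd_ca(fa, fa, top), 0)
  # rotated + translated copy superposes to zero
  R <- random_rotation()
  fb <- new_frame(sweep(a %*% t(R), 2, c(3, -1, 2), `+`))
  expect_lt(rmsd_ca(fb, fa, top), 1e-6)
  # random deformations: agree with an independent rigid-motion optimizer
  for (k in 1:4) {
    b <- a + matrix(rnorm(12, sd = 0.8), 4, 3)
    expect_equal(rmsd_ca(new_frame(b), fa, top), brute_rmsd(b, a), tolerance = 1e-4)
  }
  expect_error(rmsd_ca(fa, fa, ca_topology(2)), "C-alpha|atoms")
})

test_that("rmsd_ca_traj separates the fixture basins", {
  spec <- small_spec()
  fx <- make_topology(spec)
  tr <- sample_trajectory(spec, "telegraph", fixture = fx, n_frames = 60)
  r <- rmsd_ca_traj(tr, fx$folded)
  lab <- attr(tr, "labels")
  expect_true(all(r$rmsd[lab == "folded"] < 1))
  expect_true(all(r$rmsd[lab == "unfolded"] > 3))
})

test_that("dual-cutoff assignment commits only after a full window", {
  # constant series below the folded cutoff: folded once the window fills
  s <- assign_states_dual_cutoff(rep(1.0, 20), 1.5, 2.5, window = 5 / 1000, dt_ps = 1)
  expect_identical(as.character(s$labels[1:4]), rep("transit", 4))
  expect_true(all(s$labels[5:20] == "folded"))

  # square wave with half-period above the window: one flip per half-period
  x <- rep(c(rep(0.5, 10), rep(3.5, 10)), 4)
  s2 <- assign_states_dual_cutoff(x, 1.5, 2.5, window = 3 / 1000, dt_ps = 1)
  st <- count_transitions(s2)
  expect_equal(st$n_unfolding, 4L)
  expect_equal(st$n_folding, 3L)

  # oscillation strictly between the cutoffs never commits a transition
  x3 <- c(rep(0.5, 5), rep(2.0, 100) + 0.3 * sin(1:100))
  s3 <- assign_states_dual_cutoff(x3, 1.5, 2.5, window = 3 / 1000, dt_ps = 1)
  expect_equal(count_transitions(s3)$n_unfolding, 0L)
  expect_equal(count_transitions(s3)$n_folding, 0L)
  expect_true(all(s3$labels[5:105] == "folded"))  # hysteresis holds the state

  expect_error(assign_states_dual_cutoff(rep(1, 10), 2.5, 1.5, 1), "folded_cut")
  expect_error(assign_states_dual_cutoff(rep(1, 10), 1.5, 2.5, window = 1e-5, dt_ps = 1),
               "window")
})

test_that("hysteretic transition counts never exceed naive single-cutoff crossings", {
  set.seed(77)
  for (k in 1:10) {
    x <- c(rep(0.5, 6), cumsum(rnorm(400, sd = 0.4)) * 0.5 + 2)
    x <- pmax(x, 0)
    s <- assign_states_dual_cutoff(x, 1.5, 2.5, window = 4 / 1000, dt_ps = 1)
    n_dual <- count_transitions(s)$n_folding + count_transitions(s)$n_unfolding
    expect_lte(n_dual, naive_crossings(x, 1.5, 2.5))
  }
})

test_that("transition counting and residence times follow the committed label sequence", {
  s <- states_from_labels(c("unfolded", "unfolded", "folded", "folded", "unfolded", "folded"))
  st <- count_transitions(s)
  expect_equal(st$n_folding, 2L)
  expect_equal(st$n_unfolding, 1L)

  allf <- count_transitions(states_from_labels(rep("folded", 10)))
  expect_equal(allf$n_folding, 0L)
  expect_true(is.na(allf$mean_folding_time_us))
  expect_true(is.na(allf$mean_unfolding_time_us))
  expect_equal(allf$p_folded, 1)
})

test_that("telegraph residence times recover the generating rates", {
  # two-state Markov chain, dt = 1 ns: k_fold = 1/(10 ns), k_unfold = 1/(100 ns)
  set.seed(123)
  n <- 2e5
  a <- 0.1; b <- 0.01
  st <- character(n); st[1] <- "unfolded"
  u <- stats::runif(n)
  for (t in seq_len(n - 1L))
    st[t + 1L] <- if (st[t] == "folded") {
      if (u[t] < b) "unfolded" else "folded"
    } else if (u[t] < a) "folded" else "unfolded"
  res <- count_transitions(states_from_labels(st, dt_ps = 1000))
  expect_equal(res$mean_folding_time_us, 1e-3 / a, tolerance = 0.2)
  expect_equal(res$mean_unfolding_time_us, 1e-3 / b, tolerance = 0.2)
})

test_that("delta_F follows the two-basin population ratio with the documented sign", {
  s <- states_from_labels(rep(c("folded", "unfolded"), 50))
  expect_equal(delta_F(s, 340), 0)
  # ratio e at 340 K: exactly -kB * 340
  nF <- round(exp(1) * 1000)
  s2 <- states_from_labels(c(rep("folded", nF), rep("unfolded", 1000)))
  expect_equal(delta_F(s2, 340), -0.0019872041 * 340 * log(nF / 1000))
  expect_equal(delta_F(s2, 340), -0.6757, tolerance = 1e-3)
  # antisymmetry under basin exchange
  s3 <- states_from_labels(c(rep("unfolded", nF), rep("folded", 1000)))
  expect_equal(delta_F(s3, 340), -delta_F(s2, 340), tolerance = 1e-12)
  expect_error(delta_F(states_from_labels(rep("folded", 5)), 340), "unpopulated")
})

test_that("delta_H partitions the energy with unfolded minus folded sign", {
  lab <- c(rep("folded", 4), rep("unfolded", 4), "transit")
  s <- states_from_labels(lab)
  e <- c(rep(-10, 4), rep(-3, 4), 1e6)  # transit frame must be excluded
  expect_equal(delta_H(e, s), 7.0)
  expect_equal(delta_H(c(rep(2, 4), rep(2, 4), 0), s), 0)
  expect_error(delta_H(e[1:3], s), "aligned")

  # Gaussian basins: recovered within sampling error
  set.seed(99)
  n <- 1e4
  lab2 <- c(rep("folded", n), rep("unfolded", n))
  e2 <- c(rnorm(n, -40, 5), rnorm(n, -35, 5))
  se <- 5 * sqrt(2 / n)
  expect_lt(abs(delta_H(e2, states_from_labels(lab2)) - 5), 3 * se)
})

test_that("FES recovers closed-form bin ratios and respects weight invariances", {
  # uniform over 2 bins
  ts <- new_timeseries(data.frame(s = c(0.25, 0.25, 0.75, 0.75)))
  g <- fes(ts[, "s", drop = FALSE], kT = 1, bins = 2, limits = list(c(0, 1)))
  expect_equal(g$F, c(0, 0))
  # weight ratio e at kT = 1: F = (0, 1)
  g2 <- fes(ts[, "s", drop = FALSE], kT = 1, bins = 2, limits = list(c(0, 1)),
            weights = c(exp(1) / 2, exp(1) / 2, 0.5, 0.5))
  expect_equal(g2$F, c(0, 1), tolerance = 1e-12)
  # multiplying all weights by a constant changes nothing
  g3 <- fes(ts[, "s", drop = FALSE], kT = 1, bins = 2, limits = list(c(0, 1)),
            weights = 17 * c(exp(1) / 2, exp(1) / 2, 0.5, 0.5))
  expect_equal(g3$F, g2$F)
  # empty bins are +Inf, minimum is 0
  ts2 <- new_timeseries(data.frame(s = c(0.1, 0.1, 0.9)))
  g4 <- fes(ts2[, "s", drop = FALSE], kT = 0.6, bins = 4, limits = list(c(0, 1)))
  expect_equal(min(g4$F), 0)
  expect_true(any(is.infinite(g4$F)))
  # errors
  expect_error(fes(ts[, "s", drop = FALSE], kT = -1), "kT")
  expect_error(fes(ts[, "s", drop = FALSE], kT = 1, weights = c(0, 0, 0, 0)), "zero")
  expect_error(fes(ts[, "s", drop = FALSE], kT = 1, weights = 1:2), "length")
})

test_that("2D FES places probability mass in the correct cells", {
  set.seed(42)
  df <- data.frame(a = c(rep(0.2, 300), rep(0.8, 100)),
                   b = c(rep(0.2, 300), rep(0.8, 100)))
  g <- fes(df, kT = 1, bins = 2, limits = list(c(0, 1), c(0, 1)))
  expect_equal(dim(g$F), c(2, 2))
  expect_equal(g$F[1, 1], 0)
  expect_equal(g$F[2, 2], log(3), tolerance = 1e-12)
  expect_true(all(is.infinite(g$F[cbind(c(1, 2), c(2, 1))])))
})

test_that("bias reweighting weights recover an unbiased FES", {
  # flat biased histogram over two states; the bias held a +1 kT potential on
  # state 1, so reweighting must put state 2 lower by exactly 1 kT
  kT <- 0.65
  s <- c(rep(0.25, 500), rep(0.75, 500))       # flat sampled histogram
  V <- ifelse(s < 0.5, 0, kT * 1)
  cv <- new_timeseries(data.frame(s = s, bias = V))
  w <- fes_weights_from_bias(cv, "bias", kT)
  g <- fes(cv[, "s", drop = FALSE], kT = kT, weights = w, bins = 2, limits = list(c(0, 1)))
  expect_equal(g$F, c(kT * 1, 0), tolerance = 1e-12)
})

test_that("replica aggregation reports mean and population spread, flagging holes", {
  r <- replica_stats(c(-1, -2, -3))
  expect_equal(r$mean, -2)
  expect_equal(r$sd, 0.816, tolerance = 1e-3)
  same <- replica_stats(c(1.5, 1.5, 1.5))
  expect_equal(same$sd, 0)
  expect_error(replica_stats(1), "at least 2")

  mk <- function(vals, lim = c(0, 1)) {
    fes(new_timeseries(data.frame(s = vals))[, "s", drop = FALSE],
        kT = 1, bins = 2, limits = list(lim))
  }
  g1 <- mk(c(0.2, 0.2, 0.8)); g2 <- mk(c(0.2, 0.8, 0.8))
  agg <- replica_stats(list(g1, g2))
  expect_equal(agg$n_missing, c(0, 0))
  expect_equal(agg$mean, (g1$F + g2$F) / 2)
  # a bin empty in one replica is flagged, not averaged silently
  g3 <- mk(c(0.2, 0.2, 0.2))
  agg2 <- replica_stats(list(g1, g3))
  expect_equal(agg2$n_missing, c(0, 1))
  expect_true(is.na(agg2$mean[2]))
  expect_error(replica_stats(list(g1, mk(c(0.2, 0.8), lim = c(0, 2)))), "binning")
})

test_that("FES grids serialize as plain-text tables", {
  g <- fes(new_timeseries(data.frame(s = runif(100)))[, "s", drop = FALSE],
           kT = 1, bins = 5, limits = list(c(0, 1)))
  path <- tempfile()
  write_fes(g, path)
  tab <- utils::read.table(path, header = TRUE)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$free_energy, g$F)
})
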