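# Independent oracles and small builders shared across tests.

# Rational switch via the geometric-sum identity
# (1 - x^n) / (1 - x^m) = sum_{k<n} x^k / sum_{k<m} x^k,
# which is total at x = 1 (value n/m) with no special-casing, plus the
# same D_MAX stretching rule the implementation documents.
rational_oracle <- function(r, p) {
  core <- function(x) {
    if (x <= 0) return(1)
    sum(x^(0:(p$n - 1L))) / sum(x^(0:(p$m - 1L)))
  }
  v <- vapply((r - p$d0) / p$r0, core, numeric(1))
  if (is.finite(p$d_max)) {
    s <- core((p$d_max - p$d0) / p$r0)
    v <- (v - s) / (1 - s)
    v[r >= p$d_max] <- 0
    v[v < 0] <- 0
  }
  v
}

# Small solvated fixture used throughout (cheap to sample)
small_spec <- function(...) {
  do.call(fixture_spec, utils::modifyList(list(n_waters = 6L, n_frames = 40L), list(...)))
}

# Random rotation matrix (uniform axis, fixed by the caller's seed)
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotate_frame <- function(frame, R, t = c(0, 0, 0)) {
  ctr <- if (is.null(frame$box)) c(0, 0, 0) else frame$box / 2
  xyz <- sweep(frame$xyz, 2, ctr)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, ctr + t, `+`)
  new_frame(xyz, box = frame$box, time = frame$time)
}

frame_to_traj <- function(frame, top) {
  new_trajectory(top, array(frame$xyz, dim = c(nrow(frame$xyz), 3, 1)),
                 time = frame$time,
                 box = if (is.null(frame$box)) NULL else matrix(frame$box, 1, 3))
}

# Swap two whole water molecules (3 atoms each) in a frame
swap_waters <- function(frame, top, w1, w2) {
  wo <- which(top$atoms$is_water & top$atoms$element == "O")
  r1 <- wo[w1] + 0:2; r2 <- wo[w2] + 0:2
  xyz <- frame$xyz
  tmp <- xyz[r1, ]; xyz[r1, ] <- xyz[r2, ]; xyz[r2, ] <- tmp
  new_frame(xyz, box = frame$box, time = frame$time)
}

# Brute-force minimal RMSD: numerical optimization over rigid motions
# (independent of the Kabsch route), with multiple restarts.
brute_rmsd <- function(a, b) {
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1]); cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rx %*% Ry %*% Rz
  }
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  obj <- function(ang) sqrt(mean(rowSums((ac %*% t(rot(ang)) - bc)^2)))
  best <- Inf
  for (s in 1:12) {
    st <- stats::runif(3, 0, 2 * pi)
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# Build an fcv_states object directly from labels (for estimator tests)
states_from_labels <- function(labels, dt_ps = 1) {
  structure(list(
    labels = factor(labels, levels = c("folded", "unfolded", "transit")),
    time = dt_ps * (seq_along(labels) - 1),
    folded_cut = 1.5, unfolded_cut = 2.5, window = 1e-3 * dt_ps,
    rmsd = rep(NA_real_, length(labels))
  ), class = "fcv_states")
}

# Naive single-cutoff crossing counter (midpoint of the two cutoffs)
naive_crossings <- function(x, folded_cut, unfolded_cut) {
  lab <- x > (folded_cut + unfolded_cut) / 2
  sum(lab[-1] != lab[-length(lab)])
}
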