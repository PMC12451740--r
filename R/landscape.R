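#' C-alpha RMSD after optimal superposition
#'
#' Minimal root-mean-square deviation over C-alpha atoms after optimal
#' rigid-body (Kabsch) superposition, the discriminant used for basin
#' assignment.  Superposition and RMSD are computed with bio3d.
#'
#' @param frame,reference `fcv_frame`s over the same topology.
#' @param top The `fcv_topology` (at least 3 C-alpha atoms).
#' @return RMSD in Angstrom.
#' @export
rmsd_ca <- function(frame, reference, top) {
  .check_frame(frame, top); .check_frame(reference, top)
  ca <- which(top$atoms$is_protein & top$atoms$name == "CA")
  if (length(ca) < 3L)
    .stopf("need at least 3 C-alpha atoms for superposition (found %d)", length(ca))
  a <- as.vector(t(frame$xyz[ca, , drop = FALSE]))
  b <- as.vector(t(reference$xyz[ca, , drop = FALSE]))
  .rmsd_fit(a, b, length(ca))
}

## Kabsch superposition via bio3d::fit.xyz, RMSD from the fitted coordinates
## (bio3d::rmsd rounds to 3 decimals, too coarse for tight numerical checks)
.rmsd_fit <- function(a, b, n_atoms) {
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = b, mobile = a))
  sqrt(sum((as.numeric(fitted) - b)^2) / n_atoms)
}

#' C-alpha RMSD time series of a trajectory
#'
#' @param traj An `fcv_trajectory`.
#' @param reference Reference `fcv_frame`.
#' @return An `fcv_timeseries` with columns `time` (ps) and `rmsd`
#'   (Angstrom).
#' @export
rmsd_ca_traj <- function(traj, reference) {
  top <- traj$topology
  ca <- which(top$atoms$is_protein & top$atoms$name == "CA")
  if (length(ca) < 3L)
    .stopf("need at least 3 C-alpha atoms for superposition (found %d)", length(ca))
  b <- as.vector(t(reference$xyz[ca, , drop = FALSE]))
  nf <- n_frames(traj)
  r <- vapply(seq_len(nf), function(i) {
    a <- as.vector(t(traj$coords[ca, , i]))
    .rmsd_fit(a, b, length(ca))
  }, numeric(1))
  new_timeseries(data.frame(time = traj$time, rmsd = r))
}

#' Hysteretic dual-cutoff state assignment
#'
#' Two-threshold assignment with a minimum dwell window: the state flips
#' to folded only once the RMSD has stayed at or below `folded_cut` for a
#' full time window, and to unfolded only once it has stayed at or above
#' `unfolded_cut` for a full window.  Frames between flips inherit the
#' current state; frames before the first commitment are labelled
#' `transit`.  The hysteresis suppresses spurious recrossings when
#' counting folding transitions.
#'
#' @param rmsd An `fcv_timeseries` with columns `time` (ps) and a value
#'   column (first non-time column), or a numeric vector (then `dt_ps`
#'   gives the frame spacing).
#' @param folded_cut,unfolded_cut Cutoffs in Angstrom,
#'   `folded_cut < unfolded_cut` (e.g. 1.5 / 2.5 for a beta-hairpin
#'   mini-protein, 4.0 / 6.0 for a 20-residue three-helix one).
#' @param window Minimum dwell window in ns (e.g. 10).
#' @param dt_ps Frame spacing when `rmsd` is a bare vector.
#' @return An object of class `fcv_states`: per-frame labels in
#'   `{folded, unfolded, transit}` plus the generating parameters.
#' @export
assign_states_dual_cutoff <- function(rmsd, folded_cut, unfolded_cut, window,
                                      dt_ps = NULL) {
  if (inherits(rmsd, "fcv_timeseries") || is.data.frame(rmsd)) {
    tm <- rmsd$time
    vcol <- setdiff(names(rmsd), "time")[1]
    x <- rmsd[[vcol]]
  } else {
    x <- as.numeric(rmsd)
    if (is.null(dt_ps)) dt_ps <- 1
    tm <- dt_ps * (seq_along(x) - 1)
  }
  if (!(folded_cut < unfolded_cut)) .stopf("folded_cut must be below unfolded_cut")
  nf <- length(x)
  dt <- if (nf > 1) tm[2] - tm[1] else 1
  w <- as.integer(round(window * 1000 / dt))  # ns -> frames
  if (w < 1L) .stopf("window (%g ns) is shorter than the frame stride (%g ps)", window, dt)
  if (w > nf) .stopf("window (%d frames) exceeds the series length (%d)", w, nf)

  ## rolling "all of the trailing w frames satisfy the cutoff"
  roll_all <- function(ok) {
    cs <- cumsum(ok)
    res <- logical(nf)
    res[w:nf] <- (cs[w:nf] - c(0, cs)[(w:nf) - w + 1L]) == w
    res
  }
  okF <- roll_all(x <= folded_cut)
  okU <- roll_all(x >= unfolded_cut)

  lab <- character(nf)
  cur <- "transit"
  for (t in seq_len(nf)) {
    if (okF[t]) cur <- "folded" else if (okU[t]) cur <- "unfolded"
    lab[t] <- cur
  }
  structure(list(
    labels = factor(lab, levels = c("folded", "unfolded", "transit")),
    time = tm, folded_cut = folded_cut, unfolded_cut = unfolded_cut,
    window = window, rmsd = x
  ), class = "fcv_states")
}

#' @export
print.fcv_states <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<fcv_states> %d frames: %d folded, %d unfolded, %d transit (cutoffs %g/%g A, window %g ns)\n",
              length(x$labels), tb[["folded"]], tb[["unfolded"]], tb[["transit"]],
              x$folded_cut, x$unfolded_cut, x$window))
  invisible(x)
}

#' Count folding/unfolding transitions and residence times
#'
#' A folding transition is an unfolded-to-folded flip of the committed
#' state, an unfolding transition the reverse.  The mean folding time is
#' the mean duration of the unfolded residence segments that end in a
#' folding flip (and symmetrically for unfolding).  Zero observed
#' transitions of a kind leave the corresponding time `NA` (absent), not
#' zero.  Basin populations exclude transit frames.
#'
#' @param s An `fcv_states` from [assign_states_dual_cutoff()].
#' @return A list of class `fcv_basinstats`: `n_folding`, `n_unfolding`,
#'   `mean_folding_time_us`, `mean_unfolding_time_us`, `p_folded`,
#'   `p_unfolded` (fractions of all frames).
#' @export
count_transitions <- function(s) {
  stopifnot(inherits(s, "fcv_states"))
  lab <- as.character(s$labels)
  committed <- which(lab != "transit")
  if (length(committed) == 0L) .stopf("state series has no committed frames")
  dt <- if (length(s$time) > 1) s$time[2] - s$time[1] else 1
  runs <- rle(lab[committed])
  v <- runs$values; len <- runs$lengths
  n_fold <- 0L; n_unfold <- 0L
  fold_dwell <- numeric(0); unfold_dwell <- numeric(0)
  if (length(v) > 1L) {
    for (k in seq_len(length(v) - 1L)) {
      if (v[k] == "unfolded" && v[k + 1L] == "folded") {
        n_fold <- n_fold + 1L
        fold_dwell <- c(fold_dwell, len[k] * dt)
      } else if (v[k] == "folded" && v[k + 1L] == "unfolded") {
        n_unfold <- n_unfold + 1L
        unfold_dwell <- c(unfold_dwell, len[k] * dt)
      }
    }
  }
  structure(list(
    n_folding = n_fold, n_unfolding = n_unfold,
    mean_folding_time_us = if (n_fold > 0L) mean(fold_dwell) / 1e6 else NA_real_,
    mean_unfolding_time_us = if (n_unfold > 0L) mean(unfold_dwell) / 1e6 else NA_real_,
    p_folded = mean(lab == "folded"), p_unfolded = mean(lab == "unfolded")
  ), class = "fcv_basinstats")
}

#' @export
print.fcv_basinstats <- function(x, ...) {
  cat(sprintf("<fcv_basinstats> %d folding / %d unfolding transitions; mean folding %s us, unfolding %s us; P(folded)=%.3f\n",
              x$n_folding, x$n_unfolding,
              ifelse(is.na(x$mean_folding_time_us), "--", sprintf("%.3g", x$mean_folding_time_us)),
              ifelse(is.na(x$mean_unfolding_time_us), "--", sprintf("%.3g", x$mean_unfolding_time_us)),
              x$p_folded))
  invisible(x)
}

#' Folding free-energy difference from basin populations
#'
#' `delta_F = -kB T log(P_folded / P_unfolded)` with
#' `kB = 0.0019872041 kcal/(mol K)`; negative values mean the folded
#' basin is favoured.  Transit frames are excluded from both populations.
#'
#' @param s An `fcv_states`.
#' @param T Temperature in K.
#' @return Free-energy difference in kcal/mol.
#' @export
delta_F <- function(s, T) {
  stopifnot(inherits(s, "fcv_states"))
  lab <- as.character(s$labels)
  nF <- sum(lab == "folded"); nU <- sum(lab == "unfolded")
  if (nF == 0L || nU == 0L)
    .stopf("delta_F is undefined: the %s basin is unpopulated",
           if (nF == 0L) "folded" else "unfolded")
  -.kB * T * log(nF / nU)
}

#' Enthalpy difference from energy partitioning
#'
#' Partitions a per-frame total-energy series into the folded and
#' unfolded basins of a state series and returns
#' `delta_H = <E>_unfolded - <E>_folded` (kcal/mol): positive when the
#' unfolded basin is higher in energy.  Transit frames are excluded.
#'
#' @param energy An `fcv_timeseries` whose first non-time column is the
#'   energy (kcal/mol), or a numeric vector aligned frame-by-frame with
#'   the labels.
#' @param s An `fcv_states` of the same length.
#' @return Enthalpy difference in kcal/mol.
#' @export
delta_H <- function(energy, s) {
  stopifnot(inherits(s, "fcv_states"))
  e <- if (is.data.frame(energy)) energy[[setdiff(names(energy), "time")[1]]] else as.numeric(energy)
  if (length(e) != length(s$labels))
    .stopf("energy series (%d) and state series (%d) are not aligned", length(e), length(s$labels))
  lab <- as.character(s$labels)
  if (!any(lab == "folded") || !any(lab == "unfolded"))
    .stopf("delta_H requires both basins to be populated")
  mean(e[lab == "unfolded"]) - mean(e[lab == "folded"])
}

#' Binned free-energy surface over one or two CVs
#'
#' `F(bin) = -kT log(sum of weights in bin / sum of all weights)`,
#' shifted so the global minimum is 0.  Empty bins carry `+Inf`.
#' Unbiased samples use unit weights; for samples from a biased run,
#' supply `weights = exp(V_bias / kT)` (see [fes_weights_from_bias()]).
#'
#' @param series An `fcv_timeseries` (or data frame); all non-`time`
#'   columns (1 or 2) are the CV axes.
#' @param kT Thermal energy in kcal/mol (> 0).
#' @param weights Per-frame non-negative weights; default unit.
#' @param bins Number of bins per axis (default 50).
#' @param limits Optional list of per-axis `c(min, max)`; default the
#'   observed range.
#' @return An object of class `fcv_fes`: axis names, bin edges and
#'   centers, free energy (vector or matrix, kcal/mol), and `kT`.
#' @export
fes <- function(series, kT, weights = NULL, bins = 50, limits = NULL) {
  if (kT <= 0) .stopf("kT must be positive")
  df <- as.data.frame(series)
  cvs <- setdiff(names(df), "time")
  if (!(length(cvs) %in% 1:2)) .stopf("fes needs 1 or 2 CV columns (got %d)", length(cvs))
  n <- nrow(df)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) .stopf("weights length (%d) does not match series (%d)", length(weights), n)
  if (any(weights < 0)) .stopf("weights must be non-negative")
  if (sum(weights) <= 0) .stopf("all weights are zero")

  edges <- lapply(seq_along(cvs), function(k) {
    r <- if (!is.null(limits)) limits[[k]] else range(df[[cvs[k]]])
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  })
  idx <- lapply(seq_along(cvs), function(k) {
    i <- findInterval(df[[cvs[k]]], edges[[k]], rightmost.closed = TRUE)
    pmin(pmax(i, 1L), bins)
  })
  if (length(cvs) == 1L) {
    wsum <- vapply(seq_len(bins), function(b) sum(weights[idx[[1]] == b]), numeric(1))
  } else {
    wsum <- matrix(0, bins, bins)
    for (r in seq_len(n)) wsum[idx[[1]][r], idx[[2]][r]] <- wsum[idx[[1]][r], idx[[2]][r]] + weights[r]
  }
  Fv <- -kT * log(wsum / sum(weights))
  Fv <- Fv - min(Fv[is.finite(Fv)])
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(cv_names = cvs, edges = edges, centers = centers, F = Fv, kT = kT),
            class = "fcv_fes")
}

#' Reweighting factors from a bias column
#'
#' For configurations sampled under a (quasi-static) bias potential
#' `V(s)`, the unbiased distribution is recovered with per-frame weights
#' `exp(V / kT)`.
#'
#' @param colvar An `fcv_timeseries` (e.g. from [read_colvar()]).
#' @param bias_col Name of the bias column (kcal/mol).
#' @param kT Thermal energy in kcal/mol.
#' @return Numeric weight vector.
#' @export
fes_weights_from_bias <- function(colvar, bias_col, kT) {
  if (!bias_col %in% names(colvar)) .stopf("no column '%s' in COLVAR series", bias_col)
  v <- colvar[[bias_col]]
  exp((v - max(v)) / kT)  # shifted for numerical stability; FES is shift-invariant
}

#' @export
print.fcv_fes <- function(x, ...) {
  cat(sprintf("<fcv_fes> %s, %s bins, kT = %g kcal/mol, barrier range 0..%.3g\n",
              paste(x$cv_names, collapse = " x "),
              paste(lengths(x$centers), collapse = " x "), x$kT,
              max(x$F[is.finite(x$F)])))
  invisible(x)
}

#' @export
plot.fcv_fes <- function(x, ...) {
  if (length(x$cv_names) == 1L) {
    graphics::plot(x$centers[[1]], x$F, type = "l", xlab = x$cv_names[1],
                   ylab = "F [kcal/mol]", ...)
  } else {
    Fc <- x$F; Fc[!is.finite(Fc)] <- NA
    graphics::image(x$centers[[1]], x$centers[[2]], Fc, xlab = x$cv_names[1],
                    ylab = x$cv_names[2], col = grDevices::hcl.colors(64, "viridis"), ...)
    graphics::contour(x$centers[[1]], x$centers[[2]], Fc, add = TRUE, col = "grey20")
  }
  invisible(x)
}

#' Mean and standard deviation over replica estimates
#'
#' Aggregates independent replica estimates the way multi-replica
#' free-energy protocols report them: element-wise mean and population
#' standard deviation.  For FES grids, bins that are empty (infinite) in
#' any replica are flagged in `$n_missing` and returned as `NA` rather
#' than averaged silently.
#'
#' @param estimates A numeric vector / list of scalars, or a list of
#'   compatible `fcv_fes` grids.
#' @return For scalars, a list with `mean` and `sd`; for grids, a list of
#'   class `fcv_replica_fes` with `mean`, `sd`, `n_missing` and the grid
#'   axes.
#' @export
replica_stats <- function(estimates) {
  if (is.numeric(estimates)) estimates <- as.list(estimates)
  if (length(estimates) < 2L) .stopf("replica_stats needs at least 2 replicas")
  popsd <- function(v) sqrt(mean((v - mean(v))^2))
  if (is.numeric(estimates[[1]])) {
    v <- vapply(estimates, as.numeric, numeric(1))
    return(list(mean = mean(v), sd = popsd(v)))
  }
  stopifnot(all(vapply(estimates, inherits, logical(1), "fcv_fes")))
  e1 <- estimates[[1]]
  for (e in estimates[-1]) {
    if (!identical(lapply(e$edges, round, 10), lapply(e1$edges, round, 10)))
      .stopf("replica FES grids have incompatible binning")
  }
  arr <- simplify2array(lapply(estimates, function(e) { f <- e$F; f[!is.finite(f)] <- NA; f }))
  nd <- length(dim(arr))
  mu <- apply(arr, seq_len(nd - 1L), mean)
  sdv <- apply(arr, seq_len(nd - 1L), popsd)
  miss <- apply(arr, seq_len(nd - 1L), function(v) sum(is.na(v)))
  mu[miss > 0] <- NA; sdv[miss > 0] <- NA
  structure(list(mean = mu, sd = sdv, n_missing = miss,
                 cv_names = e1$cv_names, edges = e1$edges, centers = e1$centers,
                 kT = e1$kT),
            class = "fcv_replica_fes")
}

#' Write a 1D or 2D FES grid as a plain-text table
#'
#' Columns: bin centers and free energy, `Inf` for empty bins.
#'
#' @param x An `fcv_fes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fes <- function(x, path) {
  stopifnot(inherits(x, "fcv_fes"))
  if (length(x$cv_names) == 1L) {
    df <- data.frame(x$centers[[1]], x$F)
    names(df) <- c(x$cv_names, "free_energy")
  } else {
    g <- expand.grid(i = seq_along(x$centers[[1]]), j = seq_along(x$centers[[2]]))
    df <- data.frame(x$centers[[1]][g$i], x$centers[[2]][g$j], x$F[cbind(g$i, g$j)])
    names(df) <- c(x$cv_names, "free_energy")
  }
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
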