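#' Build folding collective variables from two end-state trajectories
#'
#' The main entry point of the package: runs the full bottom-up workflow.
#' Candidate hydrogen-bond and side-chain contacts are harvested from a
#' short unbiased folded-basin trajectory and a short unbiased
#' unfolded-basin trajectory ([harvest_contacts()]), classified native /
#' non-native by basin occupancy, scored with a per-feature Fisher
#' (LDA-like) discriminant, filtered ([filter_features()]), and assembled
#' into the two CVs ([assemble_cvs()]): `sHB`, the hydrogen-bond CV with
#' angular and protein-water / protein-protein competition terms, and
#' `sSC`, the side-chain packing CV.  Native features carry coefficient
#' +1, non-native features -1.
#'
#' @param folded,unfolded `fcv_trajectory` objects sharing one topology.
#' @param config An [harvest_config()].
#' @param score_threshold Minimum Fisher score for retention (default 1).
#' @param max_features Optional cap on retained features.
#' @return An object of class `fold_cv` with components `features` (the
#'   [feature_set()]), `cvs` (list with `sHB`, `sSC`), `candidates` (the
#'   full harvest table) and `call`.  Methods: [print.fold_cv()],
#'   [summary.fold_cv()], [coef.fold_cv()], [predict.fold_cv()],
#'   [plot.fold_cv()].
#' @export
#' @examples
#' spec <- fixture_spec(n_waters = 6, n_frames = 40)
#' fit <- fold_cv(sample_trajectory(spec, "folded"),
#'                sample_trajectory(spec, "unfolded"))
#' fit
#' head(predict(fit, sample_trajectory(spec, "folded", n_frames = 5)))
fold_cv <- function(folded, unfolded, config = harvest_config(),
                    score_threshold = 1, max_features = Inf) {
  cand <- harvest_contacts(folded, unfolded, config)
  fs <- filter_features(cand, score_threshold = score_threshold,
                        max_features = max_features)
  cvs <- assemble_cvs(fs)
  structure(list(features = fs, cvs = cvs, candidates = cand,
                 topology = fs$topology, config = config,
                 call = match.call()),
            class = "fold_cv")
}

#' @export
print.fold_cv <- function(x, ...) {
  fs <- x$features
  cat("Bottom-up folding collective variables\n")
  cat(sprintf("  sHB: %d native (+1), %d non-native (-1) hydrogen-bond features\n",
              length(fs$hb_native), length(fs$hb_nonnative)))
  cat(sprintf("  sSC: %d native (+1), %d non-native (-1) side-chain features\n",
              length(fs$sc_native), length(fs$sc_nonnative)))
  cat(sprintf("  %d candidates harvested, %d retained (Fisher score >= %.3g)\n",
              nrow(x$candidates), nrow(fs$table), min(fs$table$score)))
  invisible(x)
}

#' Summarize a fitted fold_cv object
#'
#' @param object A `fold_cv`.
#' @param ... Unused.
#' @return A data frame (invisible component of the printed summary) with
#'   one row per retained feature: id, type, class, occupancies and
#'   Fisher score.
#' @export
summary.fold_cv <- function(object, ...) {
  tab <- object$features$table[, c("id", "type", "class", "occ_folded",
                                   "occ_unfolded", "score")]
  structure(list(features = tab, n_candidates = nrow(object$candidates),
                 hash = feature_set_hash(object$features)),
            class = "summary.fold_cv")
}

#' @export
print.summary.fold_cv <- function(x, ...) {
  cat(sprintf("Retained features (%d of %d candidates), provenance %s\n",
              nrow(x$features), x$n_candidates, substr(x$hash, 1, 8)))
  print(x$features, digits = 3)
  invisible(x)
}

#' Feature coefficients of the fitted CVs
#'
#' @param object A `fold_cv`.
#' @param ... Unused.
#' @return Named numeric vector: +1 for native features, -1 for
#'   non-native, named by feature id.
#' @export
coef.fold_cv <- function(object, ...) {
  fs <- object$features
  ids <- vapply(c(fs$hb_native, fs$sc_native, fs$hb_nonnative, fs$sc_nonnative),
                function(f) f$id, character(1))
  stats::setNames(c(rep(1, length(fs$hb_native) + length(fs$sc_native)),
                    rep(-1, length(fs$hb_nonnative) + length(fs$sc_nonnative))), ids)
}

#' Evaluate the fitted CVs on a trajectory
#'
#' @param object A `fold_cv`.
#' @param newdata An `fcv_trajectory` over the same topology.
#' @param ablation Ablation mode applied to both CVs (see [ablate()]).
#' @param ... Unused.
#' @return An `fcv_timeseries` with columns `time`, `sHB`, `sSC`.
#' @export
predict.fold_cv <- function(object, newdata, ablation = "full", ...) {
  stopifnot(inherits(newdata, "fcv_trajectory"))
  if (!identical(newdata$topology$atoms, object$topology$atoms))
    .stopf("topology mismatch: trajectory atoms differ from the fitted topology")
  shb <- evaluate_cv(ablate(object$cvs$sHB, ablation), newdata)
  ssc <- evaluate_cv(ablate(object$cvs$sSC, ablation), newdata)
  out <- data.frame(time = shb$time, sHB = shb$sHB, sSC = ssc$sSC)
  new_timeseries(out)
}

#' Plot the Fisher-score spectrum of a fitted fold_cv
#'
#' Scores of the retained features by rank, split by feature type and
#' native / non-native class, with the retention threshold implied by the
#' lowest retained score.
#'
#' @param x A `fold_cv`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fold_cv <- function(x, ...) {
  tab <- x$features$table
  col <- ifelse(tab$class == "native", "#2166ac", "#b2182b")
  pch <- ifelse(tab$type == "hb", 19, 17)
  graphics::plot(seq_len(nrow(tab)), tab$score, log = "y", col = col, pch = pch,
                 xlab = "feature rank", ylab = "Fisher score", ...)
  graphics::legend("topright",
                   legend = c("native HB", "non-native HB", "native SC", "non-native SC"),
                   col = c("#2166ac", "#b2182b", "#2166ac", "#b2182b"),
                   pch = c(19, 19, 17, 17), bty = "n")
  invisible(x)
}

#' Emit the PLUMED input of a fitted fold_cv
#'
#' Convenience wrapper around [write_plumed()] using the fitted CVs and
#' topology.
#'
#' @param object A `fold_cv`.
#' @param path Output path.
#' @param ablation Ablation mode (see [ablate()]).
#' @param ... Passed to [write_plumed()].
#' @return `path`, invisibly.
#' @export
write_plumed_input <- function(object, path, ablation = "full", ...) {
  stopifnot(inherits(object, "fold_cv"))
  cvs <- list(sHB = ablate(object$cvs$sHB, ablation),
              sSC = ablate(object$cvs$sSC, ablation))
  write_plumed(cvs, object$topology, path, ...)
}
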