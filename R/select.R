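#' Configuration for contact harvesting and feature construction
#'
#' All thresholds of the bottom-up workflow in one place, recorded in the
#' provenance of every [feature_set()] built from it.
#'
#' @param hb_switch,ang_switch,water_switch,sc_switch Switch parameters for
#'   the hydrogen-bond distance, angular, water-competition and side-chain
#'   terms.
#' @param theta_F Minimum folded-basin occupancy for a native candidate
#'   (default 0.6).
#' @param theta_U Minimum unfolded-basin occupancy for a non-native
#'   candidate (default 0.25).
#' @param theta_F_max Maximum folded-basin occupancy a non-native candidate
#'   may have (default 0.1).
#' @param occupancy_cut A contact is "formed" in a frame when its raw
#'   switch value exceeds this (default 0.5), so harvesting and evaluation
#'   share one geometry definition.
#' @param min_sep Minimum residue separation for candidate pairs
#'   (default 2).
#' @param comp_dist,comp_frac,comp_max Competing protein acceptors attached
#'   to a native hydrogen-bond feature are acceptors within `comp_dist`
#'   Angstrom of the donor in at least `comp_frac` of unfolded-basin
#'   frames, capped at the `comp_max` most frequent (defaults 6 Angstrom,
#'   0.05, 4).
#' @param lambda_w,lambda_p Weights of the water / protein competition
#'   terms (default 1).
#' @param stride Use every `stride`-th frame of the end-state trajectories
#'   (default 1 = all frames).
#' @param epsilon Variance regularizer of the Fisher score (default 1e-6).
#' @return A list of class `fcv_config`.
#' @export
harvest_config <- function(hb_switch = hb_switch_params(),
                           ang_switch = angular_params(),
                           water_switch = water_switch_params(),
                           sc_switch = sc_switch_params(),
                           theta_F = 0.6, theta_U = 0.25, theta_F_max = 0.1,
                           occupancy_cut = 0.5, min_sep = 2L,
                           comp_dist = 6.0, comp_frac = 0.05, comp_max = 4L,
                           lambda_w = 1, lambda_p = 1, stride = 1L,
                           epsilon = 1e-6) {
  structure(list(
    hb_switch = hb_switch, ang_switch = ang_switch, water_switch = water_switch,
    sc_switch = sc_switch, theta_F = theta_F, theta_U = theta_U,
    theta_F_max = theta_F_max, occupancy_cut = occupancy_cut,
    min_sep = as.integer(min_sep), comp_dist = comp_dist, comp_frac = comp_frac,
    comp_max = as.integer(comp_max), lambda_w = lambda_w, lambda_p = lambda_p,
    stride = as.integer(stride), epsilon = epsilon
  ), class = "fcv_config")
}

## every stride-th frame of a trajectory
.stride_traj <- function(traj, stride) {
  if (stride <= 1L) return(traj)
  keep <- seq(1L, n_frames(traj), by = stride)
  new_trajectory(traj$topology, traj$coords[, , keep, drop = FALSE],
                 time = traj$time[keep],
                 box = if (is.null(traj$box)) NULL else traj$box[keep, , drop = FALSE])
}

#' Harvest candidate contacts from the two end-state trajectories
#'
#' Enumerates all hydrogen-bond (donor-H, acceptor) and side-chain residue
#' pairs with the configured sequence separation, evaluates their raw
#' switch value on every (strided) frame of both trajectories, and
#' classifies each contact: native if its folded-basin occupancy (fraction
#' of frames with value > `occupancy_cut`) is at least `theta_F`;
#' non-native if its unfolded-basin occupancy is at least `theta_U` and its
#' folded occupancy at most `theta_F_max`.  Contacts formed in neither
#' basin are absent from the table.
#'
#' @param folded,unfolded `fcv_trajectory` objects sharing one topology:
#'   a short unbiased run in the folded basin and one in the unfolded
#'   basin.
#' @param config An [harvest_config()].
#' @return A data frame of class `fcv_candidates`, one row per classified
#'   candidate, with occupancy and per-basin mean/variance columns.  The
#'   topology, configuration, per-donor competitor lists and provenance are
#'   attached as attributes.
#' @export
harvest_contacts <- function(folded, unfolded, config = harvest_config()) {
  stopifnot(inherits(folded, "fcv_trajectory"), inherits(unfolded, "fcv_trajectory"))
  if (n_frames(folded) == 0L || n_frames(unfolded) == 0L)
    .stopf("end-state trajectories must contain at least one frame")
  if (!identical(folded$topology$atoms, unfolded$topology$atoms))
    .stopf("folded and unfolded trajectories do not share a topology")
  top <- folded$topology
  fT <- .stride_traj(folded, config$stride)
  uT <- .stride_traj(unfolded, config$stride)

  da <- identify_donors_acceptors(top, get_frame(fT, 1))
  a <- top$atoms
  rows <- list()
  popvar <- function(v) mean((v - mean(v))^2)

  ## ---- hydrogen-bond candidates ----
  if (nrow(da$donors) > 0L && length(da$acceptors) > 0L) {
    for (di in seq_len(nrow(da$donors))) {
      dheavy <- da$donors$heavy[di]; dh <- da$donors$hydrogen[di]
      for (acc in da$acceptors) {
        if (acc == dheavy) next
        if (abs(a$resid[acc + 1L] - a$resid[dheavy + 1L]) < config$min_sep) next
        fstub <- structure(list(
          donor = dheavy, hydrogen = dh, acceptor = acc, kind = "non-native",
          dist_switch = config$hb_switch, ang_switch = config$ang_switch
        ), class = "fcv_hbond_feature")  # bare switch (no competition) for harvesting
        vf <- .eval_hb_frames(fstub, fT)
        vu <- .eval_hb_frames(fstub, uT)
        id <- sprintf("hb:%06d-%06d-%06d", dheavy, dh, acc)
        cls <- .classify(vf, vu, config)
        if (is.na(cls)) next
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, type = "hb", class = cls,
          donor = dheavy, hydrogen = dh, acceptor = acc,
          res_i = NA_integer_, res_j = NA_integer_,
          occ_folded = mean(vf > config$occupancy_cut),
          occ_unfolded = mean(vu > config$occupancy_cut),
          mean_folded = mean(vf), var_folded = popvar(vf),
          mean_unfolded = mean(vu), var_unfolded = popvar(vu),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  ## ---- side-chain candidates ----
  pres <- sort(unique(a$resid[a$is_protein]))
  if (length(pres) >= 2L) {
    for (ii in seq_along(pres)) for (jj in seq_along(pres)) {
      if (jj <= ii) next
      i <- pres[ii]; j <- pres[jj]
      if (abs(i - j) < config$min_sep) next
      f <- sc_feature(top, i, j, kind = "native", params = config$sc_switch,
                      min_sep = config$min_sep)
      vf <- .eval_sc_frames(f, fT)
      vu <- .eval_sc_frames(f, uT)
      cls <- .classify(vf, vu, config)
      if (is.na(cls)) next
      id <- sprintf("sc:%04d-%04d", i, j)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, type = "sc", class = cls,
        donor = NA_integer_, hydrogen = NA_integer_, acceptor = NA_integer_,
        res_i = i, res_j = j,
        occ_folded = mean(vf > config$occupancy_cut),
        occ_unfolded = mean(vu > config$occupancy_cut),
        mean_folded = mean(vf), var_folded = popvar(vf),
        mean_unfolded = mean(vu), var_unfolded = popvar(vu),
        stringsAsFactors = FALSE
      )
    }
  }

  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), type = character(0), class = character(0),
               donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
               res_i = integer(0), res_j = integer(0),
               occ_folded = numeric(0), occ_unfolded = numeric(0),
               mean_folded = numeric(0), var_folded = numeric(0),
               mean_unfolded = numeric(0), var_unfolded = numeric(0))
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL

  attr(tab, "topology") <- top
  attr(tab, "config") <- config
  attr(tab, "competitors") <- .competitor_map(da, uT, config)
  attr(tab, "provenance") <- list(
    folded = attr(folded, "source") %||% "<in-memory trajectory>",
    unfolded = attr(unfolded, "source") %||% "<in-memory trajectory>",
    n_frames_folded = n_frames(fT), n_frames_unfolded = n_frames(uT)
  )
  class(tab) <- c("fcv_candidates", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.classify <- function(vf, vu, config) {
  occ_f <- mean(vf > config$occupancy_cut)
  occ_u <- mean(vu > config$occupancy_cut)
  if (occ_f >= config$theta_F) return("native")
  if (occ_u >= config$theta_U && occ_f <= config$theta_F_max) return("non-native")
  NA_character_
}

## For each donor heavy atom: acceptors (at the configured sequence
## separation) within comp_dist of the donor in >= comp_frac of
## unfolded-basin frames, ranked by that fraction, capped at comp_max.
.competitor_map <- function(da, unfolded, config) {
  top <- unfolded$topology
  a <- top$atoms
  out <- list()
  if (nrow(da$donors) == 0L) return(out)
  for (dheavy in unique(da$donors$heavy)) {
    D <- .atom_series(unfolded, dheavy)
    frac <- vapply(da$acceptors, function(acc) {
      if (acc == dheavy) return(0)
      if (abs(a$resid[acc + 1L] - a$resid[dheavy + 1L]) < config$min_sep) return(0)
      mean(.pbc_dist_frames(D, .atom_series(unfolded, acc), unfolded$box) <= config$comp_dist)
    }, numeric(1))
    keep <- which(frac >= config$comp_frac)
    keep <- keep[order(-frac[keep], da$acceptors[keep])]
    out[[as.character(dheavy)]] <- da$acceptors[utils::head(keep, config$comp_max + 1L)]
    ## one extra is kept so the cap still holds after the native acceptor
    ## of a given feature is removed from its own competitor list
  }
  out
}

#' Fisher (LDA-like) discriminant score of one feature
#'
#' `score = (mu_F - mu_U)^2 / (sigma_F^2 + sigma_U^2 + epsilon)` with
#' population variances and a small regularizer so that degenerate
#' (zero-variance) features stay finite.  Symmetric under exchange of the
#' two basins, and invariant under a common rescaling of all values.  This
#' is the two-class Fisher discriminant ratio, i.e. a per-feature
#' realization of a linear-discriminant-analysis filter.
#'
#' @param values_folded,values_unfolded Non-empty numeric samples of the
#'   feature in the two basins.
#' @param epsilon Variance regularizer (default 1e-6).
#' @return Non-negative scalar.
#' @export
fisher_score <- function(values_folded, values_unfolded, epsilon = 1e-6) {
  if (length(values_folded) == 0L || length(values_unfolded) == 0L)
    .stopf("fisher_score requires non-empty samples in both basins")
  vf <- mean((values_folded - mean(values_folded))^2)
  vu <- mean((values_unfolded - mean(values_unfolded))^2)
  (mean(values_folded) - mean(values_unfolded))^2 / (vf + vu + epsilon)
}

#' Filter harvested candidates into a feature set
#'
#' Ranks candidates by Fisher score (descending, ties broken by contact
#' identity in lexicographic order), retains those with score at or above
#' `score_threshold` (optionally capped at the `max_features` top-ranked),
#' and materializes them as evaluable features.  Native hydrogen-bond
#' features receive their competing protein acceptors (harvested from the
#' unfolded basin) and water-competition terms; non-native contacts become
#' bare-switch features that the CVs subtract with coefficient -1.
#'
#' @param table An `fcv_candidates` table from [harvest_contacts()].
#' @param score_threshold Minimum Fisher score (default 1).
#' @param max_features Optional cap on the number of retained features.
#' @return An object of class `fcv_featureset`; see [feature_set()].
#' @export
filter_features <- function(table, score_threshold = 1, max_features = Inf) {
  if (!inherits(table, "fcv_candidates")) .stopf("table must come from harvest_contacts()")
  if (nrow(table) == 0L) .stopf("candidate table is empty")
  config <- attr(table, "config")
  score <- (table$mean_folded - table$mean_unfolded)^2 /
    (table$var_folded + table$var_unfolded + config$epsilon)
  ord <- order(-score, table$id)
  tab <- table[ord, , drop = FALSE]
  tab$score <- score[ord]
  keep <- tab$score >= score_threshold
  if (!any(keep))
    .stopf("no discriminative features: all %d candidates score below %g",
           nrow(tab), score_threshold)
  tab <- tab[keep, , drop = FALSE]
  if (is.finite(max_features)) tab <- utils::head(tab, max_features)
  rownames(tab) <- NULL
  feature_set(tab, attr(table, "topology"), config,
              competitors = attr(table, "competitors"),
              provenance = attr(table, "provenance"))
}

#' Construct a feature set from a retained candidate table
#'
#' Usually called via [filter_features()].
#'
#' @param tab Retained candidate rows (with a `score` column).
#' @param top The `fcv_topology`.
#' @param config The [harvest_config()] used.
#' @param competitors Per-donor competing-acceptor map.
#' @param provenance List of provenance metadata.
#' @return A list of class `fcv_featureset` with elements `hb_native`,
#'   `hb_nonnative`, `sc_native`, `sc_nonnative` (lists of features),
#'   `table` (scores), `config` and `provenance`.
#' @export
feature_set <- function(tab, top, config, competitors = list(), provenance = list()) {
  hb_native <- list(); hb_nonnative <- list()
  sc_native <- list(); sc_nonnative <- list()
  for (k in seq_len(nrow(tab))) {
    r <- tab[k, ]
    if (r$type == "hb") {
      comp <- integer(0)
      if (r$class == "native") {
        comp <- competitors[[as.character(r$donor)]] %||% integer(0)
        comp <- utils::head(setdiff(comp, r$acceptor), config$comp_max)
      }
      f <- hbond_feature(top, r$donor, r$hydrogen, r$acceptor,
                         kind = if (r$class == "native") "native" else "non-native",
                         dist_switch = config$hb_switch, ang_switch = config$ang_switch,
                         water_switch = config$water_switch, competitors = comp,
                         lambda_w = config$lambda_w, lambda_p = config$lambda_p,
                         min_sep = config$min_sep)
      f$id <- r$id; f$score <- r$score
      if (r$class == "native") hb_native[[length(hb_native) + 1L]] <- f
      else hb_nonnative[[length(hb_nonnative) + 1L]] <- f
    } else {
      f <- sc_feature(top, r$res_i, r$res_j,
                      kind = if (r$class == "native") "native" else "non-native",
                      params = config$sc_switch, min_sep = config$min_sep)
      f$id <- r$id; f$score <- r$score
      if (r$class == "native") sc_native[[length(sc_native) + 1L]] <- f
      else sc_nonnative[[length(sc_nonnative) + 1L]] <- f
    }
  }
  structure(list(
    hb_native = hb_native, hb_nonnative = hb_nonnative,
    sc_native = sc_native, sc_nonnative = sc_nonnative,
    table = as.data.frame(tab), topology = top, config = config,
    provenance = provenance
  ), class = "fcv_featureset")
}

#' @export
print.fcv_featureset <- function(x, ...) {
  cat(sprintf(
    "<fcv_featureset> HB: %d native + %d non-native; SC: %d native + %d non-native\n",
    length(x$hb_native), length(x$hb_nonnative),
    length(x$sc_native), length(x$sc_nonnative)))
  invisible(x)
}

#' Serialize a feature set to a JSON manifest
#'
#' The manifest is the human-readable unit of provenance: feature
#' identities, switch parameters, scores, thresholds and input metadata.
#' Writing the same feature set twice yields byte-identical files; the MD5
#' of the manifest is the provenance hash embedded in emitted PLUMED
#' files.
#'
#' @param fs An `fcv_featureset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fs, path) {
  writeLines(.manifest_json(fs), path)
  invisible(path)
}

.switch_plain <- function(p) list(r0 = p$r0, n = p$n, m = p$m, d0 = p$d0,
                                  d_max = if (is.finite(p$d_max)) p$d_max else "inf")

.manifest_json <- function(fs) {
  feat <- function(f) {
    if (inherits(f, "fcv_hbond_feature"))
      list(id = f$id, type = "hb", kind = f$kind, donor = f$donor,
           hydrogen = f$hydrogen, acceptor = f$acceptor,
           competitors = as.list(f$competitors), score = f$score)
    else
      list(id = f$id, type = "sc", kind = f$kind, res_i = f$i, res_j = f$j,
           score = f$score)
  }
  cfg <- fs$config
  obj <- list(
    format = "foldcv-manifest-1",
    features = lapply(c(fs$hb_native, fs$hb_nonnative, fs$sc_native, fs$sc_nonnative), feat),
    switches = list(hb = .switch_plain(cfg$hb_switch), angular = .switch_plain(cfg$ang_switch),
                    water = .switch_plain(cfg$water_switch), sc = .switch_plain(cfg$sc_switch)),
    thresholds = list(theta_F = cfg$theta_F, theta_U = cfg$theta_U,
                      theta_F_max = cfg$theta_F_max, occupancy_cut = cfg$occupancy_cut,
                      min_sep = cfg$min_sep, comp_dist = cfg$comp_dist,
                      comp_frac = cfg$comp_frac, comp_max = cfg$comp_max,
                      lambda_w = cfg$lambda_w, lambda_p = cfg$lambda_p,
                      stride = cfg$stride, epsilon = cfg$epsilon),
    provenance = fs$provenance
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Reconstruct a feature set from a JSON manifest
#'
#' Inverse of [write_manifest()]: rebuilds the evaluable features, the
#' configuration and the provenance from the manifest, against a topology.
#' The round trip preserves the provenance hash.
#'
#' @param path Manifest path.
#' @param top The `fcv_topology` the features were defined on.
#' @return An `fcv_featureset`.
#' @export
read_manifest <- function(path, top) {
  if (!file.exists(path)) .stopf("cannot read manifest '%s'", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(j$format, "foldcv-manifest-1"))
    .stopf("'%s' is not a foldcv manifest", path)
  sw <- function(l) switch_params(l$r0, l$n, l$m, d0 = l$d0,
                                  d_max = if (identical(l$d_max, "inf")) Inf else l$d_max)
  th <- j$thresholds
  config <- harvest_config(
    hb_switch = sw(j$switches$hb), ang_switch = sw(j$switches$angular),
    water_switch = sw(j$switches$water), sc_switch = sw(j$switches$sc),
    theta_F = th$theta_F, theta_U = th$theta_U, theta_F_max = th$theta_F_max,
    occupancy_cut = th$occupancy_cut, min_sep = th$min_sep,
    comp_dist = th$comp_dist, comp_frac = th$comp_frac, comp_max = th$comp_max,
    lambda_w = th$lambda_w, lambda_p = th$lambda_p, stride = th$stride,
    epsilon = th$epsilon
  )
  hb_native <- list(); hb_nonnative <- list()
  sc_native <- list(); sc_nonnative <- list()
  rows <- list()
  for (fe in j$features) {
    if (fe$type == "hb") {
      f <- hbond_feature(top, fe$donor, fe$hydrogen, fe$acceptor,
                         kind = fe$kind,
                         dist_switch = config$hb_switch, ang_switch = config$ang_switch,
                         water_switch = config$water_switch,
                         competitors = as.integer(unlist(fe$competitors)),
                         lambda_w = config$lambda_w, lambda_p = config$lambda_p,
                         min_sep = config$min_sep)
      f$id <- fe$id; f$score <- fe$score
      if (fe$kind == "native") hb_native[[length(hb_native) + 1L]] <- f
      else hb_nonnative[[length(hb_nonnative) + 1L]] <- f
    } else {
      f <- sc_feature(top, fe$res_i, fe$res_j, kind = fe$kind,
                      params = config$sc_switch, min_sep = config$min_sep)
      f$id <- fe$id; f$score <- fe$score
      if (fe$kind == "native") sc_native[[length(sc_native) + 1L]] <- f
      else sc_nonnative[[length(sc_nonnative) + 1L]] <- f
    }
    rows[[length(rows) + 1L]] <- data.frame(id = fe$id, type = fe$type,
                                            class = fe$kind, score = fe$score)
  }
  structure(list(
    hb_native = hb_native, hb_nonnative = hb_nonnative,
    sc_native = sc_native, sc_nonnative = sc_nonnative,
    table = do.call(rbind, rows), topology = top, config = config,
    provenance = j$provenance
  ), class = "fcv_featureset")
}

#' Provenance hash of a feature set
#'
#' MD5 of the JSON manifest; embedded in emitted PLUMED files so a COLVAR
#' file can be traced back to its defining features.
#'
#' @param fs An `fcv_featureset`.
#' @return Character MD5 hash.
#' @export
feature_set_hash <- function(fs) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(.manifest_json(fs), tf)
  unname(tools::md5sum(tf))
}
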