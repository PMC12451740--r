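#' Assemble the sHB and sSC collective variables from a feature set
#'
#' Each CV is a plain signed sum of its features: native contacts enter
#' with coefficient +1, non-native contacts with coefficient -1,
#' \deqn{s^{HB} = \sum_i F_i^{HB,F} - F_i^{HB,U}, \qquad
#'       s^{SC} = \sum_i F_i^{SC,F} - F_i^{SC,U}.}
#' The two definitions share no features: `sHB` sums hydrogen-bond
#' features only, `sSC` side-chain features only.
#'
#' @param fs An `fcv_featureset` with at least one native hydrogen-bond
#'   and one native side-chain feature.
#' @return A named list with `sHB` and `sSC`, each an `fcv_cv` definition.
#' @export
assemble_cvs <- function(fs) {
  stopifnot(inherits(fs, "fcv_featureset"))
  if (length(fs$hb_native) == 0L)
    .stopf("cannot assemble sHB: the feature set has no native hydrogen-bond features")
  if (length(fs$sc_native) == 0L)
    .stopf("cannot assemble sSC: the feature set has no native side-chain features")
  h <- feature_set_hash(fs)
  na <- fs$topology$n_atoms
  list(
    sHB = cv_definition("sHB", fs$hb_native, fs$hb_nonnative, fs$config, h, n_atoms = na),
    sSC = cv_definition("sSC", fs$sc_native, fs$sc_nonnative, fs$config, h, n_atoms = na)
  )
}

#' Construct a CV definition
#'
#' @param name `"sHB"` or `"sSC"`.
#' @param native,nonnative Lists of features (coefficients +1 and -1).
#' @param config The [harvest_config()] snapshot.
#' @param hash Provenance hash of the defining feature set.
#' @param ablation One of `"full"`, `"native_only"`, `"no_water_nonnative"`,
#'   `"no_protein_nonnative"`; see [ablate()].
#' @param n_atoms Atom count of the defining topology (used to detect
#'   topology mismatches at evaluation time).
#' @return An object of class `fcv_cv`.
#' @export
cv_definition <- function(name, native, nonnative, config, hash = "",
                          ablation = "full", n_atoms = NULL) {
  stopifnot(name %in% c("sHB", "sSC"))
  structure(list(name = name, native = native, nonnative = nonnative,
                 config = config, hash = hash, ablation = ablation,
                 n_atoms = n_atoms),
            class = "fcv_cv")
}

#' @export
print.fcv_cv <- function(x, ...) {
  cat(sprintf("<fcv_cv %s> %d native (+1) - %d non-native (-1) features [%s]\n",
              x$name, length(x$native), length(x$nonnative), x$ablation))
  invisible(x)
}

#' Ablation variants of a CV
#'
#' `native_only` retains only the native-contact description: the
#' non-native feature list is emptied and the water/protein competition
#' weights are zeroed.  `no_water_nonnative` switches off only the
#' protein-water competition terms (`lambda_w = 0`);
#' `no_protein_nonnative` switches off the protein non-native
#' contributions (`lambda_p = 0` and the harvested non-native features
#' removed).  `full` is the identity.
#'
#' @param cv An `fcv_cv`.
#' @param mode Ablation mode.
#' @return A modified `fcv_cv`.
#' @export
ablate <- function(cv, mode = c("full", "native_only", "no_water_nonnative",
                                "no_protein_nonnative")) {
  mode <- match.arg(mode)
  set_lambda <- function(feats, w = NULL, p = NULL) lapply(feats, function(f) {
    if (inherits(f, "fcv_hbond_feature")) {
      if (!is.null(w)) f$lambda_w <- w
      if (!is.null(p)) f$lambda_p <- p
    }
    f
  })
  out <- cv
  if (mode == "native_only") {
    out$native <- set_lambda(cv$native, w = 0, p = 0)
    out$nonnative <- list()
  } else if (mode == "no_water_nonnative") {
    out$native <- set_lambda(cv$native, w = 0)
  } else if (mode == "no_protein_nonnative") {
    out$native <- set_lambda(cv$native, p = 0)
    out$nonnative <- list()
  }
  out$ablation <- mode
  out
}

## signed per-feature evaluation matrix (frames x features), native first
.eval_feature <- function(f, traj) {
  if (inherits(f, "fcv_hbond_feature")) .eval_hb_frames(f, traj) else .eval_sc_frames(f, traj)
}

#' Evaluate a CV on a trajectory
#'
#' One value per frame: the sum of per-feature evaluations with
#' coefficients +1 (native) and -1 (non-native), honouring the CV's
#' ablation mode.
#'
#' @param cv An `fcv_cv`.
#' @param traj An `fcv_trajectory` over the same topology the features
#'   were defined on.
#' @return An `fcv_timeseries` with columns `time` and the CV name.
#' @export
evaluate_cv <- function(cv, traj) {
  stopifnot(inherits(cv, "fcv_cv"), inherits(traj, "fcv_trajectory"))
  if (!is.null(cv$n_atoms) && cv$n_atoms != traj$topology$n_atoms)
    .stopf("topology mismatch: CV was defined over %d atoms, trajectory has %d",
           cv$n_atoms, traj$topology$n_atoms)
  val <- numeric(n_frames(traj))
  for (f in cv$native) val <- val + .eval_feature(f, traj)
  for (f in cv$nonnative) val <- val - .eval_feature(f, traj)
  out <- data.frame(time = traj$time, v = val)
  names(out)[2] <- cv$name
  new_timeseries(out)
}

#' Emit a PLUMED input file defining the CVs
#'
#' Writes a single, deterministic PLUMED (>= 2.8) input defining both CVs
#' from primitive actions (`COORDINATION`, `ANGLE`, `COM`, `CUSTOM`,
#' `COMBINE`) plus a `PRINT` action producing a COLVAR file.  Atom serials
#' are 1-based, as PLUMED requires; a `UNITS LENGTH=A` directive keeps all
#' distances in Angstrom, matching the internal evaluator.  The header
#' embeds the feature-set provenance hash.
#'
#' @param cvs A list with `sHB` and `sSC` definitions (from
#'   [assemble_cvs()], possibly [ablate()]d).
#' @param top The `fcv_topology` (needed for the water-oxygen group).
#' @param path Output path.
#' @param stride `PRINT` stride in steps (default 500).
#' @param colvar_file Name of the COLVAR file the PLUMED run will write.
#' @return `path`, invisibly.
#' @export
write_plumed <- function(cvs, top, path, stride = 500, colvar_file = "COLVAR") {
  stopifnot(inherits(cvs$sHB, "fcv_cv"), inherits(cvs$sSC, "fcv_cv"))
  rs <- function(p) {  # RATIONAL switch keyword in Angstrom
    dmax <- if (is.finite(p$d_max)) sprintf(" D_MAX=%g", p$d_max) else ""
    sprintf("{RATIONAL R_0=%g D_0=%g NN=%d MM=%d%s}", p$r0, p$d0, p$n, p$m, dmax)
  }
  ## rational on u=(1+cos(x))/2 as an explicit CUSTOM expression
  ang_expr <- function(p) {
    sprintf("(1-(((1+cos(x))/2)/%.10g)^%d)/(1-(((1+cos(x))/2)/%.10g)^%d)",
            p$r0, p$n, p$r0, p$m)
  }
  L <- c(
    "# PLUMED input generated by foldcv",
    sprintf("# feature-set provenance hash: %s", cvs$sHB$hash),
    "UNITS LENGTH=A",
    ""
  )
  wo <- which(top$atoms$is_water & top$atoms$element == "O")  # 1-based serials
  need_water <- any(vapply(cvs$sHB$native, function(f) f$lambda_w != 0, logical(1)))
  if (need_water && length(wo) > 0L)
    L <- c(L, sprintf("wat: GROUP ATOMS=%s", paste(wo, collapse = ",")), "")

  hb_args <- character(0); hb_coef <- character(0)
  for (k in seq_along(cvs$sHB$native)) {
    f <- cvs$sHB$native[[k]]
    lab <- sprintf("hbf%d", k)
    if (is.null(f$hydrogen) || is.na(f$hydrogen))
      .stopf("feature %s cannot be serialized: missing hydrogen index", f$id %||% lab)
    L <- c(L,
      sprintf("%s_d: COORDINATION GROUPA=%d GROUPB=%d SWITCH=%s",
              lab, f$donor + 1L, f$acceptor + 1L, rs(f$dist_switch)),
      sprintf("%s_t: ANGLE ATOMS=%d,%d,%d", lab, f$donor + 1L, f$hydrogen + 1L, f$acceptor + 1L),
      sprintf("%s_a: CUSTOM ARG=%s_t FUNC=%s PERIODIC=NO", lab, lab, ang_expr(f$ang_switch)))
    args <- sprintf("%s_d,%s_a", lab, lab)
    expr <- "x*y"
    nextv <- c("z", "w", "v", "u")
    vi <- 1L
    if (f$lambda_w != 0 && length(wo) > 0L) {
      L <- c(L,
        sprintf("%s_wd: COORDINATION GROUPA=%d GROUPB=wat SWITCH=%s", lab, f$donor + 1L, rs(f$water_switch)),
        sprintf("%s_wa: COORDINATION GROUPA=%d GROUPB=wat SWITCH=%s", lab, f$acceptor + 1L, rs(f$water_switch)))
      args <- sprintf("%s,%s_wd,%s_wa", args, lab, lab)
      expr <- sprintf("%s-%g*(%s+%s)", expr, f$lambda_w, nextv[vi], nextv[vi + 1L])
      vi <- vi + 2L
    }
    if (f$lambda_p != 0 && length(f$competitors) > 0L) {
      L <- c(L, sprintf("%s_p: COORDINATION GROUPA=%d GROUPB=%s SWITCH=%s",
                        lab, f$donor + 1L, paste(f$competitors + 1L, collapse = ","),
                        rs(f$dist_switch)))
      args <- sprintf("%s,%s_p", args, lab)
      expr <- sprintf("%s-%g*%s", expr, f$lambda_p, nextv[vi])
    }
    L <- c(L, sprintf("%s: CUSTOM ARG=%s FUNC=%s PERIODIC=NO", lab, args, expr), "")
    hb_args <- c(hb_args, lab); hb_coef <- c(hb_coef, "1")
  }
  for (k in seq_along(cvs$sHB$nonnative)) {
    f <- cvs$sHB$nonnative[[k]]
    lab <- sprintf("hbu%d", k)
    L <- c(L,
      sprintf("%s_d: COORDINATION GROUPA=%d GROUPB=%d SWITCH=%s",
              lab, f$donor + 1L, f$acceptor + 1L, rs(f$dist_switch)),
      sprintf("%s_t: ANGLE ATOMS=%d,%d,%d", lab, f$donor + 1L, f$hydrogen + 1L, f$acceptor + 1L),
      sprintf("%s_a: CUSTOM ARG=%s_t FUNC=%s PERIODIC=NO", lab, lab, ang_expr(f$ang_switch)),
      sprintf("%s: CUSTOM ARG=%s_d,%s_a FUNC=x*y PERIODIC=NO", lab, lab, lab), "")
    hb_args <- c(hb_args, lab); hb_coef <- c(hb_coef, "-1")
  }
  L <- c(L, sprintf("shb: COMBINE ARG=%s COEFFICIENTS=%s PERIODIC=NO",
                    paste(hb_args, collapse = ","), paste(hb_coef, collapse = ",")), "")

  sc_args <- character(0); sc_coef <- character(0)
  sc_all <- c(cvs$sSC$native, cvs$sSC$nonnative)
  sc_sign <- c(rep("1", length(cvs$sSC$native)), rep("-1", length(cvs$sSC$nonnative)))
  for (k in seq_along(sc_all)) {
    f <- sc_all[[k]]
    lab <- sprintf("scf%d", k)
    L <- c(L,
      sprintf("%s_i: COM ATOMS=%s", lab, paste(f$atoms_i + 1L, collapse = ",")),
      sprintf("%s_j: COM ATOMS=%s", lab, paste(f$atoms_j + 1L, collapse = ",")),
      sprintf("%s: COORDINATION GROUPA=%s_i GROUPB=%s_j SWITCH=%s",
              lab, lab, lab, rs(f$params)), "")
    sc_args <- c(sc_args, lab); sc_coef <- c(sc_coef, sc_sign[k])
  }
  L <- c(L, sprintf("ssc: COMBINE ARG=%s COEFFICIENTS=%s PERIODIC=NO",
                    paste(sc_args, collapse = ","), paste(sc_coef, collapse = ",")), "",
         sprintf("PRINT ARG=shb,ssc FILE=%s STRIDE=%d", colvar_file, as.integer(stride)))
  writeLines(L, path)
  invisible(path)
}
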