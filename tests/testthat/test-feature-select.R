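test_that("fisher_score follows the regularized discriminant-ratio formula", {
  expect_equal(fisher_score(c(1, 2, 3), c(1, 2, 3)), 0)
  # degenerate variances stay finite through the regularizer
  expect_equal(fisher_score(rep(1, 5), rep(0, 5)), 1 / 1e-6)
  expect_error(fisher_score(numeric(0), 1:3), "non-empty")
  # symmetric under basin exchange
  set.seed(3)
  a <- rnorm(30, 1, 0.3); b <- rnorm(30, 0, 0.2)
  expect_identical(fisher_score(a, b), fisher_score(b, a))
})

test_that("fisher_score agrees with a two-class 1D LDA eigenvalue oracle", {
  vf <- c(0.9, 1.0, 1.1); vu <- c(0.0, 0.1, -0.1)
  # generalized eigenvalue of the between/within scatter problem
  Sw <- sum((vf - mean(vf))^2) + sum((vu - mean(vu))^2)
  Sb <- (mean(vf) - mean(vu))^2
  lda_eig <- as.numeric(eigen(solve(Sw) %*% Sb)$values)  # = 25 here
  # with equal class sizes n, the population-variance ratio is n * lda_eig
  expect_equal(fisher_score(vf, vu), length(vf) * lda_eig, tolerance = 1e-3)
  expect_equal(length(vf) * lda_eig, 75, tolerance = 1e-12)
})

test_that("fisher_score ranking is invariant under rescaling of a feature", {
  set.seed(9)
  for (k in 1:10) {
    a <- rnorm(40, 0.8, 0.2); b <- rnorm(40, 0.1, 0.2)
    c0 <- runif(1, 0.1, 50)
    expect_equal(fisher_score(a * c0, b * c0, epsilon = 0),
                 fisher_score(a, b, epsilon = 0), tolerance = 1e-9)
  }
})

test_that("harvesting classifies planted contacts by basin occupancy", {
  spec <- small_spec()
  folded <- sample_trajectory(spec, "folded")
  unfolded <- sample_trajectory(spec, "unfolded")
  tab <- harvest_contacts(folded, unfolded)
  a <- folded$topology$atoms
  row0 <- function(r, nm) which(a$resid == r & a$name == nm) - 1L

  # planted native hydrogen bond: always on in the folded basin, off unfolded
  id_nat <- sprintf("hb:%06d-%06d-%06d", row0(4, "N"), row0(4, "H"), row0(0, "O"))
  expect_true(id_nat %in% tab$id)
  r <- tab[tab$id == id_nat, ]
  expect_identical(r$class, "native")
  expect_equal(r$occ_folded, 1.0)
  expect_equal(r$occ_unfolded, 0.0)

  # planted misfold contact: on only in the unfolded basin
  id_mis <- sprintf("hb:%06d-%06d-%06d", row0(3, "N"), row0(3, "H"), row0(0, "O"))
  r2 <- tab[tab$id == id_mis, ]
  expect_identical(r2$class, "non-native")
  expect_gte(r2$occ_unfolded, 0.25)
  expect_lte(r2$occ_folded, 0.1)

  # a pair formed in neither basin is absent from the table
  id_absent <- sprintf("hb:%06d-%06d-%06d", row0(5, "N"), row0(5, "H"), row0(2, "O"))
  expect_false(id_absent %in% tab$id)

  # planted side-chain contacts
  expect_identical(tab$class[tab$id == "sc:0000-0005"], "native")
  expect_identical(tab$class[tab$id == "sc:0000-0003"], "non-native")
})

test_that("harvesting validates its inputs", {
  spec <- small_spec()
  folded <- sample_trajectory(spec, "folded")
  other <- sample_trajectory(fixture_spec(n_waters = 2L, n_frames = 10L), "unfolded")
  expect_error(harvest_contacts(folded, other), "topology")
})

test_that("filtering ranks by score with deterministic lexicographic ties", {
  spec <- small_spec()
  tab <- harvest_contacts(sample_trajectory(spec, "folded"),
                          sample_trajectory(spec, "unfolded"))
  fs_all <- filter_features(tab, score_threshold = 0)
  expect_equal(nrow(fs_all$table), nrow(tab))  # threshold 0 retains everything
  expect_true(all(diff(fs_all$table$score) <= 0))

  # equal scores: order by contact identity
  tied <- tab
  tied$mean_folded <- 1; tied$mean_unfolded <- 0
  tied$var_folded <- 0.01; tied$var_unfolded <- 0.01
  fs_tied <- filter_features(tied, score_threshold = 0)
  expect_identical(fs_tied$table$id, sort(tab$id))

  # an impossible threshold is an explicit error, not a silent empty set
  expect_error(filter_features(tab, score_threshold = 1e12), "no discriminative features")

  # max_features keeps the top-ranked
  fs_two <- filter_features(tab, score_threshold = 0, max_features = 2)
  expect_equal(nrow(fs_two$table), 2L)
  expect_equal(fs_two$table$score, sort(fs_all$table$score, decreasing = TRUE)[1:2])
})

test_that("retained native features originate from the folded basin and score above threshold", {
  spec <- small_spec()
  fit <- fold_cv(sample_trajectory(spec, "folded"), sample_trajectory(spec, "unfolded"))
  fs <- fit$features
  expect_true(all(fs$table$score >= 1))
  for (f in c(fs$hb_native, fs$sc_native)) expect_identical(f$origin, "folded")
  for (f in c(fs$hb_nonnative, fs$sc_nonnative)) expect_identical(f$origin, "unfolded")
  # competitor lists respect the cap and never include the native acceptor
  cfg <- fs$config
  for (f in fs$hb_native) {
    expect_lte(length(f$competitors), cfg$comp_max)
    expect_false(f$acceptor %in% f$competitors)
  }
})

test_that("identical inputs produce byte-identical manifests", {
  spec <- small_spec()
  run <- function() {
    fit <- fold_cv(sample_trajectory(spec, "folded"), sample_trajectory(spec, "unfolded"))
    path <- tempfile(fileext = ".json")
    write_manifest(fit$features, path)
    paste(readLines(path), collapse = "\n")
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1, m2)
  # and the provenance hash is stable
  fit <- fold_cv(sample_trajectory(spec, "folded"), sample_trajectory(spec, "unfolded"))
  expect_identical(feature_set_hash(fit$features), feature_set_hash(fit$features))
})

test_that("manifests reconstruct an equivalent, hash-identical feature set", {
  spec <- small_spec()
  traj_f <- sample_trajectory(spec, "folded")
  fit <- fold_cv(traj_f, sample_trajectory(spec, "unfolded"))
  path <- tempfile(fileext = ".json")
  write_manifest(fit$features, path)
  fs2 <- read_manifest(path, fit$topology)
  expect_identical(feature_set_hash(fs2), feature_set_hash(fit$features))
  # the reconstructed CVs evaluate identically
  cv1 <- evaluate_cv(fit$cvs$sHB, traj_f)$sHB
  cv2 <- evaluate_cv(assemble_cvs(fs2)$sHB, traj_f)$sHB
  expect_equal(cv2, cv1, tolerance = 1e-12)
  expect_error(read_manifest(tempfile(), fit$topology), "cannot read")
})
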