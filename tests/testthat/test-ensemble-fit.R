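test_that("R-factor follows the printed formula with I(0)-matched eta", {
  q <- c(0, 0.5, 1.0)
  expt <- scattering_curve(q, c(10, 5, 2))
  # identity
  self <- r_factor(expt, expt)
  expect_equal(self$r_factor, 0)
  expect_equal(self$eta, 1)
  # pure scaling is absorbed by eta
  double <- scattering_curve(q, 2 * c(10, 5, 2))
  sc <- r_factor(expt, double)
  expect_equal(sc$r_factor, 0)
  expect_equal(sc$eta, 0.5)
  # hand-computed 3-point example (eta = 1 by construction)
  mod <- scattering_curve(q, c(10, 4, 3))
  rf <- r_factor(expt, mod)
  expect_equal(rf$eta, 1)
  expect_equal(rf$r_factor, 100 * (0 + 1 + 1) / 17, tolerance = 1e-12)
  # mismatched grids are refused
  expect_error(r_factor(expt, scattering_curve(c(0, 0.4, 1), c(1, 1, 1))),
               "regularize")
})

test_that("R-factor is invariant to any positive scaling of the model curve", {
  q <- seq(0, 1.5, length.out = 50)
  expt <- scattering_curve(q, exp(-q^2 * 3) + 0.01)
  mod <- scattering_curve(q, exp(-q^2 * 2.5) + 0.02)
  base <- r_factor(expt, mod)$r_factor
  for (c_scale in c(0.1, 1, 10)) {
    scaled <- scattering_curve(q, c_scale * mod$intensity)
    expect_equal(r_factor(expt, scaled)$r_factor, base, tolerance = 1e-12)
  }
})

test_that("ensemble scoring gives R = 0 for the generating frame and is order-stable", {
  m <- make_mock_antibody()
  ens <- tamc_sample(m, n_moves = 120, seed = 2)
  q <- seq(0, 1.5, length.out = 72)
  planted <- 10L
  expt <- debye_intensity(set_coords(m, ens$frames[[planted]]), q,
                          bin_width = 0.02)
  scores <- score_ensemble(ens, expt, bin_width = 0.02)
  expect_equal(nrow(scores), length(ens$frames))
  expect_equal(scores$model_id, seq_along(ens$frames))
  expect_lt(scores$r_factor[planted], 1e-8)
  expect_lt(scores$r_factor[planted], median(scores$r_factor))
})

test_that("best-n selection sorts by R-factor with id tie-break", {
  sc <- tibble::tibble(model_id = 1:3, r_factor = c(3, 1, 2), eta = 1,
                       rg = 5)
  expect_equal(select_best(sc, 2), c(2L, 3L))
  expect_equal(select_best(sc, 1), 2L)
  expect_equal(sort(select_best(sc, 3)), 1:3)
  expect_error(select_best(sc, 4), "only 3")
  tie <- tibble::tibble(model_id = 1:3, r_factor = c(2, 1, 1), eta = 1,
                        rg = 5)
  expect_equal(select_best(tie, 1), 2L)
})

test_that("Kabsch superposition matches the quaternion oracle and removes rigid motion", {
  withr::with_seed(31, {
    ref <- matrix(rnorm(30), 10, 3)
    th <- 0.9
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    mob <- sweep(ref %*% R, 2, c(1, -2, 0.5), "+")
  })
  al <- superpose_set(list(mob), ref)[[1]]
  expect_lt(sqrt(mean(rowSums((al - ref)^2))), 1e-9)
  # identity transform for identical frames
  al0 <- superpose_set(list(ref), ref)[[1]]
  expect_equal(al0, ref, tolerance = 1e-12)
  # random cloud vs quaternion method
  withr::with_seed(32, {
    mob2 <- matrix(rnorm(30), 10, 3)
  })
  al1 <- superpose_set(list(mob2), ref)[[1]]
  al2 <- horn_superpose(mob2, ref)
  expect_lt(max(abs(al1 - al2)), 1e-9)
  expect_error(superpose_set(list(mob2), ref, selection = integer()),
               "Empty selection")
})

test_that("PCA recovers a planted two-cluster partition with PC1 dominant", {
  pl <- planted_cluster_frames(n_per = 25, shift = 2, spread = 0.02)
  res <- pca_cluster(pl$frames, n_components = 3, n_groups = 2, seed = 1)
  expect_equal(sum(res$variance_fractions), 1, tolerance = 1e-9)
  expect_gt(res$variance_fractions[1], 0.9)
  # perfect membership up to label permutation
  tab <- table(res$group_labels, pl$truth)
  agreement <- max(sum(diag(tab)), sum(diag(tab[2:1, ]))) / length(pl$truth)
  expect_equal(agreement, 1)
  # centroids belong to their groups
  expect_true(all(res$group_labels[res$centroid_ids] ==
                    seq_along(res$centroid_ids)))
})

test_that("degenerate PCA input (identical frames) is rejected", {
  fr <- replicate(6, matrix(1:30, 10, 3), simplify = FALSE)
  expect_error(pca_cluster(fr, n_groups = 2), "Degenerate")
  expect_error(pca_cluster(fr[1:2], n_groups = 4), "at least 4")
})

test_that("glycan stripping before PCA drops glycan coordinates from the analysis", {
  m <- asn_protein_stub()
  m2 <- attach_glycan(m, list(segment_id = "A", residue_number = 297))
  n_all <- n_atoms(m2)
  withr::with_seed(41, {
    frames <- lapply(1:6, function(i) {
      coords(m2) + matrix(rnorm(n_all * 3, sd = 0.05), n_all, 3)
    })
  })
  res <- pca_cluster(frames, n_groups = 2, topology = m2,
                     strip_glycans_first = TRUE, seed = 1)
  expect_equal(ncol(res$projections) - 2, res$n_components)
  res2 <- pca_cluster(frames, n_groups = 2, topology = m2,
                      strip_glycans_first = FALSE, seed = 1)
  expect_false(isTRUE(all.equal(res$eigenvalues[1], res2$eigenvalues[1])))
})

test_that("occupancy spread is zero for identical frames, d for a +/-d split, and rigid-invariant", {
  base <- matrix(rnorm(24), 8, 3)
  expect_equal(fc_occupancy_summary(list(base, base), 1:8), 0)
  up <- base; up[, 1] <- up[, 1] + 0.5
  dn <- base; dn[, 1] <- dn[, 1] - 0.5
  expect_equal(fc_occupancy_summary(list(up, dn), 1:8), 0.5)
  th <- 0.4
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- lapply(list(up, dn), function(f) sweep(f %*% R, 2, c(3, 1, -2), "+"))
  expect_equal(fc_occupancy_summary(moved, 1:8), 0.5, tolerance = 1e-9)
  expect_error(fc_occupancy_summary(list(base), integer()), "Empty")
})
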