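make_rt_frames <- function(base, n_frames, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      th <- runif(3, 0, 2 * pi)
      rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]),
                     cos(th[1])), 3, 3, byrow = TRUE)
      rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                     0, 0, 1), 3, 3, byrow = TRUE)
      sweep(base %*% t(rx %*% rz), 2, runif(3, -10, 10), "+")
    })
  })
}

test_that("superposition removes pure rigid-body motion and is idempotent", {
  base <- kinvar:::helix_backbone(12)
  traj <- kin_trajectory(make_rt_frames(base, 5))
  sup <- superpose_trajectory(traj)
  rmsd <- apply(sup$coords, 1, function(m) {
    sqrt(mean(rowSums((m - sup$coords[1, , ])^2)))
  })
  expect_lt(max(rmsd), 1e-6)

  again <- superpose_trajectory(sup)
  expect_lt(max(abs(again$coords - sup$coords)), 1e-9)
})

test_that("Kabsch fit matches the quaternion and bio3d oracles", {
  withr::with_seed(4, {
    for (i in 1:5) {
      ref <- matrix(rnorm(12), 4, 3)
      mov <- matrix(rnorm(12), 4, 3)
      ours <- kabsch_superpose(mov, ref)
      horn <- oracle_quaternion_superpose(mov, ref)
      expect_lt(max(abs(ours - horn)), 1e-9)
      b3d <- matrix(
        suppressWarnings(bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mov)))),
        ncol = 3, byrow = TRUE
      )
      expect_lt(max(abs(ours - b3d)), 1e-6)
    }
  })
})

test_that("covariance and correlation follow their definitions", {
  sim <- simulate_trajectory(traj_sim_spec(
    n_residues = 10, n_frames = 300, sigma_profile = 0.5, seed = 6
  ))
  co <- sim$trajectory$coords
  # clone residue 3 onto residue 7 -> perfectly correlated pair
  co[, 7, ] <- co[, 3, ] + 5
  # residue 8 mirrors residue 4's fluctuations -> perfectly anticorrelated
  mu4 <- colMeans(co[, 4, ])
  co[, 8, ] <- matrix(rep(2 * mu4, each = dim(co)[1]), ncol = 3) - co[, 4, ]
  ed <- essential_dynamics(kin_trajectory(co))
  expect_equal(ed$correlation[3, 7], 1, tolerance = 1e-9)
  expect_equal(ed$correlation[4, 8], -1, tolerance = 1e-9)
  expect_equal(diag(ed$correlation), rep(1, 10))
  expect_true(all(ed$correlation >= -1 - 1e-9 & ed$correlation <= 1 + 1e-9))
  expect_equal(ed$covariance, t(ed$covariance))
})

test_that("eigendecomposition preserves trace, rank bound and PSD", {
  sim <- simulate_trajectory(traj_sim_spec(n_residues = 8, n_frames = 12,
                                           sigma_profile = 0.8, seed = 10))
  ed <- essential_dynamics(superpose_trajectory(sim$trajectory))
  expect_equal(sum(ed$eigenvalues), sum(diag(ed$covariance)), tolerance = 1e-8)
  expect_gt(min(ed$eigenvalues), -1e-10)
  # 12 frames: at most frames - 1 nonzero modes (superposition removes more)
  expect_lte(sum(ed$eigenvalues > 1e-10), 12 - 1)
  v <- ed$eigenvectors
  expect_lt(max(abs(crossprod(v) - diag(ncol(v)))), 1e-8)
})

test_that("eigenvalues match an independent Jacobi-rotation oracle", {
  sim <- simulate_trajectory(traj_sim_spec(n_residues = 10, n_frames = 60,
                                           seed = 44))
  ed <- essential_dynamics(superpose_trajectory(sim$trajectory))
  jac <- oracle_jacobi_eigenvalues(ed$covariance)
  expect_lt(max(abs(jac - ed$eigenvalues)), 1e-8)
})

test_that("uniform fluctuations give a flat raw mobility profile", {
  sim <- simulate_trajectory(traj_sim_spec(
    n_residues = 30, n_frames = 5000, sigma_profile = 0.5, seed = 12
  ))
  ed <- essential_dynamics(superpose_trajectory(sim$trajectory))
  # flatness holds for the total fluctuation (all modes / RMSF); individual
  # top modes of an isotropic ensemble are direction-degenerate and need not
  # be flat residue-by-residue (see the methods vignette)
  all_modes <- residue_mobility(ed, k = length(ed$eigenvalues))
  expect_lt((max(all_modes$raw) - min(all_modes$raw)) / mean(all_modes$raw), 0.1)
  expect_lt((max(all_modes$rmsf) - min(all_modes$rmsf)) / mean(all_modes$rmsf), 0.1)
})

test_that("planted rigid and flexible blocks are recovered and normalised", {
  sim <- simulate_trajectory(traj_sim_spec(n_residues = 60, n_frames = 2000,
                                           seed = 13))
  prof <- residue_mobility(essential_dynamics(
    superpose_trajectory(sim$trajectory)
  ))
  expect_equal(min(prof$mobility), 0)
  expect_equal(max(prof$mobility), 1)
  flex <- sim$truth$label == "flexible"
  expect_gt(mean(prof$mobility[flex]), mean(prof$mobility[!flex]))

  cl <- classify_mobility(prof)
  expect_true(all(cl$label[cl$mobility <= quantile(cl$mobility, 0.25)] == "rigid"))
  expect_gte(mean(cl$label[flex][cl$label[flex] != "intermediate"] == "flexible"), 0.95)
  # hinges sit near the planted block boundary (residues 30/31) within window
  hinge_idx <- which(cl$hinge)
  if (length(hinge_idx) > 0) {
    expect_true(all(abs(hinge_idx - 30.5) <= 6))
  }
})

test_that("degenerate profiles classify as intermediate with no hinges", {
  prof <- structure(
    tibble::tibble(residue_id = 1:10, raw = rep(1, 10),
                   mobility = rep(0, 10), rmsf = rep(1, 10)),
    class = c("mobility_profile", class(tibble::tibble())),
    degenerate = TRUE
  )
  cl <- classify_mobility(prof)
  expect_true(all(cl$label == "intermediate"))
  expect_false(any(cl$hinge))
  expect_error(classify_mobility(prof, q_low = 0.8, q_high = 0.2), "q_low")
})

test_that("mutation sites join onto the profile with out-of-range reported", {
  sim <- simulate_trajectory(traj_sim_spec(n_residues = 40, n_frames = 800,
                                           seed = 19))
  prof <- classify_mobility(residue_mobility(essential_dynamics(
    superpose_trajectory(sim$trajectory)
  )))
  top <- prof$residue_id[which.max(prof$mobility)]
  muts <- as_mutation_table(tibble::tibble(
    kinase_id = "K", position = c(top, 3L, 999L),
    wt_aa = c("A", "A", "A"), mut_aa = c("V", "V", "V"), category = "cancer"
  ))
  joined <- mutation_site_mobility(muts, prof)
  expect_equal(joined$label[joined$position == top], "flexible")
  expect_equal(joined$label[joined$position == 999], "unmapped")
  expect_equal(nrow(attr(joined, "unmapped")), 1L)
  # inactivating sites planted at the stablest residues are labelled rigid
  stablest <- prof$residue_id[order(prof$mobility)][1:3]
  rigid_sites <- as_mutation_table(tibble::tibble(
    kinase_id = "K", position = stablest, wt_aa = "A", mut_aa = "V",
    category = "cancer", activation_status = "inactivating"
  ))
  jr <- mutation_site_mobility(rigid_sites, prof)
  expect_true(all(jr$label == "rigid"))
})

test_that("rigidity contrast behaves at its boundaries", {
  prof <- structure(
    tibble::tibble(residue_id = 1:20, raw = 1, mobility = rep(0.4, 20),
                   rmsf = 1),
    class = c("mobility_profile", class(tibble::tibble()))
  )
  rc <- rigidity_contrast(prof, 1:5, 6:10, n_perm = 99, seed = 1)
  expect_equal(rc$delta, 0)
  expect_equal(rc$p_value, 1)
  expect_error(rigidity_contrast(prof, 1:5, 5:8, n_perm = 9), "overlap")
  expect_error(rigidity_contrast(prof, integer(0), 1:3, n_perm = 9), "nonempty")
  expect_error(rigidity_contrast(prof, 1:2, c(3L, 50L), n_perm = 9), "outside")
  expect_s3_class(tidy(rc), "tbl_df")
})

test_that("contrast separates sites drawn from opposite mobility regimes", {
  sim <- simulate_trajectory(traj_sim_spec(n_residues = 60, n_frames = 1000,
                                           seed = 29))
  prof <- residue_mobility(essential_dynamics(
    superpose_trajectory(sim$trajectory)
  ))
  act <- withr::with_seed(30, sample(which(sim$truth$label == "flexible"), 5))
  inact <- withr::with_seed(31, sample(which(sim$truth$label == "rigid"), 5))
  rc <- rigidity_contrast(prof, act, inact, n_perm = 199, seed = 32)
  expect_gt(rc$delta, 0)
  expect_lt(rc$p_value, 0.05)
})
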