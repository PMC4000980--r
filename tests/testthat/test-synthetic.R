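test_that("simulators are pure functions of their spec (seed included)", {
  spec <- snp_sim_spec(n_kinases = 4, n_snps = 50, seed = 9)
  f1 <- simulate_kinase_family(spec)
  f2 <- simulate_kinase_family(spec)
  expect_identical(f1, f2)
  t1 <- simulate_snp_table(f1$truth, spec)
  t2 <- simulate_snp_table(f2$truth, spec)
  expect_identical(t1, t2)
  ts <- traj_sim_spec(n_residues = 10, n_frames = 5, seed = 9)
  expect_identical(simulate_trajectory(ts), simulate_trajectory(ts))
})

test_that("generated kinases carry the anchor motifs in order", {
  fam <- simulate_kinase_family(snp_sim_spec(n_kinases = 12, seed = 5))
  for (s in fam$sequences$sequence) {
    expect_true(grepl("G.G..G", s))
    hrd <- regexpr("HRD", s)
    dfg <- regexpr("DFG", s)
    expect_true(hrd > 0 && dfg > hrd)
  }
  # zero jitter: every kinase has identical segment lengths
  fam0 <- simulate_kinase_family(snp_sim_spec(n_kinases = 5, length_jitter = 0,
                                              seed = 5))
  lens <- fam0$truth$segments |>
    dplyr::mutate(len = end - start) |>
    dplyr::group_by(region) |>
    dplyr::summarise(n = dplyr::n_distinct(len))
  expect_true(all(lens$n == 1))
})

test_that("SNP tables conserve counts and respect the domain truth", {
  made <- make_test_family(n_kinases = 6, n_snps = 150, seed = 13)
  tab <- simulate_snp_table(made$fam$truth, made$spec)
  expect_equal(nrow(tab), 150L)
  lookup <- domain_positions(made$fam$truth)
  expect_true(all(paste(tab$kinase_id, tab$position) %in%
                    paste(lookup$kinase_id, lookup$position)))
  expect_true(all(tab$wt_aa != tab$mut_aa))

  empty <- simulate_snp_table(
    made$fam$truth,
    snp_sim_spec(n_kinases = 6, n_snps = 0, seed = 13)
  )
  expect_equal(nrow(empty), 0L)
})

test_that("neutral placement converges to region length proportions", {
  spec <- snp_sim_spec(n_kinases = 10, n_snps = 10000,
                       clustering_concentration = 1e6, seed = 31)
  fam <- simulate_kinase_family(spec)
  tab <- simulate_snp_table(fam$truth, spec)
  lookup <- domain_positions(fam$truth)
  mean_len <- lookup |>
    dplyr::count(kinase_id, region) |>
    dplyr::group_by(region) |>
    dplyr::summarise(len = mean(n))
  obs <- table(factor(tab$true_region, levels = mean_len$region))
  gof <- suppressWarnings(
    chisq.test(as.vector(obs), p = mean_len$len / sum(mean_len$len))
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("low Dirichlet concentration produces position clustering", {
  base <- function(conc, seed) {
    spec <- snp_sim_spec(n_kinases = 10, n_snps = 400,
                         clustering_concentration = conc, seed = seed)
    fam <- simulate_kinase_family(snp_sim_spec(n_kinases = 10, seed = 1))
    tab <- simulate_snp_table(fam$truth, spec)
    counts <- table(tab$true_column)
    sum(counts >= 4)
  }
  expect_gt(base(0.05, 41), base(100, 41))
})

test_that("trajectory generator honours degenerate and planted-mode specs", {
  still <- simulate_trajectory(traj_sim_spec(
    n_residues = 8, n_frames = 4, sigma_profile = 0, seed = 2
  ))
  expect_equal(max(abs(sweep(still$trajectory$coords, c(2, 3),
                             still$trajectory$coords[1, , ]))), 0)

  n <- 30
  dir <- matrix(0, n, 3)
  dir[, 1] <- sin(seq_len(n) / 3)
  spec <- traj_sim_spec(
    n_residues = n, n_frames = 2000, sigma_profile = 0.05,
    mode_specs = list(list(direction = dir, amplitude = 1.5)), seed = 8
  )
  sim <- simulate_trajectory(spec)
  # no global motion is planted, so the covariance can be taken directly;
  # superposition would project the mode's net-translation component out
  ed <- essential_dynamics(sim$trajectory)
  v1 <- ed$eigenvectors[, 1]
  planted <- as.vector(t(sim$mode_directions[[1]]))
  expect_gt(abs(sum(v1 * planted)), 0.99)
})

test_that("mobility is invariant to injected global rigid-body motion", {
  run <- function(global) {
    spec <- traj_sim_spec(n_residues = 40, n_frames = 600,
                          global_motion = global, seed = 17)
    sim <- simulate_trajectory(spec)
    residue_mobility(essential_dynamics(superpose_trajectory(sim$trajectory)))
  }
  expect_lt(max(abs(run(TRUE)$mobility - run(FALSE)$mobility)), 0.02)
})
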