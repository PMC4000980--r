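test_that("position histograms satisfy both conservation identities", {
  made <- make_test_family(n_kinases = 6, n_snps = 250, seed = 91)
  tab <- simulate_snp_table(made$fam$truth, made$spec)
  ann <- map_mutations(tab, made$fam$truth)
  cols <- unique(domain_positions(made$fam$truth)$column)
  ph <- position_histogram(ann, columns = cols)
  expect_equal(sum(ph$histogram$n_positions), ph$n_positions)
  expect_equal(sum(ph$histogram$k * ph$histogram$n_positions), ph$n_snps)
  expect_equal(ph$n_positions, length(cols))
  expect_equal(ph$n_snps, nrow(ann))

  # row order cannot matter
  ph2 <- position_histogram(ann[sample(nrow(ann)), ], columns = cols)
  expect_equal(ph2$histogram, ph$histogram)

  # no SNPs: everything in the k = 0 class
  ph0 <- position_histogram(ann[0, ], columns = cols)
  expect_equal(ph0$histogram,
               tibble::tibble(k = 0L, n_positions = length(cols)))
})

test_that("Monte Carlo null matches exact multinomial expectations", {
  # P(position has exactly k SNPs) is Binomial(N, 1/P); compare E[#positions]
  n_pos <- 3
  n_snp <- 2
  null <- mc_position_null(n_snp, n_pos, n_iter = 10000, seed = 7)
  exact <- n_pos * dbinom(null$k, n_snp, 1 / n_pos)
  expect_true(all(abs(null$mean - exact) <= 3 * null$se + 1e-12))
  # the analytic k = 0 value: 3 * (2/3)^2 = 4/3
  expect_lt(abs(null$mean[null$k == 0] - 4 / 3), 3 * null$se[null$k == 0])

  null2 <- mc_position_null(n_snp, n_pos, n_iter = 10000, seed = 7)
  expect_identical(null, null2)

  deg <- mc_position_null(0, 5, n_iter = 100, seed = 1)
  expect_equal(deg$mean[deg$k == 0], 5)
  expect_equal(deg$sd, 0)
  expect_error(mc_position_null(2, 3, n_iter = 0), "n_iter")
})

test_that("observed-vs-null comparison flags only genuine excess", {
  obs <- as_position_histogram(observed_position_histogram())
  null <- mc_position_null(obs$n_snps, obs$n_positions, n_iter = 4000, seed = 3)
  cmp <- compare_observed_to_null(obs, null)
  expect_equal(sum(cmp$observed), obs$n_positions)
  # the observed disease-SNP distribution is heavy-tailed relative to a
  # uniform random-assignment null: the far tail carries flagged excess
  expect_true(all(cmp$excess[cmp$k >= 6 & cmp$observed > 0] > 0))
  expect_true(any(cmp$flagged[cmp$k >= 6]))

  wrong <- mc_position_null(10, 10, n_iter = 100, seed = 1)
  expect_error(compare_observed_to_null(obs, wrong), "do not match")
})

test_that("null-generated histograms are rarely flagged", {
  # sparse density: the per-class z-like excess is only well calibrated when
  # class means are not minuscule (see the methods vignette)
  n_pos <- 150
  n_snp <- 30
  null <- mc_position_null(n_snp, n_pos, n_iter = 10000, seed = 11)
  draws <- withr::with_seed(12, rmultinom(200, n_snp, rep(1, n_pos)))
  flagged <- vapply(seq_len(ncol(draws)), function(i) {
    counts <- tabulate(draws[, i] + 1L)
    ph <- as_position_histogram(
      tibble::tibble(k = seq_along(counts) - 1L, n_positions = counts)
    )
    any(compare_observed_to_null(ph, null)$flagged)
  }, logical(1))
  expect_gte(mean(!flagged), 0.95)
})

test_that("clustered placement shows up in the tail classes", {
  spec <- snp_sim_spec(n_kinases = 10, n_snps = 300,
                       clustering_concentration = 0.05, seed = 23)
  fam <- simulate_kinase_family(snp_sim_spec(n_kinases = 10, seed = 1))
  tab <- simulate_snp_table(fam$truth, spec)
  cols <- unique(domain_positions(fam$truth)$column)
  ph <- position_histogram(
    dplyr::mutate(tab, column = true_column), columns = cols
  )
  null <- mc_position_null(ph$n_snps, ph$n_positions, n_iter = 4000, seed = 2)
  cmp <- compare_observed_to_null(ph, null)
  tail_cls <- cmp[cmp$k >= 4 & cmp$observed > 0, ]
  expect_true(any(tail_cls$flagged & tail_cls$excess > 0))
  # the most multiply-hit class is far beyond the null
  top <- cmp[cmp$observed > 0, ]
  expect_gt(top$excess[which.max(top$k)], 3)
})

test_that("hotspot detection counts distinct kinase genes", {
  recs <- hotspot_catalog_mutations()
  hs <- find_hotspots(recs, min_kinases = 3, position_col = "reference_position")
  counts <- setNames(hs$n_kinases, hs$reference_position)
  expect_equal(counts[["L861"]], 8L)
  expect_equal(counts[["T790"]], 6L)
  expect_equal(counts[["L858"]], 3L)
  # duplicate substitutions in one kinase count once
  dup <- dplyr::bind_rows(recs, recs)
  hs2 <- find_hotspots(dup, min_kinases = 3, position_col = "reference_position")
  expect_equal(hs2$n_kinases, hs$n_kinases)
  # row order invariance
  hs3 <- find_hotspots(recs[sample(nrow(recs)), ], min_kinases = 3,
                       position_col = "reference_position")
  expect_equal(hs3, hs)
  # sorted by descending recurrence
  expect_true(all(diff(hs$n_kinases) <= 0))
  # threshold above the maximum yields nothing
  expect_equal(nrow(find_hotspots(recs, min_kinases = 99,
                                  position_col = "reference_position")), 0L)
  expect_error(find_hotspots(recs, min_kinases = 0), "min_kinases")
})

test_that("hotspot activation status pools by majority with mixed on ties", {
  recs <- hotspot_catalog_mutations()
  hs <- find_hotspots(recs, min_kinases = 3, position_col = "reference_position")
  expect_equal(hs$activation_status[hs$reference_position == "D855"],
               "inactivating")
  expect_equal(hs$activation_status[hs$reference_position == "L861"],
               "activating")
  tie <- tibble::tibble(
    kinase_id = c("A", "B"), column = 5L,
    activation_status = c("activating", "inactivating")
  )
  expect_equal(find_hotspots(tie, min_kinases = 2)$activation_status, "mixed")
})
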