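test_that("biased energy adds the restraints it claims", {
  tm <- toy_energy_model(L = 3, A = 4, seed = 2)
  aln <- simulate_msa(2, 10, 8, 0.3, seed = 3)
  ps <- build_pssm(aln, min_coverage = 0)
  em <- pssm_energy_model(ps)
  ref <- aln$seqs[1, ]
  dec <- fit_latent(aln, k = 2, ref = ref)

  cfg0 <- sampler_config(ref = ref, w_d = 0, w_pca = 0)
  mut <- ref; mut[3] <- setdiff(aa_alphabet(), ref[3])[1]
  # w_d = w_pca = 0: U' = U
  expect_equal(biased_energy(em, cfg0, mut), model_energy(em, mut))
  # at the reference both restraints vanish
  cfgb <- sampler_config(ref = ref, w_d = 5, w_pca = 7, dec = dec)
  expect_equal(biased_energy(em, cfgb, ref), model_energy(em, ref))
  # single mutation with w_d = 2, w_pca = 0: U' - U = 2
  cfg2 <- sampler_config(ref = ref, w_d = 2)
  expect_equal(biased_energy(em, cfg2, mut) - model_energy(em, mut), 2)
  # exploration term lowers the effective energy (reward sign)
  expect_lt(biased_energy(em, sampler_config(ref = ref, w_pca = 3,
                                             dec = dec), mut),
            biased_energy(em, cfg0, mut))
  expect_error(sampler_config(ref = ref, w_pca = 1), "decomposition")
  expect_error(sampler_config(temperature = 0, ref = ref), "temperature")
})

test_that("Gibbs sampling matches exact Boltzmann enumeration on a toy", {
  # 2 positions x 2 letters, flat energies: uniform over 4 states
  flat <- custom_energy_model(function(s) 0, alphabet = c("A", "B"),
                              L = 2)
  cfg <- sampler_config(ref = c(1L, 1L), sweeps = 6000, burn_in = 200,
                        seed = 5)
  s <- gibbs_sample(flat, cfg)
  emp <- tabulate(state_index(s$states, 2L), 4) / nrow(s$states)
  expect_lt(tv_distance(emp, rep(0.25, 4)), 0.05)

  # coupled 3 x 3 table at T = 1.3 against exhaustive enumeration
  tm <- toy_energy_model(L = 3, A = 3, seed = 8)
  cfg2 <- sampler_config(temperature = 1.3, ref = c(1L, 1L, 1L),
                         sweeps = 12000, burn_in = 500, seed = 6)
  s2 <- gibbs_sample(tm$model, cfg2)
  emp2 <- tabulate(state_index(s2$states, 3L), 27) / nrow(s2$states)
  expect_lt(tv_distance(emp2, boltzmann_exact(tm$table, 1.3)), 0.03)

  # reproducible under the seed
  s2b <- gibbs_sample(tm$model, cfg2)
  expect_identical(s2$states, s2b$states)
})

test_that("mean Hamming distance is non-increasing in the distance weight", {
  aln <- simulate_msa(2, 20, 20, 0.3, seed = 13)
  em <- pssm_energy_model(build_pssm(aln, min_coverage = 0))
  ref <- aln$seqs[1, ]
  mh <- vapply(c(0, 1, 2, 4), function(wd) {
    cfg <- sampler_config(w_d = wd, ref = ref, sweeps = 1500,
                          burn_in = 200, seed = 17)
    mean(gibbs_sample(em, cfg)$hamming)
  }, numeric(1))
  expect_true(all(diff(mh) <= 0))
})

test_that("temperature calibration matches the mean energy of the reference", {
  aln <- simulate_msa(1, 30, 15, 0, within_noise = 0.05, seed = 19)
  em <- pssm_energy_model(build_pssm(aln, min_coverage = 0))
  # the consensus is near the model optimum: tiny T pins samples to it
  cons <- apply(aln$seqs, 2, function(col)
    names(which.max(table(col))))
  cal <- calibrate_temperature(em, cons, T_grid = c(0.05, 1, 3),
                               sweeps = 400, burn_in = 100, seed = 3)
  expect_equal(cal$temperature, 0.05)
  expect_true(all(diff(cal$mean_energy) > 0))  # monotone curve here
  one <- calibrate_temperature(em, cons, T_grid = 0.7, sweeps = 100,
                               burn_in = 10)
  expect_equal(one$temperature, 0.7)
  expect_error(calibrate_temperature(em, cons, numeric(0)), "grid")
})

test_that("bias-weight calibration hits the target distance and rewards controls", {
  aln <- simulate_msa(2, 30, 24, divergence = 0.2, seed = 23)
  dec <- fit_latent(aln, k = 2, ref = aln$seqs[1, ])
  em <- pssm_energy_model(build_pssm(aln, sequence_weights(aln, 0.8),
                                     min_coverage = 0))
  ref <- aln$seqs[1, ]
  top <- top_latent_mutations(dec, 3)
  ctrl <- paste0(ref[top$pos], top$pos, top$aa)
  cap <- ctrl[1]
  cal <- calibrate_bias_weights(em, dec, ref, target_distance = 2.8,
                                control_mutations = ctrl,
                                cap_mutation = cap, cap_fraction = 1,
                                w_pca_grid = c(0, 20), sweeps = 250,
                                burn_in = 50, seed = 29)
  # bisection hit the target mean distance for the selected point
  sel <- cal$grid[cal$grid$w_pca == cal$w_pca, ]
  expect_lt(abs(sel$mean_dist - 2.8) / 2.8, 0.05)
  # cap_fraction = 1 never binds: selection is the unconstrained argmax
  expect_equal(cal$grid$control_freq[which.max(cal$grid$control_freq)],
               sel$control_freq)
  # exploration weight enriches the latent-weighted controls
  expect_equal(cal$w_pca, 20)
  expect_gt(cal$grid$control_freq[cal$grid$w_pca == 20],
            cal$grid$control_freq[cal$grid$w_pca == 0])
  # an infeasible cap on a mutation the model itself favors errors out
  ps <- build_pssm(aln, min_coverage = 0)
  pos_weak <- which.min(ps$prob[cbind(match(ref, rownames(ps$prob)),
                                      seq_along(ref))])
  fav <- names(which.max(ps$prob[rownames(ps$prob) != ref[pos_weak],
                                 pos_weak]))
  expect_error(
    calibrate_bias_weights(em, dec, ref, 2.8,
                           control_mutations = ctrl,
                           cap_mutation = paste0(ref[pos_weak], pos_weak,
                                                 fav),
                           cap_fraction = 1e-9, w_pca_grid = 0,
                           sweeps = 150, burn_in = 30, seed = 1),
    "cap")
})

test_that("binding-site enumeration follows the per-position arithmetic", {
  pdb <- system.file("extdata", "synthetic_site.pdb", package = "dmscan")
  spec <- binding_site_spec(list(pdb), radius = 12)
  # residue 2's CA is outside 12 A but its CB is inside: any-atom rule
  expect_equal(shell_positions(spec), c(1L, 2L))
  # residue 3 has only a hydrogen nearby: hydrogens are excluded
  seqp <- c("G", "A", "M", "W")
  cds <- "GGCGCGATGTGG"
  lib <- enumerate_binding_site_library(spec, seqp, cds)
  # 2 positions x 2 backgrounds x (19 missense + 1 synonymous + 1 deletion)
  expect_equal(nrow(lib), 84L)
  expect_equal(as.integer(table(lib$type)[c("missense", "synonymous",
                                            "deletion")]), c(76L, 4L, 4L))
  # missense codons come from the usage table's argmax
  usage <- codon_usage_table()
  m230a_like <- lib[lib$type == "missense" & lib$new_aa == "L", ]
  expect_true(all(m230a_like$codon == "CTG"))

  # radius 0: empty library
  spec0 <- binding_site_spec(list(pdb), radius = 1e-9)
  expect_equal(nrow(enumerate_binding_site_library(spec0, seqp, cds)), 0L)

  # single-codon WT amino acid (Met): no synonymous variant, 20 designs
  spec3 <- binding_site_spec(list(pdb), radius = 31, backgrounds = "WT")
  lib3 <- enumerate_binding_site_library(spec3, seqp, cds)
  pos3 <- lib3[lib3$pos == 3L, ]
  expect_equal(nrow(pos3), 20L)
  expect_false("synonymous" %in% pos3$type)
})

test_that("position selection and synthesis frequencies match sample marginals", {
  ref <- rep("A", 6)
  samples <- matrix("A", 10, 6)
  samples[1:6, 2] <- "C"
  samples[1:3, 5] <- "D"
  samples[1, 6] <- "E"
  expect_equal(select_design_positions(samples, ref, K = 3), c(2L, 5L, 6L))
  # uniform frequencies: ties resolve to the lowest indices
  flat <- matrix(rep(c("A", "C"), each = 4 * 6), ncol = 6, byrow = FALSE)
  flat <- rbind(matrix("C", 2, 6), matrix("A", 2, 6))
  expect_equal(select_design_positions(flat, ref, K = 2), c(1L, 2L))

  des <- fit_position_frequencies(samples, c(2L, 5L), ref)
  expect_equal(unname(des$freq[["2"]]["C"]), 0.6)
  expect_equal(unname(des$freq[["2"]]["A"]), 0.4)
  expect_equal(sum(des$freq[["5"]]), 1)
  # never-mutated position: frequency 1 on the reference letter
  des4 <- fit_position_frequencies(samples, 4L, ref)
  expect_equal(unname(des4$freq[["4"]]["A"]), 1)
  # product design preserves marginals but drops correlations
  corr <- rbind(matrix(c("C", "C"), 5, 2, byrow = TRUE),
                matrix(c("A", "A"), 5, 2, byrow = TRUE))
  desc <- fit_position_frequencies(corr, c(1L, 2L), c("A", "A"))
  joint_cc <- mean(corr[, 1] == "C" & corr[, 2] == "C")
  prod_cc <- desc$freq[["1"]]["C"] * desc$freq[["2"]]["C"]
  expect_equal(joint_cc, 0.5)
  expect_equal(unname(prod_cc), 0.25)
  tab <- design_table(desc)
  expect_true(all(tab$frequency > 0))
})
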