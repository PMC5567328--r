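test_that("config validation names the offending field", {
  expect_error(synth_config(classes = data.frame(class_name = "A", N = 0L,
    weight = 1, precision_rate = 0.5, o_spec = 1, o_obs = 0, o_unk = 0,
    missing_time_rate = 0, missing_space_rate = 0)), "N must be >= 1")
  bad_mix <- data.frame(class_name = "A", N = 5L, weight = 1,
    precision_rate = 0.5, o_spec = 0.5, o_obs = 0.4, o_unk = 0.2,
    missing_time_rate = 0, missing_space_rate = 0)
  expect_error(synth_config(classes = bad_mix), "origin_mix")
  expect_error(synth_config(synonym_fraction = 1.2), "rate")
  expect_error(synth_config(glm_truth = list(b0 = 1, b1 = 0, b2 = 0, b3 = 0,
                                             k = 0)), "k must be > 0")
})

test_that("gen_backbone honours N, synonym counts, and name uniqueness", {
  one <- synth_config(classes = data.frame(class_name = "Solo", N = 5L,
    weight = 1, precision_rate = 1, o_spec = 1, o_obs = 0, o_unk = 0,
    missing_time_rate = 0, missing_space_rate = 0), synonym_fraction = 0)
  bb <- gen_backbone(one)
  expect_equal(nrow(bb), 5L)
  expect_true(all(bb$status %in% c("accepted", "doubtful")))

  cfg <- synth_config(classes = data.frame(class_name = "C", N = 100L,
    weight = 1, precision_rate = 1, o_spec = 1, o_obs = 0, o_unk = 0,
    missing_time_rate = 0, missing_space_rate = 0), synonym_fraction = 0.2)
  bb <- gen_backbone(cfg)
  expect_equal(nrow(bb), 120L)
  expect_equal(sum(bb$status == "synonym"), 20L)
  expect_equal(anyDuplicated(bb$species), 0L)
  # synonyms point at accepted names
  expect_true(all(bb[bb$status == "synonym"]$accepted_species %in%
                    bb[bb$status == "accepted"]$species))
})

test_that("same seed gives identical outputs, including file bytes", {
  cfg <- small_config(seed = 42, n = 2000)
  bb1 <- gen_backbone(cfg); bb2 <- gen_backbone(cfg)
  expect_identical(bb1, bb2)
  o1 <- gen_occurrences(cfg, bb1); o2 <- gen_occurrences(cfg, bb2)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
  f1 <- tempfile(); f2 <- tempfile()
  write_occurrences(o1, f1); write_occurrences(o2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("boundary rates behave exactly", {
  base <- data.frame(class_name = "A", N = 50L, weight = 1,
    precision_rate = 1, o_spec = 0.5, o_obs = 0.5, o_unk = 0,
    missing_time_rate = 0, missing_space_rate = 0)
  cfg <- synth_config(seed = 3, n_occurrences = 500, classes = base)
  occ <- gen_occurrences(cfg, gen_backbone(cfg))
  expect_true(all(occ$species_precise))

  base$missing_space_rate <- 1
  cfg <- synth_config(seed = 3, n_occurrences = 500, classes = base)
  occ <- gen_occurrences(cfg, gen_backbone(cfg))
  expect_true(all(is.na(occ$lat)))
  expect_equal(mean(occ$space_issue), 1)
})

test_that("occurrence species always exist in the backbone; synonyms never emitted", {
  cfg <- small_config(seed = 6, n = 3000)
  bb <- gen_backbone(cfg)
  occ <- gen_occurrences(cfg, bb)
  valid <- bb[bb$status != "synonym"]
  sp <- occ$species[nzchar(occ$species)]
  expect_true(all(sp %in% valid$species))
  expect_error(gen_occurrences(cfg, bb[0]), "empty backbone")
})

test_that("category mixes land within 3 binomial standard errors", {
  base <- data.frame(class_name = "A", N = 200L, weight = 1,
    precision_rate = 0.9, o_spec = 0.5, o_obs = 0.4, o_unk = 0.1,
    missing_time_rate = 0.3, missing_space_rate = 0.2)
  cfg <- synth_config(seed = 12, n_occurrences = 10000L, classes = base)
  occ <- gen_occurrences(cfg, gen_backbone(cfg))
  n <- nrow(occ)
  checks <- list(
    c(mean(occ$origin == "Specimen"), 0.5),
    c(mean(occ$origin == "Observation"), 0.4),
    c(mean(occ$origin == "Unknown"), 0.1),
    c(mean(occ$species_precise), 0.9),
    c(mean(is.na(occ$year)), 0.3)
  )
  for (ck in checks) {
    se <- sqrt(ck[2] * (1 - ck[2]) / n)
    expect_lt(abs(ck[1] - ck[2]), 3 * se)
  }
})

test_that("generator bookkeeping matches derived flags exactly", {
  cfg <- small_config(seed = 19, n = 4000)
  bb <- gen_backbone(cfg)
  occ <- gen_occurrences(cfg, bb)
  truth <- attr(occ, "truth")
  for (i in seq_len(nrow(truth))) {
    cl <- truth$class_name[i]
    sub <- occ[occ$class_name == cl]
    expect_equal(nrow(sub), truth$n[i])
    expect_equal(sum(sub$origin == "Specimen"), truth$n_spec[i])
    expect_equal(sum(sub$origin == "Observation"), truth$n_obs[i])
    expect_equal(sum(sub$origin == "Unknown"), truth$n_unk[i])
    expect_equal(sum(sub$time_issue), truth$n_time_missing[i])
    expect_equal(sum(sub$space_issue), truth$n_space_issue[i])
    expect_equal(sum(sub$species_precise), truth$n_precise[i])
  }
})

test_that("lognormal(0,2) abundances are heavy-tailed: singletons beat >= 20", {
  cfg <- small_config(seed = 23, n = 20000)
  occ <- gen_occurrences(cfg, gen_backbone(cfg))
  counts <- table(occ$species[nzchar(occ$species)])
  h <- occurrence_class_histogram(as.vector(counts))
  expect_gt(h[["one"]], h[["many"]])
})

test_that("clustered coordinates create spatial redundancy: p_gt20d < p_gt20 overall", {
  cfg <- small_config(seed = 29, n = 20000, cluster_sd = 0.05)
  bb <- gen_backbone(cfg)
  s <- summarize_taxa(gen_occurrences(cfg, bb), bb)
  expect_lt(sum(s$n_gt20d), sum(s$n_gt20))
})

test_that("coupled covariates correlate with counts; k -> Inf approaches Poisson", {
  cfg <- small_config(seed = 7)
  bb <- gen_backbone(cfg)
  cov <- gen_covariates(cfg, bb, mode = "coupled", n_species = 300)
  expect_gt(cor(log1p(cov$interest), log1p(cov$n_occ)), 0)
  expect_true(all(attr(cov, "truth")$expected_occurrences > 0))
  # research identical within an order
  spread <- tapply(cov$research, paste(cov$class_name, cov$order_name),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # Poisson limit: variance/mean -> 1 at fixed covariates
  cfg2 <- small_config(seed = 7,
                       glm_truth = list(b0 = 3, b1 = 0, b2 = 0, b3 = 0, k = 1e8))
  cov2 <- gen_covariates(cfg2, bb, mode = "coupled", n_species = 2000)
  vm <- var(cov2$n_occ) / mean(cov2$n_occ)
  expect_lt(abs(vm - 1), 0.15)
})
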