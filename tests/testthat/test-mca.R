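test_that("year binning and completeness categories follow the fixed vocabularies", {
  y <- c(1850, 1900, 1949, 1950, 1974, 1975, 1999, 2000, 2004, 2005, 2009,
         2010, 2014, 2015, 2016, NA)
  got <- bin_year(y)
  expect_equal(as.character(got), c(
    "<1900", "1900-1949", "1900-1949", "1950-1974", "1950-1974", "1975-1999",
    "1975-1999", "2000-2004", "2000-2004", "2005-2009", "2005-2009",
    "2010-2014", "2010-2014", ">=2015", ">=2015", "Unknown Year"
  ))
  expect_equal(levels(got), YEAR_BINS)
  # a time issue forces Unknown Year even when a year value exists
  expect_equal(as.character(bin_year(2000, time_issue = TRUE)), "Unknown Year")
  cc <- completeness_category(c(FALSE, TRUE, FALSE, TRUE),
                              c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.character(cc), c("No issue", "Temporal issue",
                                   "Spatial issues", "Both issues"))
})

test_that("ventilation reassigns rare categories and preserves row count", {
  set.seed(1)
  tab <- data.frame(
    a = factor(rep(c("x", "y", "z", "rare"), c(500, 300, 196, 4))),
    b = factor(rep(c("u", "v"), 500))
  )
  out <- ventilate(tab, threshold = 0.005, seed = 2)
  expect_equal(nrow(out), 1000L)
  expect_false("rare" %in% levels(out$a))
  expect_equal(sum(table(out$a)), 1000L)
  expect_equal(as.character(out$b), as.character(tab$b))  # untouched variable

  # no category below threshold: fixed point
  expect_equal(ventilate(tab[c("b")], threshold = 0.005), tab[c("b")])

  # 99.8/0.2 split collapses to one category -> variable dropped with warning
  tab2 <- data.frame(
    a = factor(rep(c("big", "tiny"), c(998, 2))),
    b = factor(rep(c("u", "v"), 500))
  )
  expect_warning(out2 <- ventilate(tab2, threshold = 0.005, seed = 1),
                 "dropped")
  expect_equal(names(out2), "b")
  expect_equal(nrow(out2), 1000L)
})

test_that("ventilation reassignment is proportional to remaining frequencies", {
  tab <- data.frame(a = factor(rep(c("x", "y", "rare"), c(6000, 3960, 40))))
  out <- ventilate(tab, threshold = 0.005, seed = 3)
  moved_to_x <- sum(out$a == "x") - 6000
  # of 40 moved rows, ~60% should land in x; 3 binomial SE band
  expect_lt(abs(moved_to_x / 40 - 6000 / 9960), 3 * sqrt(0.6 * 0.4 / 40))
})

test_that("fit_mca matches the brute-force indicator-matrix CA oracle to 1e-8", {
  set.seed(14)
  tab <- data.frame(
    v1 = factor(sample(c("a", "b", "c"), 200, TRUE, prob = c(.5, .3, .2))),
    v2 = factor(sample(c("p", "q"), 200, TRUE)),
    v3 = factor(sample(c("s", "t", "u", "w"), 200, TRUE))
  )
  fit <- fit_mca(tab)
  ora <- oracle_mca(tab)
  k <- length(fit$eigenvalues)
  expect_equal(fit$eigenvalues, ora$eigenvalues[seq_len(k)], tolerance = 1e-8)
  # axis signs are arbitrary: flip oracle axes to the fitted orientation
  flips <- sign(colSums(ora$col_coords[, seq_len(k), drop = FALSE] *
                          fit$col_coords))
  oc <- sweep(ora$col_coords[, seq_len(k), drop = FALSE], 2, flips, `*`)
  or <- sweep(ora$row_coords[, seq_len(k), drop = FALSE], 2, flips, `*`)
  expect_lt(max(abs(oc - fit$col_coords)), 1e-8)
  expect_lt(max(abs(or - fit$row_coords)), 1e-8)
})

test_that("eigenvalue identities and axis ordering hold on generated inputs", {
  cfg <- two_class_config(seed = 3, n = 800)
  occ <- gen_occurrences(cfg, gen_backbone(cfg))
  tab <- mca_table(occ)
  fit <- fit_mca(tab, n_axes = 100L)  # capped internally at J - Q
  expect_equal(length(fit$eigenvalues), fit$J - fit$Q)
  expect_equal(sum(fit$eigenvalues), fit$J / fit$Q - 1, tolerance = 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(fit$eigenvalues >= -1e-12 & fit$eigenvalues <= 1 + 1e-12))
  # deterministic orientation: largest |loading| per axis positive
  for (k in seq_along(fit$eigenvalues)) {
    expect_gt(fit$col_coords[which.max(abs(fit$col_coords[, k])), k], 0)
  }
})

test_that("perfectly associated balanced binary variables put all association on axis 1", {
  tab <- data.frame(
    a = factor(rep(c("a1", "a2"), each = 50)),
    b = factor(rep(c("b1", "b2"), each = 50))
  )
  fit <- fit_mca(tab)
  expect_equal(fit$eigenvalues[1], 1, tolerance = 1e-12)
  # associated categories coincide in sign on axis 1
  expect_equal(unname(sign(fit$col_coords["a.a1", 1])),
               unname(sign(fit$col_coords["b.b1", 1])))
  expect_equal(unname(sign(fit$col_coords["a.a2", 1])),
               unname(sign(fit$col_coords["b.b2", 1])))
})

test_that("constant variables are rejected with advice to ventilate", {
  tab <- data.frame(a = factor(rep("only", 10)),
                    b = factor(rep(c("x", "y"), 5)))
  expect_error(fit_mca(tab), "ventilate")
})

test_that("class barycentres are row-score means with the expected geometry", {
  # single-row class: barycentre equals that row's score
  set.seed(5)
  tab <- data.frame(
    cl = factor(c("solo", rep(c("m1", "m2"), each = 20))),
    v = factor(sample(c("x", "y"), 41, TRUE)),
    w = factor(sample(c("s", "t"), 41, TRUE))
  )
  fit <- fit_mca(tab)
  bary <- class_barycentres(fit, tab$cl)
  expect_equal(unlist(bary[bary$taxon == "solo", -1], use.names = FALSE),
               fit$row_coords[1, 1:2])

  # opposite profiles land on opposite half-planes of axis 1
  tab2 <- data.frame(
    cl = factor(rep(c("old_spec", "new_obs"), each = 100)),
    origin = factor(rep(c("Specimen", "Observation"), each = 100)),
    age = factor(rep(c("pre1950", "post2010"), each = 100)),
    noise = factor(sample(c("n1", "n2"), 200, TRUE))
  )
  fit2 <- fit_mca(tab2)
  b2 <- class_barycentres(fit2, tab2$cl)
  expect_lt(b2$axis1[1] * b2$axis1[2], 0)
  # identical category profiles give identical barycentres
  tab3 <- data.frame(
    cl = factor(rep(c("t1", "t2"), each = 4)),
    v = factor(rep(c("x", "x", "y", "y"), 2)),
    w = factor(rep(c("s", "t"), 4))
  )
  fit3 <- fit_mca(tab3[-1])
  b3 <- class_barycentres(fit3, tab3$cl)
  expect_equal(unlist(b3[1, -1]), unlist(b3[2, -1]), tolerance = 1e-10)
})

test_that("subsample replicates give stable axis-1 category orderings", {
  cfg <- small_config(seed = 37, n = 50000)
  occ <- gen_occurrences(cfg, gen_backbone(cfg))
  ords <- lapply(1:3, function(s) {
    tab <- mca_table(occ, sample_size = 2500, seed = s)
    fit <- fit_mca(ventilate(tab, seed = s))
    co <- fit$col_coords[, 1]
    co[order(names(co))]
  })
  common <- Reduce(intersect, lapply(ords, names))
  for (i in 2:3) {
    expect_gt(cor(rank(ords[[1]][common]), rank(ords[[i]][common]),
                  method = "spearman"), 0.9)
  }
})
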