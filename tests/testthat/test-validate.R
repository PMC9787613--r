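test_that("compute_metrics reproduces hand arithmetic", {
  m <- compute_metrics(c(1, 2), c(2, 2))
  expect_equal(m$mpe, 50)
  expect_equal(m$mae, 0.5)
  expect_equal(m$mape, 50)
  expect_equal(m$maape, atan(1) / 2)
  expect_equal(m$maape, 0.3927, tolerance = 1e-4)

  ident <- compute_metrics(c(0.3, 7, 50), c(0.3, 7, 50))
  expect_equal(unlist(ident[c("mpe", "mae", "mape", "maape")]),
               c(mpe = 0, mae = 0, mape = 0, maape = 0))

  single <- compute_metrics(1, 3)
  expect_equal(single$mpe, 200)
  expect_equal(single$mape, 200)
  expect_equal(single$maape, atan(2))
  expect_equal(single$maape, 1.1071, tolerance = 1e-4)

  # optional x100 scale
  expect_equal(compute_metrics(1, 3, times_100 = TRUE)$maape, 100 * atan(2))

  expect_error(compute_metrics(numeric(0), numeric(0)), "empty")
  expect_error(compute_metrics(c(1, -1), c(1, 1)), "positive")
})

test_that("metric inequalities hold on random prediction sets", {
  set.seed(8)
  for (r in 1:200) {
    n <- sample(1:40, 1)
    a <- stats::rlnorm(n, 1, 1)
    p <- a * stats::rlnorm(n, 0, 0.7)
    m <- compute_metrics(a, p)
    expect_gte(m$mape, abs(m$mpe))
    expect_gte(m$maape, 0)
    expect_lt(m$maape, pi / 2)
    expect_gte(m$mae, 0)
  }
})

test_that("kfold_cv partitions, is seed-reproducible, and pools held-out pairs", {
  tr <- sim_trees(n = 240, seed = 14)
  cv <- kfold_cv(tr, model_spec("eq2"), k = 6, seed = 42)
  expect_equal(nrow(cv$pairs), nrow(tr))            # every record held out once
  expect_equal(sort(cv$pairs$actual), sort(tr$leaf_mass))
  expect_equal(nrow(cv$per_unit), 6)
  expect_equal(sum(cv$per_unit$n), nrow(tr))
  # pooled = metrics of the union
  expect_equal(cv$pooled$mape,
               compute_metrics(cv$pairs$actual, cv$pairs$predicted)$mape)
  cv2 <- kfold_cv(tr, model_spec("eq2"), k = 6, seed = 42)
  expect_identical(cv$pairs, cv2$pairs)
  cv3 <- kfold_cv(tr, model_spec("eq2"), k = 6, seed = 43)
  expect_false(identical(cv$pairs$predicted, cv3$pairs$predicted))
})

test_that("kfold correction uses the training-fold variance", {
  tr <- sim_trees(n = 120, seed = 15)
  cvc <- kfold_cv(tr, model_spec("eq3"), k = 4, seed = 2, correct = TRUE)
  cvu <- kfold_cv(tr, model_spec("eq3"), k = 4, seed = 2, correct = FALSE)
  ratio <- cvc$pairs$predicted / cvu$pairs$predicted
  # constant within a fold, equal to exp(sigma2_fold / 2) > 1
  by_fold <- tapply(ratio, cvc$pairs$unit, function(x) diff(range(x)))
  expect_true(all(by_fold < 1e-12))
  expect_true(all(ratio > 1))
  # and the fold factors differ across folds (training sets differ)
  expect_gt(diff(range(tapply(ratio, cvc$pairs$unit, mean))), 0)
})

test_that("kfold errors when a training fold misses a crown class", {
  tr <- sim_trees(n = 60, seed = 16)
  tr$cc <- "codominant"
  tr$cc[1] <- "open_grown"   # a single open-grown tree
  expect_error(kfold_cv(tr, model_spec("eq2"), k = 60, seed = 1),
               "stratify|crown class")
})

test_that("loso_cv refits once per species and predicts every record", {
  # 3-species toy set: exactly 3 refits, each excluding one species. Species
  # traits are constant within species, so a spec without trait terms is
  # needed for 2-species training sets to stay full rank.
  toy <- sim_trees(n = 90, seed = 17, pool_n = 3)
  cv3 <- loso_cv(toy, model_spec("eq4"))
  expect_equal(nrow(cv3$per_unit), 3)
  expect_setequal(cv3$per_unit$unit, unique(toy$species))
  expect_equal(nrow(cv3$pairs), nrow(toy))

  tr <- sim_trees(n = 240, seed = 17, pool_n = 6)
  cv <- loso_cv(tr, model_spec("eq2"))
  expect_equal(nrow(cv$per_unit), length(unique(tr$species)))
  expect_equal(nrow(cv$pairs), nrow(tr))
  expect_true(all(c("mean_error", "mpe", "mape") %in% names(cv$per_unit)))
  # a species with N = 1 still yields a held-out prediction
  one <- attach_traits(data.frame(species = "Ilex opaca", dbh = 18.8,
                                  lcr = 0.48, cc = "codominant", sg_obs = 0.47,
                                  leaf_mass = 3.81, mat = 15, map = 1300,
                                  tree_id = "x", study_id = "s"))
  tr2 <- rbind(tr[names(tr)], one[names(tr)])
  cv2 <- loso_cv(tr2, model_spec("eq2"))
  expect_true("Ilex opaca" %in% cv2$per_unit$unit)
  expect_equal(cv2$per_unit$n[cv2$per_unit$unit == "Ilex opaca"], 1)
  expect_error(loso_cv(tr[tr$species == tr$species[1], ], model_spec("eq2")),
               "2 species")
})

test_that("a species-level mass offset shows up as signed LOSO error", {
  tr <- sim_trees(n = 500, seed = 18)
  sp <- names(sort(table(tr$species), decreasing = TRUE))[1]
  tr$leaf_mass[tr$species == sp] <- tr$leaf_mass[tr$species == sp] * 3
  cv <- loso_cv(tr, model_spec("eq2"))
  # held-out predictions can't see the offset -> underestimation (negative MPE)
  expect_lt(cv$per_unit$mpe[cv$per_unit$unit == sp], 0)
})

test_that("logo_cv generalizes loso and validates its group field", {
  tr <- sim_trees(n = 240, seed = 19, pool_n = 6)
  loso <- loso_cv(tr, model_spec("eq2"))
  logo <- logo_cv(tr, model_spec("eq2"), group_field = "species")
  expect_equal(logo$pairs$predicted, loso$pairs$predicted)
  expect_equal(logo$pooled$mape, loso$pooled$mape)
  # one row per group label, one refit per group
  bysite <- logo_cv(tr, model_spec("eq2"), group_field = "study_id")
  expect_equal(sort(unique(bysite$per_unit$unit)), sort(unique(tr$study_id)))
  expect_error(logo_cv(tr, model_spec("eq2"), group_field = "nope"),
               "not present")
})

test_that("error_distribution matches a sort-based oracle and flags skew", {
  set.seed(20)
  a <- stats::rlnorm(100)
  p <- a * stats::rlnorm(100, 0, 0.5)
  ed <- error_distribution(a, p)
  e <- 100 * (p - a) / a
  expect_equal(ed$errors_pct, e)
  expect_equal(ed$median, sort(e)[50:51][1] / 2 + sort(e)[50:51][2] / 2)
  # symmetric errors: median ~ mean
  sym <- error_distribution(rep(10, 101), 10 + seq(-1, 1, length.out = 101))
  expect_equal(sym$median, sym$mean, tolerance = 1e-9)
  # one huge overestimate among near-zero errors: mean >> median
  skewed <- error_distribution(rep(1, 50), c(rep(1.01, 49), 30))
  expect_gt(skewed$mean, skewed$median + 10)
  expect_gt(skewed$skewness, 1)
})
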