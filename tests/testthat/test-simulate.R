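test_that("generators are deterministic under their seed", {
  s1 <- gen_wellbeing_items(wellbeing_sim_spec(50, seed = 41))
  s2 <- gen_wellbeing_items(wellbeing_sim_spec(50, seed = 41))
  expect_identical(s1$responses, s2$responses)
  s3 <- gen_wellbeing_items(wellbeing_sim_spec(50, seed = 42))
  expect_false(identical(s1$responses, s3$responses))

  c1 <- gen_covariates(30, seed = 41)
  c2 <- gen_covariates(30, seed = 41)
  expect_identical(c1, c2)

  gs <- load_gene_set(exclude = "IL6")
  sc <- score_mhcsf(s1)
  cv <- gen_covariates(50, seed = 43)
  e1 <- gen_expression(expression_sim_spec(gs, seed = 44), sc, cv)
  e2 <- gen_expression(expression_sim_spec(gs, seed = 44), sc, cv)
  expect_identical(unclass(e1)[, ], unclass(e2)[, ])
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(gen_wellbeing_items(wellbeing_sim_spec(10, seed = 1)))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero loadings give independent items with near-zero alpha", {
  spec <- wellbeing_sim_spec(5000, loadings = 0, seed = 45)
  it <- gen_wellbeing_items(spec)
  R <- it$responses
  cors <- cor(R)[lower.tri(diag(14))]
  expect_lt(max(abs(cors)), 0.05)
  expect_lt(abs(cronbach_alpha(R[, 1:3])), 0.05)
})

test_that("scored correlation tracks the closed-form attenuation oracle", {
  Phi <- matrix(c(1, 0.74, 0.74, 1), 2, 2)
  spec <- wellbeing_sim_spec(5000, factor_model = 2, loadings = 0.8,
                             factor_correlations = Phi, seed = 46)
  sc <- score_mhcsf(gen_wellbeing_items(spec))
  implied <- oracle_scale_cor(lam = 0.8, phi = 0.74, k1 = 3, k2 = 11)
  expect_lt(abs(cor(sc$hedonic, sc$eudaimonic) - implied), 0.05)
})

test_that("non-PSD factor correlations are rejected with a diagnostic", {
  Phi <- matrix(c(1, 0.95, -0.95, 0.95, 1, 0.95, -0.95, 0.95, 1), 3, 3)
  spec <- wellbeing_sim_spec(100, factor_correlations = Phi, seed = 47)
  expect_error(gen_wellbeing_items(spec), "positive semi-definite")
})

test_that("moment fidelity at the confirmation-study conditions", {
  it <- gen_wellbeing_items(wellbeing_sim_spec(4000, seed = 48))
  sc <- score_mhcsf(it)
  R <- it$responses
  map <- mhcsf_item_map()
  expect_lt(abs(cor(sc$hedonic, sc$eudaimonic) - 0.74), 0.05)
  expect_lt(abs(cor(sc$psychological, sc$social) - 0.80), 0.05)
  expect_lt(abs(cronbach_alpha(R[, map$scale == "hedonic"]) - 0.87), 0.04)
  expect_lt(abs(cronbach_alpha(R[, map$scale != "hedonic"]) - 0.92), 0.03)
  expect_lt(abs(mean(sc$hedonic) - 3.63), 0.12)
  expect_lt(abs(mean(sc$eudaimonic) - 3.08), 0.12)
  prop <- sign_test_predominance(sc)$proportion
  expect_lt(abs(prop - 0.22), 0.05)
})

test_that("Ryff generator reproduces scale means and reliabilities", {
  it <- gen_wellbeing_items(wellbeing_sim_spec(3000, instrument = "Ryff-PWB",
                                               seed = 49))
  sc <- score_ryff(it)
  expect_lt(abs(mean(sc$purpose_in_life) - 43.2), 1.5)
  expect_lt(abs(mean(sc$autonomy) - 38.6), 1.5)
  # reverse-keyed items must correlate with their scale after re-keying
  map <- ryff_item_map()
  R <- it$responses
  R[, map$item[map$reverse]] <- 7 - R[, map$item[map$reverse]]
  a <- cronbach_alpha(R[, map$scale == "self_acceptance"])
  expect_lt(abs(a - 0.82), 0.06)
})

test_that("covariate generator matches the sampled population profile", {
  cv <- gen_covariates(122, seed = 50)
  expect_lt(abs(mean(cv$age) - 48.4), 3)
  expect_true(all(cv$age >= 35 & cv$age <= 64))
  expect_true(all(cv$illness_symptoms >= 0 & cv$illness_symptoms <= 8))
  expect_setequal(unique(cv$sex), c("female", "male"))
  one <- gen_covariates(1, seed = 51)
  expect_equal(nrow(one), 1)
  expect_error(gen_covariates(0), ">= 1")
  miss <- gen_covariates(500, seed = 52, missing_rate = 0.1)
  expect_gt(sum(is.na(miss$bmi)), 0)
})

test_that("null expression structure has near-zero residual correlations", {
  gs <- load_gene_set(exclude = "IL6")
  sc <- score_mhcsf(gen_wellbeing_items(wellbeing_sim_spec(2000, seed = 53)))
  cv <- gen_covariates(2000, seed = 54)
  spec <- expression_sim_spec(gs, b_true = c(eudaimonic = 0), sigma_g = 1,
                              rho = 0, seed = 55)
  ex <- gen_expression(spec, sc, cv)
  lg <- log2(ex[gs$symbol, ])
  cors <- cor(t(lg))[lower.tri(diag(52))]
  expect_lt(mean(abs(cors)), 0.05)
})

test_that("within-subject residual correlation matches rho", {
  gs <- load_gene_set(exclude = "IL6")
  sc <- score_mhcsf(gen_wellbeing_items(wellbeing_sim_spec(2000, seed = 56)))
  cv <- gen_covariates(2000, seed = 57)
  spec <- expression_sim_spec(gs, b_true = c(eudaimonic = 0), sigma_g = 1,
                              rho = 0.3, seed = 58)
  ex <- gen_expression(spec, sc, cv)
  lg <- log2(ex[gs$symbol, ])
  # noise is attached behind the gene's contrast sign, so re-align first
  lg <- lg * gs$sign
  cors <- cor(t(lg))[lower.tri(diag(52))]
  expect_lt(abs(mean(cors) - 0.3), 0.03)
})

test_that("per-gene variance equals sigma_g despite the embedded signal", {
  gs <- load_gene_set(exclude = "IL6")
  sc <- score_mhcsf(gen_wellbeing_items(wellbeing_sim_spec(3000, seed = 59)))
  cv <- gen_covariates(3000, seed = 60)
  spec <- expression_sim_spec(gs, b_true = c(eudaimonic = -0.5), sigma_g = 1,
                              rho = 0.1, seed = 61)
  ex <- gen_expression(spec, sc, cv)
  sds <- apply(log2(ex[gs$symbol, ]), 1, sd)
  expect_lt(max(abs(sds - 1)), 0.08)
})

test_that("study bundle round-trips through the package readers", {
  dir <- withr::local_tempdir()
  paths <- gen_study_bundle(dir, n_subjects = 25, seed = 62,
                            exclude_genes = "IL6")
  expect_true(all(file.exists(paths)))
  ex <- read_expression_tsv(paths["expression"])
  expect_equal(nrow(ex), 52 + 8)
  it <- read_phenotypes(paths["items"], "items")
  cv <- read_phenotypes(paths["covariates"], "covariates")
  expect_equal(nrow(it$responses), 25)
  expect_equal(nrow(cv), 25)
  # regenerate: identical files under the same seed
  dir2 <- withr::local_tempdir()
  paths2 <- gen_study_bundle(dir2, n_subjects = 25, seed = 62,
                             exclude_genes = "IL6")
  for (k in names(paths)) {
    expect_identical(readLines(paths[k]), readLines(paths2[k]))
  }
  # round-trip: reader output equals in-memory generator output
  direct <- gen_expression(
    expression_sim_spec(load_gene_set(exclude = "IL6"), seed = 62 + 2L),
    score_mhcsf(gen_wellbeing_items(wellbeing_sim_spec(25, seed = 62))),
    gen_covariates(25, seed = 62 + 1L))
  expect_equal(ex, unclass(direct)[, ], tolerance = 1e-6)
})
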