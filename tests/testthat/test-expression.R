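toy_matrix <- function(vals, genes, subjects) {
  expression_matrix(matrix(vals, length(genes), length(subjects),
                           dimnames = list(genes, subjects)))
}

test_that("quantile normalization equals hand-computed rank-mean on a 3x3 toy", {
  x <- toy_matrix(c(2, 4, 6,
                    1, 9, 5,
                    3, 8, 7), c("a", "b", "c"), c("s1", "s2", "s3"))
  qn <- quantile_normalize(x)
  # reference distribution: means of column-sorted values
  ref <- rowMeans(apply(unclass(x), 2, sort))
  expect_equal(sort(qn[, 1]), ref, ignore_attr = TRUE)
  expect_equal(sort(qn[, 2]), ref, ignore_attr = TRUE)
  expect_equal(sort(qn[, 3]), ref, ignore_attr = TRUE)
  # within-column ranks preserved
  for (j in 1:3) expect_equal(order(qn[, j]), order(x[, j]))
  # hand computation: sorted columns (2,4,6),(1,5,9),(3,7,8) -> ref (2,16/3,23/3)
  expect_equal(ref, c(2, 16 / 3, 23 / 3))
})

test_that("quantile normalization fixes identical-distribution input", {
  x <- toy_matrix(c(1, 5, 9, 9, 1, 5, 5, 9, 1), letters[1:3], paste0("s", 1:3))
  expect_equal(unclass(quantile_normalize(x))[, ],
               unclass(x)[, ], tolerance = 1e-12)
})

test_that("quantile normalization rejects incomplete input", {
  x <- toy_matrix(c(1, NA, 3, 4), c("a", "b"), c("s1", "s2"))
  expect_error(quantile_normalize(x), "complete")
})

test_that("gene standardization matches hand-computed z-scores", {
  x <- expression_matrix(matrix(c(1, 2, 3, 4,
                                  10, 20, 40, 30), 2, 4, byrow = TRUE,
                                dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
                         value_space = "log2")
  z <- standardize_genes(x)
  manual <- t(apply(matrix(c(1, 2, 3, 4, 10, 20, 40, 30), 2, 4, byrow = TRUE),
                    1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(unclass(z)[, ], manual, ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 1, sd)), c(1, 1))
})

test_that("standardization is location-invariant and honors scale_sd = FALSE", {
  x <- expression_matrix(matrix(rnorm(20), 4, 5,
                                dimnames = list(paste0("g", 1:4), paste0("s", 1:5))),
                         value_space = "log2")
  shifted <- expression_matrix(unclass(x) + 7, value_space = "log2")
  expect_equal(unclass(standardize_genes(x))[, ],
               unclass(standardize_genes(shifted))[, ])
  z <- standardize_genes(x, scale_sd = FALSE)
  expect_equal(unname(apply(z, 1, sd)), unname(apply(x, 1, sd)))
  flat <- expression_matrix(rbind(unclass(x), gflat = rep(1, 5)),
                            value_space = "log2")
  expect_error(standardize_genes(flat), "gflat")
})

test_that("sign adjustment negates exactly the negative-sign rows, once", {
  gs <- data.frame(symbol = c("g1", "g2", "g3"), sign = c(1, -1, 1),
                   category = "x")
  x <- toy_matrix(rnorm(9), c("g1", "g2", "g3"), paste0("s", 1:3))
  adj <- sign_adjust(x, gs)
  expect_equal(adj["g1", ], x["g1", ])
  expect_equal(adj["g2", ], -x["g2", ])
  expect_equal(adj["g3", ], x["g3", ])
  expect_error(sign_adjust(adj, gs), "already")
  back <- sign_adjust(adj, gs, force = TRUE)
  expect_equal(unclass(back)[, ], unclass(x)[, ])
  # all-positive set: identity
  gs_pos <- transform(gs, sign = 1)
  expect_equal(unclass(sign_adjust(x, gs_pos))[, ], unclass(x)[, ])
})

test_that("sign adjustment commutes with SD-standardization", {
  gs <- load_gene_set(exclude = "IL6")
  set.seed(4)
  x <- expression_matrix(matrix(rnorm(52 * 20, 8), 52, 20,
                                dimnames = list(gs$symbol, paste0("s", 1:20))),
                         value_space = "log2")
  a <- sign_adjust(standardize_genes(x), gs)
  b <- standardize_genes(
    expression_matrix(unclass(sign_adjust(x, gs)), value_space = "log2"))
  expect_lt(max(abs(unclass(a) - unclass(b))), 1e-12)
})

test_that("marker covariates extract exactly the 8 marker rows", {
  mk <- default_marker_transcripts()
  genes <- c("IL1B", unname(mk))
  x <- toy_matrix(seq_len(9 * 4), genes, paste0("s", 1:4))
  tab <- marker_covariates(x)
  expect_equal(names(tab), c("subject_id", unname(mk)))
  expect_equal(tab$CD14, unname(x["CD14", ]))
  expect_error(marker_covariates(x, mk[1:7]), "exactly 8")
  x2 <- toy_matrix(1:8, c("IL1B", "IL8"), paste0("s", 1:4))
  expect_error(marker_covariates(x2), "absent")
})

test_that("long-format assembly is complete-case, ordered and invertible", {
  gs <- load_gene_set(exclude = "IL6")
  set.seed(5)
  n <- 122
  x <- expression_matrix(matrix(rnorm(52 * n), 52, n,
                                dimnames = list(gs$symbol, sprintf("S%03d", 1:n))),
                         value_space = "log2")
  covs <- data.frame(subject_id = sprintf("S%03d", 1:n), bmi = rnorm(n),
                     age = rnorm(n))
  long <- to_long_format(x, gs, covs)
  expect_equal(nrow(long), 52 * 122)    # 6344 rows
  expect_equal(attr(long, "n_dropped"), 0)
  expect_equal(unclass(long_to_wide(long))[, ], unclass(x)[, ])

  covs$bmi[7] <- NA
  expect_message(long2 <- to_long_format(x, gs, covs), "121 of 122")
  expect_equal(nrow(long2), 52 * 121)
  expect_false(covs$subject_id[7] %in% long2$subject_id)
  expect_equal(attr(long2, "n_dropped"), 1)
})

test_that("prepared response keeps markers disjoint from CTRA rows", {
  gs <- load_gene_set(exclude = "IL6")
  sc <- score_mhcsf(gen_wellbeing_items(wellbeing_sim_spec(40, seed = 6)))
  cv <- gen_covariates(40, seed = 7)
  ex <- gen_expression(expression_sim_spec(gs, seed = 8), sc, cv)
  prep <- prepare_ctra_response(ex, gs, merge(sc["subject_id"], cv,
                                              by = "subject_id"),
                                quantile = FALSE)
  expect_length(intersect(rownames(prep$matrix),
                          setdiff(names(prep$markers), "subject_id")), 0)
  expect_equal(sort(unique(prep$long$gene)), sort(gs$symbol))
})
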