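# One synthetic confirmation-scale study (52-gene panel, n = 122, MHC-SF
# 2-d analysis with the full covariate set) fitted end to end. With
# `pipeline = TRUE` the raw matrix runs through the standard preparation
# (log2, sample standardization, sign adjustment); with `pipeline = FALSE`
# the response is assembled on the model's own scale (centered log2 divided
# by the known generating SD, sign-aligned), i.e. data that satisfy the
# fitted model's assumptions exactly — the right substrate for testing the
# estimator's calibration in isolation from preparation noise.
confirmation_fit <- function(seed, b_true = c(eudaimonic = -0.5),
                             n = 122, rho = 0.30, pipeline = TRUE,
                             method = "reml") {
  gs <- load_gene_set(exclude = "IL6")
  mk <- unname(default_marker_transcripts())
  sc <- score_mhcsf(gen_wellbeing_items(wellbeing_sim_spec(n, seed = seed)))
  cv <- gen_covariates(n, seed = seed + 500000L)
  cv$sex_female <- as.integer(cv$sex == "female")
  es <- expression_sim_spec(gs, b_true = b_true, rho = rho,
                            seed = seed + 1000000L)
  ex <- gen_expression(es, sc, cv)
  pred <- merge(cv[c("subject_id", "age", "sex_female", "race_white", "bmi",
                     "smoking", "alcohol", "illness_symptoms")],
                sc[c("subject_id", "hedonic", "eudaimonic")],
                by = "subject_id")
  if (pipeline) {
    prep <- suppressMessages(prepare_ctra_response(ex, gs, pred,
                                                   quantile = FALSE))
    long <- prep$long
  } else {
    lg <- log2(ex[gs$symbol, ])
    lg <- (lg - rowMeans(lg)) / es$sigma_g * gs$sign
    mkv <- t(log2(ex[mk, ]))
    pred <- cbind(pred, mkv[match(pred$subject_id, rownames(mkv)), ])
    long <- to_long_format(expression_matrix(lg, "standardized"), gs, pred)
  }
  suppressMessages(fit_ctra_model(
    long,
    c("hedonic", "eudaimonic", "age", "sex_female", "race_white", "bmi",
      "smoking", "alcohol", "illness_symptoms", mk),
    method = method, n_starts = 1))
}
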