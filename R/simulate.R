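#' Run code with a private, reproducible RNG state
#'
#' All generators route randomness through this helper: the global RNG state
#' is saved, the given seed applied, and the previous state restored on exit,
#' so generators are deterministic under their `seed` argument and do not
#' disturb user code.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulation layout for well-being item responses
#'
#' Defines a factor-structured latent model for instrument items: each item
#' loads on exactly one factor, factors are correlated, and discrete
#' responses arise by rounding a located/scaled latent Gaussian to the
#' instrument's integer range. Defaults reproduce the confirmation-study
#' conditions: scale reliabilities around .82-.93, a hedonic-eudaimonic
#' scale correlation near .74 and a psychological-social correlation near
#' .80, with scale means/SDs matching the reported sample
#' (hedonic 3.63 (1.08), psychological 3.40 (1.11), social 2.70 (1.14)).
#'
#' @param n_subjects Number of subjects.
#' @param instrument `"MHC-SF"` or `"Ryff-PWB"`.
#' @param factor_model For the MHC-SF: 1, 2 or 3 factors (3 = hedonic /
#'   psychological / social; 2 pools psychological + social into one
#'   eudaimonic factor; 1 = a single well-being factor). Ryff always uses
#'   its 6-factor layout.
#' @param loadings Optional per-item loadings in (0, 1) overriding the
#'   calibrated defaults (named by item or a single value).
#' @param factor_correlations Optional symmetric PSD correlation matrix for
#'   the factors (unit diagonal) overriding defaults.
#' @param mixture_prop Proportion of subjects drawn from a second
#'   subpopulation whose eudaimonic factors are shifted down by
#'   `mixture_shift` latent SD (hedonic > eudaimonic profile). Off by
#'   default; the subpopulation's parameters are not identified by the
#'   reported moments.
#' @param mixture_shift Latent downward shift for the mixture component.
#' @param seed Integer seed.
#' @return A `wellbeing_sim_spec` list.
#' @export
wellbeing_sim_spec <- function(n_subjects, instrument = c("MHC-SF", "Ryff-PWB"),
                               factor_model = 3, loadings = NULL,
                               factor_correlations = NULL,
                               mixture_prop = 0, mixture_shift = 1,
                               seed = 1L) {
  instrument <- match.arg(instrument)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (instrument == "MHC-SF") {
    stopifnot(factor_model %in% 1:3)
    map <- mhcsf_item_map()
    # calibrated so discretized items reproduce alphas .87/.89/.82 (hedonic/
    # psychological/social), .92 (11-item eudaimonic) and scored correlations
    # r(hed, eud) ~ .74, r(psych, soc) ~ .80
    lam3 <- c(hedonic = 0.852, psychological = 0.777, social = 0.709)
    mu <- c(hedonic = 3.63, psychological = 3.40, social = 2.70)
    ssd <- c(hedonic = 1.08, psychological = 1.11, social = 1.14)
    if (factor_model == 3) {
      fac <- map$scale
      Phi <- matrix(c(1, .827, .827,
                      .827, 1, .937,
                      .827, .937, 1), 3, 3,
                    dimnames = rep(list(c("hedonic", "psychological", "social")), 2))
      lam <- lam3[map$scale]
    } else if (factor_model == 2) {
      fac <- ifelse(map$scale == "hedonic", "hedonic", "eudaimonic")
      Phi <- matrix(c(1, .827, .827, 1), 2, 2,
                    dimnames = rep(list(c("hedonic", "eudaimonic")), 2))
      lam <- ifelse(map$scale == "hedonic", lam3["hedonic"], 0.733)
    } else {
      fac <- rep("wellbeing", 14)
      Phi <- matrix(1, 1, 1, dimnames = rep(list("wellbeing"), 2))
      lam <- ifelse(map$scale == "hedonic", 0.75, 0.72)
    }
    k <- table(map$scale)[map$scale]
    rbar <- lam3[map$scale]^2
    layout <- data.frame(
      item = map$item, factor = fac, loading = unname(lam),
      mu = unname(mu[map$scale]),
      sigma = unname(ssd[map$scale] * sqrt(as.numeric(k) / (1 + (as.numeric(k) - 1) * rbar))),
      reverse = FALSE, stringsAsFactors = FALSE
    )
    scale_range <- c(0, 5)
    eud_factors <- setdiff(unique(fac), "hedonic")
  } else {
    map <- ryff_item_map()
    scales <- unique(map$scale)
    # loadings back-solved from reported alphas .67/.78/.82/.81/.82/.83
    lam6 <- c(purpose_in_life = 0.44, environmental_mastery = 0.55,
              self_acceptance = 0.60, autonomy = 0.58,
              personal_growth = 0.60, positive_relations = 0.61)
    mus <- c(purpose_in_life = 43.2, environmental_mastery = 41.9,
             self_acceptance = 41.9, autonomy = 38.6,
             personal_growth = 43.6, positive_relations = 43.8) / 9
    ssd <- c(purpose_in_life = 6.2, environmental_mastery = 6.5,
             self_acceptance = 7.3, autonomy = 7.2,
             personal_growth = 6.8, positive_relations = 7.7)
    rbar <- lam6[map$scale]^2
    layout <- data.frame(
      item = map$item, factor = map$scale, loading = unname(lam6[map$scale]),
      mu = unname(mus[map$scale]),
      sigma = unname(ssd[map$scale] / sqrt(9 + 72 * rbar)),
      reverse = map$reverse, stringsAsFactors = FALSE
    )
    Phi <- matrix(0.62, 6, 6, dimnames = list(scales, scales))
    diag(Phi) <- 1
    scale_range <- c(1, 6)
    eud_factors <- scales
  }
  if (!is.null(loadings)) {
    layout$loading <- if (length(loadings) == 1L) rep(loadings, nrow(layout)) else {
      stopifnot(length(loadings) == nrow(layout)); loadings
    }
  }
  if (!is.null(factor_correlations)) {
    stopifnot(nrow(factor_correlations) == nrow(Phi))
    dimnames(factor_correlations) <- dimnames(Phi)
    Phi <- factor_correlations
  }
  if (any(layout$loading < 0 | layout$loading >= 1)) {
    stop("loadings must lie in [0, 1)")
  }
  spec <- list(n_subjects = n_subjects, instrument = instrument,
               factor_model = if (instrument == "MHC-SF") factor_model else 6,
               layout = layout, Phi = Phi, scale_range = scale_range,
               eud_factors = eud_factors,
               mixture_prop = mixture_prop, mixture_shift = mixture_shift,
               seed = seed)
  class(spec) <- "wellbeing_sim_spec"
  spec
}

check_psd <- function(Phi, what = "factor_correlations") {
  if (any(abs(diag(Phi) - 1) > 1e-12)) stop(what, " must have unit diagonal")
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                 what, min(ev)))
  }
  invisible(TRUE)
}

#' Generate well-being item responses
#'
#' Draws correlated factor scores, builds latent item values
#' `mu + sigma * (loading * eta + sqrt(1 - loading^2) * noise)`, and
#' discretizes by rounding into the instrument's integer range. Reverse-keyed
#' Ryff items are emitted reversed so that standard scoring recovers them.
#'
#' @param spec A [wellbeing_sim_spec()].
#' @return An [item_matrix()].
#' @export
gen_wellbeing_items <- function(spec) {
  stopifnot(inherits(spec, "wellbeing_sim_spec"))
  check_psd(spec$Phi)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    q <- nrow(spec$Phi)
    eta <- MASS::mvrnorm(n, mu = rep(0, q), Sigma = spec$Phi)
    eta <- matrix(eta, n, q, dimnames = list(NULL, rownames(spec$Phi)))
    if (spec$mixture_prop > 0) {
      grp <- stats::runif(n) < spec$mixture_prop
      eta[grp, spec$eud_factors] <- eta[grp, spec$eud_factors] - spec$mixture_shift
    }
    lay <- spec$layout
    R <- matrix(NA_real_, n, nrow(lay),
                dimnames = list(sprintf("S%03d", seq_len(n)), lay$item))
    for (j in seq_len(nrow(lay))) {
      l <- lay$loading[j]
      latent <- lay$mu[j] + lay$sigma[j] *
        (l * eta[, lay$factor[j]] + sqrt(1 - l^2) * stats::rnorm(n))
      v <- pmin(spec$scale_range[2], pmax(spec$scale_range[1], round(latent)))
      if (isTRUE(lay$reverse[j])) v <- 7 - v
      R[, j] <- v
    }
    item_matrix(R, instrument = spec$instrument)
  })
}

#' Generate subject covariates
#'
#' Demographic and behavioral covariates patterned on the confirmation
#' sample: age ~ N(48.4, 8.8) truncated to 35-64, 60% female, 76% white,
#' BMI ~ N(27.4, 6.2) truncated to 16-50, 3.3% smokers, 74.6% alcohol
#' consumers, illness symptoms ~ Gamma matched to mean 1.05 / SD 0.9 on the
#' 0-8 scale, CES-D depressive symptoms ~ N(12.5, 9.4) truncated to 0-60.
#' Covariates are generated independently of well-being.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param missing_rate MCAR missingness rate applied to BMI, alcohol and
#'   illness symptoms (exercises complete-case handling downstream).
#' @return Data frame with `subject_id`, `age`, `sex`, `race`, `race_white`,
#'   `bmi`, `smoking`, `alcohol`, `illness_symptoms`, `cesd`.
#' @export
gen_covariates <- function(n, seed = 1L, missing_rate = 0) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    rtnorm <- function(n, mu, sd, lo, hi) {
      u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
      stats::qnorm(u, mu, sd)
    }
    age <- round(rtnorm(n, 48.4, 8.8, 35, 64), 1)
    sex <- ifelse(stats::runif(n) < 0.60, "female", "male")
    race <- sample(c("white", "black", "hispanic", "asian"), n, replace = TRUE,
                   prob = c(0.761, 0.154, 0.026, 0.059))
    bmi <- round(rtnorm(n, 27.4, 6.2, 16, 50), 1)
    smoking <- as.integer(stats::runif(n) < 0.033)
    alcohol <- as.integer(stats::runif(n) < 0.746)
    ill <- pmin(8, round(stats::rgamma(n, shape = (1.05 / 0.9)^2,
                                       rate = 1.05 / 0.9^2), 1))
    cesd <- round(pmin(60, pmax(0, stats::rnorm(n, 12.5, 9.4))))
    out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      age = age, sex = sex, race = race,
                      race_white = as.integer(race == "white"),
                      bmi = bmi, smoking = smoking, alcohol = alcohol,
                      illness_symptoms = ill, cesd = cesd,
                      stringsAsFactors = FALSE)
    if (missing_rate > 0) {
      for (col in c("bmi", "alcohol", "illness_symptoms")) {
        out[[col]][stats::runif(n) < missing_rate] <- NA
      }
    }
    out
  })
}

#' Simulation settings for CTRA expression
#'
#' Ground-truth data model for the gene-by-subject matrix: for gene g and
#' subject i,
#' `y_gi = mu_g + sigma_g * sign_g * (x_i' b_true + e_gi)` on the log2 scale,
#' with `e_i` mean-zero, unit-variance noise under a heterogeneous
#' compound-symmetry correlation (common within-subject correlation `rho`).
#' Noise is scaled by `sqrt(1 - var(x'b))` so each gene's total variance is
#' `sigma_g^2` and `b_true` is expressed directly in SD-of-standardized-
#' expression per SD-of-predictor units — the scale on which pooled
#' association coefficients are reported.
#'
#' @param gene_set A [load_gene_set()] result.
#' @param b_true Named vector of true effects for score columns
#'   (e.g. `c(eudaimonic = -0.5, hedonic = 0)`).
#' @param covariate_effects Named vector of effects for covariate columns
#'   (defaults to none).
#' @param sigma_g Per-gene residual SD; a single value is recycled; default
#'   is a deterministic heterogeneous profile in [0.67, 1.49].
#' @param rho Common within-subject residual correlation,
#'   in (-1/(G-1), 1); default 0.30, reflecting the substantial shared
#'   variance of co-regulated inflammatory and interferon transcripts.
#' @param mu_g Per-gene baseline log2 abundance (default spread over 6-12).
#' @param marker_genes Marker transcript symbols appended as independent
#'   N(8, 1) log2 rows.
#' @param seed Integer seed.
#' @export
expression_sim_spec <- function(gene_set, b_true = c(eudaimonic = -0.5),
                                covariate_effects = NULL, sigma_g = NULL,
                                rho = 0.30, mu_g = NULL,
                                marker_genes = default_marker_transcripts(),
                                seed = 1L) {
  G <- nrow(gene_set)
  if (is.null(sigma_g)) sigma_g <- exp(seq(-0.4, 0.4, length.out = G))
  if (length(sigma_g) == 1L) sigma_g <- rep(sigma_g, G)
  stopifnot(length(sigma_g) == G, all(sigma_g > 0))
  if (rho <= -1 / (G - 1) || rho >= 1) {
    stop(sprintf("rho must lie in (%.4f, 1) for G = %d", -1 / (G - 1), G))
  }
  if (is.null(mu_g)) mu_g <- seq(6, 12, length.out = G)
  if (length(mu_g) == 1L) mu_g <- rep(mu_g, G)
  structure(list(gene_set = gene_set, b_true = b_true,
                 covariate_effects = covariate_effects, sigma_g = sigma_g,
                 rho = rho, mu_g = mu_g,
                 marker_genes = unname(marker_genes), seed = seed),
            class = "expression_sim_spec")
}

#' Generate a CTRA expression matrix with known ground truth
#'
#' @param spec An [expression_sim_spec()].
#' @param scores Well-being scores data frame (needs `subject_id` and the
#'   columns named in `spec$b_true`).
#' @param covariates Covariate data frame (needs `subject_id` and any
#'   columns named in `spec$covariate_effects`).
#' @return Raw-intensity matrix (`2^log2`), CTRA genes plus 8 marker rows,
#'   subjects in columns; attribute `truth` records the generating
#'   parameters.
#' @export
gen_expression <- function(spec, scores, covariates) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (!identical(sort(scores$subject_id), sort(covariates$subject_id))) {
    stop("scores and covariates must cover the same subjects")
  }
  covariates <- covariates[match(scores$subject_id, covariates$subject_id), ]
  eff <- c(spec$b_true, spec$covariate_effects)
  pred <- cbind(as.matrix(scores[names(spec$b_true)]),
                if (length(spec$covariate_effects)) {
                  as.matrix(covariates[names(spec$covariate_effects)])
                })
  if (anyNA(pred)) stop("predictors used for simulation contain NA")
  n <- nrow(pred)
  Xs <- scale(pred)
  lin <- as.vector(Xs %*% eff)
  v <- if (n > 1) stats::var(lin) * (n - 1) / n else 0
  if (v >= 1) stop("b_true implies predictor variance share >= 1; reduce effects")
  gs <- spec$gene_set
  G <- nrow(gs)
  with_seed(spec$seed, {
    M <- matrix(spec$rho, G, G); diag(M) <- 1
    L <- chol(M)
    E <- t(matrix(stats::rnorm(n * G), n, G) %*% L)  # G x n, unit variance, HCS corr
    signal <- matrix(lin, G, n, byrow = TRUE)
    Y <- spec$mu_g + spec$sigma_g * gs$sign * (signal + sqrt(1 - v) * E)
    dimnames(Y) <- list(gs$symbol, scores$subject_id)
    MK <- matrix(stats::rnorm(length(spec$marker_genes) * n, mean = 8, sd = 1),
                 length(spec$marker_genes), n,
                 dimnames = list(spec$marker_genes, scores$subject_id))
    out <- 2^rbind(Y, MK)
    attr(out, "truth") <- list(b_true = spec$b_true,
                               covariate_effects = spec$covariate_effects,
                               sigma_g = spec$sigma_g, rho = spec$rho,
                               var_linear = v)
    out
  })
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates items, covariates and expression under one configuration and
#' writes three plain-text files (`items.csv`, `covariates.csv`,
#' `expression.tsv`) that round-trip through the package readers.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_subjects,seed Study size and seed.
#' @param instrument,factor_model Passed to [wellbeing_sim_spec()].
#' @param b_true,rho,covariate_effects Passed to [expression_sim_spec()].
#' @param exclude_genes Genes dropped from the panel (e.g. `"IL6"` for the
#'   52-gene confirmation panel).
#' @param missing_rate Covariate MCAR rate (see [gen_covariates()]).
#' @return Named character vector of file paths (invisibly).
#' @export
gen_study_bundle <- function(out_dir, n_subjects = 122, seed = 1L,
                             instrument = "MHC-SF", factor_model = 3,
                             b_true = c(eudaimonic = -0.5), rho = 0.30,
                             covariate_effects = NULL,
                             exclude_genes = character(),
                             missing_rate = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  wspec <- wellbeing_sim_spec(n_subjects, instrument = instrument,
                              factor_model = factor_model, seed = seed)
  items <- gen_wellbeing_items(wspec)
  scores <- if (instrument == "MHC-SF") score_mhcsf(items) else score_ryff(items)
  covs <- gen_covariates(n_subjects, seed = seed + 1L,
                         missing_rate = missing_rate)
  gs <- load_gene_set(exclude = exclude_genes)
  espec <- expression_sim_spec(gs, b_true = b_true, rho = rho,
                               covariate_effects = covariate_effects,
                               seed = seed + 2L)
  expr <- gen_expression(espec, scores, covs)
  paths <- c(items = file.path(out_dir, "items.csv"),
             covariates = file.path(out_dir, "covariates.csv"),
             expression = file.path(out_dir, "expression.tsv"))
  it <- data.frame(subject_id = rownames(items$responses), items$responses,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(it, paths["items"], row.names = FALSE)
  utils::write.csv(covs, paths["covariates"], row.names = FALSE)
  et <- data.frame(symbol = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(et, paths["expression"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
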