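#' Well-being item matrices
#'
#' Container for per-subject instrument responses. The MHC-SF has 14 items
#' rated 0 ("never") to 5 ("every day"): 3 hedonic, 5 social and
#' 6 psychological well-being items. The Ryff psychological well-being
#' inventory (9-item version) has 6 scales x 9 items rated 1 ("strongly
#' disagree") to 6 ("strongly agree"), some reverse-keyed.
#'
#' @param responses Integer matrix, subjects x items; rownames are subject
#'   ids (generated when absent), colnames item ids.
#' @param instrument `"MHC-SF"` or `"Ryff-PWB"`.
#' @param item_map Data frame mapping items to scales, columns `item`,
#'   `scale` and (Ryff) `reverse`; defaults to the instrument's standard map.
#' @return An `item_matrix` object.
#' @export
item_matrix <- function(responses, instrument = c("MHC-SF", "Ryff-PWB"),
                        item_map = NULL) {
  instrument <- match.arg(instrument)
  responses <- as.matrix(responses)
  if (is.null(rownames(responses))) {
    rownames(responses) <- sprintf("S%03d", seq_len(nrow(responses)))
  }
  if (is.null(item_map)) {
    item_map <- switch(instrument,
                       "MHC-SF" = mhcsf_item_map(),
                       "Ryff-PWB" = ryff_item_map())
  }
  if (is.null(colnames(responses))) colnames(responses) <- item_map$item
  if (!setequal(colnames(responses), item_map$item)) {
    stop("response columns do not match the item map")
  }
  responses <- responses[, item_map$item, drop = FALSE]
  rng <- item_range(instrument)
  bad <- which(!is.na(responses) &
                 (responses < rng[1] | responses > rng[2] |
                    responses != round(responses)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("out-of-range response for subject %s, item %s: %s",
                 rownames(responses)[bad[1, 1]],
                 colnames(responses)[bad[1, 2]],
                 responses[bad[1, , drop = FALSE]]))
  }
  structure(list(instrument = instrument, responses = responses,
                 item_map = item_map),
            class = "item_matrix")
}

item_range <- function(instrument) {
  if (instrument == "MHC-SF") c(0, 5) else c(1, 6)
}

#' Standard MHC-SF item map (Keyes)
#'
#' Items 1-3 hedonic, 4-8 social, 9-14 psychological. The alternative 3-d
#' allocation of Brown and colleagues (2 social items moved to the
#' psychological scale) can be obtained with `variant = "brown"`; which two
#' items move is configurable.
#'
#' @param variant `"keyes"` (default) or `"brown"`.
#' @param reallocate Items moved from social to psychological under
#'   `"brown"`.
#' @export
mhcsf_item_map <- function(variant = c("keyes", "brown"),
                           reallocate = c("mhcsf_07", "mhcsf_08")) {
  variant <- match.arg(variant)
  map <- data.frame(
    item = sprintf("mhcsf_%02d", 1:14),
    scale = rep(c("hedonic", "social", "psychological"), c(3, 5, 6)),
    stringsAsFactors = FALSE
  )
  if (variant == "brown") {
    if (!all(reallocate %in% map$item[map$scale == "social"])) {
      stop("reallocated items must be social-scale items")
    }
    map$scale[map$item %in% reallocate] <- "psychological"
  }
  map
}

#' Standard Ryff item map
#'
#' Six scales of 9 items; by convention here items 3, 6 and 9 of each scale
#' are reverse-keyed (the published inventory's reverse items vary by form,
#' so the map is configurable).
#' @export
ryff_item_map <- function() {
  scales <- c("purpose_in_life", "environmental_mastery", "self_acceptance",
              "autonomy", "personal_growth", "positive_relations")
  data.frame(
    item = sprintf("ryff_%s_%d", rep(abbreviate(scales, 4), each = 9), 1:9),
    scale = rep(scales, each = 9),
    reverse = rep(c(FALSE, FALSE, TRUE), 3),
    stringsAsFactors = FALSE
  )
}

scale_items <- function(items, scale) {
  items$item_map$item[items$item_map$scale %in% scale]
}

#' Score the MHC-SF
#'
#' Produces the four representations of well-being used in CTRA analyses:
#' \describe{
#'   \item{3d}{hedonic, psychological and social scale scores (item means,
#'     range 0-5);}
#'   \item{2d}{hedonic and eudaimonic scores, the latter the mean of the 11
#'     psychological + social items;}
#'   \item{1d}{total well-being, the mean of all 14 items;}
#'   \item{categorical}{the flourishing classification
#'     (see [classify_flourishing()]).}
#' }
#' All representations are returned together; subjects missing any item are
#' scored `NA` (complete-case scoring, no imputation).
#'
#' @param items An MHC-SF [item_matrix()].
#' @return Data frame: `subject_id`, `hedonic`, `psychological`, `social`,
#'   `eudaimonic`, `total`, `flourishing`.
#' @export
score_mhcsf <- function(items) {
  stopifnot(inherits(items, "item_matrix"))
  if (items$instrument != "MHC-SF") stop("expected an MHC-SF item matrix")
  R <- items$responses
  sc <- function(cols) {
    v <- rowMeans(R[, cols, drop = FALSE])
    v  # rowMeans propagates NA, implementing complete-case scoring
  }
  hed <- sc(scale_items(items, "hedonic"))
  psy <- sc(scale_items(items, "psychological"))
  soc <- sc(scale_items(items, "social"))
  eud <- sc(scale_items(items, c("psychological", "social")))
  tot <- sc(items$item_map$item)
  data.frame(subject_id = rownames(R), hedonic = hed, psychological = psy,
             social = soc, eudaimonic = eud, total = tot,
             flourishing = classify_flourishing(items),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Categorical flourishing classification
#'
#' A subject flourishes when at least 1 of the 3 hedonic items and at least
#' 6 of the 11 eudaimonic (psychological + social) items are experienced
#' "every day" or "5-6 times a week", i.e. response >= 4 on the 0-5 scale.
#'
#' @param items An MHC-SF [item_matrix()].
#' @return Logical vector, one element per subject (`NA` when any item is
#'   missing).
#' @export
classify_flourishing <- function(items) {
  stopifnot(inherits(items, "item_matrix"))
  if (items$instrument != "MHC-SF") stop("expected an MHC-SF item matrix")
  R <- items$responses
  hed <- rowSums(R[, scale_items(items, "hedonic"), drop = FALSE] >= 4)
  eud <- rowSums(R[, scale_items(items, c("psychological", "social")),
                   drop = FALSE] >= 4)
  unname(hed >= 1 & eud >= 6)
}

#' Score the Ryff psychological well-being scales
#'
#' Reverse-keys the items flagged in the item map (response x becomes 7-x),
#' sums within each 9-item scale (range 9-54), and averages the 6 scale
#' scores into the total PWB score.
#'
#' @param items A Ryff-PWB [item_matrix()].
#' @return Data frame: `subject_id`, the 6 scale scores, `total_pwb`.
#' @export
score_ryff <- function(items) {
  stopifnot(inherits(items, "item_matrix"))
  if (items$instrument != "Ryff-PWB") stop("expected a Ryff-PWB item matrix")
  R <- items$responses
  rev <- items$item_map$item[items$item_map$reverse]
  R[, rev] <- 7 - R[, rev]
  scales <- unique(items$item_map$scale)
  out <- data.frame(subject_id = rownames(R), row.names = NULL,
                    stringsAsFactors = FALSE)
  for (s in scales) {
    out[[s]] <- rowSums(R[, scale_items(items, s), drop = FALSE])
  }
  out$total_pwb <- rowMeans(as.matrix(out[scales]))
  out
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the item sum).
#'
#' @param x Subjects x items matrix for one scale (>= 2 items, >= 3 complete
#'   subjects).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2L) stop("alpha needs at least 2 items")
  if (nrow(x) < 3L) stop("alpha needs at least 3 subjects")
  vt <- stats::var(rowSums(x))
  if (vt == 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / vt)
}

#' Bivariate association with exact-test p-value
#'
#' Pearson or point-biserial correlation (both via the product-moment
#' formula, `point_biserial` requiring a 2-level x), or the ANOVA effect
#' size r = sqrt(SS_between / SS_total) for a categorical x, with the
#' p-value from the one-way ANOVA F test.
#'
#' @param x,y Vectors of matched length (>= 3 complete pairs).
#' @param kind `"pearson"`, `"point_biserial"` or `"anova_r"`.
#' @return List: `r`, `p`, `n` (complete pairs used).
#' @export
correlate <- function(x, y, kind = c("pearson", "point_biserial", "anova_r")) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(y) == 0) stop("y is constant; correlation undefined")
  if (kind == "anova_r") {
    x <- factor(x)
    if (nlevels(x) < 2L) stop("x has fewer than 2 levels")
    fit <- stats::aov(y ~ x)
    tab <- summary(fit)[[1]]
    r <- sqrt(tab$`Sum Sq`[1] / sum(tab$`Sum Sq`))
    p <- tab$`Pr(>F)`[1]
    return(list(r = r, p = p, n = length(y)))
  }
  if (kind == "point_biserial") {
    ux <- unique(x)
    if (length(ux) != 2L) stop("point-biserial requires a 2-level x")
    x <- as.numeric(x == ux[2])
  } else {
    x <- as.numeric(x)
  }
  if (stats::var(x) == 0) stop("x is constant; correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(y))
}

#' Sign test for eudaimonic predominance
#'
#' Proportion of subjects whose eudaimonic score is at least their hedonic
#' score, with an exact two-sided binomial sign test. Ties (eudaimonic ==
#' hedonic) count toward the proportion, per the ">=" definition, but are
#' excluded from the test as is standard for sign tests.
#'
#' @param scores A [score_mhcsf()] data frame (needs `eudaimonic` and
#'   `hedonic` columns).
#' @return List: `proportion`, `p`, `n`, `n_tied`.
#' @export
sign_test_predominance <- function(scores) {
  ok <- stats::complete.cases(scores$eudaimonic, scores$hedonic)
  e <- scores$eudaimonic[ok]; h <- scores$hedonic[ok]
  if (length(e) == 0L) stop("no complete score pairs")
  prop <- mean(e >= h)
  nt <- sum(e != h)
  p <- if (nt == 0L) 1 else stats::binom.test(sum(e > h), nt, p = 0.5)$p.value
  list(proportion = prop, p = p, n = length(e), n_tied = length(e) - nt)
}
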