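#' Expression-matrix containers
#'
#' Expression matrices are plain numeric matrices (genes in rows, subjects in
#' columns) carrying two attributes: `value_space` (one of `"raw"`, `"log2"`,
#' `"standardized"`) and `quantile_normalized` (logical). The helpers below
#' move a matrix through the fixed preparation pipeline:
#' quantile-normalize -> log2 -> standardize within gene -> sign-adjust ->
#' long format.
#'
#' @param x Numeric matrix, genes x subjects.
#' @param value_space Value space of `x`.
#' @param quantile_normalized Has `x` been quantile normalized?
#' @return The matrix with container attributes set.
#' @export
expression_matrix <- function(x, value_space = c("raw", "log2", "standardized"),
                              quantile_normalized = FALSE) {
  value_space <- match.arg(value_space)
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (is.null(rownames(x))) stop("x must have gene symbols as rownames")
  if (is.null(colnames(x))) stop("x must have subject ids as colnames")
  attr(x, "value_space") <- value_space
  attr(x, "quantile_normalized") <- quantile_normalized
  x
}

value_space <- function(x) attr(x, "value_space") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile normalization across subjects
#'
#' Forces every subject column to share the cross-subject rank-mean reference
#' distribution while preserving within-column ranks (the standard microarray
#' normalization; delegated to [limma::normalizeQuantiles()]).
#'
#' @param x Expression matrix in raw value space, no missing values,
#'   at least 2 subjects.
#' @return Quantile-normalized matrix, still in raw value space.
#' @export
quantile_normalize <- function(x) {
  if (anyNA(x)) stop("quantile normalization requires a complete matrix")
  if (ncol(x) < 2L) stop("quantile normalization requires >= 2 subjects")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  expression_matrix(out, value_space = value_space(x), quantile_normalized = TRUE)
}

#' Log2 transform with a floor
#'
#' @param x Matrix in raw value space.
#' @param floor Intensities are clipped below at this value before log2
#'   (guards non-positive values); default 1 so the floor maps to 0.
#' @export
log2_transform <- function(x, floor = 1) {
  if (value_space(x) == "log2") return(x)
  out <- log2(pmax(x, floor))
  dimnames(out) <- dimnames(x)
  expression_matrix(out, value_space = "log2",
                    quantile_normalized = isTRUE(attr(x, "quantile_normalized")))
}

#' Standardize expression within gene
#'
#' Centers every gene row to mean 0; when `scale_sd` is `TRUE` also scales to
#' SD 1 (confirmation-study convention). With `scale_sd = FALSE` rows retain
#' their native log2 dispersion (generalization-study convention).
#'
#' @param x Matrix in log2 value space.
#' @param scale_sd Scale rows to unit SD?
#' @export
standardize_genes <- function(x, scale_sd = TRUE) {
  if (value_space(x) == "raw") stop("standardize log2 values, not raw intensities")
  m <- rowMeans(x)
  out <- x - m
  if (scale_sd) {
    s <- apply(x, 1L, stats::sd)
    bad <- which(s == 0)
    if (length(bad)) {
      stop("zero-variance gene(s): ", paste(rownames(x)[bad], collapse = ", "))
    }
    out <- out / s
  }
  dimnames(out) <- dimnames(x)
  out <- expression_matrix(out, value_space = "standardized",
                           quantile_normalized = isTRUE(attr(x, "quantile_normalized")))
  attr(out, "scaled_sd") <- scale_sd
  out
}

#' Sign-adjust inverse CTRA indicators
#'
#' Multiplies rows of negative-sign genes (interferon and antibody related)
#' by -1, so that larger values uniformly indicate a more adverse (CTRA-like)
#' profile. Adjustment is recorded and applying it twice is refused unless
#' `force = TRUE` (in which case it is an involution).
#'
#' @param x Expression matrix whose rownames all appear in `gene_set`.
#' @param gene_set A [load_gene_set()] result.
#' @param force Allow re-application (undo).
#' @export
sign_adjust <- function(x, gene_set, force = FALSE) {
  if (isTRUE(attr(x, "sign_adjusted")) && !force) {
    stop("matrix is already sign-adjusted (use force = TRUE to re-apply)")
  }
  idx <- match(rownames(x), gene_set$symbol)
  if (anyNA(idx)) {
    stop("genes not in gene set: ",
         paste(rownames(x)[is.na(idx)], collapse = ", "))
  }
  sgn <- gene_set$sign[idx]
  out <- x * sgn
  dimnames(out) <- dimnames(x)
  for (a in c("value_space", "quantile_normalized", "scaled_sd")) {
    attr(out, a) <- attr(x, a)
  }
  attr(out, "sign_adjusted") <- !isTRUE(attr(x, "sign_adjusted"))
  out
}

#' Extract leukocyte-marker covariate columns
#'
#' Pulls the 8 marker transcript rows out of the full expression matrix as
#' subject-level covariates (log2 values), for adjustment of leukocyte subset
#' prevalence.
#'
#' @param x Full (log2) expression matrix including marker rows.
#' @param markers Character vector of exactly 8 marker symbols.
#' @return Data frame: subject_id plus one column per marker.
#' @export
marker_covariates <- function(x, markers = default_marker_transcripts()) {
  markers <- unname(markers)
  if (length(markers) != 8L) stop("exactly 8 marker transcripts required")
  absent <- setdiff(markers, rownames(x))
  if (length(absent)) {
    stop("marker transcript(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  }
  out <- as.data.frame(t(x[markers, , drop = FALSE]))
  data.frame(subject_id = colnames(x), out, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the long-format repeated-measures response
#'
#' Joins the prepared (standardized, sign-adjusted) CTRA response matrix to
#' subject-level predictors, one row per subject x gene, keeping complete
#' cases only. Subjects missing any predictor are dropped and the attrition
#' is recorded in the `n_dropped` attribute and a message.
#'
#' @param x Prepared response matrix (genes x subjects).
#' @param gene_set Gene set whose symbols must cover `rownames(x)`.
#' @param predictors Data frame with `subject_id` and predictor columns.
#' @return Data frame with columns `subject_id`, `gene`, `value`, plus
#'   predictors; exactly `nrow(x)` rows per retained subject, ordered by
#'   subject then gene.
#' @export
to_long_format <- function(x, gene_set, predictors) {
  if (!"subject_id" %in% names(predictors)) stop("predictors need subject_id")
  if (!all(rownames(x) %in% gene_set$symbol)) {
    stop("response rows not covered by gene set")
  }
  predictors <- predictors[match(colnames(x), predictors$subject_id), , drop = FALSE]
  if (anyNA(predictors$subject_id)) {
    stop("expression subjects missing from predictor table")
  }
  complete <- stats::complete.cases(predictors)
  n_in <- ncol(x)
  keep <- predictors$subject_id[complete]
  if (length(keep) < n_in) {
    message(sprintf("complete-case filter: %d of %d subjects retained (%d dropped)",
                    length(keep), n_in, n_in - length(keep)))
  }
  x <- x[, keep, drop = FALSE]
  predictors <- predictors[complete, , drop = FALSE]
  G <- nrow(x)
  long <- data.frame(
    subject_id = rep(keep, each = G),
    gene = rep(rownames(x), times = length(keep)),
    value = as.vector(x),
    stringsAsFactors = FALSE
  )
  long <- cbind(long, predictors[rep(seq_along(keep), each = G),
                                 setdiff(names(predictors), "subject_id"),
                                 drop = FALSE])
  rownames(long) <- NULL
  attr(long, "n_input") <- n_in
  attr(long, "n_dropped") <- n_in - length(keep)
  attr(long, "n_genes") <- G
  long
}

#' Pivot a long response back to the wide gene-by-subject matrix
#'
#' Inverse of [to_long_format()]; mainly used for checks.
#' @param long A [to_long_format()] result.
#' @export
long_to_wide <- function(long) {
  subs <- unique(long$subject_id)
  genes <- unique(long$gene)
  out <- matrix(NA_real_, length(genes), length(subs),
                dimnames = list(genes, subs))
  out[cbind(match(long$gene, genes), match(long$subject_id, subs))] <- long$value
  out
}

#' Run the whole expression-preparation pipeline
#'
#' Fixed order: quantile-normalize -> log2 -> standardize within gene ->
#' sign-adjust -> long format. Marker transcripts are extracted before the
#' CTRA rows are subset, so marker covariates are log2 values of the
#' normalized matrix and never overlap the response genes.
#'
#' @param raw Raw genes-by-subjects intensity matrix (CTRA + marker rows).
#' @param gene_set CTRA gene set.
#' @param covariates Subject covariate data frame with `subject_id`.
#' @param markers Marker transcript symbols (8).
#' @param scale_sd Standardize genes to unit SD (see [standardize_genes()]).
#' @param already_log2 Set when `raw` is already log2 (skips the transform
#'   but still quantile-normalizes).
#' @param quantile Quantile-normalize first? Use the default (`TRUE`) for
#'   raw array data covering many genes; set `FALSE` for matrices that are
#'   already normalized or that contain only the indicator panel, where
#'   rank-mean normalization over a few dozen rows would erase genuine
#'   between-subject differences.
#' @return List: `long` (response + predictors), `markers` (covariate
#'   columns), `matrix` (prepared wide response).
#' @export
prepare_ctra_response <- function(raw, gene_set, covariates,
                                  markers = default_marker_transcripts(),
                                  scale_sd = TRUE, already_log2 = FALSE,
                                  quantile = TRUE) {
  raw <- expression_matrix(unclass_keep(raw),
                           value_space = if (already_log2) "log2" else "raw")
  qn <- if (quantile) quantile_normalize(raw) else raw
  lg <- if (already_log2) qn else log2_transform(qn)
  mk <- marker_covariates(lg, markers)
  ctra_rows <- intersect(rownames(lg), gene_set$symbol)
  if (length(ctra_rows) == 0L) stop("no CTRA genes found in matrix")
  resp <- lg[ctra_rows, , drop = FALSE]
  resp <- standardize_genes(expression_matrix(resp, "log2"), scale_sd = scale_sd)
  resp <- sign_adjust(resp, gene_set)
  predictors <- merge(covariates, mk, by = "subject_id", sort = FALSE)
  long <- to_long_format(resp, gene_set, predictors)
  list(long = long, markers = mk, matrix = resp)
}

unclass_keep <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}
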