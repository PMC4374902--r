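#' Read a GEO series-matrix file
#'
#' Parses the plain-text series-matrix format: `!`-prefixed header lines
#' become a sample attribute table, and the block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` becomes the
#' probes-by-samples expression matrix. The matrix must be complete.
#'
#' @param path Path to a (possibly gzipped) series-matrix text file.
#' @param probe_map Optional data frame with columns `probe`, `symbol`; when
#'   given, probes are collapsed to gene symbols (see [collapse_probes()]).
#' @return List: `matrix` (numeric, probes or genes x samples),
#'   `sample_info` (data frame of `!Sample_*` attributes).
#' @export
read_geo_series_matrix <- function(path, probe_map = NULL) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop("malformed series matrix: table delimiters not found (lines ",
         paste(c(beg, end), collapse = "/"), ")")
  }
  hdr <- lines[seq_len(beg - 1L)]
  smp <- hdr[startsWith(hdr, "!Sample_")]
  sample_info <- NULL
  if (length(smp)) {
    parsed <- lapply(smp, function(l) {
      parts <- strsplit(l, "\t")[[1]]
      parts <- gsub('^"|"$', "", parts)
      parts
    })
    keys <- sub("^!Sample_", "", vapply(parsed, `[`, "", 1L))
    vals <- lapply(parsed, function(x) x[-1L])
    nmax <- max(lengths(vals))
    keys <- make.unique(keys)
    sample_info <- as.data.frame(stats::setNames(vals, keys),
                                 stringsAsFactors = FALSE,
                                 check.names = TRUE)
  }
  tab <- utils::read.delim(textConnection(lines[(beg + 1L):(end - 1L)]),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "ID_REF") {
    stop("malformed series matrix: first table column must be ID_REF (line ",
         beg + 1L, ")")
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- as.character(tab[[1L]])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("series matrix contains missing values; complete matrix required")
  if (!is.null(probe_map)) mat <- collapse_probes(mat, probe_map)
  list(matrix = mat, sample_info = sample_info)
}

#' Collapse probes to gene symbols
#'
#' When several probes map to one symbol, keeps the probe with the maximum
#' mean intensity (`"max_mean"`, default) or averages probes (`"mean"`).
#'
#' @param mat Probes x samples matrix.
#' @param probe_map Data frame with columns `probe`, `symbol`.
#' @param method `"max_mean"` or `"mean"`.
#' @export
collapse_probes <- function(mat, probe_map, method = c("max_mean", "mean")) {
  method <- match.arg(method)
  probe_map <- probe_map[probe_map$probe %in% rownames(mat), , drop = FALSE]
  if (!nrow(probe_map)) stop("no probes in common between matrix and map")
  split_probes <- split(probe_map$probe, probe_map$symbol)
  rows <- lapply(split_probes, function(pr) {
    sub <- mat[pr, , drop = FALSE]
    if (method == "mean" || nrow(sub) == 1L) colMeans(sub) else
      sub[which.max(rowMeans(sub)), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(split_probes)
  out
}

#' Read an expression TSV (genes x subjects)
#'
#' First column `symbol`, remaining columns one per subject.
#' @param path TSV path.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "symbol") stop("expression TSV must start with a symbol column")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab$symbol
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("expression matrix contains missing values")
  mat
}

#' Read phenotype tables (items or covariates)
#'
#' Reads CSV (or XLSX when the readxl package is installed) into a validated
#' [item_matrix()] or covariate data frame. A logical/0-1 subset flag column
#' (e.g. marking the analyzable subjects) is honored when named.
#'
#' @param path CSV or XLSX file; items files have `subject_id` plus one
#'   column per item.
#' @param type `"items"` or `"covariates"`.
#' @param instrument Instrument for items files.
#' @param subset_flag Optional name of a flag column selecting rows.
#' @param item_map Optional custom item map.
#' @return An [item_matrix()] (`type = "items"`) or data frame.
#' @export
read_phenotypes <- function(path, type = c("items", "covariates"),
                            instrument = "MHC-SF", subset_flag = NULL,
                            item_map = NULL) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!"subject_id" %in% names(tab)) stop("phenotype file needs a subject_id column")
  if (!is.null(subset_flag)) {
    if (!subset_flag %in% names(tab)) stop("subset flag column not found: ", subset_flag)
    keep <- as.logical(tab[[subset_flag]])
    message(sprintf("subset flag '%s': %d of %d subjects retained",
                    subset_flag, sum(keep, na.rm = TRUE), nrow(tab)))
    tab <- tab[which(keep), setdiff(names(tab), subset_flag), drop = FALSE]
  }
  if (type == "covariates") return(tab)
  R <- as.matrix(tab[, setdiff(names(tab), "subject_id"), drop = FALSE])
  rownames(R) <- tab$subject_id
  item_matrix(R, instrument = instrument, item_map = item_map)
}

#' Run a full analysis from a configuration
#'
#' Orchestrates the pipeline end to end: read (or simulate) items,
#' covariates and expression; score the instrument; optionally run the
#' nested CFA comparisons; prepare the CTRA response; fit the
#' repeated-measures association model for each requested representation;
#' and write report tables. Reports are shaped like the published
#' association tables: one row per well-being term with b, SE, t, df, p and
#' VIF.
#'
#' @param config Named list or path to a YAML file. Recognized fields:
#'   `synthetic` (list passed to the generators: `n_subjects`, `seed`,
#'   `b_true`, `rho`, `missing_rate`, ...) or `inputs` (list with `items`,
#'   `covariates`, `expression` paths); `instrument`; `representations`
#'   (subset of `"1d"`, `"2d"`, `"3d"`, `"categorical"`, `"ryff1d"`,
#'   `"ryff6d"`); `exclude_genes`; `structure` (`"hcs"`, `"cs"`, `"un"`);
#'   `covariates` (names used for adjustment); `cfa` (logical); `scale_sd`;
#'   `out_dir` (reports written when given); `seed`.
#' @return List with `scores`, `cfa`, `fits` (one per representation),
#'   `tables` (report data frames), `log` (attrition and config record).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    instrument = "MHC-SF",
    representations = c("2d"),
    exclude_genes = character(),
    structure = "hcs",
    covariates = c("age", "sex_female", "race_white", "bmi", "smoking",
                   "alcohol", "illness_symptoms"),
    cfa = FALSE, scale_sd = TRUE, seed = 1L, out_dir = NULL,
    quantile = NULL, markers = default_marker_transcripts()
  ), config)
  # synthetic expression emulates already-normalized abundances and covers
  # only the indicator panel, so quantile normalization defaults off there
  if (is.null(cfg$quantile)) cfg$quantile <- is.null(config$synthetic)
  log <- list(config = cfg, stages = character())
  stage <- function(msg) {
    log$stages <<- c(log$stages, msg)
    message(msg)
  }

  gs <- load_gene_set(exclude = cfg$exclude_genes)
  if (!is.null(cfg$synthetic)) {
    syn <- utils::modifyList(list(n_subjects = 122, seed = cfg$seed,
                                  b_true = c(eudaimonic = -0.5), rho = 0.30,
                                  factor_model = 3, missing_rate = 0,
                                  covariate_effects = NULL), cfg$synthetic)
    wspec <- wellbeing_sim_spec(syn$n_subjects, instrument = cfg$instrument,
                                factor_model = syn$factor_model, seed = syn$seed)
    items <- gen_wellbeing_items(wspec)
    covs <- gen_covariates(syn$n_subjects, seed = syn$seed + 1L,
                           missing_rate = syn$missing_rate)
    scores <- if (cfg$instrument == "MHC-SF") score_mhcsf(items) else score_ryff(items)
    espec <- expression_sim_spec(gs, b_true = syn$b_true, rho = syn$rho,
                                 covariate_effects = syn$covariate_effects,
                                 seed = syn$seed + 2L)
    expr <- gen_expression(espec, scores, covs)
    stage(sprintf("simulated study: %d subjects, %d CTRA genes + %d markers",
                  syn$n_subjects, nrow(gs), 8L))
  } else {
    items <- read_phenotypes(cfg$inputs$items, "items",
                             instrument = cfg$instrument,
                             subset_flag = cfg$inputs$subset_flag)
    covs <- read_phenotypes(cfg$inputs$covariates, "covariates")
    expr <- read_expression_tsv(cfg$inputs$expression)
    scores <- if (cfg$instrument == "MHC-SF") score_mhcsf(items) else score_ryff(items)
    stage(sprintf("loaded study: %d subjects with items, %d expression columns",
                  nrow(scores), ncol(expr)))
  }
  covs$sex_female <- as.integer(covs$sex == "female")

  cfa_res <- NULL
  if (isTRUE(cfg$cfa) && cfg$instrument == "MHC-SF") {
    f1 <- fit_cfa_ml(items, cfa_mhcsf_model(1), seed = cfg$seed)
    f2 <- fit_cfa_ml(items, cfa_mhcsf_model(2), seed = cfg$seed)
    f3 <- fit_cfa_ml(items, cfa_mhcsf_model(3), seed = cfg$seed)
    cfa_res <- list(fit_1f = f1, fit_2f = f2, fit_3f = f3,
                    test_2v1 = nested_chisq_test(f1, f2),
                    test_3v2 = nested_chisq_test(f2, f3))
    stage(sprintf("CFA: dX2(2v1) = %.2f on %d df; dX2(3v2) = %.2f on %d df",
                  cfa_res$test_2v1$delta_chisq, cfa_res$test_2v1$delta_df,
                  cfa_res$test_3v2$delta_chisq, cfa_res$test_3v2$delta_df))
  }

  rep_terms <- list(
    "1d" = "total", "2d" = c("hedonic", "eudaimonic"),
    "3d" = c("hedonic", "psychological", "social"),
    "categorical" = "flourishing",
    "ryff1d" = "total_pwb",
    "ryff6d" = c("purpose_in_life", "environmental_mastery", "self_acceptance",
                 "autonomy", "personal_growth", "positive_relations"))
  scores_use <- scores
  if ("flourishing" %in% names(scores_use)) {
    scores_use$flourishing <- as.numeric(scores_use$flourishing)
  }
  predictors_base <- merge(scores_use, covs, by = "subject_id", sort = FALSE)
  fits <- list(); tables <- list()
  for (rep in cfg$representations) {
    terms <- rep_terms[[rep]]
    if (is.null(terms) || !all(terms %in% names(predictors_base))) {
      stop("representation not available for this instrument: ", rep)
    }
    keep_cols <- c("subject_id", terms, cfg$covariates)
    prep <- prepare_ctra_response(expr, gs,
                                  predictors_base[keep_cols],
                                  markers = cfg$markers,
                                  scale_sd = cfg$scale_sd,
                                  quantile = cfg$quantile)
    fit <- fit_ctra_model(prep$long,
                          predictors = c(terms, cfg$covariates,
                                         unname(cfg$markers)),
                          structure = cfg$structure, seed = cfg$seed)
    fits[[rep]] <- fit
    tab <- fit$coefficients[fit$coefficients$term %in% terms, , drop = FALSE]
    tab <- cbind(representation = rep, tab)
    tables[[rep]] <- tab
    stage(sprintf("fit %s (%s): n = %d analyzable subjects, df = %d",
                  rep, cfg$structure, fit$n_subjects, fit$df))
  }
  report <- do.call(rbind, tables)
  rownames(report) <- NULL

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(cfg$out_dir, "association_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(log = log$stages,
           n_subjects = unname(vapply(fits, function(f) f$n_subjects, 0L)),
           representations = names(fits)),
      file.path(cfg$out_dir, "run_log.json"), auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(scores, file.path(cfg$out_dir, "scores.csv"),
                     row.names = FALSE)
  }
  list(scores = scores, cfa = cfa_res, fits = fits, tables = report, log = log)
}
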