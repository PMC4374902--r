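#' CTRA indicator gene sets
#'
#' The conserved transcriptional response to adversity (CTRA) is summarised
#' over a fixed panel of indicator genes: pro-inflammatory transcripts
#' (e.g. IL1B, IL8, PTGS2, TNF) contribute with positive sign, while Type I
#' interferon response genes (IFI-, ISG-, MX-, OAS-family) and
#' antibody-synthesis genes (e.g. IGJ) are inverse indicators and contribute
#' with negative sign. The full discovery panel has 53 genes
#' (19 positive, 31 interferon + 3 antibody negative); dropping IL6 gives the
#' 52-gene panel used when IL6 assays are unavailable.
#'
#' @param path Path to a CSV file with columns `symbol`, `sign` (+1/-1) and
#'   `category`. Defaults to the panel shipped with the package.
#' @param exclude Character vector of gene symbols to drop (e.g. `"IL6"`).
#' @return A `ctra_gene_set` data frame with columns `symbol`, `sign`,
#'   `category`.
#' @examples
#' gs <- load_gene_set()                 # 53 genes
#' gs52 <- load_gene_set(exclude = "IL6")  # 52-gene confirmation panel
#' @export
load_gene_set <- function(path = NULL, exclude = character()) {
  if (is.null(path)) {
    path <- system.file("extdata", "ctra_gene_set.csv", package = "ctrawb")
  }
  gs <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("symbol", "sign", "category")
  if (!all(req %in% names(gs))) {
    stop("gene set file must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(gs$sign %in% c(-1L, 1L))) {
    stop("gene set signs must be +1 or -1")
  }
  if (anyDuplicated(gs$symbol)) {
    stop("duplicated gene symbols in gene set")
  }
  if (length(exclude)) {
    missing <- setdiff(exclude, gs$symbol)
    if (length(missing)) {
      stop("exclusions not in gene set: ", paste(missing, collapse = ", "))
    }
    gs <- gs[!gs$symbol %in% exclude, , drop = FALSE]
  }
  if (nrow(gs) == 0L) stop("gene set is empty after exclusions")
  rownames(gs) <- NULL
  class(gs) <- c("ctra_gene_set", "data.frame")
  gs
}

#' @export
print.ctra_gene_set <- function(x, ...) {
  cat(sprintf("CTRA gene set: %d genes (%d positive, %d negative)\n",
              nrow(x), sum(x$sign > 0), sum(x$sign < 0)))
  print(table(x$category))
  invisible(x)
}

#' Default leukocyte-subset marker transcripts
#'
#' Eight transcripts used as subject-level covariates indexing the relative
#' prevalence of CD4+ and CD8+ T lymphocytes, B lymphocytes, NK cells and
#' monocytes in the PBMC pool. Published CTRA analyses do not agree on a
#' fixed transcript list, so this default is a replaceable, clearly synthetic
#' stand-in of canonical subset markers.
#'
#' @param path Optional CSV with columns `symbol`, `subset`.
#' @return Character vector of 8 gene symbols (names give the subset).
#' @export
default_marker_transcripts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_transcripts.csv", package = "ctrawb")
  }
  mk <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(mk$symbol, mk$subset)
}
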