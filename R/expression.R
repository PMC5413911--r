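#' Validate a stage expression matrix
#'
#' A stage expression matrix is an ordinary numeric matrix of non-negative,
#' finite expression values (FPKM) with unique gene identifiers as row names
#' and ordered stage labels as column names (e.g. O, Z, 2C, 4C, 8C, M, B).
#'
#' @param x numeric matrix, genes x stages.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_stage_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(x) > 0L && is.null(rownames(x)))
    stop(what, " must have gene identifiers as row names", call. = FALSE)
  if (is.null(colnames(x)))
    stop(what, " must have stage labels as column names", call. = FALSE)
  if (ncol(x) < 2L)
    stop(what, " needs at least 2 stages, got ", ncol(x), call. = FALSE)
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup))
    stop(what, " has duplicated gene ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    g <- rownames(x)[bad[1L, 1L]]
    s <- colnames(x)[bad[1L, 2L]]
    stop(what, " has a missing, non-finite or negative value at gene '", g,
         "', stage '", s, "'", call. = FALSE)
  }
  invisible(x)
}

#' Read a gene x stage expression matrix from TSV
#'
#' Expected layout: a header row `gene<TAB>stage1<TAB>...<TAB>stageN`
#' followed by one row per gene. Tab-separated, '.' decimal, no quoting;
#' lines starting with `#` are treated as metadata comments and skipped.
#'
#' @param path path to a TSV file.
#' @return validated numeric matrix (genes x stages) with gene ids as row
#'   names and stage labels as column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("expression TSV needs a gene column plus >= 2 stage columns",
         call. = FALSE)
  genes <- as.character(df[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, function(col) is.numeric(col) || all(is.na(col)),
                logical(1L))
  if (!all(num))
    stop("non-numeric stage column(s): ",
         paste(names(vals)[!num], collapse = ", "), call. = FALSE)
  x <- as.matrix(vals)
  storage.mode(x) <- "double"
  dimnames(x) <- list(if (length(genes)) genes, names(vals))
  validate_stage_matrix(x)
  x
}

#' Write a stage expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: full-precision (17 significant
#' digit) values so that a read/write round trip is exact. An empty matrix
#' writes a header-only file.
#'
#' @param x validated stage expression matrix.
#' @param path output path.
#' @param comment optional character vector written as leading `# ` comment
#'   lines (metadata such as seed and config hash).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, comment = NULL) {
  validate_stage_matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comment))
    writeLines(paste0("# ", comment), con)
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  if (nrow(x)) {
    body <- apply(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                  1L, paste, collapse = "\t")
    writeLines(paste(rownames(x), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Filter to expressed, variable genes
#'
#' Retains genes whose maximum stage expression reaches `min_expr` (the
#' "expressed" floor; FPKM below 2 is conventionally treated as
#' unexpressed) and whose variance across stages is at least `min_var`.
#' Gene order is preserved. Setting `min_expr = 0` disables the expressed
#' filter.
#'
#' @param x stage expression matrix.
#' @param min_expr minimum per-gene maximum FPKM to count as expressed
#'   (default 2).
#' @param min_var minimum variance across stages (default 5, FPKM^2).
#' @param var_method `"sample"` (n-1 denominator, default) or
#'   `"population"` (n denominator).
#' @return the filtered matrix (possibly zero rows).
#' @export
filter_expressed_variance <- function(x, min_expr = 2, min_var = 5,
                                      var_method = c("sample", "population")) {
  validate_stage_matrix(x)
  var_method <- match.arg(var_method)
  if (!nrow(x)) return(x)
  mx <- apply(x, 1L, max)
  v <- apply(x, 1L, stats::var)
  if (var_method == "population")
    v <- v * (ncol(x) - 1L) / ncol(x)
  keep <- mx >= min_expr & v >= min_var
  x[keep, , drop = FALSE]
}

#' Standardize per-gene stage profiles
#'
#' Transforms each gene's stage profile to mean 0 and standard deviation 1
#' so that clustering groups trajectory shapes rather than expression
#' magnitudes. Default is the sample-sd (n-1 denominator) convention, the
#' one used by the standard fuzzy-clustering preprocessing for expression
#' time courses, so each output row satisfies `sd(row) == 1` exactly.
#'
#' @param x stage expression matrix (every row must have nonzero variance;
#'   guaranteed after [filter_expressed_variance()] with `min_var > 0`).
#' @param sd_method `"sample"` (default) or `"population"`.
#' @return matrix of per-gene z-scores, same shape and dimnames.
#' @export
standardize_profiles <- function(x, sd_method = c("sample", "population")) {
  # accepts already-centred input (z-scores are idempotent), so negative
  # values are allowed here, unlike raw FPKM matrices
  if (!is.matrix(x) || !is.numeric(x) || is.null(rownames(x)) ||
      is.null(colnames(x)) || any(!is.finite(x)))
    stop("need a finite numeric matrix with gene and stage names",
         call. = FALSE)
  sd_method <- match.arg(sd_method)
  if (!nrow(x)) return(x)
  mu <- rowMeans(x)
  centred <- x - mu
  ss <- rowSums(centred^2)
  denom <- if (sd_method == "population") ncol(x) else ncol(x) - 1L
  sdv <- sqrt(ss / denom)
  zero <- which(sdv == 0)
  if (length(zero))
    stop("cannot standardize constant profile(s): ",
         paste(rownames(x)[zero], collapse = ", "), call. = FALSE)
  centred / sdv
}

#' Normalize each gene to its maximal stage
#'
#' The reporting convention used for profile heat maps: values below the
#' expression floor are treated as unexpressed (set to 0) and each gene is
#' then scaled to the stage where it is most highly expressed, so the row
#' maximum is exactly 1 (or the row is all zeros if nothing reaches the
#' floor).
#'
#' @param x stage expression matrix.
#' @param floor FPKM below which values are treated as unexpressed
#'   (default 2).
#' @return matrix of values in \[0, 1\], same shape and dimnames.
#' @export
normalize_to_max <- function(x, floor = 2) {
  validate_stage_matrix(x)
  if (!nrow(x)) return(x)
  y <- x
  y[y < floor] <- 0
  mx <- apply(y, 1L, max)
  pos <- mx > 0
  y[pos, ] <- y[pos, , drop = FALSE] / mx[pos]
  y
}
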