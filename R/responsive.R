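#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: with ordered p-values p_(1) <=
#' ... <= p_(m), the adjusted value is q_(i) = min_{j >= i} p_(j) m / j,
#' clipped at 1 and returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA not allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Fold change between two condition means
#'
#' Direction and magnitude of the expression change from control to
#' treated, with magnitude always expressed as a ratio >= 1 (treated /
#' control for increases, control / treated for decreases). A zero
#' denominator gives an infinite magnitude so that fold-change thresholds
#' stay total-ordered; two zeros (or equal means) give direction "none"
#' and magnitude 1.
#'
#' @param mean_control,mean_treated non-negative condition means (FPKM);
#'   vectors are processed elementwise.
#' @return data frame with columns `direction` ("up", "down" or "none")
#'   and `magnitude` (>= 1, possibly Inf).
#' @export
fold_change <- function(mean_control, mean_treated) {
  if (any(mean_control < 0) || any(mean_treated < 0))
    stop("condition means must be >= 0", call. = FALSE)
  n <- max(length(mean_control), length(mean_treated))
  ctl <- rep_len(mean_control, n)
  trt <- rep_len(mean_treated, n)
  direction <- rep("none", n)
  magnitude <- rep(1, n)
  up <- trt > ctl
  dn <- trt < ctl
  direction[up] <- "up"
  direction[dn] <- "down"
  magnitude[up] <- trt[up] / ctl[up]      # Inf when control is 0
  magnitude[dn] <- ctl[dn] / trt[dn]      # Inf when treated is 0
  data.frame(direction = direction, magnitude = magnitude)
}

#' Read a differential-expression result table from TSV
#'
#' Layout: `gene<TAB>mean_control<TAB>mean_treated<TAB>p_raw<TAB>p_adj`,
#' with "NA" allowed in exactly one of the two p columns per table (a table
#' may carry raw p-values only, pre-adjusted values only, or both).
#'
#' @param path path to the TSV file.
#' @return data frame with columns `gene`, `mean_control`, `mean_treated`,
#'   `p_raw`, `p_adj`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "mean_control", "mean_treated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"p_raw" %in% names(df)) df$p_raw <- NA_real_
  if (!"p_adj" %in% names(df)) df$p_adj <- NA_real_
  validate_de_table(df)
  df[c("gene", "mean_control", "mean_treated", "p_raw", "p_adj")]
}

#' @rdname read_de_table
#' @param table a DE-table data frame to validate.
#' @export
validate_de_table <- function(table) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(table$gene))
    stop("duplicated gene ids in DE table", call. = FALSE)
  if (any(table$mean_control < 0, na.rm = TRUE) ||
      any(table$mean_treated < 0, na.rm = TRUE))
    stop("condition means must be >= 0", call. = FALSE)
  for (col in c("p_raw", "p_adj")) {
    v <- table[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " outside [0, 1]", call. = FALSE)
  }
  if (any(is.na(table$p_raw) & is.na(table$p_adj)))
    stop("each gene needs p_raw or p_adj", call. = FALSE)
  invisible(table)
}

#' Build responsive gene sets from a differential-expression table
#'
#' Applies the response filters to every row: a gene is upregulated if its
#' adjusted p-value is at most `alpha`, its treated mean exceeds its
#' control mean by at least `min_fold`-fold, and it is upregulated *to* at
#' least `min_fpkm` (treated mean >= `min_fpkm`); downregulated genes
#' symmetrically must be downregulated *from* at least `min_fpkm`
#' (control mean >= `min_fpkm`). If the table has no pre-adjusted p-values
#' they are computed from `p_raw` over the whole table by [bh_adjust()];
#' where both are present `p_adj` wins.
#'
#' @param table DE-table data frame (see [read_de_table()]).
#' @param alpha adjusted p-value cutoff (default 0.05).
#' @param min_fpkm expression floor for the regulated endpoint (default 2).
#' @param min_fold minimal fold change, as a ratio (default 1.3, i.e. a
#'   30 percent increase or decrease).
#' @return object of class `responsive_sets`: list with character vectors
#'   `up` and `down` (disjoint), and `filter_params`.
#' @export
filter_responsive <- function(table, alpha = 0.05, min_fpkm = 2,
                              min_fold = 1.3) {
  validate_de_table(table)
  p <- table$p_adj
  if (anyNA(p)) {
    if (all(is.na(p))) {
      p <- bh_adjust(table$p_raw)
    } else {
      stop("p_adj must be present for all genes or none; mixed tables ",
           "are ambiguous", call. = FALSE)
    }
  }
  fc <- fold_change(table$mean_control, table$mean_treated)
  sig <- p <= alpha & fc$magnitude >= min_fold
  up <- sig & fc$direction == "up" & table$mean_treated >= min_fpkm
  down <- sig & fc$direction == "down" & table$mean_control >= min_fpkm
  structure(list(up = table$gene[up], down = table$gene[down],
                 filter_params = list(alpha = alpha, min_fpkm = min_fpkm,
                                      min_fold = min_fold)),
            class = "responsive_sets")
}

#' @export
print.responsive_sets <- function(x, ...) {
  p <- x$filter_params
  cat("Responsive gene sets: ", length(x$up), " up, ", length(x$down),
      " down\n  (alpha = ", p$alpha, ", endpoint FPKM >= ", p$min_fpkm,
      ", fold >= ", p$min_fold, ")\n", sep = "")
  invisible(x)
}

#' Write responsive gene sets to disk
#'
#' Writes `up.txt` and `down.txt` (one gene id per line) plus
#' `responsive_summary.json` holding the counts and filter parameters.
#'
#' @param sets a `responsive_sets` object.
#' @param dir output directory (created if needed).
#' @param meta optional named list of extra metadata for the JSON summary.
#' @return the directory, invisibly.
#' @export
write_responsive_sets <- function(sets, dir, meta = NULL) {
  stopifnot(inherits(sets, "responsive_sets"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(sets$up, file.path(dir, "up.txt"))
  writeLines(sets$down, file.path(dir, "down.txt"))
  summary <- c(list(n_up = length(sets$up), n_down = length(sets$down),
                    filter_params = sets$filter_params), meta)
  jsonlite::write_json(summary, file.path(dir, "responsive_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
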