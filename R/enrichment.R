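#' Tabulate responsive genes by temporal profile
#'
#' For each profile counts how many of the supplied genes it contains;
#' genes present in no profile are dropped (their count is reported, not
#' carried into the tests).
#'
#' @param genes character vector of gene ids (e.g. a responsive set).
#' @param profiles a `profile_set`.
#' @return object of class `profile_counts`: `profile_ids`, `observed`,
#'   `sizes`, `n_responsive_assigned`, `n_dropped`, `universe_size`.
#' @export
tabulate_by_profile <- function(genes, profiles) {
  stopifnot(inherits(profiles, "profile_set"))
  genes <- unique(genes)
  observed <- vapply(profiles$gene_sets,
                     function(g) sum(genes %in% g), integer(1L))
  n_assigned <- sum(observed)
  structure(list(profile_ids = profiles$profile_ids,
                 observed = stats::setNames(observed, profiles$profile_ids),
                 sizes = profiles$sizes,
                 n_responsive_assigned = n_assigned,
                 n_dropped = length(genes) - n_assigned,
                 universe_size = profiles$universe_size),
            class = "profile_counts")
}

#' Pearson chi-square goodness of fit over profiles
#'
#' Tests whether responsive genes are differentially assigned among
#' profiles. The expected count for profile i is proportional to its size:
#' E_i = n * size_i / universe (or uniform across profiles with
#' `expected = "uniform"`); the statistic is sum (O_i - E_i)^2 / E_i with
#' #profiles - 1 degrees of freedom and an upper-tail p-value.
#'
#' @param counts a `profile_counts` object.
#' @param expected `"size"` (proportional to profile sizes, default) or
#'   `"uniform"`.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_gof <- function(counts, expected = c("size", "uniform")) {
  stopifnot(inherits(counts, "profile_counts"))
  expected <- match.arg(expected)
  k <- length(counts$observed)
  if (k < 2L) stop("need >= 2 profiles for a chi-square test", call. = FALSE)
  if (counts$n_responsive_assigned <= 0)
    stop("no responsive genes assigned to any profile", call. = FALSE)
  E <- .expected_counts(counts, expected)
  if (any(E == 0)) stop("zero expected count (empty profile)", call. = FALSE)
  stat <- sum((counts$observed - E)^2 / E)
  df <- k - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

.expected_counts <- function(counts, expected = "size") {
  n <- counts$n_responsive_assigned
  if (expected == "size")
    n * counts$sizes / counts$universe_size
  else
    rep(n / length(counts$observed), length(counts$observed))
}

#' Per-profile Pearson contributions
#'
#' The per-profile term (O_i - E_i)^2 / E_i of the chi-square statistic,
#' used to rank which profiles drive a significant test, together with the
#' direction of departure (enriched if observed exceeds expected, depleted
#' if below, none at equality).
#'
#' @inheritParams chi2_gof
#' @return data frame with columns `profile_id`, `observed`, `expected`,
#'   `contribution`, `direction`.
#' @export
pearson_contributions <- function(counts, expected = c("size", "uniform")) {
  stopifnot(inherits(counts, "profile_counts"))
  expected <- match.arg(expected)
  E <- .expected_counts(counts, expected)
  O <- counts$observed
  contribution <- (O - E)^2 / E
  direction <- ifelse(O > E, "enriched", ifelse(O < E, "depleted", "none"))
  data.frame(profile_id = counts$profile_ids, observed = as.numeric(O),
             expected = as.numeric(E), contribution = as.numeric(contribution),
             direction = direction, row.names = NULL)
}

#' Stepwise selection of enriched/depleted profiles
#'
#' Iterates the goodness-of-fit test: while the chi-square p-value over the
#' remaining profiles is at most `alpha` (and at least two profiles
#' remain), the profile with the largest Pearson contribution is selected
#' (ties break to the smaller profile id in the current ordering), its
#' direction recorded, and it is removed — its genes leave the universe
#' and its observed responsive genes leave the total — before re-testing
#' the remaining profiles.
#'
#' @inheritParams chi2_gof
#' @param alpha stopping significance level (default 0.05).
#' @return list with `chi2_initial` (the first test), `steps` (data frame:
#'   `profile_id`, `direction`, `observed`, `expected`, `contribution`,
#'   and the chi-square `statistic`, `df`, `p` of the test that triggered
#'   the selection), `chi2_final` (the first non-significant test, or the
#'   last computable one) and `alpha`.
#' @export
stepwise_select <- function(counts, alpha = 0.05,
                            expected = c("size", "uniform")) {
  stopifnot(inherits(counts, "profile_counts"))
  expected <- match.arg(expected)
  cur <- counts
  steps <- NULL
  chi2_initial <- NULL
  repeat {
    if (length(cur$observed) < 2L || cur$n_responsive_assigned <= 0) {
      test <- NULL
      break
    }
    test <- chi2_gof(cur, expected)
    if (is.null(chi2_initial)) chi2_initial <- test
    if (test$p > alpha) break
    contrib <- pearson_contributions(cur, expected)
    pick <- which.max(contrib$contribution)   # first max = smallest index
    steps <- rbind(steps, data.frame(
      profile_id = contrib$profile_id[pick],
      direction = contrib$direction[pick],
      observed = contrib$observed[pick],
      expected = contrib$expected[pick],
      contribution = contrib$contribution[pick],
      statistic = test$statistic, df = test$df, p = test$p,
      row.names = NULL))
    keep <- -pick
    cur <- structure(list(
      profile_ids = cur$profile_ids[keep],
      observed = cur$observed[keep],
      sizes = cur$sizes[keep],
      n_responsive_assigned = cur$n_responsive_assigned -
        contrib$observed[pick],
      n_dropped = cur$n_dropped,
      universe_size = cur$universe_size - cur$sizes[pick]),
      class = "profile_counts")
  }
  list(chi2_initial = chi2_initial,
       steps = if (is.null(steps))
         data.frame(profile_id = character(0), direction = character(0),
                    observed = numeric(0), expected = numeric(0),
                    contribution = numeric(0), statistic = numeric(0),
                    df = integer(0), p = numeric(0))
       else steps,
       chi2_final = test, alpha = alpha)
}

#' Exact test on a 2x2 contingency table
#'
#' Fisher's exact test on the table
#' \preformatted{ a  b      a = in set 1 and set 2 (e.g. in profile and responsive)
#'  c  d}
#' computed from the hypergeometric distribution conditional on the
#' margins. `"greater"` is P(X >= a), `"less"` is P(X <= a), and the
#' two-sided p-value sums all point probabilities not exceeding P(X = a)
#' (with the conventional 1 + 1e-7 relative slack). The odds ratio is the
#' sample cross-product ratio a d / (b c), Inf or 0 at zero cells.
#'
#' All four cell arguments may be vectors (recycled elementwise).
#'
#' @param a,b,c,d non-negative integer cells.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return data frame with columns `a`, `b`, `c`, `d`, `odds_ratio`, `p`.
#' @export
fisher_contingency <- function(a, b, c, d,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  cells <- cbind(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  K <- a + b          # responsive margin
  nn <- a + c         # profile margin
  N <- a + b + c + d
  p <- switch(alternative,
    greater = stats::phyper(a - 1, K, N - K, nn, lower.tail = FALSE),
    less = stats::phyper(a, K, N - K, nn),
    two.sided = vapply(seq_len(n), function(i)
      .fisher_two_sided(a[i], K[i], nn[i], N[i]), numeric(1L)))
  or <- ifelse(b * c > 0, (a * d) / (b * c),
               ifelse(a * d > 0, Inf, NaN))
  data.frame(a = a, b = b, c = c, d = d, odds_ratio = or,
             p = pmin(p, 1))
}

# two-sided Fisher p: sum of hypergeometric point probabilities <= P(X = a)
.fisher_two_sided <- function(a, K, n, N) {
  support <- max(0L, K + n - N):min(K, n)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Fisher's exact test for a profile against a responsive set
#'
#' Builds the 2x2 table for one profile (or a union of profiles) against a
#' responsive gene set inside a universe of profile-assigned genes, and
#' runs the exact test. The responsive set should contain only
#' profile-assigned genes (as produced by the tabulation step); genes in
#' neither set make up the remainder cell.
#'
#' @param profile_genes character vector: genes of the profile (or the
#'   union of several profiles).
#' @param responsive character vector of responsive gene ids, counted only
#'   among profile-assigned genes.
#' @param universe_size total number of profile-assigned genes.
#' @param alternative tail convention, see [fisher_contingency()].
#' @return list with `table` (named a/b/c/d), `odds_ratio`, `p`,
#'   `alternative`.
#' @export
fisher_profile <- function(profile_genes, responsive, universe_size,
                           alternative = c("two.sided", "greater",
                                           "less")) {
  alternative <- match.arg(alternative)
  a <- length(intersect(profile_genes, responsive))
  b <- length(unique(responsive)) - a
  cc <- length(unique(profile_genes)) - a
  d <- universe_size - a - b - cc
  if (min(a, b, cc, d) < 0)
    stop("inconsistent inputs: negative derived cell (a=", a, ", b=", b,
         ", c=", cc, ", d=", d, ")", call. = FALSE)
  res <- fisher_contingency(a, b, cc, d, alternative)
  list(table = c(a = a, b = b, c = cc, d = d),
       odds_ratio = res$odds_ratio, p = res$p, alternative = alternative)
}

#' Full stepwise enrichment analysis for up- and downregulated sets
#'
#' The complete four-step procedure, run separately for the up- and
#' downregulated sets: (1) tabulate responsive genes by profile, dropping
#' genes assigned to no profile; (2) chi-square goodness of fit for
#' differential assignment among profiles; (3) while significant, peel off
#' the profile with the largest Pearson contribution and re-test the
#' remainder; (4) Fisher's exact test for each selected profile
#' individually and for the pooled union of same-direction selections
#' (the "combined" tests, one for enriched and one for depleted profiles).
#'
#' @param up,down character vectors of up-/downregulated gene ids.
#' @param profiles a `profile_set`.
#' @param alpha stopping level for the stepwise chi-square (default 0.05).
#' @param alternative Fisher tail convention (default two-sided).
#' @param expected expected-count model for the chi-square, see
#'   [chi2_gof()].
#' @return object of class `enrichment_report`: a list with one entry per
#'   direction (`up`, `down`), each holding `counts`, `chi2_initial`,
#'   `steps`, `fisher_individual` (data frame), `fisher_combined_enriched`,
#'   `fisher_combined_depleted`, `alpha`.
#' @export
run_enrichment <- function(up, down, profiles, alpha = 0.05,
                           alternative = c("two.sided", "greater", "less"),
                           expected = c("size", "uniform")) {
  stopifnot(inherits(profiles, "profile_set"))
  alternative <- match.arg(alternative)
  expected <- match.arg(expected)
  res <- lapply(list(up = up, down = down), function(genes)
    .enrich_one(genes, profiles, alpha, alternative, expected))
  structure(c(res, list(alpha = alpha, alternative = alternative)),
            class = "enrichment_report")
}

.enrich_one <- function(genes, profiles, alpha, alternative, expected) {
  counts <- tabulate_by_profile(genes, profiles)
  empty <- list(counts = counts, chi2_initial = NULL,
                steps = stepwise_select_empty(), fisher_individual = NULL,
                fisher_combined_enriched = NULL,
                fisher_combined_depleted = NULL, alpha = alpha)
  if (counts$n_responsive_assigned == 0 || length(counts$observed) < 2L)
    return(empty)
  sel <- stepwise_select(counts, alpha, expected)
  assigned <- intersect(unique(genes),
                        unlist(profiles$gene_sets, use.names = FALSE))
  fi <- NULL
  for (pid in sel$steps$profile_id) {
    f <- fisher_profile(profiles$gene_sets[[pid]], assigned,
                        profiles$universe_size, alternative)
    fi <- rbind(fi, data.frame(
      profile_id = pid,
      direction = sel$steps$direction[sel$steps$profile_id == pid],
      a = f$table[["a"]], b = f$table[["b"]], c = f$table[["c"]],
      d = f$table[["d"]], odds_ratio = f$odds_ratio, p = f$p,
      row.names = NULL))
  }
  combined <- function(dir) {
    ids <- sel$steps$profile_id[sel$steps$direction == dir]
    if (!length(ids)) return(NULL)
    pool <- unlist(profiles$gene_sets[ids], use.names = FALSE)
    f <- fisher_profile(pool, assigned, profiles$universe_size, alternative)
    c(f, list(profile_ids = ids))
  }
  list(counts = counts, chi2_initial = sel$chi2_initial, steps = sel$steps,
       fisher_individual = fi,
       fisher_combined_enriched = combined("enriched"),
       fisher_combined_depleted = combined("depleted"),
       alpha = alpha)
}

stepwise_select_empty <- function() {
  data.frame(profile_id = character(0), direction = character(0),
             observed = numeric(0), expected = numeric(0),
             contribution = numeric(0), statistic = numeric(0),
             df = integer(0), p = numeric(0))
}

#' @export
print.enrichment_report <- function(x, ...) {
  for (dir in c("up", "down")) {
    r <- x[[dir]]
    cat(toupper(dir), ": ", r$counts$n_responsive_assigned,
        " responsive genes assigned (", r$counts$n_dropped, " dropped)\n",
        sep = "")
    if (!is.null(r$chi2_initial))
      cat("  initial chi-square: X2 = ",
          format(r$chi2_initial$statistic, digits = 4), ", df = ",
          r$chi2_initial$df, ", p = ",
          format(r$chi2_initial$p, digits = 3), "\n", sep = "")
    if (nrow(r$steps))
      cat("  selected: ",
          paste0(r$steps$profile_id, " (", r$steps$direction, ")",
                 collapse = ", "), "\n", sep = "")
    else cat("  no profiles selected\n")
    for (comb in c("fisher_combined_enriched", "fisher_combined_depleted")) {
      f <- r[[comb]]
      if (!is.null(f))
        cat("  combined ", sub("fisher_combined_", "", comb), " Fisher p = ",
            format(f$p, digits = 3), " (profiles ",
            paste(f$profile_ids, collapse = ", "), ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Write an enrichment report to disk
#'
#' Writes `enrichment_<dir>.json` with the full report and a per-profile
#' TSV `profile_counts_<dir>.tsv` of observed/expected/contribution/
#' direction for each direction.
#'
#' @param report an `enrichment_report`.
#' @param dir output directory (created if needed).
#' @param meta optional named metadata list added to the JSON.
#' @return the directory, invisibly.
#' @export
write_enrichment_report <- function(report, dir, meta = NULL) {
  stopifnot(inherits(report, "enrichment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("up", "down")) {
    r <- report[[d]]
    contrib <- if (!is.null(r$chi2_initial))
      pearson_contributions(r$counts) else NULL
    utils::write.table(contrib,
                       file.path(dir, paste0("profile_counts_", d, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(
      n_responsive_assigned = r$counts$n_responsive_assigned,
      n_dropped = r$counts$n_dropped,
      universe_size = r$counts$universe_size,
      chi2_initial = r$chi2_initial,
      steps = r$steps,
      fisher_individual = r$fisher_individual,
      fisher_combined_enriched = r$fisher_combined_enriched,
      fisher_combined_depleted = r$fisher_combined_depleted,
      alpha = r$alpha, alternative = report$alternative)
    out <- c(out, meta)
    jsonlite::write_json(out, file.path(dir, paste0("enrichment_", d,
                                                    ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  }
  invisible(dir)
}
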