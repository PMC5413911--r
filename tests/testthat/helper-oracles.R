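# Shared fixtures and independent oracles used across test files.

# small well-formed stage matrix
toy_matrix <- function(genes = 3L, stages = 7L, seed = 1L) {
  set.seed(seed)
  x <- matrix(stats::rexp(genes * stages, rate = 0.1), genes, stages)
  dimnames(x) <- list(paste0("g", seq_len(genes)),
                      paste0("S", seq_len(stages)))
  x
}

# profile_counts object built by hand
make_counts <- function(observed, sizes) {
  ids <- paste0("P", seq_along(observed))
  structure(list(profile_ids = ids,
                 observed = stats::setNames(observed, ids),
                 sizes = stats::setNames(sizes, ids),
                 n_responsive_assigned = sum(observed),
                 n_dropped = 0L,
                 universe_size = sum(sizes)),
            class = "profile_counts")
}

# a fixed 20-profile universe used by calibration tests: moderately unequal
# sizes (proportional to 31..50 over `G` genes) so every expected count
# stays near or above 10 even for modest responsive draws
calibration_profiles <- function(G = 8000L, k = 20L) {
  props <- (30 + seq_len(k)) / sum(30 + seq_len(k))
  sizes <- floor(props * G)
  sizes[k] <- sizes[k] + (G - sum(sizes))
  genes <- sprintf("g%05d", seq_len(G))
  gene_sets <- split(genes, rep(seq_len(k), sizes))
  names(gene_sets) <- paste0("P", seq_len(k))
  profile_set(gene_sets)
}

# independent Fisher oracle: enumerate the hypergeometric pmf from choose()
# and take tails by direct summation
oracle_fisher <- function(a, b, c, d, alternative) {
  N <- a + b + c + d
  K <- a + b
  n <- a + c
  support <- max(0, K + n - N):min(K, n)
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  pa <- probs[match(a, support)]
  p <- switch(alternative,
              greater = sum(probs[support >= a]),
              less = sum(probs[support <= a]),
              two.sided = sum(probs[probs <= pa * (1 + 1e-7)]))
  min(p, 1)
}

# independent BH oracle: literal step-up on the sorted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force re-application of the four responsive-filter clauses, row by
# row, independent of filter_responsive's vectorized path
oracle_filter <- function(table, alpha, min_fpkm, min_fold) {
  p <- table$p_adj
  if (all(is.na(p))) p <- oracle_bh(table$p_raw)
  up <- character(0); down <- character(0)
  for (i in seq_len(nrow(table))) {
    ctl <- table$mean_control[i]; trt <- table$mean_treated[i]
    if (p[i] > alpha) next
    if (trt > ctl) {
      mag <- if (ctl == 0) Inf else trt / ctl
      if (mag >= min_fold && trt >= min_fpkm) up <- c(up, table$gene[i])
    } else if (trt < ctl) {
      mag <- if (trt == 0) Inf else ctl / trt
      if (mag >= min_fold && ctl >= min_fpkm) down <- c(down, table$gene[i])
    }
  }
  list(up = up, down = down)
}
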