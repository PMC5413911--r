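#' Fuzzy c-means clustering of standardized stage profiles
#'
#' Alternating-optimization fuzzy c-means with Euclidean distance on the
#' rows of `X`. Memberships follow the standard fixed point
#' \deqn{u_{ic} = 1 / \sum_j (d_{ic}/d_{ij})^{2/(m-1)}}
#' and centroids are the membership^m-weighted means of the data. A point
#' coinciding with one or more centroids (distance < 1e-12) has its
#' membership mass split equally among the coinciding centroids. Iteration
#' stops when the decrease of the objective
#' \eqn{J = \sum_{i,c} u_{ic}^m d_{ic}^2} falls below `tol` or after
#' `max_iter` sweeps.
#'
#' Initial centroids are `c` distinct rows of `X` chosen by the seeded RNG,
#' so identical seed and input give bit-identical results. Optional
#' multi-restart keeps the run with the lowest final objective.
#'
#' @param X standardized profile matrix (genes x stages), e.g. from
#'   [standardize_profiles()].
#' @param c number of clusters, `1 <= c <= nrow(X)`.
#' @param m fuzzifier, > 1; values near 1 approach hard k-means. Default
#'   1.25, a common choice for short standardized time courses.
#' @param seed integer RNG seed for reproducible initialization.
#' @param tol convergence tolerance on the objective decrease.
#' @param max_iter maximum number of alternating sweeps.
#' @param restarts number of seeded restarts; the best objective wins.
#' @param verify_monotone if TRUE, error if the objective ever increases
#'   beyond numerical noise (debug aid).
#' @return object of class `fuzzy_cmeans`: list with `centroids` (c x S),
#'   `memberships` (G x c, rows summing to 1), `m`, `objective`,
#'   `objective_trace`, `n_iter`, `converged`, `seed`.
#' @export
fuzzy_cmeans <- function(X, c, m = 1.25, seed = 1L, tol = 1e-6,
                         max_iter = 1000L, restarts = 1L,
                         verify_monotone = FALSE) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix", call. = FALSE)
  G <- nrow(X)
  if (c < 1L) stop("c must be >= 1", call. = FALSE)
  if (c > G) stop("c = ", c, " exceeds the number of genes (", G, ")",
                  call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .fcm_once(X, c, m, seed + (r - 1L), tol, max_iter,
                     verify_monotone)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best$seed <- seed
  best
}

.fcm_once <- function(X, c, m, seed, tol, max_iter, verify_monotone) {
  set.seed(seed)
  G <- nrow(X)
  V <- X[sample.int(G, c), , drop = FALSE]
  expo <- 2 / (m - 1)
  trace <- numeric(0)
  J_prev <- Inf
  converged <- FALSE
  U <- NULL
  for (it in seq_len(max_iter)) {
    D2 <- .sqdist(X, V)                       # G x c squared distances
    U <- .fcm_memberships(D2, expo)
    Um <- U^m
    denom <- colSums(Um)
    # a centroid with no membership mass keeps its previous position
    alive <- denom > 0
    Vnew <- V
    Vnew[alive, ] <- crossprod(Um[, alive, drop = FALSE], X) /
      denom[alive]
    V <- Vnew
    J <- sum(Um * .sqdist(X, V))
    trace <- c(trace, J)
    if (verify_monotone && J > J_prev + 1e-8 * max(1, abs(J_prev)))
      stop("fuzzy c-means objective increased: ", J_prev, " -> ", J,
           call. = FALSE)
    if (is.finite(J_prev) && abs(J_prev - J) < tol) {
      converged <- TRUE
      J_prev <- J
      break
    }
    J_prev <- J
  }
  rownames(U) <- rownames(X)
  colnames(U) <- paste0("k", seq_len(c))
  dimnames(V) <- list(paste0("k", seq_len(c)), colnames(X))
  structure(list(centroids = V, memberships = U, m = m,
                 objective = J_prev, objective_trace = trace,
                 n_iter = length(trace), converged = converged,
                 seed = seed),
            class = "fuzzy_cmeans")
}

# squared Euclidean distances between rows of X (G x S) and V (c x S)
.sqdist <- function(X, V) {
  d2 <- outer(rowSums(X^2), rowSums(V^2), "+") - 2 * tcrossprod(X, V)
  d2[d2 < 0] <- 0
  d2
}

# membership update with the exact-coincidence rule
.fcm_memberships <- function(D2, expo) {
  coincide <- D2 < 1e-24                      # squared distance < 1e-12^2
  w <- D2^(-expo / 2)                         # d^(-2/(m-1))
  U <- w / rowSums(w)
  hit <- rowSums(coincide) > 0
  if (any(hit)) {
    U[hit, ] <- 0
    U[hit, ] <- coincide[hit, , drop = FALSE] /
      rowSums(coincide[hit, , drop = FALSE])
  }
  U
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat("Fuzzy c-means fit: ", nrow(x$memberships), " genes, ",
      nrow(x$centroids), " clusters, m = ", x$m, "\n",
      "objective ", format(x$objective), " after ", x$n_iter,
      " iterations (", if (x$converged) "converged" else "max_iter",
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Hard cluster assignment from fuzzy memberships
#'
#' Assigns each gene to its cluster of maximal membership; ties break to
#' the lowest cluster index. Clusters receiving no genes are simply absent
#' from the result and are dropped by downstream profile construction.
#'
#' @param clustering a `fuzzy_cmeans` object.
#' @return named integer vector, gene id -> initial cluster index.
#' @export
harden <- function(clustering) {
  stopifnot(inherits(clustering, "fuzzy_cmeans"))
  a <- apply(clustering$memberships, 1L, which.max)   # first max = lowest index
  stats::setNames(as.integer(a), rownames(clustering$memberships))
}

#' Collapse correlated clusters into temporal profiles
#'
#' Computes pairwise Pearson correlation between the centroids of the
#' non-empty clusters and merges clusters connected by correlations at or
#' above `r_threshold`. The default merge policy is single linkage
#' (connected components of the r >= threshold graph), which is
#' deterministic and order-independent; `"complete"` requires every pair
#' within a merged group to reach the threshold. Collapsed profiles are
#' labelled C1, C2, ... in decreasing gene-set size (ties: smallest
#' original cluster index), and each profile's mean profile is the
#' per-stage mean of its member genes' standardized profiles.
#'
#' @param clustering a `fuzzy_cmeans` object.
#' @param assignments named gene -> cluster map from [harden()].
#' @param X the standardized matrix the clustering was fitted to (used for
#'   mean profiles).
#' @param r_threshold Pearson correlation at or above which clusters merge
#'   (default 0.95).
#' @param method `"single"` (connected components, default) or
#'   `"complete"` linkage.
#' @return object of class `profile_set`: `profile_ids`, `gene_sets`
#'   (named list of disjoint gene-id vectors), `sizes`, `mean_profiles`
#'   (k x S), `provenance` (initial cluster -> profile id),
#'   `universe_size`, `r_threshold`.
#' @export
collapse_profiles <- function(clustering, assignments, X,
                              r_threshold = 0.95,
                              method = c("single", "complete")) {
  stopifnot(inherits(clustering, "fuzzy_cmeans"))
  method <- match.arg(method)
  if (ncol(clustering$centroids) < 3L)
    stop("need >= 3 stages for centroid correlations", call. = FALSE)
  used <- sort(unique(assignments))
  if (!length(used)) stop("no non-empty clusters", call. = FALSE)
  V <- clustering$centroids[used, , drop = FALSE]
  sds <- apply(V, 1L, stats::sd)
  if (any(sds == 0))
    warning("constant centroid(s) ", paste(used[sds == 0], collapse = ", "),
            "; their correlations are taken as 0", call. = FALSE)
  R <- suppressWarnings(stats::cor(t(V)))
  R[!is.finite(R)] <- 0
  adj <- R >= r_threshold
  diag(adj) <- TRUE
  comp <- if (method == "single") .components(adj) else .complete_groups(adj)
  profiles <- split(seq_along(used), comp)
  gene_sets <- lapply(profiles, function(ix)
    names(assignments)[assignments %in% used[ix]])
  sizes <- lengths(gene_sets)
  first_cluster <- vapply(profiles, function(ix) min(used[ix]), integer(1L))
  ord <- order(-sizes, first_cluster)
  profiles <- profiles[ord]
  gene_sets <- gene_sets[ord]
  sizes <- sizes[ord]
  ids <- paste0("C", seq_along(profiles))
  names(gene_sets) <- ids
  names(sizes) <- ids
  mp <- t(vapply(gene_sets, function(g)
    colMeans(X[g, , drop = FALSE]), numeric(ncol(X))))
  dimnames(mp) <- list(ids, colnames(X))
  prov <- character(0)
  for (i in seq_along(profiles))
    prov[as.character(used[profiles[[i]]])] <- ids[i]
  structure(list(profile_ids = ids, gene_sets = gene_sets, sizes = sizes,
                 mean_profiles = mp, provenance = prov,
                 universe_size = sum(sizes), r_threshold = r_threshold),
            class = "profile_set")
}

# connected components of a logical adjacency matrix (union-find)
.components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

# greedy complete-linkage grouping: a cluster joins a group only if it
# reaches the threshold with every current member
.complete_groups <- function(adj) {
  n <- nrow(adj)
  group <- integer(n)
  ng <- 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (g in seq_len(ng)) {
      members <- which(group == g)
      if (all(adj[i, members])) { group[i] <- g; placed <- TRUE; break }
    }
    if (!placed) { ng <- ng + 1L; group[i] <- ng }
  }
  group
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Profile set: ", length(x$profile_ids), " collapsed profiles over ",
      x$universe_size, " genes (r >= ", x$r_threshold, ")\n", sep = "")
  show <- utils::head(x$sizes, 10L)
  cat(paste0("  ", names(show), ": ", show, " genes", collapse = "\n"), "\n")
  if (length(x$sizes) > 10L) cat("  ...\n")
  invisible(x)
}

#' Construct a profile set directly from gene sets
#'
#' Convenience constructor for enrichment analyses where the profile
#' membership is already known (e.g. synthetic truth or externally
#' published profiles) and no clustering is needed.
#'
#' @param gene_sets named list of disjoint gene-id vectors.
#' @param mean_profiles optional k x S matrix of profile means.
#' @param r_threshold recorded threshold (metadata only).
#' @return a `profile_set`.
#' @export
profile_set <- function(gene_sets, mean_profiles = NULL, r_threshold = NA) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  all_g <- unlist(gene_sets, use.names = FALSE)
  if (anyDuplicated(all_g))
    stop("gene_sets must be disjoint", call. = FALSE)
  sizes <- lengths(gene_sets)
  structure(list(profile_ids = names(gene_sets), gene_sets = gene_sets,
                 sizes = stats::setNames(sizes, names(gene_sets)),
                 mean_profiles = mean_profiles,
                 provenance = stats::setNames(names(gene_sets),
                                              names(gene_sets)),
                 universe_size = length(all_g), r_threshold = r_threshold),
            class = "profile_set")
}
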