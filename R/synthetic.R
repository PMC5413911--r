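#' Archetype specification for synthetic stage profiles
#'
#' Describes one temporal archetype used by [simulate_expression()]:
#' `"pulse"` (baseline 0.5 FPKM with a single peak of height `amplitude`
#' at `peak_stage` — below the conventional expressed floor of 2 off-peak,
#' so pulse genes pass a max-expression filter yet read as unexpressed
#' elsewhere, the shape of a zygotic-activation burst), `"monotone_up"` /
#' `"monotone_down"` (linear ramp between 0.5 and `amplitude`) and
#' `"flat"` (constant at `amplitude`).
#'
#' @param kind one of `"pulse"`, `"monotone_up"`, `"monotone_down"`,
#'   `"flat"`.
#' @param proportion fraction of genes drawn from this archetype.
#' @param amplitude FPKM scale of the template (default 50).
#' @param peak_stage 1-based stage index of the pulse peak (pulse only).
#' @return list of class `archetype_spec`.
#' @export
archetype_spec <- function(kind = c("pulse", "monotone_up",
                                    "monotone_down", "flat"),
                           proportion, amplitude = 50, peak_stage = NULL) {
  kind <- match.arg(kind)
  if (kind == "pulse" && is.null(peak_stage))
    stop("pulse archetype needs a peak_stage", call. = FALSE)
  stopifnot(proportion >= 0, amplitude > 0)
  structure(list(kind = kind, proportion = proportion,
                 amplitude = amplitude, peak_stage = peak_stage),
            class = "archetype_spec")
}

.archetype_template <- function(spec, S) {
  switch(spec$kind,
    pulse = {
      if (spec$peak_stage > S)
        stop("peak_stage ", spec$peak_stage, " exceeds stage count ", S,
             call. = FALSE)
      tmpl <- rep(0.5, S)
      tmpl[spec$peak_stage] <- spec$amplitude
      tmpl
    },
    monotone_up = seq(0.5, spec$amplitude, length.out = S),
    monotone_down = seq(spec$amplitude, 0.5, length.out = S),
    flat = rep(spec$amplitude, S))
}

#' Default archetype mix
#'
#' Four well-separated stage-specific pulses in equal proportions, placed
#' at evenly spaced stages. For the default 7-stage series they mimic the
#' dominant burst classes of pre-implantation expression: maternal
#' transcripts peaking in the oocyte, a minor zygotic-activation burst
#' (2-cell), the major activation burst (8-cell) and a blastocyst-specific
#' burst. Pulses are internally tight after standardization (one stage
#' dominates), which is what makes them cleanly separable archetypes;
#' monotone and flat shapes are available via [archetype_spec()] for less
#' idealized mixtures.
#'
#' @param S stage count (default 7).
#' @return list of `archetype_spec`s.
#' @export
default_archetypes <- function(S = 7L) {
  peaks <- unique(round(seq(1L, S, length.out = 4L)))
  lapply(peaks, function(p)
    archetype_spec("pulse", 1 / length(peaks), peak_stage = as.integer(p)))
}

#' Simulate a stage-course expression matrix with known archetypes
#'
#' Each gene is assigned to an archetype (proportions must sum to 1) and
#' its profile is the archetype template perturbed by multiplicative
#' log-normal noise — `value * exp(N(0, noise_sd))` per cell — which keeps
#' FPKM non-negative and right-skewed; an additive Gaussian mode is
#' available for comparison (clipped at 0). All randomness is driven by
#' `seed`.
#'
#' @param G gene count.
#' @param S stage count (>= 3).
#' @param archetypes list of [archetype_spec()]s; proportions must sum
#'   to 1 (default [default_archetypes()]).
#' @param noise_sd noise standard deviation: log-scale for
#'   `noise = "lognormal"`, FPKM-scale for `"additive"`.
#' @param seed integer RNG seed.
#' @param stage_labels optional stage names; default O, Z, 2C, 4C, 8C, M,
#'   B for S = 7, else S1..SS.
#' @param noise `"lognormal"` (default) or `"additive"`.
#' @return list with `matrix` (a validated stage expression matrix) and
#'   `truth` (class `synthetic_truth`: `archetype` labels per gene,
#'   `archetypes`, `seed`).
#' @export
simulate_expression <- function(G, S = 7L, archetypes = default_archetypes(S),
                                noise_sd = 0.2, seed = 1L,
                                stage_labels = NULL,
                                noise = c("lognormal", "additive")) {
  stopifnot(G >= 1L, S >= 3L, noise_sd >= 0)
  noise <- match.arg(noise)
  props <- vapply(archetypes, `[[`, numeric(1L), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop("archetype proportions must sum to 1 (got ", sum(props), ")",
         call. = FALSE)
  if (is.null(stage_labels))
    stage_labels <- if (S == 7L) c("O", "Z", "2C", "4C", "8C", "M", "B")
                    else paste0("S", seq_len(S))
  set.seed(seed)
  # deterministic archetype sizes (largest-remainder), random gene order
  sizes <- .apportion(props, G)
  labels <- sample(rep.int(seq_along(archetypes), sizes))
  templates <- t(vapply(archetypes, .archetype_template, numeric(S), S = S))
  X <- templates[labels, , drop = FALSE]
  if (noise_sd > 0) {
    if (noise == "lognormal") {
      X <- X * exp(matrix(stats::rnorm(G * S, 0, noise_sd), G, S))
    } else {
      X <- X + matrix(stats::rnorm(G * S, 0, noise_sd), G, S)
    }
  }
  X[X < 0] <- 0
  dimnames(X) <- list(sprintf("g%05d", seq_len(G)), stage_labels)
  truth <- structure(list(
    archetype = stats::setNames(labels, rownames(X)),
    archetypes = archetypes, seed = seed), class = "synthetic_truth")
  list(matrix = X, truth = truth)
}

# largest-remainder apportionment of G genes to proportions
.apportion <- function(props, G) {
  raw <- props * G
  sizes <- floor(raw)
  left <- G - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes)
}

#' Draw a responsive gene set spiked in one archetype
#'
#' Samples `n_responsive` genes without replacement with weights `rr` for
#' genes of the spiked archetype and 1 for all others. `rr = 1` is the
#' null (uniform sampling); large `rr` concentrates the responsive set in
#' the spiked archetype.
#'
#' @param truth a `synthetic_truth` from [simulate_expression()], or any
#'   named vector of archetype labels.
#' @param spiked archetype label (index) to enrich.
#' @param n_responsive number of responsive genes to draw.
#' @param rr relative risk (sampling weight ratio), >= 1.
#' @param seed integer RNG seed.
#' @return character vector of responsive gene ids.
#' @export
spike_responsive <- function(truth, spiked, n_responsive, rr = 2,
                             seed = 1L) {
  labels <- if (inherits(truth, "synthetic_truth")) truth$archetype else truth
  stopifnot(rr >= 1, n_responsive >= 0)
  if (n_responsive > length(labels))
    stop("n_responsive exceeds the number of genes", call. = FALSE)
  set.seed(seed)
  w <- ifelse(labels == spiked, rr, 1)
  sample(names(labels), n_responsive, prob = w)
}

#' Simulate a differential-expression table with known truth
#'
#' Null genes get uniform raw p-values and fold changes near 1; true up-
#' and downregulated genes get small raw p-values (Beta(`p_shape`, 1)) and
#' a fold change of exactly `effect_fold` in the proper direction, with
#' the regulated endpoint at FPKM >= 2 so the endpoint filter never
#' removes a true effect. Running [filter_responsive()] on the output
#' recovers the truth with calibrated sensitivity.
#'
#' @param G gene count.
#' @param frac_up,frac_down fractions of truly up-/downregulated genes
#'   (sum <= 1).
#' @param effect_fold fold change of true effects (>= 1.3).
#' @param p_shape beta shape of true-effect raw p-values (default 0.01;
#'   smaller means stronger signal).
#' @param seed integer RNG seed.
#' @return list with `table` (DE-table data frame with `p_raw` filled and
#'   `p_adj` NA), `truth_up`, `truth_down` (character vectors).
#' @export
simulate_de_table <- function(G, frac_up = 0.05, frac_down = 0.05,
                              effect_fold = 2, p_shape = 0.01, seed = 1L) {
  stopifnot(G >= 1L, frac_up >= 0, frac_down >= 0,
            frac_up + frac_down <= 1, effect_fold >= 1)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(G))
  n_up <- round(frac_up * G)
  n_down <- round(frac_down * G)
  status <- rep("null", G)
  status[seq_len(n_up)] <- "up"
  if (n_down > 0) status[n_up + seq_len(n_down)] <- "down"
  status <- sample(status)
  # baseline expression, right-skewed around ~10 FPKM
  base <- stats::rlnorm(G, meanlog = log(10), sdlog = 1)
  ctl <- base
  trt <- base
  p_raw <- stats::runif(G)
  is_up <- status == "up"
  is_down <- status == "down"
  # regulated endpoint forced to >= 2 FPKM
  ctl[is_up] <- pmax(base[is_up], 2) / effect_fold
  trt[is_up] <- pmax(base[is_up], 2)
  ctl[is_down] <- pmax(base[is_down], 2)
  trt[is_down] <- pmax(base[is_down], 2) / effect_fold
  # nulls wobble by < 30 percent so they cannot pass the fold filter
  wobble <- stats::runif(sum(status == "null"), 1 / 1.25, 1.25)
  trt[status == "null"] <- trt[status == "null"] * wobble
  p_raw[is_up | is_down] <- stats::rbeta(n_up + n_down, p_shape, 1)
  table <- data.frame(gene = genes, mean_control = ctl, mean_treated = trt,
                      p_raw = p_raw, p_adj = NA_real_,
                      stringsAsFactors = FALSE)
  list(table = table, truth_up = genes[is_up], truth_down = genes[is_down])
}
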