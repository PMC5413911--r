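#' Pipeline configuration
#'
#' Assembles and validates the configuration shared by the pipeline
#' commands. Defaults carry the analysis constants: expression floor 2
#' FPKM, variance filter 5, 160 initial clusters, collapse threshold
#' r = 0.95, significance level 0.05 and fold-change threshold 1.3.
#'
#' @param matrix path to the expression-matrix TSV (NULL when simulating).
#' @param de_table path to the DE-table TSV.
#' @param out_dir output directory.
#' @param min_expr expressed floor, FPKM (default 2).
#' @param min_var variance filter, FPKM^2 (default 5).
#' @param c initial cluster count (default 160).
#' @param m fuzzifier (default 1.25).
#' @param seed RNG seed (default 1).
#' @param tol fuzzy c-means convergence tolerance (default 1e-6).
#' @param max_iter fuzzy c-means iteration cap (default 1000).
#' @param r_threshold collapse correlation threshold (default 0.95).
#' @param alpha significance level for filtering and stepwise tests
#'   (default 0.05).
#' @param min_fold fold-change threshold (default 1.3).
#' @param min_fpkm endpoint expression floor for responsive genes
#'   (default 2).
#' @param fisher_alternative Fisher tail convention (default two-sided).
#' @param sim parameters for [cmd_simulate()]: a list with `G`, `S`,
#'   `noise_sd`, `frac_up`, `frac_down`, `effect_fold`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix = NULL, de_table = NULL,
                            out_dir = "tempenrich_out",
                            min_expr = 2, min_var = 5, c = 160L, m = 1.25,
                            seed = 1L, tol = 1e-6, max_iter = 1000L,
                            r_threshold = 0.95, alpha = 0.05,
                            min_fold = 1.3, min_fpkm = 2,
                            fisher_alternative = "two.sided",
                            sim = list(G = 2000L, S = 7L, noise_sd = 0.2,
                                       frac_up = 0.05, frac_down = 0.05,
                                       effect_fold = 2)) {
  cfg <- list(matrix = matrix, de_table = de_table, out_dir = out_dir,
              min_expr = min_expr, min_var = min_var, c = c, m = m,
              seed = seed, tol = tol, max_iter = max_iter,
              r_threshold = r_threshold, alpha = alpha,
              min_fold = min_fold, min_fpkm = min_fpkm,
              fisher_alternative = fisher_alternative, sim = sim)
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a configuration list to validate.
#' @export
validate_config <- function(cfg) {
  chk <- function(field, ok)
    if (!ok) stop("invalid config field '", field, "'", call. = FALSE)
  chk("min_expr", is.numeric(cfg$min_expr) && cfg$min_expr >= 0)
  chk("min_var", is.numeric(cfg$min_var) && cfg$min_var >= 0)
  chk("c", is.numeric(cfg$c) && cfg$c >= 1)
  chk("m", is.numeric(cfg$m) && cfg$m > 1)
  chk("seed", is.numeric(cfg$seed) && cfg$seed == round(cfg$seed))
  chk("tol", is.numeric(cfg$tol) && cfg$tol > 0)
  chk("max_iter", is.numeric(cfg$max_iter) && cfg$max_iter >= 1)
  chk("r_threshold", is.numeric(cfg$r_threshold))
  chk("alpha", is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha <= 1)
  chk("min_fold", is.numeric(cfg$min_fold) && cfg$min_fold >= 1)
  chk("min_fpkm", is.numeric(cfg$min_fpkm) && cfg$min_fpkm >= 0)
  chk("fisher_alternative",
      cfg$fisher_alternative %in% c("two.sided", "greater", "less"))
  known <- c("matrix", "de_table", "out_dir", "min_expr", "min_var", "c",
             "m", "seed", "tol", "max_iter", "r_threshold", "alpha",
             "min_fold", "min_fpkm", "fisher_alternative", "sim")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read or write a pipeline configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`); unknown keys are rejected with
#' the offending field named.
#'
#' @param path config file path.
#' @return for `read_config`, a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- pipeline_config()
  cfg <- utils::modifyList(unclass(defaults), raw)
  for (f in c("matrix", "de_table"))          # keep explicit NULL slots
    if (!f %in% names(cfg)) cfg[f] <- list(NULL)
  cfg <- cfg[names(defaults)]
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(unclass(cfg), path)
  else jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                            pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

# short md5 of the analysis parameters (paths excluded, so the same
# parameters hash identically wherever the files live)
config_hash <- function(cfg) {
  params <- unclass(cfg)
  params <- params[setdiff(names(params), c("matrix", "de_table",
                                            "out_dir"))]
  params <- params[order(names(params))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(params, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  substr(unname(tools::md5sum(tmp)), 1L, 12L)
}

.meta <- function(cfg) {
  list(seed = cfg$seed, config_hash = config_hash(cfg))
}

.log <- function(...) message("[tempenrich] ", ...)

#' Simulate pipeline inputs
#'
#' Writes a synthetic expression matrix (`matrix.tsv`), DE table
#' (`de_table.tsv`), truth tables (`truth_archetypes.tsv`,
#' `truth_de.json`) and the resolved config (`config.json`) into
#' `cfg$out_dir`. Every file carries the seed and config hash.
#'
#' @param cfg a `pipeline_config` (the `sim` entry sets sizes and effect
#'   parameters).
#' @return invisibly, a list with the generated objects and file paths.
#' @export
cmd_simulate <- function(cfg = pipeline_config()) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- .meta(cfg)
  hdr <- paste0(c("seed=", "config="), unlist(meta))
  sim <- cfg$sim
  expr <- simulate_expression(G = sim$G, S = sim$S, noise_sd = sim$noise_sd,
                              seed = cfg$seed)
  de <- simulate_de_table(G = sim$G, frac_up = sim$frac_up,
                          frac_down = sim$frac_down,
                          effect_fold = sim$effect_fold,
                          seed = cfg$seed + 1L)
  mpath <- file.path(cfg$out_dir, "matrix.tsv")
  write_expression_matrix(expr$matrix, mpath, comment = hdr)
  dpath <- file.path(cfg$out_dir, "de_table.tsv")
  con <- file(dpath, "wt")
  writeLines(paste0("# ", hdr), con)
  suppressWarnings(utils::write.table(de$table, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  close(con)
  tpath <- file.path(cfg$out_dir, "truth_archetypes.tsv")
  utils::write.table(data.frame(gene = names(expr$truth$archetype),
                                archetype = expr$truth$archetype),
                     tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  jpath <- file.path(cfg$out_dir, "truth_de.json")
  jsonlite::write_json(c(list(truth_up = de$truth_up,
                              truth_down = de$truth_down), meta),
                       jpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_config(cfg, file.path(cfg$out_dir, "config.json"))
  .log("simulated ", sim$G, " genes x ", sim$S, " stages (seed ", cfg$seed,
       ")")
  invisible(list(matrix = expr$matrix, truth = expr$truth, de = de,
                 paths = c(matrix = mpath, de_table = dpath,
                           truth = tpath, truth_de = jpath)))
}

#' Build temporal profiles from an expression matrix
#'
#' Runs filter -> standardize -> fuzzy c-means -> hard assignment ->
#' collapse, writing `assignments.tsv`
#' (`gene<TAB>initial_cluster<TAB>profile_id`) and `profiles.json`. Gene
#' counts at each stage are logged.
#'
#' @param cfg a `pipeline_config`; `cfg$matrix` must point at an
#'   expression TSV.
#' @return invisibly, a list with the `profile_set`, the clustering, the
#'   assignments and file paths.
#' @export
cmd_profiles <- function(cfg) {
  cfg <- validate_config(cfg)
  if (is.null(cfg$matrix) || !file.exists(cfg$matrix))
    stop("config 'matrix' must point at an existing expression TSV",
         call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  x <- read_expression_matrix(cfg$matrix)
  .log("loaded ", nrow(x), " genes x ", ncol(x), " stages")
  xf <- filter_expressed_variance(x, cfg$min_expr, cfg$min_var)
  .log("retained ", nrow(xf), " expressed genes with variance >= ",
       cfg$min_var)
  if (nrow(xf) < cfg$c)
    stop("only ", nrow(xf), " genes retained but c = ", cfg$c,
         "; use a smaller c", call. = FALSE)
  z <- standardize_profiles(xf)
  fit <- fuzzy_cmeans(z, c = cfg$c, m = cfg$m, seed = cfg$seed,
                      tol = cfg$tol, max_iter = cfg$max_iter)
  assign <- harden(fit)
  .log(length(unique(assign)), " of ", cfg$c, " clusters non-empty")
  ps <- collapse_profiles(fit, assign, z, r_threshold = cfg$r_threshold)
  .log("collapsed to ", length(ps$profile_ids), " profiles at r >= ",
       cfg$r_threshold)
  meta <- .meta(cfg)
  apath <- file.path(cfg$out_dir, "assignments.tsv")
  con <- file(apath, "wt")
  writeLines(paste0("# seed=", meta$seed, " config=", meta$config_hash), con)
  utils::write.table(data.frame(
    gene = names(assign), initial_cluster = assign,
    profile_id = ps$provenance[as.character(assign)]),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  ppath <- file.path(cfg$out_dir, "profiles.json")
  write_profile_set(ps, ppath,
                    meta = c(meta, list(c = cfg$c, m = cfg$m)))
  invisible(list(profiles = ps, clustering = fit, assignments = assign,
                 standardized = z,
                 paths = c(assignments = apath, profiles = ppath)))
}

#' Serialize / load a profile set as JSON
#'
#' @param ps a `profile_set`.
#' @param path JSON path.
#' @param meta optional named metadata list.
#' @return the path (write) or a `profile_set` (read), invisibly for
#'   write.
#' @export
write_profile_set <- function(ps, path, meta = NULL) {
  stopifnot(inherits(ps, "profile_set"))
  out <- c(list(profile_ids = ps$profile_ids,
                sizes = as.list(ps$sizes),
                gene_sets = ps$gene_sets,
                mean_profiles = ps$mean_profiles,
                provenance = as.list(ps$provenance),
                universe_size = ps$universe_size,
                r_threshold = ps$r_threshold), meta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_profile_set
#' @export
read_profile_set <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gs <- lapply(raw$gene_sets, as.character)
  mp <- raw$mean_profiles
  if (!is.null(mp)) {
    mp <- as.matrix(mp)
    rownames(mp) <- raw$profile_ids
  }
  structure(list(profile_ids = raw$profile_ids, gene_sets = gs,
                 sizes = stats::setNames(unlist(raw$sizes),
                                         names(raw$sizes)),
                 mean_profiles = mp,
                 provenance = stats::setNames(unlist(raw$provenance),
                                              names(raw$provenance)),
                 universe_size = raw$universe_size,
                 r_threshold = raw$r_threshold),
            class = "profile_set")
}

#' Filter a DE table into responsive gene sets
#'
#' @param cfg a `pipeline_config`; `cfg$de_table` must exist.
#' @return invisibly, the `responsive_sets` and output directory.
#' @export
cmd_filter_de <- function(cfg) {
  cfg <- validate_config(cfg)
  if (is.null(cfg$de_table) || !file.exists(cfg$de_table))
    stop("config 'de_table' must point at an existing DE TSV",
         call. = FALSE)
  table <- read_de_table(cfg$de_table)
  sets <- filter_responsive(table, alpha = cfg$alpha,
                            min_fpkm = cfg$min_fpkm,
                            min_fold = cfg$min_fold)
  .log(length(sets$up), " up / ", length(sets$down),
       " down responsive genes of ", nrow(table))
  write_responsive_sets(sets, cfg$out_dir, meta = .meta(cfg))
  invisible(list(sets = sets, out_dir = cfg$out_dir))
}

#' Run the enrichment stage of the pipeline
#'
#' Loads a profile set (`profiles.json` in `out_dir` unless `profiles` is
#' given) and responsive sets (from the DE table via the filter rules, or
#' pre-computed `up.txt`/`down.txt`), then runs [run_enrichment()] and
#' writes its reports. Empty responsive sets produce a report plus a
#' warning, not an error.
#'
#' @param cfg a `pipeline_config`.
#' @param profiles optional `profile_set` (else read from
#'   `out_dir/profiles.json`).
#' @return invisibly, the `enrichment_report`.
#' @export
cmd_enrich <- function(cfg, profiles = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(profiles))
    profiles <- read_profile_set(file.path(cfg$out_dir, "profiles.json"))
  if (!is.null(cfg$de_table)) {
    sets <- cmd_filter_de(cfg)$sets
    up <- sets$up; down <- sets$down
  } else {
    upf <- file.path(cfg$out_dir, "up.txt")
    dnf <- file.path(cfg$out_dir, "down.txt")
    if (!file.exists(upf) || !file.exists(dnf))
      stop("need a de_table or ", upf, " / ", dnf, call. = FALSE)
    up <- readLines(upf); down <- readLines(dnf)
  }
  if (!length(up) && !length(down))
    warning("both responsive sets are empty; writing empty report",
            call. = FALSE)
  report <- run_enrichment(up, down, profiles, alpha = cfg$alpha,
                           alternative = cfg$fisher_alternative)
  for (d in c("up", "down"))
    .log(d, ": ", report[[d]]$counts$n_responsive_assigned, " assigned, ",
         report[[d]]$counts$n_dropped, " dropped, ",
         nrow(report[[d]]$steps), " profiles selected")
  write_enrichment_report(report, cfg$out_dir, meta = .meta(cfg))
  invisible(report)
}

#' Write the max-normalized matrix used for heat-map-style reporting
#'
#' @param cfg a `pipeline_config` with `matrix` set; writes
#'   `normalized.tsv` in `out_dir`.
#' @return invisibly, the normalized matrix.
#' @export
cmd_normalize <- function(cfg) {
  cfg <- validate_config(cfg)
  if (is.null(cfg$matrix) || !file.exists(cfg$matrix))
    stop("config 'matrix' must point at an existing expression TSV",
         call. = FALSE)
  x <- read_expression_matrix(cfg$matrix)
  nx <- normalize_to_max(x, floor = cfg$min_expr)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- .meta(cfg)
  write_expression_matrix(nx, file.path(cfg$out_dir, "normalized.tsv"),
                          comment = paste0("seed=", meta$seed, " config=",
                                           meta$config_hash))
  invisible(nx)
}
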