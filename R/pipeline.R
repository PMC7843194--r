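# end-to-end orchestration: filtering -> surface Laplacian -> hidden-size
# selection -> stacked-autoencoder training -> feature extraction -> RPFA ->
# conditional Granger causality

condition_bands <- function(condition) {
  switch(condition,
         awake = list(band_spec("alpha"), band_spec("beta")),
         fatigue = ,
         sleep_deprivation = list(band_spec("delta"), band_spec("theta")),
         stop_param("unknown condition: ", condition))
}

#' Pipeline configuration
#'
#' Collects every stage's settings. `input` is either
#' `list(type = "synthetic", spec = synthetic_spec(...))` or
#' `list(type = "edf", path =, montage =, areas =)` (montage/areas as used by
#' [eeg_recording()]). The awake condition scores RPFA over alpha + beta;
#' fatigue and sleep deprivation over delta + theta.
#'
#' @param input input description (see above); default: the synthetic spec's
#'   defaults.
#' @param condition `"awake"`, `"fatigue"` or `"sleep_deprivation"`.
#' @param bandpass `NULL` to skip, else
#'   `list(lo =, hi =, notch_lo =, notch_hi =)` (`notch_*` may be `NULL` to
#'   skip the notch). The default applies the 0.5 Hz high-pass edge at the
#'   120 Hz working rate (no notch; no mains component below that Nyquist);
#'   for native 1200 Hz recordings use `lo = 0.5, hi = 100` with a 48-52 Hz
#'   notch.
#' @param laplacian apply the surface Laplacian? (default `TRUE`).
#' @param decimate_to target rate in Hz or `NULL` to keep the native rate.
#' @param selection a [selection_config()], or `NULL` to skip the grid search
#'   and use `fixed_nm`.
#' @param fixed_nm integer vector `c(n, m)` used when `selection` is `NULL`.
#' @param train a [train_config()].
#' @param gc list: `p_max`, `n_perm`, `alpha`.
#' @param out_dir artifact directory or `NULL` for in-memory results only.
#' @param seed global seed; stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = list(type = "synthetic",
                                         spec = synthetic_spec()),
                            condition = "awake",
                            bandpass = list(lo = 0.5, hi = 40,
                                            notch_lo = NULL, notch_hi = NULL),
                            laplacian = TRUE,
                            decimate_to = NULL,
                            selection = selection_config(U_def = 30, C_def = 8,
                                                         C_com = 5),
                            fixed_nm = c(8L, 3L),
                            train = train_config(),
                            gc = list(p_max = 20, n_perm = 199, alpha = 0.01),
                            out_dir = NULL,
                            seed = 1L) {
  condition <- match.arg(condition, c("awake", "fatigue", "sleep_deprivation"))
  structure(list(input = input, condition = condition, bandpass = bandpass,
                 laplacian = laplacian, decimate_to = decimate_to,
                 selection = selection, fixed_nm = fixed_nm, train = train,
                 gc = gc, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `input.spec`, `selection`, and `train` sub-maps are passed to their
#' constructors. Rhythm and coupling lists inside a synthetic spec use the
#' plain-list form of [synthetic_spec()] with `band` given as a band name.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  y <- yaml::read_yaml(path)
  input <- y$input %||% list(type = "synthetic")
  if (identical(input$type, "synthetic")) {
    sp <- input$spec %||% list()
    if (!is.null(sp$rhythms))
      sp$rhythms <- lapply(sp$rhythms, function(r) {
        r$band <- band_spec(r$band %||% "custom", r$lo, r$hi)
        r[c("band", "center", "amplitude")]
      })
    input$spec <- do.call(synthetic_spec, sp)
  }
  args <- list(input = input)
  for (k in c("condition", "laplacian", "decimate_to", "out_dir", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$bandpass)) args$bandpass <- y$bandpass
  if (!is.null(y$selection))
    args$selection <- do.call(selection_config, y$selection)
  if (!is.null(y$fixed_nm)) args$fixed_nm <- as.integer(unlist(y$fixed_nm))
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$gc)) args$gc <- utils::modifyList(
    list(p_max = 20, n_perm = 199, alpha = 0.01), y$gc)
  do.call(pipeline_config, args)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_input <- function(cfg) {
  if (identical(cfg$input$type, "synthetic")) {
    sp <- cfg$input$spec
    sp$seed <- child_seed(cfg$seed, 11L)
    gen <- generate_synthetic(sp)
    list(rec = gen$recording, truth = gen$adjacency)
  } else if (identical(cfg$input$type, "edf")) {
    rec <- read_edf(cfg$input$path)
    rec$montage <- cfg$input$montage
    rec$areas <- cfg$input$areas
    validate_recording(rec)
    list(rec = rec, truth = NULL)
  } else stop_param("unknown input type: ", cfg$input$type)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: input (EDF or synthetic) -> optional band-pass/notch ->
#' optional surface Laplacian -> optional decimation -> per-area hidden-size
#' selection (c_f grid search, scores averaged across areas to pick one
#' shared `(n, m)`) -> per-area stacked-autoencoder training and feature
#' extraction -> RPFA comparison table (original / PCA / SDAE) -> VAR order
#' selection and conditional Granger causality with permutation significance.
#' Every artifact carries the configuration hash and seed; a rerun with the
#' same configuration and seed reproduces all numbers exactly.
#'
#' @param cfg a [pipeline_config()].
#' @return list: `recording` (preprocessed), `selection` (per-area grids and
#'   shared choice), `models` (per-area `sdae_model`), `features`
#'   (areas x samples matrix), `rpfa` (data frame), `order` (selected VAR
#'   order + diagnostics), `connectivity` (a `connectivity_result`), `edges`
#'   (significant edge list), `truth` (ground-truth adjacency or `NULL`),
#'   `meta` (config hash, seed, versions).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))

  inp <- stage("input", pipeline_input(cfg))
  rec <- inp$rec
  if (!is.null(cfg$bandpass))
    rec <- stage("bandpass", bandpass_notch(
      rec, band_spec("custom", cfg$bandpass$lo, cfg$bandpass$hi),
      cfg$bandpass$notch_lo, cfg$bandpass$notch_hi))
  if (isTRUE(cfg$laplacian))
    rec <- stage("laplacian", surface_laplacian(rec))
  if (!is.null(cfg$decimate_to) && cfg$decimate_to < rec$fs)
    rec <- stage("decimate", decimate_recording(rec, cfg$decimate_to))
  if (is.null(rec$areas)) stop_param("no area map attached to the recording")

  tcfg <- cfg$train
  tcfg$seed <- child_seed(cfg$seed, 23L)

  # hidden-size selection: per-area c_f grids, averaged to one shared (n, m)
  sel <- NULL
  if (!is.null(cfg$selection)) {
    grids <- stage("selection", lapply(names(rec$areas), function(a)
      grid_search(area_matrix(rec, a), rec$fs, cfg$selection, tcfg)$grid))
    mean_cf <- Reduce(`+`, lapply(grids, function(g) g$cf)) / length(grids)
    best <- which(mean_cf == max(mean_cf))
    best <- best[order(grids[[1]]$m[best], grids[[1]]$n[best])][1]
    nm <- c(n = grids[[1]]$n[best], m = grids[[1]]$m[best])
    sel <- list(grids = stats::setNames(grids, names(rec$areas)),
                mean_cf = mean_cf, chosen = nm)
  } else {
    nm <- c(n = as.integer(cfg$fixed_nm[1]), m = as.integer(cfg$fixed_nm[2]))
  }

  models <- stage("train", lapply(names(rec$areas), function(a)
    stack_train(area_matrix(rec, a), nm["n"], nm["m"], tcfg)))
  names(models) <- names(rec$areas)
  features <- stage("extract", t(vapply(names(rec$areas), function(a)
    extract_feature(models[[a]], area_matrix(rec, a)),
    numeric(ncol(rec$data)))))

  bands <- condition_bands(cfg$condition)
  rpfa_tab <- stage("rpfa", rpfa_table(rec, models, bands))

  ord <- stage("gca", select_order(features, cfg$gc$p_max))
  conn <- stage("gca", significance(features, ord$p,
                                    n_perm = cfg$gc$n_perm,
                                    alpha = cfg$gc$alpha,
                                    seed = child_seed(cfg$seed, 37L)))
  edges <- connectivity_graph(names(rec$areas), conn)

  meta <- list(config_hash = config_hash(cfg), seed = cfg$seed,
               chosen_n = unname(nm["n"]), chosen_m = unname(nm["m"]),
               var_order = ord$p, condition = cfg$condition,
               package_version = as.character(utils::packageVersion("eegsdae")),
               r_version = R.version.string)
  out <- list(recording = rec, selection = sel, models = models,
              features = features, rpfa = rpfa_tab, order = ord,
              connectivity = conn, edges = edges, truth = inp$truth,
              meta = meta)
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(out, cfg$out_dir)
  out
}

write_pipeline_artifacts <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- out$meta
  utils::write.csv(cbind(out$rpfa, config_hash = meta$config_hash),
                   file.path(dir, "rpfa.csv"), row.names = FALSE)
  edges <- out$edges
  edges$config_hash <- rep(meta$config_hash, nrow(edges))
  utils::write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  if (!is.null(out$selection)) {
    g <- do.call(rbind, lapply(names(out$selection$grids), function(a)
      cbind(area = a, out$selection$grids[[a]])))
    utils::write.csv(cbind(g, config_hash = meta$config_hash),
                     file.path(dir, "selection_grid.csv"), row.names = FALSE)
  }
  feat <- out$features
  utils::write.table(format(feat, digits = 17, trim = TRUE),
                     file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
                     row.names = rownames(feat), col.names = FALSE)
  jsonlite::write_json(
    list(meta = meta,
         F = out$connectivity$F, pvals = out$connectivity$pvals,
         adjacency = out$connectivity$adjacency,
         alpha = out$connectivity$alpha,
         order_table = out$order$table),
    file.path(dir, "connectivity.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor", na = "null")
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
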