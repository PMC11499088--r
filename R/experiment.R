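# End-to-end experiment driver: generate a labelled synthetic cohort, build
# the reduction-level dataset variants, register, establish correspondence,
# fit the shape models, compute the evaluation metric curves, cluster each
# level's scores against the ground-truth labels, and emit a comparison
# report. Fully deterministic given the master seed.

#' Experiment configuration
#'
#' Desk-scale defaults (40 shapes, 256 particles) keep a full run in the
#' minutes range; `paper_scale = TRUE` switches to the full-study conditions
#' (85 shapes, 1024 particles, 0.5 mm meshes).
#'
#' @param cohort a [cohort_spec()]; built from `master_seed` when NULL.
#' @param levels integer reduction factors; 1 (the reference) is always
#'   included.
#' @param K,K_init particle counts for correspondence.
#' @param n_m_max largest mode count in the evaluation curves.
#' @param M specificity draws per mode count.
#' @param threshold variance threshold for retained PCs.
#' @param k_min,k_max silhouette search range.
#' @param register run multiview registration (`max_rounds` rounds); the
#'   generator emits shapes in a shared canonical frame, so registration
#'   mainly exercises the pipeline and tidies residual pose differences.
#' @param max_rounds multiview refinement rounds.
#' @param n_shapes cohort size used when `cohort` is NULL.
#' @param master_seed seed for everything.
#' @param out_dir output directory or NULL for no file output.
#' @param paper_scale use full-study conditions.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = NULL, levels = c(1L, 2L, 4L, 8L, 16L),
                              K = 256L, K_init = 128L, n_m_max = 12L, M = 250L,
                              threshold = 0.85, k_min = 2L, k_max = 10L,
                              register = TRUE, max_rounds = 2L,
                              n_shapes = 40L, master_seed = 1L,
                              out_dir = NULL, paper_scale = FALSE) {
  if (paper_scale) {
    n_shapes <- 85L
    K <- 1024L
    K_init <- 128L
  }
  if (is.null(cohort))
    cohort <- cohort_spec(n_shapes = n_shapes,
                          mesh_resolution = if (paper_scale) 0.5 else 0.8,
                          master_seed = master_seed)
  levels <- sort(unique(as.integer(c(1L, levels))))
  structure(list(cohort = cohort, levels = levels, K = as.integer(K),
                 K_init = as.integer(K_init), n_m_max = as.integer(n_m_max),
                 M = as.integer(M), threshold = threshold,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 register = register, max_rounds = as.integer(max_rounds),
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Load an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; cohort
#' parameters go under a `cohort:` mapping with [cohort_spec()] argument
#' names.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @export
read_experiment_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  cohort <- if (!is.null(cfg$cohort)) do.call(cohort_spec, cfg$cohort) else NULL
  cfg$cohort <- NULL
  args <- utils::modifyList(cfg, list(...))
  args$cohort <- cohort
  do.call(experiment_config, args)
}

stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the full detail-preservation experiment
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return object of class `experiment_report`: list with `levels`,
#'   `curves`, `diff`, `clustering` (per level), `headline` (AMI of the
#'   reference vs the 4x level), `detail_energy`, `registration`, `labels`,
#'   `config`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$master_seed
  t_start <- Sys.time()

  stage_msg(quiet, "generating cohort of %d shapes", config$cohort$n_shapes)
  cohort <- generate_cohort(config$cohort)
  meshes <- lapply(cohort$meshes, normalize_volume)

  reg_report <- NULL
  if (config$register) {
    stage_msg(quiet, "registering (max %d multiview rounds)", config$max_rounds)
    reg <- withCallingHandlers(
      multiview_register(meshes, reference_index = 1L,
                         max_rounds = config$max_rounds,
                         seed = derive_seed(seed, 201L)),
      morphodetail_warning = function(w) invokeRestart("muffleWarning"))
    meshes <- reg$meshes
    reg_report <- reg$report
  }

  level_names <- paste0("R", config$levels)
  datasets <- list()
  detail <- numeric(0)
  smooth_refs <- lapply(seq_along(meshes), function(i) {
    sm <- normalize_volume(smooth_counterpart(cohort$specs[[i]]))
    if (config$register && !is.null(reg_report))
      sm <- transform_mesh(sm, reg$transforms[[i]]$rotation,
                           reg$transforms[[i]]$translation)
    sm
  })
  for (li in seq_along(config$levels)) {
    R <- config$levels[li]
    stage_msg(quiet, "building dataset R=%d", R)
    datasets[[level_names[li]]] <-
      simplify_dataset(meshes, reduction_level(R), seed = derive_seed(seed, 301L, R))
    detail[level_names[li]] <- mean(vapply(seq_along(meshes), function(i)
      detail_energy(datasets[[level_names[li]]][[i]], smooth_refs[[i]]),
      numeric(1)))
  }

  corr <- list()
  models <- list()
  for (nm in level_names) {
    stage_msg(quiet, "correspondence + PCA for %s (K=%d)", nm, config$K)
    corr[[nm]] <- establish_correspondence(datasets[[nm]], K = config$K,
                                           K_init = config$K_init,
                                           seed = derive_seed(seed, 401L, match(nm, level_names)))
    models[[nm]] <- fit_pca(corr[[nm]])
  }

  stage_msg(quiet, "evaluation curves")
  ev <- evaluation_suite(corr, n_m_max = config$n_m_max, M = config$M,
                         seed = derive_seed(seed, 501L), reference = "R1")

  stage_msg(quiet, "clustering")
  ref_n_m <- retain_pcs(models[["R1"]], config$threshold)
  clust <- lapply(level_names, function(nm)
    cluster_and_score(models[[nm]], cohort$labels,
                      reference_n_m = if (nm == "R1") NULL else ref_n_m,
                      threshold = config$threshold,
                      k_min = config$k_min, k_max = config$k_max))
  names(clust) <- level_names

  headline <- list(
    reference_level = "R1",
    comparison_level = if ("R4" %in% level_names) "R4" else utils::tail(level_names, 1),
    ami_reference = clust[["R1"]]$ami,
    ami_comparison = clust[[if ("R4" %in% level_names) "R4" else utils::tail(level_names, 1)]]$ami
  )

  report <- structure(list(
    levels = level_names,
    curves = ev$curves,
    diff = ev$diff,
    clustering = clust,
    headline = headline,
    detail_energy = detail,
    registration = reg_report,
    labels = cohort$labels,
    retained_n_m = ref_n_m,
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    config = config
  ), class = "experiment_report")

  if (!is.null(config$out_dir)) write_experiment_report(report, config$out_dir)
  report
}

#' Write an experiment report bundle (CSV + JSON)
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in report$levels)
    utils::write.csv(report$curves[[nm]],
                     file.path(dir, sprintf("curves_%s.csv", nm)), row.names = FALSE)
  utils::write.csv(report$diff, file.path(dir, "diff_vs_reference.csv"),
                   row.names = FALSE)
  for (nm in report$levels) {
    cl <- report$clustering[[nm]]
    jsonlite::write_json(
      list(level = nm, n_m = cl$n_m, variance_covered = cl$variance_covered,
           k = cl$k, silhouette = cl$silhouette, ami = cl$ami,
           cluster_sizes = cl$cluster_sizes, cluster_labels = cl$cluster_labels,
           stable = cl$stable),
      file.path(dir, sprintf("clustering_%s.json", nm)),
      auto_unbox = TRUE, digits = NA)
    merge_tab <- data.frame(id_a = cl$linkage$merge[, 1],
                            id_b = cl$linkage$merge[, 2],
                            height = cl$linkage$height)
    utils::write.csv(merge_tab, file.path(dir, sprintf("linkage_%s.csv", nm)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(levels = report$levels, headline = report$headline,
         detail_energy = as.list(report$detail_energy),
         retained_n_m = report$retained_n_m,
         labels = report$labels,
         registration_converged = if (is.null(report$registration)) NA
           else report$registration$converged,
         master_seed = report$config$master_seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' One-row-per-level summary of an experiment report
#'
#' @param report an `experiment_report`.
#' @param n_m mode count at which curve values are quoted; defaults to the
#'   retained-PC count of the reference level.
#' @return data.frame, printed by [print.experiment_report()].
#' @export
report_summary <- function(report, n_m = NULL) {
  if (length(report$levels) == 0L)
    return(data.frame(level = character(0)))
  n_m <- as.integer(n_m %||% min(report$retained_n_m,
                                 nrow(report$curves[[1]])))
  do.call(rbind, lapply(report$levels, function(nm) {
    cur <- report$curves[[nm]]
    row <- cur[min(n_m, nrow(cur)), ]
    cl <- report$clustering[[nm]]
    data.frame(level = nm, n_m = row$n_m,
               compactness = row$compactness_norm,
               generalisation_mm = row$generalisation_mm,
               specificity_mm = row$specificity_mm,
               detail_energy_mm = unname(report$detail_energy[nm]),
               k = cl$k, silhouette = cl$silhouette, ami = cl$ami)
  }))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment: %d levels, %d shapes, seed %d (%.1f s)\n",
              length(x$levels), length(x$labels), x$config$master_seed,
              x$runtime_s))
  print(report_summary(x), row.names = FALSE, digits = 4)
  cat(sprintf("headline: AMI %s = %.4f vs %s = %.4f\n",
              x$headline$reference_level, x$headline$ami_reference,
              x$headline$comparison_level, x$headline$ami_comparison))
  invisible(x)
}
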