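#' Assemble a pipeline run configuration
#'
#' Either `generator` (a [generator_config()], a list of its arguments,
#' or a path to a YAML/JSON file with a `generator` section) or the three
#' ingest paths (`site_file`, `contact_file`, `annotation_file`) must be
#' supplied. The analysis defaults reproduce the published parameters:
#' convergence radius 300 nm, minimum expected count 0.5, fit-class
#' thresholds 0.05 / 0.003.
#'
#' @param generator Generator configuration (see above), or `NULL` when ingesting.
#' @param site_file,contact_file,annotation_file Ingest paths.
#' @param radius Convergence radius, nm.
#' @param coverage_radii Radii grid for coverage curves, nm.
#' @param min_expected Bin-retention threshold for the chi-square fits.
#' @param df_convention Degrees-of-freedom convention, see [chi2_gof()].
#' @param seed Overrides the generator seed when given.
#' @return List of class `run_config`.
#' @export
run_config <- function(generator = NULL, site_file = NULL,
                       contact_file = NULL, annotation_file = NULL,
                       radius = 300, coverage_radii = seq(0, 5000, by = 100),
                       min_expected = 0.5,
                       df_convention = c("bins", "bins_minus_2"),
                       seed = NULL) {
  df_convention <- match.arg(df_convention)
  if (is.null(generator) && is.null(site_file))
    stop("supply either a generator configuration or ingest file paths", call. = FALSE)
  if (!is.null(generator) && !inherits(generator, "generator_config")) {
    if (is.character(generator)) generator <- read_generator_config(generator)
    else generator <- do.call(generator_config, generator)
  }
  if (!is.null(generator) && !is.null(seed)) generator$seed <- as.integer(seed)
  structure(
    list(generator = generator, site_file = site_file,
         contact_file = contact_file, annotation_file = annotation_file,
         radius = radius, coverage_radii = coverage_radii,
         min_expected = min_expected, df_convention = df_convention,
         seed = if (!is.null(seed)) as.integer(seed) else
           if (!is.null(generator)) generator$seed else NULL),
    class = "run_config")
}

read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  gen <- cfg$generator
  if (!is.null(gen)) {
    args <- gen
    if (!is.null(args$n_kc)) args$n_kc <- unlist(args$n_kc)
    if (!is.null(args$compartment_length))
      args$compartment_length <- unlist(args$compartment_length)
    gen <- do.call(generator_config, args)
  }
  rad <- cfg$coverage_radii_nm
  radii <- if (is.null(rad)) seq(0, 5000, by = 100) else
    seq(rad$from, rad$to, by = rad$by)
  run_config(generator = gen,
             site_file = cfg$site_file, contact_file = cfg$contact_file,
             annotation_file = cfg$annotation_file,
             radius = if (is.null(cfg$radius)) 300 else cfg$radius,
             coverage_radii = radii,
             min_expected = if (is.null(cfg$min_expected)) 0.5 else
               cfg$min_expected,
             df_convention = if (is.null(cfg$df_convention)) "bins" else
               cfg$df_convention,
             seed = cfg$seed)
}

#' Run the full wiring-analysis pipeline
#'
#' Generation (or ingestion), wiring tables, Poisson-fit grid with colour
#' classes, motif detection and fractions, volume-transmission coverage,
#' and (when skeletons are present) input-position profiles — written as
#' delimited tables plus a JSON metrics bundle. Identical configuration
#' and seed give a byte-identical metrics file. Every number in the
#' metrics is reproducible by calling the underlying function directly.
#'
#' @param config A [run_config()], or a path to a YAML run configuration.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress stage progress messages.
#' @return The metrics list, invisibly; files are written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[mbwiring] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  metrics <- list()

  # --- ingest / generate ----------------------------------------------
  truth <- NULL
  x <- stage("input", {
    if (!is.null(config$generator)) {
      say("generating synthetic connectome (seed ", config$generator$seed, ")")
      g <- generate_connectome(config$generator)
      truth <- g$truth
      g$connectome
    } else {
      say("reading synapse tables")
      read_synapse_table(config$site_file, config$contact_file,
                         config$annotation_file, quiet = quiet)
    }
  })
  say(nrow(x$sites), " sites, ", nrow(x$contacts), " contacts, ",
      nrow(x$neurons), " neurons")
  metrics$n_neurons <- nrow(x$neurons)
  metrics$n_sites <- nrow(x$sites)
  metrics$n_synapses <- n_synapses(x)

  # --- wiring tables ---------------------------------------------------
  stage("tables", {
    say("aggregating wiring tables")
    export_edges(x, "cell_type", file.path(out_dir, "edges_by_type.csv"))
    mbons <- x$neurons$neuron_id[x$neurons$type_class == "MBON"]
    if (length(mbons)) {
      wt <- wiring_table(x, "KC", mbons)
      utils::write.table(wt, file.path(out_dir, "kc_mbon_summary.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      metrics$kc_mbon_total <- sum(wt$total_synapses)
      metrics$kc_mbon_mean_per_connected <-
        stats::setNames(as.list(round(wt$mean_per_connected, 6)), wt$post_cell)
    }
  })

  # --- poisson fits ----------------------------------------------------
  grid <- stage("poisson", {
    say("fitting Poisson wiring null model")
    g <- poisson_fit_grid(x, min_pairs = 5L,
                          df_convention = config$df_convention)
    utils::write.table(g, file.path(out_dir, "poisson_grid.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    g
  })
  if (nrow(grid)) {
    metrics$poisson_n_fits <- nrow(grid)
    metrics$poisson_green_fraction <- mean(grid$fit_class == "green")
  }

  # --- motifs ----------------------------------------------------------
  stage("motifs", {
    mbons <- x$neurons$neuron_id[x$neurons$type_class == "MBON"]
    if (length(mbons)) {
      say("detecting convergences and rosettes (radius ", config$radius, " nm)")
      cl <- find_rosettes(find_convergences(x, "MBON", config$radius), x)
      utils::write.table(as.data.frame(cl),
                         file.path(out_dir, "convergence_members.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      mf <- motif_fractions(x, "MBON", clusters = cl)
      metrics$percent_kc_mbon_sites_in_convergence <- mf$percent_in_convergence
      metrics$percent_kc_mbon_sites_in_rosette <- mf$percent_in_rosette
      tri <- triangle_motifs(x, clusters = cl)
      metrics$n_triangle_motifs <- nrow(tri)
      if (!is.null(truth) && nrow(truth$clusters)) {
        metrics$planted_convergence_fraction <-
          sum(truth$convergence_fraction$n_in_cluster) /
          max(sum(truth$convergence_fraction$n_sites), 1L)
      }
    }
  })

  # --- volume-transmission coverage ------------------------------------
  stage("coverage", {
    dan <- x$neurons$neuron_id[x$neurons$type_class == "DAN"]
    if (length(dan) && nrow(kc_mbon_contacts(x))) {
      say("computing DAN proximity and coverage curves")
      metrics$dan_proximity_fraction_300nm <- dan_proximity_fraction(x, 300)
      cv <- coverage_curve(x, config$coverage_radii)
      utils::write.table(cv, file.path(out_dir, "coverage_curve.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      at <- function(r) {
        i <- which(cv$radius_nm >= r)[1]
        if (is.na(i)) length(cv$radius_nm) else i
      }
      i <- at(2500)
      metrics$coverage_same_2500nm <- cv$same_compartment_fraction[i]
      metrics$coverage_adjacent_2500nm <- cv$adjacent_compartment_fraction[i]
    }
  })

  # --- dendrite geometry ----------------------------------------------
  stage("geometry", {
    if (length(x$skeletons)) {
      say("computing input-position profiles")
      profs <- lapply(names(x$skeletons), function(nid)
        input_profile(x, nid))
      names(profs) <- names(x$skeletons)
      metrics$mean_input_distance_um <-
        lapply(profs, function(p) p$mean_distance_um)
    } else {
      say("no skeletons supplied; geometry stage skipped")
      metrics$geometry_stage <- "skipped (no skeletons)"
    }
  })

  # --- provenance + metrics -------------------------------------------
  prov <- list(radius = config$radius,
               coverage_radii = range(config$coverage_radii),
               min_expected = config$min_expected,
               df_convention = config$df_convention,
               seed = config$seed,
               generator = if (!is.null(config$generator))
                 config$generator[setdiff(names(config$generator),
                                          c("wiring", "extrinsic"))])
  jsonlite::write_json(prov, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote metrics to ", file.path(out_dir, "metrics.json"))
  invisible(metrics)
}
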