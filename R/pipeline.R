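# End-to-end orchestration: a single YAML (or list) configuration drives
# the analysis stages and every output is written with a JSON manifest so
# a run can be reproduced from its manifest alone.

#' Default pipeline configuration
#'
#' Every numeric default is the analysis protocol's stated value:
#' side-chain contact cutoff 0.55 nm, 20 x 20 free-energy grid,
#' hydrogen-bond cutoff 0.35 nm, polar expansion radius 0.14 nm, patch
#' significance 300 A^2 (top 5), neighbor threshold 3.6 A, interaction
#' persistence 50 %, commute-time threshold 0.1, contact-map cutoff 7 A,
#' unfolded RMSD window 0.3-0.9 nm.
#'
#' @return nested list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    contacts = list(cutoff_nm = 0.55, min_sep = 3),
    fes = list(n_bins = 20, temperature_K = 400),
    hbonds = list(distance_cutoff_nm = 0.35, angle_cutoff_deg = 30),
    patches = list(probe_nm = 0.14, polar_expansion_nm = 0.14,
                   significance_A2 = 300, top_k = 5, dot_density = 960),
    network = list(neighbor_threshold_A = 3.6, frame_fraction = 0.5,
                   interaction_cutoff_A = 3.9, ct_threshold = 0.1),
    contact_map = list(cutoff_A = 7, min_sep = 3, metric = "calpha"),
    melt = list(unfolded_window_nm = c(0.3, 0.9)),
    simulate = list(populations = c(0.8, 0.2), n_frames = 50000,
                    noise_sigma_nm = 0.02, temperature_K = 400),
    seed = 1
  )
}

# Recursively overlay user values onto the defaults.
#' @keywords internal
merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]])
    } else user[[k]]
  }
  base
}

PIPELINE_STAGES <- c("simulate", "fes", "extract", "ss", "hbonds", "patches",
                     "ehsc", "contacts", "network", "melt")

#' Run the analysis pipeline
#'
#' Executes the requested stages against a configuration (a YAML file path
#' or a nested list layered over [pipeline_defaults()]), writes per-stage
#' TSV/JSON outputs into `output_dir` and a JSON manifest recording inputs,
#' parameters and seed. With no external structure input, the `simulate`
#' stage generates the two-state synthetic ensemble and downstream stages
#' run on it.
#'
#' @param config YAML file path or nested list; `NULL` for defaults.
#' @param stages character vector of stage names (subset of simulate, fes,
#'   extract, ss, hbonds, patches, ehsc, contacts, network, melt).
#' @param output_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = NULL, stages = c("simulate", "fes", "extract"),
                         output_dir = tempfile("unfoldscape_run")) {
  cfg <- pipeline_defaults()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), c(names(cfg), "structure", "trajectory"))
    if (length(unknown)) stop("unknown configuration key(s): ",
                              paste(unknown, collapse = ", "))
    cfg <- merge_config(cfg, config)
  }
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("unfoldscape")),
                   stages = stages, parameters = cfg, outputs = list())
  state <- list()

  for (stage in stages) {
    out <- switch(stage,
      simulate = {
        sim <- make_two_state_trajectory(
          populations = cfg$simulate$populations,
          n_frames = cfg$simulate$n_frames,
          noise_sigma = cfg$simulate$noise_sigma_nm,
          temperature = cfg$simulate$temperature_K,
          seed = cfg$seed)
        state$trajectory <- sim$trajectory
        state$native <- sim$conformer_a
        state$states <- sim$states
        character(0)
      },
      fes = {
        stopifnot(!is.null(state$trajectory))
        nc <- native_contacts(state$native, "sidechain",
                              cfg$contacts$cutoff_nm, cfg$contacts$min_sep)
        state$series <- data.frame(
          rmsd = rmsd_series(state$trajectory, state$native),
          rho = rho(state$trajectory, nc))
        state$map <- build_map(state$series$rmsd, state$series$rho,
                               cfg$fes$temperature_K, cfg$fes$n_bins,
                               axis_names = c("rmsd_nm", "rho"))
        f <- write_series_tsv(state$series, file.path(output_dir, "series.tsv"))
        c(f, write_map(state$map, file.path(output_dir, "fes")))
      },
      extract = {
        stopifnot(!is.null(state$series))
        qs <- stats::quantile(state$series$rmsd, c(0.05, 0.95))
        sel <- extract_ensemble(state$series$rmsd, state$series$rho,
                                c(qs[1], qs[2]), c(0, 1), label = "window")
        f <- file.path(output_dir, "selection.tsv")
        utils::write.table(data.frame(frame = sel$frame_indices), f,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        f
      },
      ss = {
        stopifnot(!is.null(state$trajectory))
        labels <- ss_matrix(state$trajectory)
        native_labels <- assign_secondary_structure(state$native)
        state$events <- classify_transition_events(native_labels, labels)
        prop <- propensity(labels, native_labels)
        f1 <- file.path(output_dir, "propensity.tsv")
        f2 <- file.path(output_dir, "events.tsv")
        utils::write.table(prop, f1, sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(state$events, f2, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        c(f1, f2)
      },
      hbonds = {
        stopifnot(!is.null(state$trajectory))
        cr <- hbond_criterion(cfg$hbonds$distance_cutoff_nm,
                              cfg$hbonds$angle_cutoff_deg)
        counts <- vapply(seq_len(n_frames(state$trajectory)), function(f) {
          count_mainchain_hbonds(frame_coords(state$trajectory, f),
                                 state$trajectory$topology, cr)
        }, integer(1))
        f <- file.path(output_dir, "mainchain_hbonds.tsv")
        utils::write.table(data.frame(frame = seq_along(counts), hbonds = counts),
                           f, sep = "\t", quote = FALSE, row.names = FALSE)
        f
      },
      patches = {
        stopifnot(!is.null(state$native))
        ps <- find_patches(state$native, cfg$patches$probe_nm,
                           cfg$patches$polar_expansion_nm,
                           cfg$patches$dot_density,
                           significance_threshold = cfg$patches$significance_A2,
                           top_k = cfg$patches$top_k)
        state$patches <- ps
        f <- file.path(output_dir, "patches.tsv")
        write_patch_report(ps, state$native, f)
        f
      },
      ehsc = {
        stopifnot(!is.null(state$patches), !is.null(state$events))
        att <- tryCatch(ehsc(state$patches, state$events),
                        error = function(e) NULL)
        f <- file.path(output_dir, "ehsc.json")
        jsonlite::write_json(as.list(att), f, auto_unbox = TRUE, digits = NA)
        f
      },
      contacts = {
        stopifnot(!is.null(state$trajectory))
        cm <- residue_contact_map(state$trajectory, state$native,
                                  cfg$contact_map$metric,
                                  cfg$contact_map$cutoff_A,
                                  cfg$contact_map$min_sep)
        write_contact_map(cm, file.path(output_dir, "contacts"))
      },
      network = {
        stopifnot(!is.null(state$trajectory))
        nw <- build_network(state$trajectory,
                            cfg$network$neighbor_threshold_A,
                            cfg$network$frame_fraction,
                            cfg$network$interaction_cutoff_A,
                            cfg$network$ct_threshold)
        f1 <- file.path(output_dir, "network.graphml")
        f2 <- file.path(output_dir, "pathways.tsv")
        export_graph(nw, f1)
        write_pathways(nw, f2)
        c(f1, f2)
      },
      melt = {
        stopifnot(!is.null(state$trajectory))
        # fraction-unfolded of the current ensemble at its temperature only;
        # multi-temperature curves are built by calling melting_curve directly
        rmsd <- if (!is.null(state$series)) state$series$rmsd else
          rmsd_series(state$trajectory, state$native)
        w <- cfg$melt$unfolded_window_nm
        f <- file.path(output_dir, "unfolded_fraction.json")
        jsonlite::write_json(list(temperature_K = state$trajectory$temperature,
                                  fraction_unfolded = mean(rmsd >= w[1] & rmsd <= w[2])),
                             f, auto_unbox = TRUE, digits = NA)
        f
      })
    manifest$outputs[[stage]] <- out
  }
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
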