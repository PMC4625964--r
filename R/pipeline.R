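# End-to-end workflow: structural dynamics -> end-point energies ->
# per-residue decomposition -> hydrogen bonds, with a config echo, a
# MANIFEST marking stage completion, and a machine-readable summary.

#' Build a run configuration
#'
#' A run configuration is a plain, fully serializable list; its echo in the
#' output directory is sufficient to reproduce the run.
#'
#' @param pdb path to a (multi-)model PDB file (frames of the complex).
#' @param sidecar path to the topology sidecar.
#' @param trajectory_txt optional plain-text trajectory overriding the PDB
#'   models (see [read_trajectory_txt()]).
#' @param output_dir output directory.
#' @param frame_start,frame_end,frame_stride optional analysis window (ps);
#'   default: all frames.
#' @param temperature temperature in K for the entropy stage.
#' @param compute_entropy run normal-mode binding entropy (slow for large
#'   toys; default FALSE).
#' @param gb,np,sie,surface,hbonds parameter sets ([gb_params()],
#'   [nonpolar_params()], [sie_params()], [surface_params()],
#'   [hbond_criteria()]).
#' @param seed RNG seed recorded in the echo.
#' @param verbose print stage progress.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pdb, sidecar, output_dir, trajectory_txt = NULL,
                       frame_start = NULL, frame_end = NULL,
                       frame_stride = NULL, temperature = 300,
                       compute_entropy = FALSE, gb = gb_params(),
                       np = nonpolar_params(), sie = sie_params(),
                       surface = surface_params(radius_scale = 1),
                       hbonds = hbond_criteria(), seed = 1,
                       verbose = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' @keywords internal
#' @noRd
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

#' Run the full analysis workflow
#'
#' Executes the pipeline stages on the configured inputs and writes, to the
#' output directory: the RMSD series (backbone), RMSF profile and DCCM and
#' PCA spectrum (C-alpha), the MM-GBSA and SIE component tables with their
#' snapshot means and dispersions, the per-residue interaction
#' decomposition, the hydrogen-bond occupancy table, a JSON `summary.json`,
#' a YAML config echo, and a `MANIFEST` marking each stage `ok`. Any stage
#' failure aborts with the stage name; completed outputs are retained and
#' the MANIFEST records the failure.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$output_dir, "MANIFEST")
  manifest <- character()
  note <- function(stage, status) {
    manifest <<- c(manifest, paste(stage, status))
    writeLines(manifest, manifest_path)
    if (config$verbose) message("[", stage, "] ", status)
  }
  stage <- function(name, code) {
    res <- tryCatch(force(code), error = function(e) {
      note(name, paste("FAILED:", conditionMessage(e)))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    note(name, "ok")
    res
  }
  echo <- config
  echo$gb <- unclass(config$gb); echo$np <- unclass(config$np)
  echo$sie <- unclass(config$sie); echo$surface <- unclass(config$surface)
  echo$hbonds <- unclass(config$hbonds)
  yaml::write_yaml(unclass(echo), file.path(config$output_dir, "config.yaml"))

  inputs <- stage("load_inputs", {
    traj <- if (!is.null(config$trajectory_txt))
      read_trajectory_txt(config$trajectory_txt)
    else read_pdb_models(config$pdb)
    top <- read_topology_sidecar(config$sidecar, n_atoms = traj$n_atoms)
    traj$topology <- top
    if (!is.null(config$frame_start)) {
      sel <- frame_selection(config$frame_start, config$frame_end,
                             config$frame_stride)
      traj <- select_frames(traj, sel)
    }
    list(traj = traj, top = top)
  })
  traj <- inputs$traj; top <- inputs$top
  ca <- calpha_selection(top)
  if (!length(ca)) ca <- top$receptor
  bb <- backbone_selection(top)
  if (length(bb) < 3) bb <- seq_len(top$n_atoms)

  rmsd_res <- stage("rmsd", {
    r <- rmsd_series(traj, frame_coords(traj, 1), bb)
    .write_tsv(data.frame(time = r$times, rmsd = r$rmsd),
               file.path(config$output_dir, "rmsd.tsv"))
    r
  })
  rmsf_res <- stage("rmsf", {
    if (length(ca) >= 3 && n_frames(traj) >= 2) {
      p <- rmsf_profile(traj, ca)
      .write_tsv(p, file.path(config$output_dir, "rmsf.tsv"))
      p
    } else NULL
  })
  dccm_res <- stage("dccm", {
    if (length(ca) >= 3 && n_frames(traj) >= 2) {
      m <- dccm(traj, ca)
      utils::write.table(format(unclass(m), digits = 6),
                         file.path(config$output_dir, "dccm.tsv"),
                         sep = "\t", quote = FALSE)
      m
    } else NULL
  })
  pca_res <- stage("pca", {
    if (length(ca) >= 3 && n_frames(traj) >= 2) {
      k <- min(6, 3 * length(ca))
      p <- covariance_pca(traj, ca, k = k)
      .write_tsv(data.frame(eigenvalue = p$eigenvalues,
                            cumulative_fraction = p$cumulative_fraction),
                 file.path(config$output_dir, "pca.tsv"))
      p
    } else NULL
  })
  entropy <- NA_real_
  if (isTRUE(config$compute_entropy))
    entropy <- stage("nmode", {
      binding_entropy(frame_coords(traj, 1), top,
                      temperature = config$temperature)$minus_T_dS
    })
  mmgbsa_res <- stage("mmgbsa", {
    r <- mmgbsa_pipeline(traj, top, gb = config$gb, np = config$np,
                         surface = config$surface, minus_T_dS = entropy)
    tab <- data.frame(
      component = c("dE_ele", "dE_vdw", "dG_pol", "dG_nonpol", "-TdS",
                    "dG_bind"),
      mean = c(r$mean["ele"], r$mean["vdw"], r$mean["gpol"],
               r$mean["gnonpol"], entropy, r$dG),
      sd = c(r$sd["ele"], r$sd["vdw"], r$sd["gpol"], r$sd["gnonpol"],
             NA, NA))
    .write_tsv(tab, file.path(config$output_dir, "mmgbsa_components.tsv"))
    r
  })
  sie_res <- stage("sie", {
    r <- sie_pipeline(traj, top, params = config$sie)
    tab <- data.frame(
      component = c("dE_vdW", "dE_c", "gamma_dMSA", "dG_R", "C", "dG_bind"),
      mean = c(r$mean["vdw"], r$mean["coulomb_Din"], r$mean["msa_term"],
               r$mean["reaction_field"], config$sie$constant_C, r$dG),
      sd = c(r$sd["vdw"], r$sd["coulomb_Din"], r$sd["msa_term"],
             r$sd["reaction_field"], 0, r$sd["dG"]))
    .write_tsv(tab, file.path(config$output_dir, "sie_components.tsv"))
    r
  })
  decomp <- stage("decompose", {
    d <- residue_decomposition(traj, top, gb = config$gb)
    .write_tsv(d, file.path(config$output_dir, "residue_decomposition.tsv"))
    d
  })
  hb <- stage("hbonds", {
    h <- hbond_occupancy(traj, top, config$hbonds)
    .write_tsv(h, file.path(config$output_dir, "hbonds.tsv"))
    h
  })
  summary <- list(
    n_frames = n_frames(traj), n_atoms = traj$n_atoms,
    rmsd_mean = rmsd_res$mean, rmsd_range = rmsd_res$range,
    pca_first_k_fraction = if (!is.null(pca_res)) pca_res$first_k_fraction
      else NA,
    mmgbsa = as.list(mmgbsa_res$mean), mmgbsa_dG = mmgbsa_res$dG,
    minus_T_dS = entropy,
    sie = as.list(sie_res$mean), sie_dG = sie_res$dG,
    n_hbonds = nrow(hb),
    top_residues = utils::head(
      decomp$residue_index[order(decomp$total)], 5),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  note("summary", "ok")
  invisible(summary)
}
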