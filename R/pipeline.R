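## Orchestration: validated configuration, stage subcommands, TSV reports
## with JSON sidecars, and stderr logging of the config hash and seeds.

.default_config <- list(
  seed = 1L,
  salt_bridge_max_dist = 5.0,
  hbond_max_dist = 2.5,
  hbond_heavy_dist = 3.5,
  attractive_max_dist = 5.6,
  pi_pi_max_dist = 5.5,
  alkyl_max_dist = 5.5,
  pi_alkyl_max_dist = 6.0,
  disorder_threshold = 0.5,
  helix_coverage = 0.75,
  exposure_threshold = 0.25,
  dock_n_poses = 500L,
  dock_weight_attractive = 1,
  dock_weight_clash = 1,
  dock_cluster_rmsd = 3,
  his_positive = TRUE,
  zscore_null_size = 200L,
  inputs = list())

#' Pipeline configuration
#'
#' Builds a validated configuration with every tunable cutoff present at its
#' default; unknown keys are rejected. Defaults: salt bridge 5.0 A, hydrogen
#' bond 2.5 A (heavy fallback 3.5 A), attractive charge 5.6 A, pi-pi 5.5 A,
#' alkyl 5.5 A, pi-alkyl 6.0 A, disorder probability threshold 0.5,
#' helix-present coverage 0.75, exposure threshold 0.25 relative ASA.
#'
#' @param ... overrides of the default keys.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.default_config))
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.default_config, over)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with a subset of the configuration keys.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

log_msg <- function(...) message("[nuprtools] ", ...)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Run a pipeline stage
#'
#' Subcommands:
#' * `simulate` - write synthetic fixtures (candidate models + negative
#'   control, a protein-DNA complex on an A10-T10 duplex, a scheduled
#'   ensemble, a motif-embedded sequence, a prediction table) under
#'   `out_dir`.
#' * `evaluate-models` - all-against-all RMSD/Z-score matrices, consensus
#'   statistics and ranking for `inputs$models` (named PDB paths) with
#'   `inputs$control` naming the negative control.
#' * `analyze-structure` - helix spans, turns, Ramachandran regions, ASA and
#'   buried/exposed labels for `inputs$structure`.
#' * `analyze-interface` - interface interaction report for
#'   `inputs$complex` between `inputs$receptor_chains` and
#'   `inputs$ligand_chains`; optional `inputs$mutations` (named vector) adds
#'   a mutant report and rewiring summary.
#' * `dock` - rigid-body docking of `inputs$protein` onto a duplex built
#'   from `inputs$dna_sequence`.
#' * `analyze-ensemble` - RMSF, pairwise frame-RMSD matrix and per-span
#'   helix persistence for the multi-model PDB `inputs$ensemble`
#'   (`inputs$spans` = list of c(start, end)).
#' * `scan-motifs` - NLS/NES/DBD scans plus hydropathy and physicochemical
#'   summaries for the FASTA `inputs$sequences`.
#' * `meta-score` - consensus meta-scores for the prediction table TSV
#'   `inputs$table`.
#'
#' Every run logs the configuration hash and seed to standard error and
#' writes TSV reports with a JSON sidecar under `out_dir`. Identical
#' configuration and seeds give byte-identical reports.
#'
#' @param command subcommand name.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(command, config = pipeline_config(),
                         out_dir = "nuprtools_run") {
  if (!inherits(config, "pipeline_config"))
    stop("config must be built by pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg("command: ", command, "; config ", config_hash(config),
          "; seed ", config$seed)
  inputs <- config$inputs
  need <- function(key) {
    if (is.null(inputs[[key]]))
      stop("missing input for ", command, ": inputs$", key)
    inputs[[key]]
  }
  written <- switch(
    command,
    "simulate" = stage_simulate(config, out_dir),
    "evaluate-models" = stage_evaluate_models(config, need("models"),
                                              need("control"), out_dir),
    "analyze-structure" = stage_analyze_structure(config, need("structure"),
                                                  out_dir),
    "analyze-interface" = stage_analyze_interface(
      config, need("complex"), need("receptor_chains"),
      need("ligand_chains"), inputs$mutations, out_dir),
    "dock" = stage_dock(config, need("protein"), need("dna_sequence"),
                        out_dir),
    "analyze-ensemble" = stage_analyze_ensemble(config, need("ensemble"),
                                                inputs$spans, out_dir),
    "scan-motifs" = stage_scan_motifs(config, need("sequences"), out_dir),
    "meta-score" = stage_meta_score(config, need("table"), out_dir),
    stop("unknown subcommand: ", command))
  invisible(written)
}

read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(unlist(seqs)), path)
  path
}

## --- stages -----------------------------------------------------------------

## demo sequence used by the simulate stage: 100 residues, helix-loop-helix
## span layout (20-33, 65-72, 80-98) with a basic DNA-binding stretch
.demo_sequence <- paste0(
  "MATFPPTSSD", "SLEVLAPHNE",      # 1-20: acidic N-terminal tail
  "ESSLDALYEA", "LSSPFDQDLH",      # 21-40: helix 1 region
  "SMNESTPHSE", "NAPDSWEEPS",      # 41-60
  "DNERKGRTKR", "EASTPDSHQE",      # 61-80: helix 2 + AT-hook-like core
  "QKKRGARRHM", "SDLTAEEYAC"       # 81-100: helix 3 + basic cluster
)

stage_simulate <- function(config, out_dir) {
  seed <- config$seed
  files <- list()
  ## candidate models: same fold perturbed at increasing noise + an
  ## unrelated extended negative control
  spans <- list(c(20, 33), c(65, 72), c(80, 98))
  noises <- c(0.2, 0.5, 0.8, 1.2, 1.6)
  for (k in seq_along(noises)) {
    m <- build_ideal_helix(.demo_sequence, spans, seed = seed + k,
                           noise = noises[k])
    files[[paste0("model", k)]] <-
      file.path(out_dir, sprintf("model_%d.pdb", k))
    write_pdb(m, files[[paste0("model", k)]])
  }
  control <- build_ideal_helix(.demo_sequence, list(), seed = seed + 99,
                               noise = 0.3)
  files$control <- file.path(out_dir, "control.pdb")
  write_pdb(control, files$control)

  ## interface fixture with one engineered contact per category, plus a
  ## cationic toy binder for docking onto an ideal A10-T10 duplex
  files$complex <- file.path(out_dir, "complex.pdb")
  write_pdb(engineered_contact_fixture(), files$complex)
  files$binder <- file.path(out_dir, "binder.pdb")
  write_pdb(build_toy_binder(charged = TRUE, seed = seed), files$binder)

  ## scheduled ensemble
  base <- build_ideal_helix(.demo_sequence, spans)
  sch <- helix_schedule(spans, c(1.0, 0.15, 0.5))
  ens <- generate_ensemble(base, sch, n_frames = 120, seed = seed)
  files$ensemble <- file.path(out_dir, "ensemble.pdb")
  write_pdb(ens, files$ensemble)

  ## motif-embedded sequence and prediction table
  seqs <- c(demo = .demo_sequence,
            planted = embed_motifs(120, list(
              list(motif = "LAAALAALAL", start = 29),
              list(motif = "RKGRTKR", start = 60),
              list(motif = "KKRGARR", start = 81)), seed = seed))
  files$sequences <- write_fasta(as.list(seqs),
                                 file.path(out_dir, "sequences.fasta"))
  tab <- generate_prediction_table(prediction_table_spec(
    n_sites = 20,
    programs = list(phospho = paste0("phos", 1:10),
                    acetyl = paste0("acet", 1:8),
                    methyl = paste0("meth", 1:4),
                    ubiq = paste0("ubiq", 1:3),
                    sumo = paste0("sumo", 1:5)),
    agreement = 0.5, seed = seed))
  files$table <- write_tsv(tab, file.path(out_dir, "prediction_table.tsv"))
  files
}

stage_evaluate_models <- function(config, model_paths, control, out_dir) {
  models <- lapply(model_paths, read_pdb)
  if (is.null(names(models))) stop("inputs$models must be a named list")
  rm_mat <- rmsd_matrix(models, control_label = control)
  z_mat <- zscore_matrix(models, null_size = config$zscore_null_size,
                         seed = config$seed, control_label = control)
  stats <- consensus_stats(rm_mat, z_mat, control)
  rama <- lapply(models, function(m) ramachandran(m)$percentages)
  files <- list(
    rmsd = write_matrix_tsv(rm_mat$values,
                            file.path(out_dir, "model_rmsd_matrix.tsv")),
    zscore = write_matrix_tsv(z_mat$values,
                              file.path(out_dir, "model_zscore_matrix.tsv")),
    consensus = write_tsv(format_report(as.data.frame(stats)),
                          file.path(out_dir, "model_consensus.tsv")),
    json = write_json_sidecar(
      list(consensus = as.data.frame(stats),
           ranking = rank_models(stats),
           ramachandran_percent = rama),
      file.path(out_dir, "model_consensus.json")))
  files
}

stage_analyze_structure <- function(config, path, out_dir) {
  s <- read_pdb(path)
  helices <- assign_helices(s)
  beta <- detect_beta_turns(s, helices)
  gamma <- detect_gamma_turns(s)
  dihed <- backbone_dihedrals(s)
  asa <- classify_exposure(asa_shrake_rupley(s),
                           threshold = config$exposure_threshold)
  per_res <- merge(dihed, asa, by = c("chain", "resno", "resname"),
                   all = TRUE, sort = FALSE)
  per_res <- per_res[order(per_res$chain, per_res$resno), ]
  per_res$helix <- FALSE
  for (k in seq_len(nrow(helices)))
    per_res$helix <- per_res$helix | (per_res$chain == helices$chain[k] &
                                        per_res$resno >= helices$start[k] &
                                        per_res$resno <= helices$end[k])
  per_res$region <- ifelse(is.na(per_res$phi) | is.na(per_res$psi), NA,
                           rama_region(per_res$phi, per_res$psi))
  spans <- rbind(helices[, c("kind", "chain", "start", "end", "length")],
                 beta[, c("kind", "chain", "start", "end", "length")],
                 gamma[, c("kind", "chain", "start", "end", "length")])
  list(residues = write_tsv(format_report(per_res),
                            file.path(out_dir, "structure_residues.tsv")),
       spans = write_tsv(spans, file.path(out_dir, "structure_spans.tsv")),
       json = write_json_sidecar(
         list(spans = spans,
              ramachandran_percent = as.list(ramachandran(s)$percentages)),
         file.path(out_dir, "structure_summary.json")))
}

stage_analyze_interface <- function(config, path, receptor, ligand,
                                    mutations, out_dir) {
  cx <- read_pdb(path)
  rep_wt <- interaction_report(cx, receptor, ligand,
                               his_positive = config$his_positive)
  files <- list(interactions = write_tsv(
    format_report(rep_wt), file.path(out_dir, "interface_interactions.tsv")))
  side <- list(wild_type = rep_wt)
  if (!is.null(mutations)) {
    mut <- mutate_residues(cx, unlist(mutations))
    rep_mut <- interaction_report(mut, receptor, ligand,
                                  his_positive = config$his_positive)
    rw <- rewiring(rep_wt, rep_mut)
    files$mutant <- write_tsv(format_report(rep_mut),
                              file.path(out_dir, "interface_mutant.tsv"))
    side$mutant <- rep_mut
    side$rewiring <- unclass(rw)
  }
  files$json <- write_json_sidecar(side,
                                   file.path(out_dir, "interface.json"))
  files
}

stage_dock <- function(config, protein_path, dna_sequence, out_dir) {
  protein <- read_pdb(protein_path)
  dna <- build_bdna(dna_sequence)
  res <- dock_to_bdna(protein, dna, n_poses = config$dock_n_poses,
                      seed = config$seed,
                      weights = c(attractive = config$dock_weight_attractive,
                                  clash = config$dock_weight_clash),
                      cluster_rmsd = config$dock_cluster_rmsd,
                      his_positive = config$his_positive)
  ## write the best pose of each of the top 5 clusters as a multi-model PDB
  top <- utils::head(res$clusters, 5)
  frames <- lapply(seq_len(nrow(top)), function(k) {
    ci <- top$cluster[k]
    p <- res$poses[res$poses$cluster == ci, ]
    best <- p$pose[which.max(p$score)]
    tr <- res$transforms[[best]]
    pm <- protein$atoms[protein$atoms$model == protein$atoms$model[1], ]
    cmp <- colMeans(coords(pm))
    xyz <- sweep(sweep(coords(pm), 2, cmp) %*% t(tr$rotation), 2,
                 tr$translation, "+")
    pm$model <- k
    pm$x <- xyz[, 1]; pm$y <- xyz[, 2]; pm$z <- xyz[, 3]
    pm
  })
  poses_struct <- new_structure3d(do.call(rbind, frames))
  list(poses = write_tsv(format_report(res$poses),
                         file.path(out_dir, "dock_poses.tsv")),
       clusters = write_tsv(format_report(res$clusters),
                            file.path(out_dir, "dock_clusters.tsv")),
       pdb = { write_pdb(poses_struct, file.path(out_dir, "dock_top_poses.pdb"))
               file.path(out_dir, "dock_top_poses.pdb") },
       json = write_json_sidecar(
         list(top_score = res$top_score,
              clusters = res$clusters),
         file.path(out_dir, "dock.json")))
}

stage_analyze_ensemble <- function(config, path, spans, out_dir) {
  ens <- read_pdb(path)
  rmsf <- rmsf_per_residue(ens)
  mat <- pairwise_frame_rmsd(ens)
  persist <- NULL
  if (!is.null(spans)) {
    persist <- do.call(rbind, lapply(spans, function(sp) {
      data.frame(start = sp[1], end = sp[2],
                 persistence = helix_persistence(
                   ens, c(sp[1], sp[2]),
                   chain = ens$atoms$chain[1],
                   coverage = config$helix_coverage))
    }))
  }
  files <- list(
    rmsf = write_tsv(format_report(rmsf),
                     file.path(out_dir, "ensemble_rmsf.tsv")),
    matrix = write_matrix_tsv(round(mat$values, 4),
                              file.path(out_dir, "ensemble_rmsd_matrix.tsv")))
  if (!is.null(persist))
    files$persistence <- write_tsv(format_report(persist),
                                   file.path(out_dir,
                                             "ensemble_persistence.tsv"))
  files$json <- write_json_sidecar(
    list(mean_rmsf = mean(rmsf$rmsf),
         mean_pairwise_rmsd = mean(mat$values[upper.tri(mat$values)]),
         persistence = persist),
    file.path(out_dir, "ensemble.json"))
  files
}

stage_scan_motifs <- function(config, path, out_dir) {
  seqs <- read_fasta(path)
  hits <- do.call(rbind, lapply(names(seqs), function(nm) {
    h <- rbind(scan_nls(seqs[[nm]]), scan_nes(seqs[[nm]]),
               scan_dbd(seqs[[nm]]))
    if (nrow(h) > 0L) cbind(sequence = nm, h) else NULL
  }))
  phys <- do.call(rbind, lapply(names(seqs), function(nm) {
    pc <- physchem(seqs[[nm]])
    data.frame(sequence = nm, length = nchar(seqs[[nm]]),
               mw = pc$mw, pi = pc$pi)
  }))
  if (is.null(hits)) hits <- cbind(sequence = character(0), empty_hits())
  list(hits = write_tsv(format_report(hits),
                        file.path(out_dir, "motif_hits.tsv")),
       physchem = write_tsv(format_report(phys),
                            file.path(out_dir, "physchem.tsv")),
       json = write_json_sidecar(list(hits = hits, physchem = phys),
                                 file.path(out_dir, "motifs.json")))
}

stage_meta_score <- function(config, path, out_dir) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- ptm_meta_score(tab)
  list(meta = write_tsv(format_report(meta),
                        file.path(out_dir, "meta_scores.tsv")),
       json = write_json_sidecar(meta, file.path(out_dir, "meta_scores.json")))
}

## round numeric report columns to 2 decimals (distances as printed in
## interface tables); leaves integers and non-numerics alone
format_report <- function(df) {
  for (cc in names(df)) {
    if (is.numeric(df[[cc]]) && !is.integer(df[[cc]]))
      df[[cc]] <- round(df[[cc]], 2)
  }
  df
}

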