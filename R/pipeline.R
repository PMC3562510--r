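## End-to-end orchestration: simulate -> dedup/group/features/tropism ->
## diversity -> motif scan -> mine -> neighbors, under one configuration
## with a reproducibility manifest.

#' Default pipeline configuration
#'
#' A complete run configuration with the package's standard thresholds
#' (98% mining identity, 100 kb neighbor window, 0.85 feature identity,
#' 0.75 motif similarity, p < 0.05) and a compact simulated genome so a full
#' run stays interactive.
#'
#' @param seed Integer seed recorded in the manifest and used by every
#'   stochastic stage.
#' @param out_dir Output directory.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L, out_dir = "ervkit_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, u3 = TRUE, diversity = TRUE,
                  trescan = TRUE, mine = TRUE, neighbors = TRUE),
    simulate = list(n_chromosomes = 1L, chrom_length = 4e5,
                    n_proviruses = 3L, n_solo_ltrs = 1L),
    u3 = list(k = 7L, feature_threshold = 0.85),
    diversity = list(groupby = "condition"),
    trescan = list(min_similarity = 0.75),
    mine = list(min_identity = 0.98, size_window = c(5000, 12000)),
    neighbors = list(window = 100000)
  )
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic dataset
#' generated under `config$seed`, writes every stage's tables under
#' `config$out_dir`, and returns (and writes) a manifest recording the
#' package version, seed, per-stage row counts and md5 checksums of all
#' outputs. Reruns with the same configuration are bit-identical.
#'
#' @param config Configuration list (see [default_run_config()]) or path to
#'   a YAML file with the same structure.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  config <- utils::modifyList(base, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  counts <- list()
  outputs <- character(0)
  say <- function(...) message("[ervkit] ", ...)

  if (!isTRUE(config$stages$simulate)) {
    stop("pipeline requires the simulate stage in this release", call. = FALSE)
  }
  say("simulate")
  clone_spec <- config$simulate$clone_library
  if (is.null(clone_spec)) clone_spec <- default_clone_library_spec()
  sc <- synthetic_config(
    seed = config$seed,
    n_chromosomes = config$simulate$n_chromosomes,
    chrom_length = config$simulate$chrom_length,
    n_proviruses = config$simulate$n_proviruses,
    n_solo_ltrs = config$simulate$n_solo_ltrs,
    clone_library = clone_spec)
  sim <- build_genome(sc)
  clones <- build_clone_library(sc)
  ann <- build_gene_annotation(sim$truth, config$simulate$chrom_length,
                               seed = config$seed + 1L)
  paths <- write_simulation(sim, clones, config$out_dir)
  gff_path <- file.path(config$out_dir, "annotation.gff3")
  write_gff3(ann, gff_path)
  outputs <- c(outputs, unname(paths), gff_path)
  results$sim <- sim
  results$clones <- clones
  counts$simulate <- nrow(sim$truth)

  dd <- dedup(clones)
  uniq <- dd$unique
  if (isTRUE(config$stages$u3)) {
    say("u3: dedup/group/features/tropism")
    branches <- group_u3(uniq, k = config$u3$k)
    feature_lib <- sc$feature_library
    prof_rows <- lapply(seq_len(nrow(uniq)), function(i) {
      prof <- annotate_features(uniq[i, ], feature_lib,
                                config$u3$feature_threshold)
      sym <- render_profile(prof)
      data.frame(id = uniq$id[i], group = branches$assignment[[uniq$id[i]]],
                 length = uniq$length[i], multiplicity = uniq$multiplicity[i],
                 t(sym),
                 tropism = call_tropism(prof, u3_length = uniq$length[i]),
                 stringsAsFactors = FALSE, check.names = FALSE)
    })
    profiles <- do.call(rbind, prof_rows)
    p_prof <- file.path(config$out_dir, "u3_profiles.tsv")
    write.table(profiles, p_prof, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p_tree <- file.path(config$out_dir, "u3_tree.nwk")
    writeLines(branches$tree, p_tree)
    p_uni <- file.path(config$out_dir, "u3_unique.fa")
    dss <- Biostrings::DNAStringSet(uniq$sequence)
    names(dss) <- uniq$id
    Biostrings::writeXStringSet(dss, p_uni)
    outputs <- c(outputs, p_prof, p_tree, p_uni)
    results$branches <- branches
    results$profiles <- profiles
    counts$u3 <- nrow(profiles)
  }

  if (isTRUE(config$stages$diversity)) {
    say("diversity statistics")
    stats <- diversity_by_group(clones, config$diversity$groupby)
    report <- compare_groups(stats)
    p_div <- file.path(config$out_dir, "diversity.tsv")
    write.table(report, p_div, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p_div)
    results$diversity <- report
    counts$diversity <- nrow(report)
  }

  if (isTRUE(config$stages$trescan)) {
    say("motif scan")
    motifs <- load_motif_library()
    hits <- scan_motifs_set(uniq, motifs, config$trescan$min_similarity)
    meta <- data.frame(u3_id = uniq$id,
                       group = ifelse(uniq$condition == "no_burn",
                                      "no_burn", "burn"))
    occ <- occurrence_table(hits, meta)
    p_occ <- file.path(config$out_dir, "motif_occurrence.tsv")
    write.table(occ, p_occ, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p_occ)
    results$motif_hits <- hits
    results$motif_occurrence <- occ
    counts$trescan <- nrow(hits)
  }

  if (isTRUE(config$stages$mine)) {
    say("provirus mining")
    report <- mine(sim$genome, uniq,
                   min_identity = config$mine$min_identity,
                   size_window = config$mine$size_window,
                   pbs_library = sc$pbs_library,
                   reference_model = sc$reference_model)
    p_mine <- file.path(config$out_dir, "provirus_report.tsv")
    write.table(report, p_mine, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p_mine)
    results$loci <- report
    counts$mine <- nrow(report)
  }

  if (isTRUE(config$stages$neighbors)) {
    if (is.null(results$loci)) {
      say("neighbors skipped: mining stage disabled")
    } else {
      say("neighbor genes")
      nb <- neighbors(results$loci, ann, window = config$neighbors$window)
      p_nb <- file.path(config$out_dir, "neighbor_genes.tsv")
      write.table(nb, p_nb, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, p_nb)
      results$neighbors <- nb
      counts$neighbors <- nrow(nb)
    }
  }

  manifest <- list(
    package = "ervkit",
    version = as.character(utils::packageVersion("ervkit")),
    seed = config$seed,
    stage_row_counts = counts,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", length(outputs), " outputs in ", config$out_dir)
  invisible(list(manifest = manifest, results = results))
}
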