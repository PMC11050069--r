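#' Pipeline configuration
#'
#' Bundles the analysis thresholds with a simulation configuration. The
#' defaults are the study's operating points: per-cohort DEG calls at
#' p < 0.05 and FDR < 0.1, PIEA on genes with more than 5 interactants at
#' FDR < 0.05, signature enrichment reported at FDR < 0.01 with O/E > 1.5,
#' and network edges kept at score > 0.4 when a scored edge list is read.
#'
#' @param simulation A [simulation_config()].
#' @param deg_p,deg_fdr Strict per-cohort DEG thresholds.
#' @param piea_min_degree Strict lower bound on tested neighborhood size.
#' @param piea_fdr Strict FDR cut for master-regulator calls.
#' @param enrich_fdr,enrich_oe Strict enrichment reporting filter.
#' @param edge_min_score Strict lower bound on edge scores.
#' @param mcode_vwp,mcode_min_size MCODE parameters.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            deg_p = 0.05, deg_fdr = 0.1,
                            piea_min_degree = 5, piea_fdr = 0.05,
                            enrich_fdr = 0.01, enrich_oe = 1.5,
                            edge_min_score = 0.4,
                            mcode_vwp = 0.2, mcode_min_size = 3) {
  assert_that(deg_p > 0 && deg_p <= 1 && deg_fdr > 0 && deg_fdr <= 1 &&
                piea_fdr > 0 && piea_fdr <= 1 &&
                enrich_fdr > 0 && enrich_fdr <= 1,
              "probability thresholds must lie in (0, 1]")
  assert_that(piea_min_degree >= 0 && enrich_oe >= 0,
              "degree and O/E bounds must be non-negative")
  structure(list(simulation = simulation, deg_p = deg_p, deg_fdr = deg_fdr,
                 piea_min_degree = piea_min_degree, piea_fdr = piea_fdr,
                 enrich_fdr = enrich_fdr, enrich_oe = enrich_oe,
                 edge_min_score = edge_min_score,
                 mcode_vwp = mcode_vwp, mcode_min_size = mcode_min_size),
            class = "PipelineConfig")
}

# Evaluate recovered sets against planted truth.
set_recovery <- function(found, planted) {
  tp <- length(intersect(found, planted))
  list(recall = if (length(planted) > 0) tp / length(planted) else NA_real_,
       precision = if (length(found) > 0) tp / length(found) else NA_real_)
}

#' Run the full consensus-ploidy pipeline on a simulated study
#'
#' Simulates a study, writes its inputs, then runs every analysis stage:
#' per-cohort normalization and moderated testing (mouse cohorts translated
#' to the human namespace through the 1:1 ortholog map first), direction
#' matrix and consensus calling, PIEA master-regulator detection on the
#' interaction network, signature enrichment of the consensus up and down
#' sets, MCODE complex extraction from the consensus-induced subgraph with
#' per-complex enrichment, and overlap validation against the held-out
#' cohort. All intermediate tables, a manifest and a summary are written
#' under `outdir`; outputs are a pure function of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param outdir Run directory (created; existing files overwritten).
#' @return Invisibly, a list with every stage's in-memory result
#'   (`study`, `differential`, `direction_matrix`, `consensus`,
#'   `master_regulators`, `enrichment_up`, `enrichment_down`, `complexes`,
#'   `complex_enrichment`, `overlap`, `summary`, `outdir`).
#' @export
run_ploidy_pipeline <- function(config = pipeline_config(),
                                outdir = tempfile("ploidy_run_")) {
  assert_that(inherits(config, "PipelineConfig"),
              "config must come from pipeline_config()")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  study <- simulate_study(config$simulation)
  input_dir <- p("inputs")
  write_simulation(study, input_dir)

  # per-cohort differential testing in the shared human namespace
  differential <- lapply(study$datasets, function(ds) {
    ds <- apply_orthologs(ds, study$ortholog_map, "human")
    cohort_differential(ds, p_cut = config$deg_p, fdr_cut = config$deg_fdr)
  })
  for (nm in names(differential)) {
    write.table(differential[[nm]], p(paste0("deg_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  dmat <- build_direction_matrix(differential, p_cut = config$deg_p,
                                 fdr_cut = config$deg_fdr)
  consensus <- call_consensus(dmat)
  write.table(data.frame(gene_id = rownames(dmat),
                         unclass(dmat)[, , drop = FALSE],
                         check.names = FALSE),
              p("direction_matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gene_set(consensus$up, p("consensus_up.tsv"))
  write_gene_set(consensus$down, p("consensus_down.tsv"))

  piea_background <- intersect(rownames(dmat),
                               igraph::V(study$network)$name)
  mr <- piea_master_regulators(study$network, consensus, piea_background,
                               min_degree = config$piea_min_degree,
                               fdr_cut = config$piea_fdr)
  write.table(mr$records, p("piea_records.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gene_set(mr$up, p("master_regulators_up.tsv"))
  write_gene_set(mr$down, p("master_regulators_down.tsv"))

  enr_up <- enrich(consensus$up, study$signatures, study$gene_universe,
                   fdr_cut = config$enrich_fdr, oe_cut = config$enrich_oe)
  enr_down <- enrich(consensus$down, study$signatures, study$gene_universe,
                     fdr_cut = config$enrich_fdr, oe_cut = config$enrich_oe)
  write_enrichment_report(enr_up, p("enrichment_up.tsv"))
  write_enrichment_report(enr_down, p("enrichment_down.tsv"))
  write_enrichment_report(enr_up, p("enrichment_up_full.tsv"), filtered = FALSE)
  write_enrichment_report(enr_down, p("enrichment_down_full.tsv"),
                          filtered = FALSE)

  deg_graph <- induced_subgraph_genes(study$network,
                                      c(consensus$up, consensus$down))
  complexes <- mcode(deg_graph, vwp = config$mcode_vwp,
                     min_size = config$mcode_min_size)
  write_mcode_report(complexes, p("mcode_complexes.tsv"))
  complex_enrichment <- lapply(complexes, function(cx) {
    enrich(cx$members, study$signatures, study$gene_universe,
           fdr_cut = config$enrich_fdr, oe_cut = config$enrich_oe)
  })

  overlap <- NULL
  if (length(study$validation) > 0) {
    vres <- cohort_differential(study$validation[[1]],
                                p_cut = config$deg_p, fdr_cut = config$deg_fdr)
    vdeg <- select_degs(vres, p_cut = config$deg_p, fdr_cut = config$deg_fdr)
    overlap <- match_signature(consensus, vdeg$up, vdeg$down,
                               intersect(rownames(dmat), vres$gene_id))
    write_gene_set(overlap$matched_up, p("overlap_matched_up.tsv"))
    write_gene_set(overlap$matched_down, p("overlap_matched_down.tsv"))
  }

  truth <- study$truth
  rec_up <- set_recovery(consensus$up, truth$planted_up)
  rec_down <- set_recovery(consensus$down, truth$planted_down)
  hub_rec <- set_recovery(c(mr$up, mr$down), truth$planted_hubs)
  summary_tab <- data.frame(
    key = c("n_cohorts", "universe_size",
            "consensus_up", "consensus_down",
            "consensus_up_recall", "consensus_up_precision",
            "consensus_down_recall", "consensus_down_precision",
            "master_regulators_up", "master_regulators_down",
            "hub_recall",
            "enriched_signatures_up", "enriched_signatures_down",
            "mcode_complexes",
            "overlap_matched_up", "overlap_matched_down"),
    value = c(consensus$n_cohorts, nrow(dmat),
              length(consensus$up), length(consensus$down),
              round(rec_up$recall, 6), round(rec_up$precision, 6),
              round(rec_down$recall, 6), round(rec_down$precision, 6),
              length(mr$up), length(mr$down),
              round(hub_rec$recall, 6),
              sum(enr_up$selected), sum(enr_down$selected),
              length(complexes),
              if (is.null(overlap)) NA else overlap$n_matched_up,
              if (is.null(overlap)) NA else overlap$n_matched_down),
    stringsAsFactors = FALSE
  )
  write.table(summary_tab, p("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  input_files <- sort(list.files(input_dir, full.names = TRUE))
  manifest <- list(
    package = "ploidysig",
    version = as.character(utils::packageVersion("ploidysig")),
    seed = config$simulation$seed,
    thresholds = unclass(config)[setdiff(names(config), "simulation")],
    simulation = unclass(config$simulation)[setdiff(names(config$simulation),
                                                    c("network_params",
                                                      "signature_params"))],
    network_params = config$simulation$network_params,
    signature_params = config$simulation$signature_params,
    input_hashes = as.list(setNames(unname(tools::md5sum(input_files)),
                                    basename(input_files)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(study = study, differential = differential,
                 direction_matrix = dmat, consensus = consensus,
                 master_regulators = mr, enrichment_up = enr_up,
                 enrichment_down = enr_down, complexes = complexes,
                 complex_enrichment = complex_enrichment, overlap = overlap,
                 summary = summary_tab, outdir = outdir))
}
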