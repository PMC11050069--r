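#' Simulation configuration for a multi-cohort ploidy study
#'
#' Describes a study layout of several independent diploid-vs-polyploid
#' cohorts on mixed platforms (sequencing counts and array intensities) and
#' two species linked by an ortholog map, with a shared planted ploidy
#' signal, cohort-specific noise DEGs, a scale-free interaction network with
#' planted hub regulators, and a signature collection with planted enriched
#' sets.
#'
#' @param n_cohorts Number of consensus cohorts (default 5).
#' @param n_genes Genome size (human namespace).
#' @param samples_per_group Samples per ploidy group per cohort.
#' @param n_planted_up,n_planted_down Genes with a shared cross-cohort
#'   ploidy effect (induced / suppressed).
#' @param effect_size Mean log2 shift of planted (and noise) genes in
#'   polyploid samples.
#' @param cohort_noise_degs Cohort-specific (non-consensus) DEGs per cohort.
#' @param platform_kinds Per-cohort platform, `"counts"` or `"intensity"`;
#'   recycled to `n_cohorts`.
#' @param species Per-cohort species label (`"human"`/`"mouse"`); recycled.
#' @param ortholog_one_to_one_fraction Fraction of the genome with a clean
#'   1:1 human-mouse ortholog pair; the remainder is wired many-to-one to
#'   exercise the mapping rules. Planted genes are always 1:1 (a consensus
#'   signal must be resolvable across species to exist at all).
#' @param network_params List: `attachment` (preferential-attachment edges
#'   per node), `n_planted_hubs`, `hub_neighborhood_size`,
#'   `hub_deg_fraction` (fraction of a hub's neighbors drawn from the
#'   planted set sharing its direction).
#' @param signature_params List: `n_signatures`, `size_range` (length-2),
#'   `n_enriched`, `enrichment_fraction` (fraction of an enriched
#'   signature's members drawn from the planted genes).
#' @param n_validation_cohorts Extra held-out cohorts (counts, human) for
#'   external overlap validation.
#' @param seed Integer master seed; fans out to per-component child seeds.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_cohorts = 5,
                              n_genes = 2000,
                              samples_per_group = 6,
                              n_planted_up = 50,
                              n_planted_down = 50,
                              effect_size = 2,
                              cohort_noise_degs = 100,
                              platform_kinds = c("intensity", "counts",
                                                 "intensity", "counts", "counts"),
                              species = c("human", "mouse", "mouse",
                                          "human", "human"),
                              ortholog_one_to_one_fraction = 0.95,
                              network_params = list(attachment = 3,
                                                    n_planted_hubs = 20,
                                                    hub_neighborhood_size = 20,
                                                    hub_deg_fraction = 0.8),
                              signature_params = list(n_signatures = 200,
                                                      size_range = c(20, 200),
                                                      n_enriched = 10,
                                                      enrichment_fraction = 0.5),
                              n_validation_cohorts = 1,
                              seed = 1) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_genes = as.integer(n_genes),
              samples_per_group = as.integer(samples_per_group),
              n_planted_up = as.integer(n_planted_up),
              n_planted_down = as.integer(n_planted_down),
              effect_size = effect_size,
              cohort_noise_degs = as.integer(cohort_noise_degs),
              platform_kinds = rep_len(platform_kinds, n_cohorts),
              species = rep_len(species, n_cohorts),
              ortholog_one_to_one_fraction = ortholog_one_to_one_fraction,
              network_params = network_params,
              signature_params = signature_params,
              n_validation_cohorts = as.integer(n_validation_cohorts),
              seed = as.integer(seed))
  assert_that(cfg$n_cohorts >= 1 && cfg$n_genes >= 1 &&
                cfg$samples_per_group >= 2,
              "n_cohorts and n_genes must be positive; samples_per_group >= 2")
  assert_that(cfg$n_planted_up >= 0 && cfg$n_planted_down >= 0 &&
                cfg$cohort_noise_degs >= 0 && cfg$effect_size >= 0,
              "planted counts, noise counts and effect size must be non-negative")
  assert_that(cfg$n_planted_up + cfg$n_planted_down +
                cfg$cohort_noise_degs * cfg$n_cohorts <= cfg$n_genes,
              "planted and cohort-noise genes exceed the genome size")
  assert_that(all(cfg$platform_kinds %in% c("counts", "intensity")),
              "platform kinds must be 'counts' or 'intensity'")
  assert_that(all(cfg$species %in% c("human", "mouse")),
              "species must be 'human' or 'mouse'")
  assert_that(cfg$ortholog_one_to_one_fraction > 0 &&
                cfg$ortholog_one_to_one_fraction <= 1,
              "ortholog_one_to_one_fraction must lie in (0, 1]")
  np <- cfg$network_params
  assert_that(all(c("attachment", "n_planted_hubs", "hub_neighborhood_size",
                    "hub_deg_fraction") %in% names(np)),
              "network_params is missing required fields")
  assert_that(np$hub_neighborhood_size <= cfg$n_genes,
              "hub_neighborhood_size cannot exceed n_genes")
  assert_that(np$hub_deg_fraction >= 0 && np$hub_deg_fraction <= 1,
              "hub_deg_fraction must lie in [0, 1]")
  sp <- cfg$signature_params
  assert_that(all(c("n_signatures", "size_range", "n_enriched",
                    "enrichment_fraction") %in% names(sp)),
              "signature_params is missing required fields")
  assert_that(sp$n_enriched <= sp$n_signatures,
              "n_enriched cannot exceed n_signatures")
  structure(cfg, class = "SimulationConfig")
}

human_gene_ids <- function(n) sprintf("HSG%05d", seq_len(n))

# Ortholog table: a 1:1 pair for most genes; the remainder is grouped in
# pairs of human genes sharing one mouse gene (many-to-one), with a possible
# leftover human gene given two mouse genes (one-to-many).
build_ortholog_map <- function(config, planted) {
  genes <- human_gene_ids(config$n_genes)
  set.seed(child_seed(config$seed, "orthologs"))
  n_non11 <- round((1 - config$ortholog_one_to_one_fraction) * config$n_genes)
  pool <- setdiff(genes, planted)
  non11 <- sort(sample(pool, min(n_non11, length(pool))))
  one11 <- setdiff(genes, non11)
  mouse_of <- function(h) sub("^HSG", "MMG", h)
  human <- one11
  mouse <- mouse_of(one11)
  if (length(non11) >= 2) {
    k <- length(non11) %/% 2
    a <- non11[seq_len(k) * 2 - 1]
    b <- non11[seq_len(k) * 2]
    human <- c(human, a, b)
    mouse <- c(mouse, mouse_of(a), mouse_of(a))  # b shares a's mouse gene
  }
  if (length(non11) %% 2 == 1) {
    last <- non11[length(non11)]
    human <- c(human, last, last)
    mouse <- c(mouse, mouse_of(last), paste0(mouse_of(last), "B"))
  }
  ord <- order(human, mouse)
  map <- data.frame(human = human[ord], mouse = mouse[ord],
                    stringsAsFactors = FALSE)
  ortholog_map(map)
}

simulate_one_cohort <- function(config, truth, index, seed_component,
                                platform, sp, noise_genes) {
  set.seed(child_seed(config$seed, seed_component, index))
  genes <- human_gene_ids(config$n_genes)
  n <- config$samples_per_group
  delta <- setNames(rep(0, config$n_genes), genes)
  delta[truth$planted_up] <- config$effect_size
  delta[truth$planted_down] <- -config$effect_size
  if (length(noise_genes) > 0) {
    delta[noise_genes] <- sample(c(-1, 1), length(noise_genes),
                                 replace = TRUE) * config$effect_size
  }
  samples <- c(sprintf("c%d_dip_%02d", index, seq_len(n)),
               sprintf("c%d_pol_%02d", index, seq_len(n)))
  groups <- setNames(rep(c("diploid", "polyploid"), each = n), samples)
  if (platform == "counts") {
    # expressed-gene range: consensus-callable genes must be measurable on
    # every platform, i.e. pass standard low-expression filtering
    base <- runif(config$n_genes, 4, 11)  # log2 mean counts 16..2048
    mu <- cbind(matrix(2^base, config$n_genes, n),
                matrix(2^(base + delta), config$n_genes, n))
    phi <- 0.05 + 1 / mu  # dispersion trend ~ 1/mean
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
                config$n_genes, 2 * n)
  } else {
    base <- runif(config$n_genes, 5, 12)  # log2 intensities
    mean_mat <- cbind(matrix(base, config$n_genes, n),
                      matrix(base + delta, config$n_genes, n))
    m <- mean_mat + matrix(rnorm(length(mean_mat), sd = 0.5),
                           config$n_genes, 2 * n)
  }
  dimnames(m) <- list(genes, samples)
  if (sp == "mouse") {
    # a mouse cohort measures mouse genes; signal follows the (first)
    # human ortholog of each mouse gene
    map <- truth$ortholog_map
    first <- !duplicated(map$mouse)
    m <- m[map$human[first], , drop = FALSE]
    rownames(m) <- map$mouse[first]
  }
  expression_dataset(m, groups, platform = platform, species = sp)
}

#' Simulate the cohort expression matrices and ground truth
#'
#' Counts cohorts are drawn from a negative-binomial model with a 1/mean
#' dispersion trend; intensity cohorts from Gaussian noise around log2-scale
#' group means. Planted genes are shifted by `effect_size` in the same
#' direction in every cohort (polyploid vs diploid); cohort-noise genes are
#' shifted in one cohort only, with random sign. Mouse cohorts are emitted
#' under mouse identifiers resolvable only through the ortholog map.
#'
#' @param config A [simulation_config()].
#' @return List: `datasets` (per-cohort [expression_dataset()]s),
#'   `validation` (held-out cohorts), `truth` (class `GroundTruth`:
#'   planted/hub/noise/enriched-signature sets plus the ortholog map) and
#'   `ortholog_map`.
#' @export
simulate_cohorts <- function(config) {
  assert_that(inherits(config, "SimulationConfig"),
              "config must come from simulation_config()")
  genes <- human_gene_ids(config$n_genes)
  set.seed(child_seed(config$seed, "planting"))
  planted <- sample(genes, config$n_planted_up + config$n_planted_down)
  planted_up <- sort(planted[seq_len(config$n_planted_up)])
  planted_down <- sort(setdiff(planted, planted_up))
  rest <- setdiff(genes, planted)
  noise <- list()
  for (i in seq_len(config$n_cohorts + config$n_validation_cohorts)) {
    noise[[i]] <- sort(sample(rest, config$cohort_noise_degs))
    rest <- setdiff(rest, noise[[i]])
  }
  nh <- config$network_params$n_planted_hubs
  n_hub_up <- min(ceiling(nh / 2), length(planted_up))
  hubs_up <- sort(sample(planted_up, n_hub_up))
  hubs_down <- sort(sample(planted_down, min(nh - n_hub_up, length(planted_down))))
  sp <- config$signature_params
  sig_names <- sprintf("SIG%04d", seq_len(sp$n_signatures))
  enriched <- sort(sample(sig_names, sp$n_enriched))
  truth <- structure(list(planted_up = planted_up,
                          planted_down = planted_down,
                          hubs_up = hubs_up,
                          hubs_down = hubs_down,
                          planted_hubs = sort(c(hubs_up, hubs_down)),
                          noise_degs = noise[seq_len(config$n_cohorts)],
                          validation_noise = if (config$n_validation_cohorts > 0)
                            noise[config$n_cohorts + seq_len(config$n_validation_cohorts)]
                          else list(),
                          signature_names = sig_names,
                          enriched_signatures = enriched),
                     class = "GroundTruth")
  truth$ortholog_map <- build_ortholog_map(config,
                                           c(planted_up, planted_down))
  datasets <- lapply(seq_len(config$n_cohorts), function(i) {
    simulate_one_cohort(config, truth, i, "cohort",
                        config$platform_kinds[i], config$species[i],
                        truth$noise_degs[[i]])
  })
  names(datasets) <- sprintf("cohort%d", seq_len(config$n_cohorts))
  validation <- lapply(seq_len(config$n_validation_cohorts), function(i) {
    simulate_one_cohort(config, truth, config$n_cohorts + i, "validation",
                        "counts", "human", truth$validation_noise[[i]])
  })
  if (config$n_validation_cohorts > 0)
    names(validation) <- sprintf("validation%d", seq_len(config$n_validation_cohorts))
  list(datasets = datasets, validation = validation, truth = truth,
       ortholog_map = truth$ortholog_map)
}

#' Simulate the interaction network with planted hub regulators
#'
#' A scale-free-like background graph is grown by preferential attachment
#' over the whole gene universe; each planted hub is then rewired so that a
#' fraction `hub_deg_fraction` of its `hub_neighborhood_size` neighbors are
#' planted genes sharing the hub's direction.
#'
#' @param config A [simulation_config()].
#' @param truth The `GroundTruth` from [simulate_cohorts()].
#' @return Undirected simple igraph over the human gene identifiers.
#' @export
simulate_network <- function(config, truth) {
  assert_that(inherits(truth, "GroundTruth"),
              "truth must come from simulate_cohorts()")
  np <- config$network_params
  set.seed(child_seed(config$seed, "network"))
  g <- igraph::sample_pa(config$n_genes, power = 1, m = np$attachment,
                         directed = FALSE)
  igraph::V(g)$name <- human_gene_ids(config$n_genes)
  planted_all <- c(truth$planted_up, truth$planted_down)
  non_deg <- setdiff(human_gene_ids(config$n_genes), planted_all)
  n_deg_nb <- round(np$hub_deg_fraction * np$hub_neighborhood_size)
  wire_hub <- function(g, hub, planted_dir) {
    pool <- setdiff(planted_dir, truth$planted_hubs)
    assert_that(length(pool) >= n_deg_nb,
                "not enough planted genes to wire a hub neighborhood")
    nb <- c(sample(pool, n_deg_nb),
            sample(setdiff(non_deg, hub),
                   np$hub_neighborhood_size - n_deg_nb))
    g <- igraph::delete_edges(g, igraph::incident(g, hub))
    igraph::add_edges(g, as.vector(rbind(hub, nb)))
  }
  for (h in truth$hubs_up) g <- wire_hub(g, h, truth$planted_up)
  for (h in truth$hubs_down) g <- wire_hub(g, h, truth$planted_down)
  igraph::simplify(g)
}

#' Simulate a gene-signature collection with planted enrichment
#'
#' Enriched signatures draw `enrichment_fraction` of their members from the
#' planted (up and down) genes and the rest from the unplanted genome; null
#' signatures are drawn uniformly from the whole genome.
#'
#' @inheritParams simulate_network
#' @return A `SignatureCollection`.
#' @export
simulate_signatures <- function(config, truth) {
  assert_that(inherits(truth, "GroundTruth"),
              "truth must come from simulate_cohorts()")
  sp <- config$signature_params
  set.seed(child_seed(config$seed, "signatures"))
  genes <- human_gene_ids(config$n_genes)
  planted <- c(truth$planted_up, truth$planted_down)
  other <- setdiff(genes, planted)
  sets <- lapply(truth$signature_names, function(nm) {
    size <- sample(seq(sp$size_range[1], sp$size_range[2]), 1)
    if (nm %in% truth$enriched_signatures) {
      k <- min(round(sp$enrichment_fraction * size), length(planted))
      sort(c(sample(planted, k), sample(other, size - k)))
    } else {
      sort(sample(genes, size))
    }
  })
  names(sets) <- truth$signature_names
  signature_collection(sets,
                       setNames(rep("synthetic signature",
                                    length(sets)), names(sets)))
}

#' Simulate a complete study
#'
#' Runs [simulate_cohorts()], [simulate_network()] and
#' [simulate_signatures()] under one configuration.
#'
#' @param config A [simulation_config()].
#' @return List: `config`, `datasets`, `validation`, `truth`,
#'   `ortholog_map`, `network`, `signatures`, `gene_universe`.
#' @export
simulate_study <- function(config = simulation_config()) {
  sim <- simulate_cohorts(config)
  list(config = config,
       datasets = sim$datasets,
       validation = sim$validation,
       truth = sim$truth,
       ortholog_map = sim$ortholog_map,
       network = simulate_network(config, sim$truth),
       signatures = simulate_signatures(config, sim$truth),
       gene_universe = human_gene_ids(config$n_genes))
}

#' Write all simulated study inputs to a directory
#'
#' Emits per-cohort expression and metadata TSVs, the ortholog map, the
#' network edge list, the signature GMT, the gene universe and the
#' ground-truth gene lists. Output bytes are a pure function of the
#' configuration (including its seed).
#'
#' @param study Output of [simulate_study()].
#' @param outdir Directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  all_ds <- c(study$datasets, study$validation)
  for (nm in names(all_ds)) {
    write_expression(all_ds[[nm]], p(paste0(nm, "_expression.tsv")),
                     p(paste0(nm, "_samples.tsv")))
  }
  write_ortholog_map(study$ortholog_map, p("orthologs.tsv"))
  write_edge_list(study$network, p("network_edges.tsv"))
  write_gmt(study$signatures, p("signatures.gmt"))
  write_gene_set(study$gene_universe, p("gene_universe.tsv"))
  write_gene_set(study$truth$planted_up, p("truth_planted_up.tsv"))
  write_gene_set(study$truth$planted_down, p("truth_planted_down.tsv"))
  write_gene_set(study$truth$planted_hubs, p("truth_planted_hubs.tsv"))
  write_gene_set(study$truth$enriched_signatures,
                 p("truth_enriched_signatures.tsv"))
  invisible(outdir)
}
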