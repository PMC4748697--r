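# Two-phase workflow orchestration behind a config carrying the method's
# named parameters.

#' Default pipeline configuration
#'
#' All named parameters of the method with their default values:
#' `minSeqLen` (1,000 bp), `candidatePlTopPercentThreshold` (0.1),
#' `placeContigsFromTheSameScaffold` (TRUE), `agThreshold` (0.3),
#' `assignedPartThreshold` (0.5), `rankIdCut` ("species"),
#' `minGenomesWgs` (3), `minBpPerSpecies` (300,000), `minBpToModel`
#' (100,000), `maxLeafClades` (50), `maxSSDfileSize` (400,000), `K`
#' (4,5,6), `nbc_k` (8), `n_bootstrap` (100), plus classifier training
#' knobs (`fragmentLen`, `maxFragsPerClass`, `holdoutFraction`,
#' `stopQuantile`) and `rng_seed`.
#'
#' @param ... Overrides for individual fields.
#' @return Named list of class `selfbin_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    minSeqLen = 1000L,
    candidatePlTopPercentThreshold = 0.1,
    placeContigsFromTheSameScaffold = TRUE,
    agThreshold = 0.3,
    assignedPartThreshold = 0.5,
    rankIdCut = "species",
    minGenomesWgs = 3L,
    minBpPerSpecies = 3e5,
    minBpToModel = 1e5,
    maxLeafClades = 50L,
    maxSSDfileSize = 4e5,
    K = c(4L, 5L, 6L),
    nbc_k = 8L,
    n_bootstrap = 100L,
    fragmentLen = 1000L,
    maxFragsPerClass = 300L,
    holdoutFraction = 0.1,
    stopQuantile = 0,
    rng_seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "selfbin_config")
}

#' Read a YAML config file (missing fields take defaults)
#'
#' @param path YAML file whose keys use the parameter names of
#'   [default_config()].
#' @return A `selfbin_config`.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Write a config as YAML
#'
#' @param config A `selfbin_config`.
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.selection_params_from <- function(config) {
  selection_params(minBpToModel = config$minBpToModel,
                   minBpPerSpecies = config$minBpPerSpecies,
                   minGenomesWgs = config$minGenomesWgs,
                   maxLeafClades = config$maxLeafClades,
                   maxSSDfileSize = config$maxSSDfileSize)
}

.consensus_params_from <- function(config) {
  consensus_params(agThreshold = config$agThreshold,
                   assignedPartThreshold = config$assignedPartThreshold,
                   enabled = config$placeContigsFromTheSameScaffold)
}

#' Phase 1: automatic taxon selection and training-data assembly
#'
#' Runs marker extraction, naive Bayes marker assignment, fragment
#' consensus, the optional scaffold-consistency step, rank truncation,
#' modelable-taxa selection, abundant-taxa pruning and training-data
#' balancing, in that order.
#'
#' @param contigs Named character vector of sample contigs.
#' @param scaffold_map Scaffold map `data.frame` (or `NULL`).
#' @param hits Precomputed marker-hit `data.frame`
#'   ([read_marker_hits()]).
#' @param mg_seqs Named character vector of marker reference sequences.
#' @param mg_labels `data.frame` `seq_id`, `taxon_id` labeling `mg_seqs`.
#' @param tree A [taxonomy()] object.
#' @param catalog A [reference_catalog()].
#' @param config A `selfbin_config`.
#' @return List: `model_spec`, `assignments` (final phase-1 per-contig
#'   assignments incl. unassigned rows), `log` (per-step assigned bp and
#'   taxon counts).
#' @export
run_plus_phase <- function(contigs, scaffold_map, hits, mg_seqs,
                           mg_labels, tree, catalog,
                           config = default_config()) {
  contigs <- .named_chr(contigs)
  lengths <- stats::setNames(nchar(contigs), names(contigs))
  empty <- data.frame(seq_id = names(contigs),
                      taxon_id = NA_character_, confidence = 0,
                      stringsAsFactors = FALSE)
  logrows <- list()
  note <- function(step, a) {
    ok <- !is.na(a$taxon_id)
    logrows[[step]] <<- data.frame(
      step = step, assigned_bp = sum(lengths[a$seq_id[ok]]),
      n_taxa = length(unique(a$taxon_id[ok])), stringsAsFactors = FALSE)
  }

  hits <- detect_markers(contigs, hits)
  if (nrow(hits) == 0L) {
    warning("no usable marker hits: phase 1 produces an empty model spec")
    ms <- structure(list(leaves = character(0),
                         training = data.frame(seq_id = character(0),
                                               taxon_id = character(0),
                                               confidence = numeric(0),
                                               length = numeric(0)),
                         assignments = empty), class = "model_spec")
    return(list(model_spec = ms, assignments = empty,
                log = data.frame(step = "markers", assigned_bp = 0,
                                 n_taxa = 0L)))
  }
  nbc <- train_nbc(unname(mg_seqs[mg_labels$seq_id]), mg_labels$taxon_id,
                   k = config$nbc_k)
  ma <- assign_markers(nbc, hits, n_bootstrap = config$n_bootstrap,
                       seed = config$rng_seed)
  frag <- assign_fragments(ma, tree,
                           threshold = config$candidatePlTopPercentThreshold)
  a <- empty
  ix <- match(frag$seq_id, a$seq_id)
  a$taxon_id[ix] <- frag$taxon_id
  a$confidence[ix] <- frag$confidence
  note("marker_assignment", a)

  if (!is.null(scaffold_map))
    a <- scaffold_consensus(a, scaffold_map, tree,
                            .consensus_params_from(config), lengths)
  note("scaffold_consensus", a)

  a <- truncate_assignments(a, tree, config$rankIdCut)
  note("rank_truncation", a)

  sel_params <- .selection_params_from(config)
  sel <- select_modelable_taxa(a, catalog, tree, sel_params, lengths)
  a <- sel$assignments
  note("modelable_selection", a)

  pr <- prune_to_max_leaves(a, tree, sel_params, lengths)
  a <- pr$assignments
  note("abundance_pruning", a)

  ms <- balance_training_data(a, tree, sel_params, lengths)
  note("balancing", ms$training)

  list(model_spec = ms, assignments = a,
       log = do.call(rbind, c(logrows, list(make.row.names = FALSE))))
}

#' Phase 2: train (if needed) and bin the sample
#'
#' @param model A trained `hier_model`, or a `model_spec` to train from.
#' @param contigs Named character vector of contigs to bin.
#' @param scaffold_map Optional scaffold map for the final consistency
#'   pass.
#' @param tree A [taxonomy()] object.
#' @param catalog A [reference_catalog()] (training only).
#' @param config A `selfbin_config`.
#' @param model_dir Optional directory: a trained model is persisted
#'   there ([save_model()]) and can be reused for later samples without
#'   retraining.
#' @return List: `predictions` (per-contig assignments), `model`,
#'   `trained` (whether training ran in this call).
#' @export
run_binning <- function(model, contigs, scaffold_map = NULL, tree,
                        catalog = NULL, config = default_config(),
                        model_dir = NULL) {
  trained <- FALSE
  if (inherits(model, "model_spec")) {
    model <- train_hierarchical(
      model, contigs, catalog, tree, K = config$K,
      fragment_len = config$fragmentLen,
      min_seq_len = config$minSeqLen,
      max_frags_per_class = config$maxFragsPerClass,
      holdout = config$holdoutFraction,
      stop_quantile = config$stopQuantile,
      seed = config$rng_seed + 1L)
    trained <- TRUE
    if (!is.null(model_dir)) save_model(model, model_dir)
  } else if (!inherits(model, "hier_model")) {
    stop("need a trained model or a model_spec (usage error)")
  }
  preds <- bin_sample(model, contigs, scaffold_map = scaffold_map,
                      tree = tree,
                      params = .consensus_params_from(config))
  list(predictions = preds, model = model, trained = trained)
}

#' Evaluate predictions against ground truth
#'
#' @param pred Predictions `data.frame`.
#' @param truth Truth `data.frame` (`seq_id`, `taxon_id`, `length`).
#' @param tree A [taxonomy()] object.
#' @param config A `selfbin_config`.
#' @param scaffold_pred,scaffold_map Optional scaffold-level predictions
#'   and map for agreement columns.
#' @return An `eval_report` ([evaluate_binning()]).
#' @export
run_evaluate <- function(pred, truth, tree, config = default_config(),
                         scaffold_pred = NULL, scaffold_map = NULL) {
  missing <- setdiff(pred$seq_id, truth$seq_id)
  if (length(missing) > 0L)
    stop("predictions without truth entries: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ...")
  evaluate_binning(pred, truth, tree, scaffold_pred = scaffold_pred,
                   scaffold_map = scaffold_map)
}

#' Run both phases end-to-end on a generated community
#'
#' Convenience wrapper for benchmarking: phase 1, phase 2 and evaluation
#' against the community's ground truth.
#'
#' @param comm Output of [generate_community()].
#' @param config A `selfbin_config`.
#' @return List: `plus` (phase-1 output), `binning` (phase-2 output),
#'   `report` (per-rank evaluation).
#' @export
run_pipeline <- function(comm, config = default_config()) {
  plus <- run_plus_phase(comm$contigs, comm$scaffold_map, comm$hits,
                         comm$mg_seqs, comm$mg_labels, comm$tree,
                         comm$catalog, config)
  binning <- run_binning(plus$model_spec, comm$contigs,
                         scaffold_map = comm$scaffold_map,
                         tree = comm$tree, catalog = comm$catalog,
                         config = config)
  report <- run_evaluate(binning$predictions, comm$truth, comm$tree,
                         config)
  list(plus = plus, binning = binning, report = report)
}
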