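# Declarative pipeline orchestration over the four-file input interface
# (kg.tsv, KG_labels.tsv, Drugs.csv, Drug_combinations.csv).

PIPELINE_STAGES <- c("enrich", "embed", "evaluate", "ml", "predict", "cop",
                     "repurpose")

#' Default pipeline configuration
#'
#' Every stage parameter in one declarative list; [run_pipeline()] rejects
#' unknown keys so typos cannot silently fall back to defaults.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    kg = NULL, labels = NULL, drugs = NULL, combinations = NULL,
    out_dir = NULL,
    t_syn = 10, t_ant = -10, include_additive = FALSE,
    model = "HolE", dim = 64L, epochs = 100L, batch_size = 256L,
    negatives = 4L, learning_rate = 0.01,
    test_frac = 0.2, val_frac = 0.2,
    ml_models = "random_forest", ml_mode = "embedding",
    whitelist = CAUSAL_WHITELIST, hub_types = "Pathology",
    degree_threshold = NULL,
    anchors = character(0), exclusion = character(0),
    disease = NULL, max_len = 4L,
    seed = 1L)
}

#' Run the enrichment-to-repurposing pipeline
#'
#' Executes the requested stages in fixed workflow order (enrich, embed,
#' evaluate, ml, predict, cop, repurpose), chaining each stage's output files
#' into the next and writing a JSON run manifest (config, input hashes,
#' outputs, wall time) to the output directory. A stage whose upstream
#' artifact is missing fails with an error naming the stage to run first.
#'
#' @param config configuration list; see [default_config()] for the keys.
#'   Unknown keys are rejected.
#' @param stages subset of the stage names, any order (executed in workflow
#'   order).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), stages = PIPELINE_STAGES) {
  unknown <- setdiff(names(config), names(default_config()))
  if (length(unknown))
    abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(default_config(), config)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% match.arg(stages,
                                                           PIPELINE_STAGES,
                                                           several.ok = TRUE)]
  if (is.null(cfg$out_dir)) abort("config$out_dir is required")
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  need <- function(path, producer)
    if (!file.exists(path))
      abort("missing artifact %s: run stage '%s' first", path, producer)
  t0 <- Sys.time()
  outputs <- character(0)
  emit <- function(f) outputs <<- union(outputs, f)

  for (stage in stages) {
    switch(stage,
      enrich = {
        if (is.null(cfg$kg) || is.null(cfg$combinations))
          abort("enrich needs config$kg and config$combinations")
        kg <- read_kg_tsv(cfg$kg, labels_path = cfg$labels)
        combos <- utils::read.csv(cfg$combinations, stringsAsFactors = FALSE)
        labels <- consistency_filter(combos, c(cfg$t_syn, cfg$t_ant))
        enriched <- enrich_kg(kg, labels,
                              include_additive = cfg$include_additive)
        write_kg_tsv(enriched, out("enriched.tsv"),
                     labels_path = out("enriched_labels.tsv"))
        utils::write.csv(labels, out("pair_labels.csv"), row.names = FALSE)
        emit(out("enriched.tsv")); emit(out("enriched_labels.tsv"))
        emit(out("pair_labels.csv"))
      },
      embed = {
        need(out("enriched.tsv"), "enrich")
        kg <- read_kg_tsv(out("enriched.tsv"),
                          labels_path = out("enriched_labels.tsv"))
        split <- split_triples(kg, cfg$test_frac, cfg$val_frac,
                               seed = cfg$seed)
        for (part in c("train", "validation", "test"))
          write.table(split[[part]][, c("head", "relation", "tail")],
                      out(paste0("split_", part, ".tsv")), sep = "\t",
                      quote = FALSE, row.names = FALSE, col.names = FALSE)
        fit <- kge(knowledge_graph(split$train), model = cfg$model,
                   dim = cfg$dim, epochs = cfg$epochs,
                   batch_size = cfg$batch_size, negatives = cfg$negatives,
                   learning_rate = cfg$learning_rate, seed = cfg$seed)
        saveRDS(fit, out("model.rds"))
        for (part in c("train", "validation", "test"))
          emit(out(paste0("split_", part, ".tsv")))
        emit(out("model.rds"))
      },
      evaluate = {
        need(out("model.rds"), "embed")
        need(out("split_test.tsv"), "embed")
        fit <- readRDS(out("model.rds"))
        te <- read.delim(out("split_test.tsv"), header = FALSE,
                         col.names = c("head", "relation", "tail"),
                         colClasses = "character")
        te <- te[te$head %in% fit$entities & te$tail %in% fit$entities, ]
        rankings <- lapply(seq_len(nrow(te)), function(i)
          rank_relations(fit, te$head[i], te$tail[i]))
        res <- true_prediction_percentage(rankings, te,
                                          k = seq_len(min(3, length(fit$relations))))
        write.table(res, out("rank_eval.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        score_mat <- t(vapply(rankings, function(r)
          r$score[match(fit$relations, r$relation)],
          numeric(length(fit$relations))))
        colnames(score_mat) <- fit$relations
        metrics <- if (length(unique(te$relation)) >= 2L)
          multiclass_roc_auc(te$relation, score_mat)
        else list(macro_auc = NA, per_type_auc = NULL)
        jsonlite::write_json(
          list(rank_percentages = res, macro_auc = metrics$macro_auc,
               per_type_auc = as.list(metrics$per_type_auc)),
          out("metrics.json"), auto_unbox = TRUE, digits = NA)
        emit(out("rank_eval.tsv")); emit(out("metrics.json"))
      },
      ml = {
        need(out("pair_labels.csv"), "enrich")
        labels <- utils::read.csv(out("pair_labels.csv"),
                                  stringsAsFactors = FALSE)
        labels <- labels[labels$label %in% c("synergism", "antagonism"), ]
        if (cfg$ml_mode %in% c("embedding", "both"))
          need(out("model.rds"), "embed")
        fit <- if (cfg$ml_mode %in% c("embedding", "both"))
          readRDS(out("model.rds")) else NULL
        kg <- if (cfg$ml_mode %in% c("handcrafted", "both"))
          read_kg_tsv(out("enriched.tsv"),
                      labels_path = out("enriched_labels.tsv")) else NULL
        physchem <- if (!is.null(cfg$drugs))
          utils::read.csv(cfg$drugs, stringsAsFactors = FALSE) else NULL
        if (cfg$ml_mode == "embedding")
          labels <- labels[labels$drug_a %in% fit$entities &
                           labels$drug_b %in% fit$entities, ]
        feats <- t(vapply(seq_len(nrow(labels)), function(i)
          build_pair_features(labels$drug_a[i], labels$drug_b[i], kg = kg,
                              physchem = physchem, mode = cfg$ml_mode,
                              embeddings = fit),
          build_pair_features(labels$drug_a[1], labels$drug_b[1], kg = kg,
                              physchem = physchem, mode = cfg$ml_mode,
                              embeddings = fit)))
        report <- nested_cv(feats, labels$label, models = cfg$ml_models,
                            seed = cfg$seed)
        jsonlite::write_json(
          list(sizes = report$sizes,
               holdout_auc = lapply(report$models, `[[`, "holdout_auc")),
          out("cv_report.json"), auto_unbox = TRUE, digits = NA)
        emit(out("cv_report.json"))
      },
      predict = {
        need(out("model.rds"), "embed")
        fit <- readRDS(out("model.rds"))
        lab_path <- out("enriched_labels.tsv")
        need(lab_path, "enrich")
        lab <- read.delim(lab_path, header = FALSE,
                          col.names = c("node", "type"),
                          colClasses = "character")
        drugs <- intersect(lab$node[lab$type == "Drug"], fit$entities)
        known <- NULL
        if (file.exists(out("pair_labels.csv")))
          known <- utils::read.csv(out("pair_labels.csv"),
                                   stringsAsFactors = FALSE)
        preds <- predict_all_pairs(fit, drugs, known_pairs = known)
        kept <- mutual_filter(preds)
        seg <- segregate(kept)
        write.table(preds, out("pair_predictions.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(seg$synergism, out("predicted_synergism.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(seg$antagonism, out("predicted_antagonism.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        emit(out("pair_predictions.tsv")); emit(out("predicted_synergism.tsv"))
        emit(out("predicted_antagonism.tsv"))
      },
      cop = {
        need(out("enriched.tsv"), "enrich")
        kg <- read_kg_tsv(out("enriched.tsv"),
                          labels_path = out("enriched_labels.tsv"))
        built <- build_cop(kg, whitelist = cfg$whitelist,
                           hub_types = cfg$hub_types,
                           degree_threshold = cfg$degree_threshold)
        write_kg_tsv(built$cop, out("cop.tsv"),
                     labels_path = out("cop_labels.tsv"))
        write_kg_tsv(built$cop_with_disease, out("cop_with_disease.tsv"),
                     labels_path = out("cop_with_disease_labels.tsv"))
        write.table(built$removal_log, out("prune_log.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit(out("cop.tsv")); emit(out("cop_with_disease.tsv"))
        emit(out("prune_log.tsv"))
      },
      repurpose = {
        need(out("predicted_synergism.tsv"), "predict")
        if (is.null(cfg$disease)) abort("repurpose needs config$disease")
        syn <- read.delim(out("predicted_synergism.tsv"),
                          stringsAsFactors = FALSE)
        path_kg <- if (file.exists(out("cop_with_disease.tsv")))
          read_kg_tsv(out("cop_with_disease.tsv"),
                      labels_path = out("cop_with_disease_labels.tsv"))
        else read_kg_tsv(out("enriched.tsv"),
                         labels_path = out("enriched_labels.tsv"))
        report <- nominate_candidates(syn, cfg$anchors, cfg$exclusion,
                                      path_kg, cfg$disease,
                                      max_len = cfg$max_len)
        write.table(report, out("repurposing_report.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        emit(out("repurposing_report.tsv"))
      })
  }

  input_files <- Filter(function(p) is.character(p) && length(p) == 1 &&
                          file.exists(p),
                        cfg[c("kg", "labels", "drugs", "combinations")])
  manifest <- list(
    stages = stages,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    input_md5 = as.list(tools::md5sum(unlist(input_files))),
    output_md5 = as.list(tools::md5sum(setdiff(outputs, out("model.rds")))),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("kgsynergy")),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
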