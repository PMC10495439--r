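#' Default pipeline configuration
#'
#' Every tunable of the staged pipeline with its default. Values can be
#' overridden by a YAML file whose keys match these names.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    alpha = 0.05,            # per-endpoint screen significance level
    i2_threshold = 75,       # percent I2 flagging heterogeneous pools
    pdl1_gene = "CD274",
    score_reference = "TREATED_ARM",
    stratify_mode = "IHC2",
    stratify_reference = "TREATED_ARM",
    orr_denominator = "ITT",
    consensus_reps = 1000,
    consensus_p_item = 0.8,
    consensus_maxK = 6,
    preset = "paper-pattern",
    simulate = sim_config()[c("n_cancers", "trials_per_cancer", "per_arm_n",
                              "tau", "n_decoy_genes", "cohort_n",
                              "samples_per_cancer", "censor_rate")])
}

#' Load a pipeline configuration
#'
#' Reads a YAML key-value file and overlays it on
#' \code{\link{pipeline_defaults}}; unknown keys are rejected.
#'
#' @param path Optional path to a YAML config file.
#' @return Named configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    .assert(file.exists(path), paste("config file not found:", path))
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      .assert(length(unknown) == 0,
              paste("unknown config key(s):", paste(unknown, collapse = ", ")))
      for (k in names(user)) {
        if (k == "simulate") {
          cfg$simulate[names(user$simulate)] <- user$simulate
        } else cfg[[k]] <- user[[k]]
      }
    }
  }
  cfg
}

.log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

.stage_path <- function(out_dir, file) file.path(out_dir, file)

.need_inputs <- function(out_dir, files, producer) {
  missing <- files[!file.exists(file.path(out_dir, files))]
  .assert(length(missing) == 0,
          sprintf("missing input(s) %s: run the '%s' stage first",
                  paste(missing, collapse = ", "), producer))
}

.stage_simulate <- function(cfg, out_dir, seed) {
  sc <- do.call(sim_config, c(list(seed = seed, preset = cfg$preset),
                              cfg$simulate))
  tt <- simulate_trial_table(sc)
  pn <- simulate_expression_panel(sc)
  ch <- simulate_cohort(sc)
  write_tsv(tt$trials, .stage_path(out_dir, "trials.tsv"))
  write_panel_tsv(pn$panel, .stage_path(out_dir, "panel.tsv"),
                  .stage_path(out_dir, "sample_map.tsv"))
  write_cohort_tsv(ch$cohort, .stage_path(out_dir, "clinical.tsv"),
                   .stage_path(out_dir, "patient_expr.tsv"),
                   .stage_path(out_dir, "cell_fractions.tsv"))
  truth <- list(trial = unclass(tt$truth), panel = unclass(pn$truth),
                cohort = unclass(ch$truth))
  write_truth_json(truth, .stage_path(out_dir, "truth.json"))
  .log_stage("simulate", sprintf("%d trial rows, %d panel samples, %d patients",
                                 nrow(tt$trials), ncol(pn$panel$matrix),
                                 nrow(ch$cohort$clinical)))
  c("trials.tsv", "panel.tsv", "sample_map.tsv", "clinical.tsv",
    "patient_expr.tsv", "cell_fractions.tsv", "truth.json")
}

.stage_meta <- function(cfg, out_dir, seed) {
  .need_inputs(out_dir, "trials.tsv", "simulate")
  trials <- read_trials_tsv(.stage_path(out_dir, "trials.tsv"))
  pred <- rbind(
    as.data.frame(compute_predictiveness(trials, "OS", cfg$i2_threshold)),
    as.data.frame(compute_predictiveness(trials, "PFS", cfg$i2_threshold)))
  write_tsv(pred, .stage_path(out_dir, "predictiveness.tsv"))
  .log_stage("meta", sprintf("%d cancer x endpoint rows", nrow(pred)))
  "predictiveness.tsv"
}

.stage_screen <- function(cfg, out_dir, seed) {
  .need_inputs(out_dir, c("panel.tsv", "sample_map.tsv"), "simulate")
  .need_inputs(out_dir, "predictiveness.tsv", "meta")
  panel <- read_panel_tsv(.stage_path(out_dir, "panel.tsv"),
                          .stage_path(out_dir, "sample_map.tsv"))
  pred <- .read_tsv(.stage_path(out_dir, "predictiveness.tsv"))
  med <- median_profile(panel)
  scr <- cross_cancer_screen(med, pred[pred$endpoint == "OS", ],
                             pred[pred$endpoint == "PFS", ], cfg$alpha)
  write_tsv(scr, .stage_path(out_dir, "screen.tsv"))
  write_tsv(data.frame(cancer = rownames(med), med, check.names = FALSE),
            .stage_path(out_dir, "medians.tsv"))
  .log_stage("screen", sprintf("%d genes screened, %d pass", nrow(scr),
                               sum(scr$passes)))
  c("screen.tsv", "medians.tsv")
}

.stage_rank <- function(cfg, out_dir, seed) {
  .need_inputs(out_dir, c("clinical.tsv", "patient_expr.tsv"), "simulate")
  .need_inputs(out_dir, "screen.tsv", "screen")
  cohort <- read_cohort_tsv(.stage_path(out_dir, "clinical.tsv"),
                            .stage_path(out_dir, "patient_expr.tsv"))
  scr <- .read_tsv(.stage_path(out_dir, "screen.tsv"))
  cand <- scr$gene[scr$passes]
  if (length(cand) == 0) cand <- scr$gene
  cand <- intersect(cand, rownames(cohort$expr))
  .assert(length(cand) >= 1L, "no screened candidate genes in the cohort")
  treated <- subset_cohort(
    cohort, cohort$clinical$patient_id[cohort$clinical$arm == "ICI"])
  ints <- rbind(
    rank_interactions(treated, cfg$pdl1_gene, cand, "OS"),
    rank_interactions(treated, cfg$pdl1_gene, cand, "PFS"))
  write_tsv(ints, .stage_path(out_dir, "interactions.tsv"))
  .log_stage("rank", sprintf("%d candidates x 2 endpoints", length(cand)))
  "interactions.tsv"
}

.stage_score <- function(cfg, out_dir, seed) {
  .need_inputs(out_dir, c("medians.tsv", "predictiveness.tsv"), "screen")
  .need_inputs(out_dir, "interactions.tsv", "rank")
  ints <- .read_tsv(.stage_path(out_dir, "interactions.tsv"))
  os <- ints[ints$endpoint == "OS" & ints$estimable, ]
  .assert(nrow(os) >= 1L, "no estimable OS interaction: cannot pick a modulator")
  top_gene <- os$gene[which.max(os$z)]
  meds <- .read_tsv(.stage_path(out_dir, "medians.tsv"))
  pred <- .read_tsv(.stage_path(out_dir, "predictiveness.tsv"))
  pred_os <- pred[pred$endpoint == "OS", ]
  psm <- fit_ps_model(setNames(meds[[top_gene]], meds$cancer),
                      setNames(pred_os$hrd, pred_os$cancer),
                      gene = top_gene)
  cohort <- read_cohort_tsv(.stage_path(out_dir, "clinical.tsv"),
                            .stage_path(out_dir, "patient_expr.tsv"))
  scores <- score_and_split(cohort, psm, cfg$score_reference)
  scores$cutoff_used <- attr(scores, "cutoff")
  scores$reference_population <- attr(scores, "reference")
  write_tsv(scores, .stage_path(out_dir, "scores.tsv"))
  jsonlite::write_json(
    list(gene = psm$gene, slope = psm$slope, intercept = psm$intercept,
         loocv_rmse = psm$loocv_rmse, n_points = psm$n_points),
    .stage_path(out_dir, "ps_model.json"), auto_unbox = TRUE, digits = NA)
  .log_stage("score", sprintf("modulator %s, slope %.3f, intercept %.3f",
                              psm$gene, psm$slope, psm$intercept))
  c("scores.tsv", "ps_model.json")
}

.stage_evaluate <- function(cfg, out_dir, seed) {
  .need_inputs(out_dir, c("clinical.tsv", "patient_expr.tsv"), "simulate")
  .need_inputs(out_dir, "scores.tsv", "score")
  cohort <- read_cohort_tsv(.stage_path(out_dir, "clinical.tsv"),
                            .stage_path(out_dir, "patient_expr.tsv"))
  scores <- .read_tsv(.stage_path(out_dir, "scores.tsv"))
  strat <- stratify_pdl1(cohort, cfg$stratify_mode, cfg$stratify_reference,
                         cfg$pdl1_gene)
  grid <- rbind(
    efficacy_grid(cohort, scores, strat, "POS_vs_NEG_within_ICI",
                  orr_denominator = cfg$orr_denominator),
    efficacy_grid(cohort, scores, strat, "ICI_vs_CHEMO_within_stratum",
                  orr_denominator = cfg$orr_denominator))
  write_tsv(as.data.frame(grid), .stage_path(out_dir, "efficacy.tsv"))
  .log_stage("evaluate", sprintf("%d grid rows", nrow(grid)))
  "efficacy.tsv"
}

.stage_profile <- function(cfg, out_dir, seed) {
  .need_inputs(out_dir, c("patient_expr.tsv", "cell_fractions.tsv"),
               "simulate")
  expr <- .read_tsv(.stage_path(out_dir, "patient_expr.tsv"))
  mat <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  rownames(mat) <- expr$gene
  norm <- normalize_expression(mat)
  sets <- list(CD8_score = c("CD8A", "CD8B"))
  sets <- c(sets, list(modulator_axis = intersect(c("MOD1", "CD274"),
                                                  rownames(norm))))
  sig <- signature_scores(norm, sets)
  write_tsv(data.frame(sample = rownames(sig), sig, check.names = FALSE),
            .stage_path(out_dir, "signatures.tsv"))
  fr <- .read_tsv(.stage_path(out_dir, "cell_fractions.tsv"))
  cf <- as.matrix(fr[, setdiff(names(fr), "sample"), drop = FALSE])
  rownames(cf) <- fr$sample
  cc <- consensus_cluster(cf, maxK = cfg$consensus_maxK,
                          reps = cfg$consensus_reps,
                          p_item = cfg$consensus_p_item, seed = seed)
  asn <- data.frame(sample = rownames(cf))
  for (k in names(cc$assignments)) asn[[paste0("k", k)]] <- cc$assignments[[k]]
  asn$chosen_k <- cc$chosen_k
  write_tsv(asn, .stage_path(out_dir, "consensus_assignments.tsv"))
  cm <- cc$consensus[[as.character(cc$chosen_k)]]
  write_tsv(data.frame(sample = rownames(cm), cm, check.names = FALSE),
            .stage_path(out_dir, "consensus_matrix.tsv"))
  .log_stage("profile", sprintf("%d signature columns, chosen k = %d",
                                ncol(sig), cc$chosen_k))
  c("signatures.tsv", "consensus_assignments.tsv", "consensus_matrix.tsv")
}

#' Run the staged analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> meta -> screen -> rank -> score -> evaluate -> profile),
#' each reading and writing only its documented TSVs under \code{out_dir},
#' and writes a JSON run manifest (config snapshot, input digests, seed,
#' stage timings, output inventory) atomically at the end.
#'
#' @param config Path to a YAML config file, a configuration list from
#'   \code{\link{load_config}}, or NULL for defaults.
#' @param stages Ordered subset of
#'   \code{c("simulate","meta","screen","rank","score","evaluate","profile")};
#'   default all.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest and used by every
#'   stochastic stage.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("simulate", "meta", "screen", "rank",
                                    "score", "evaluate", "profile"),
                         out_dir = "pipeline_out", seed = 1) {
  all_stages <- c(simulate = ".stage_simulate", meta = ".stage_meta",
                  screen = ".stage_screen", rank = ".stage_rank",
                  score = ".stage_score", evaluate = ".stage_evaluate",
                  profile = ".stage_profile")
  .assert(all(stages %in% names(all_stages)),
          paste("unknown stage(s):",
                paste(setdiff(stages, names(all_stages)), collapse = ", ")))
  stages <- names(all_stages)[names(all_stages) %in% stages]
  cfg <- if (is.character(config)) load_config(config) else
    if (is.null(config)) load_config() else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(); timings <- list()
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    outputs[[st]] <- do.call(all_stages[[st]],
                             list(cfg = cfg, out_dir = out_dir, seed = seed))
    timings[[st]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  files <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    tool = "pdl1ps",
    version = as.character(utils::packageVersion("pdl1ps")),
    config = cfg, seed = seed, stages = stages, timings = timings,
    outputs = files,
    digests = as.list(tools::md5sum(file.path(out_dir, files))))
  tmp <- tempfile(tmpdir = out_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the \code{inst/cli/pdl1ps} Rscript wrapper.
#' Subcommands: \code{simulate}, \code{meta}, \code{screen}, \code{rank},
#' \code{score}, \code{evaluate}, \code{profile}, \code{run-all}. Global
#' flags: \code{--config FILE}, \code{--seed INT}, \code{--out-dir DIR},
#' \code{--preset NAME}.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pdl1ps <simulate|meta|screen|rank|score|evaluate|profile|run-all>",
    "[--config FILE] [--seed INT] [--out-dir DIR] [--preset NAME]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  opt <- list(config = NULL, seed = 1L, out_dir = "pipeline_out",
              preset = NULL)
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    key <- gsub("-", "_", key)
    .assert(key %in% names(opt), paste("unknown flag:", rest[i]))
    .assert(i + 1 <= length(rest), paste("flag needs a value:", rest[i]))
    opt[[key]] <- rest[i + 1]
    i <- i + 2
  }
  cfg <- load_config(opt$config)
  if (!is.null(opt$preset)) cfg$preset <- opt$preset
  stages <- if (cmd == "run-all") {
    c("simulate", "meta", "screen", "rank", "score", "evaluate", "profile")
  } else cmd
  ok <- c("simulate", "meta", "screen", "rank", "score", "evaluate",
          "profile")
  if (!all(stages %in% ok)) { message(usage); return(invisible(1L)) }
  run_pipeline(cfg, stages = stages, out_dir = opt$out_dir,
               seed = as.integer(opt$seed))
  invisible(0L)
}
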