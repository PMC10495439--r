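#' Simulation configuration with study-condition defaults
#'
#' Bundles every knob of the three generators. Defaults emulate the
#' statistical structure the pipeline assumes: a planted modulator whose
#' per-cancer median expression maps linearly to HRD with slope -0.76 and
#' intercept 2.81, trial tables with between-trial heterogeneity, and
#' patient cohorts whose hazards follow a proportional-hazards model with a
#' treatment x biomarker x modulator interaction. Two coefficient presets
#' are shipped: \code{"paper-pattern"} plants the qualitative
#' Predictiveness-High / Predictiveness-Low reversal (within the treated
#' arm the biomarker log-HR is -0.5 when the modulator is low and +0.3 when
#' it is high, i.e. an interaction of d = 0.8), and \code{"null"} zeroes
#' every coefficient.
#'
#' @param seed Integer seed.
#' @param preset \code{"paper-pattern"} (default) or \code{"null"}.
#' @param n_cancers Number of cancer types (default 10).
#' @param trials_per_cancer Trials per cancer per subgroup (default 3).
#' @param per_arm_n Patients per trial arm driving the trial-level SEs
#'   (default 300).
#' @param tau Between-trial SD of the log-HR (default 0.1).
#' @param hrd_range Range of planted per-cancer HRDs (default
#'   \code{c(-0.3, 1.0)}, mirroring the observed spread from glioblastoma
#'   to colorectal).
#' @param modulator_slope,modulator_intercept Planted linear map from the
#'   modulator's per-cancer median to HRD (defaults -0.76 and 2.81).
#' @param median_noise_sd SD of per-cancer noise on the planted medians
#'   (default 0.05).
#' @param within_sd Within-cancer sample SD of expression (default 1).
#' @param samples_per_cancer Samples per cancer in the expression panel
#'   (default 100, the order of a smaller TCGA cohort).
#' @param n_decoy_genes Decoy genes with cancer-permuted medians
#'   (default 30).
#' @param cohort_n Patients in the two-arm cohort (default 1200, i.e.
#'   600 per arm).
#' @param coef Named log-hazard coefficients \code{bT}, \code{bP},
#'   \code{bV}, \code{bPV}, \code{bTP}, \code{bTPV} for the hazard
#'   \eqn{h_0 \exp(bT T + bP P + bV V + bPV PV + bTP TP + bTPV TPV)}.
#' @param response_coef Logistic analogues (plus \code{b0} baseline
#'   log-odds) for the best-response model.
#' @param baseline_hazard Events per month at reference (default 0.06).
#' @param censor_rate Target censoring fraction in [0, 1) (default 0.25).
#' @param frailty_sd SD of the shared log-normal frailty linking OS and
#'   PFS (default 0.3).
#' @param pdl1_ihc_link List with \code{scale}, \code{offset} and
#'   \code{noise_sd} tying IHC percent to PD-L1 gene expression through a
#'   logistic link: \code{100 * plogis((expr - median - offset)/scale)}
#'   plus Normal noise, truncated to [0, 100]. The defaults place about
#'   half the cohort at or above the 1-percent cutoff and about a tenth at
#'   or above 50 percent, mirroring the IHC distributions of the NSCLC
#'   trials this emulates.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1,
                       preset = c("paper-pattern", "null"),
                       n_cancers = 10,
                       trials_per_cancer = 3,
                       per_arm_n = 300,
                       tau = 0.1,
                       hrd_range = c(-0.3, 1.0),
                       modulator_slope = -0.76,
                       modulator_intercept = 2.81,
                       median_noise_sd = 0.05,
                       within_sd = 1,
                       samples_per_cancer = 100,
                       n_decoy_genes = 30,
                       cohort_n = 1200,
                       coef = NULL,
                       response_coef = NULL,
                       baseline_hazard = 0.06,
                       censor_rate = 0.25,
                       frailty_sd = 0.3,
                       pdl1_ihc_link = list(scale = 0.28, offset = 1.29,
                                            noise_sd = 5)) {
  preset <- match.arg(preset)
  if (is.null(coef)) {
    coef <- if (preset == "paper-pattern") {
      c(bT = -0.2, bP = 0, bV = 0, bPV = 0, bTP = -0.5, bTPV = 0.8)
    } else c(bT = 0, bP = 0, bV = 0, bPV = 0, bTP = 0, bTPV = 0)
  }
  if (is.null(response_coef)) {
    response_coef <- if (preset == "paper-pattern") {
      c(b0 = -2, bT = 0.3, bP = 0, bV = 0, bPV = 0, bTP = 1.2, bTPV = -2)
    } else c(b0 = -2, bT = 0, bP = 0, bV = 0, bPV = 0, bTP = 0, bTPV = 0)
  }
  need <- c("bT", "bP", "bV", "bPV", "bTP", "bTPV")
  .assert(all(need %in% names(coef)), "coef must name bT,bP,bV,bPV,bTP,bTPV")
  .assert(all(c("b0", need) %in% names(response_coef)),
          "response_coef must name b0,bT,bP,bV,bPV,bTP,bTPV")
  .assert(n_cancers >= 1 && trials_per_cancer >= 1 && per_arm_n >= 1 &&
            cohort_n >= 1 && samples_per_cancer >= 1,
          "all counts must be >= 1")
  .assert(tau >= 0 && censor_rate >= 0 && censor_rate < 1,
          "tau must be >= 0 and censor_rate in [0, 1)")
  structure(list(
    seed = as.integer(seed), preset = preset, n_cancers = n_cancers,
    trials_per_cancer = trials_per_cancer, per_arm_n = per_arm_n, tau = tau,
    hrd_range = hrd_range, modulator_slope = modulator_slope,
    modulator_intercept = modulator_intercept,
    median_noise_sd = median_noise_sd, within_sd = within_sd,
    samples_per_cancer = samples_per_cancer,
    n_decoy_genes = n_decoy_genes, cohort_n = cohort_n,
    coef = coef[need], response_coef = response_coef[c("b0", need)],
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    frailty_sd = frailty_sd, pdl1_ihc_link = pdl1_ihc_link),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config [%s preset], seed %d\n", x$preset, x$seed))
  cat(sprintf("  %d cancers x %d trials/subgroup, tau %.2f, per-arm n %d\n",
              x$n_cancers, x$trials_per_cancer, x$tau, x$per_arm_n))
  cat(sprintf("  modulator line: HRD = %.2f x V + %.2f; %d decoys\n",
              x$modulator_slope, x$modulator_intercept, x$n_decoy_genes))
  cat(sprintf("  cohort n %d, hazard coef: %s\n", x$cohort_n,
              paste(names(x$coef), x$coef, sep = "=", collapse = " ")))
  invisible(x)
}

.planted_hrds <- function(config) {
  setNames(seq(config$hrd_range[1], config$hrd_range[2],
               length.out = config$n_cancers),
           sprintf("cancer%02d", seq_len(config$n_cancers)))
}

.manifest <- function(config, ...) {
  structure(c(list(seed = config$seed, preset = config$preset), list(...)),
            class = "truth_manifest")
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat("Truth manifest (", x$preset, " preset, seed ", x$seed, ")\n", sep = "")
  str <- utils::capture.output(utils::str(unclass(x), max.level = 1))
  cat(str, sep = "\n")
  invisible(x)
}

#' Serialize a truth manifest losslessly to JSON
#'
#' Named numeric vectors (per-cancer HRDs, coefficient maps) become JSON
#' objects so that names survive the round trip.
#'
#' @param truth A \code{"truth_manifest"} (or a plain list of them).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  enc <- rapply(list(unclass(truth)), function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  }, how = "replace")[[1]]
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a trial-level subgroup hazard-ratio table
#'
#' For each cancer type, true subgroup hazard ratios are placed
#' symmetrically about 1 so that \eqn{HR_{neg} - HR_{pos}} equals that
#' cancer's planted HRD. Each trial adds Normal(0, tau) between-trial
#' heterogeneity on the log scale plus finite-sample noise with the SE
#' implied by the per-arm event count, and both subgroups are emitted as
#' one record per trial.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{trials} (the trial table data frame) and
#'   \code{truth} (a \code{"truth_manifest"} with the planted per-cancer
#'   HRDs).
#' @export
simulate_trial_table <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  hrds <- .planted_hrds(config)
  event_frac <- 0.8
  se_trial <- 2 / sqrt(2 * config$per_arm_n * event_frac)
  rows <- list()
  for (cn in names(hrds)) {
    hr_pos <- 1 - hrds[[cn]] / 2
    hr_neg <- 1 + hrds[[cn]] / 2
    .assert(hr_pos > 0 && hr_neg > 0,
            "planted HRD out of range: subgroup HR would be non-positive")
    for (ep in c("OS", "PFS")) {
      for (tr in seq_len(config$trials_per_cancer)) {
        theta <- c(BM_POS = log(hr_pos), BM_NEG = log(hr_neg)) +
          rnorm(2, 0, config$tau)
        for (sg in c("BM_POS", "BM_NEG")) {
          y <- rnorm(1, theta[[sg]], se_trial)
          rows[[length(rows) + 1L]] <- data.frame(
            trial_id = sprintf("%s_trial%02d", cn, tr), cancer = cn,
            endpoint = ep, subgroup = sg, hr = exp(y),
            ci_low = exp(y - Z975 * se_trial),
            ci_high = exp(y + Z975 * se_trial),
            n = 2L * config$per_arm_n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials,
       truth = .manifest(config, hrd = hrds, tau = config$tau,
                         se_trial = se_trial))
}

#' Simulate a per-cancer expression panel with a planted modulator
#'
#' The planted modulator's per-cancer median is the inversion of the
#' planted predictiveness line, \eqn{(HRD_c - \beta)/\alpha}, plus
#' Normal(0, median_noise_sd) noise. Decoy genes receive cancer-permuted
#' copies of the planted medians (so their marginal distribution matches
#' but the HRD gradient is destroyed). Sample values are the cancer median
#' plus Normal(0, within_sd) noise.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{panel} (an \code{"expression_panel"}) and
#'   \code{truth} (planted gene id, per-cancer HRDs and true medians).
#' @export
simulate_expression_panel <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed + 1L)
  hrds <- .planted_hrds(config)
  true_med <- (hrds - config$modulator_intercept) / config$modulator_slope
  genes <- c("MOD1", sprintf("DECOY%03d", seq_len(config$n_decoy_genes)))
  med_mat <- rbind(true_med + rnorm(length(hrds), 0, config$median_noise_sd))
  for (g in seq_len(config$n_decoy_genes))
    med_mat <- rbind(med_mat, sample(med_mat[1, ]))
  rownames(med_mat) <- genes
  samples <- unlist(lapply(names(hrds), function(cn)
    sprintf("%s_s%03d", cn, seq_len(config$samples_per_cancer))))
  sample_cancer <- setNames(rep(names(hrds),
                                each = config$samples_per_cancer), samples)
  mat <- med_mat[, sample_cancer, drop = FALSE] +
    rnorm(length(genes) * length(samples), 0, config$within_sd)
  colnames(mat) <- samples
  list(panel = expression_panel(mat, sample_cancer),
       truth = .manifest(config, planted_gene = "MOD1", hrd = hrds,
                         true_medians = setNames(as.numeric(med_mat[1, ]),
                                                 names(hrds)),
                         slope = config$modulator_slope,
                         intercept = config$modulator_intercept))
}

# administrative censoring window hitting the target censoring fraction:
# with event time ~ exp(rate) and censor time ~ U(0, Cmax),
# P(censored) = (1 - exp(-rate * Cmax)) / (rate * Cmax), averaged over rates
.censor_window <- function(rates, target) {
  if (target <= 0) return(Inf)
  pc <- function(cmax) mean((1 - exp(-rates * cmax)) / (rates * cmax)) - target
  uniroot(pc, c(1e-6, 1e6))$root
}

#' Simulate a patient-level two-arm cohort with planted interactions
#'
#' Gene expression is Normal per gene (the PD-L1 gene "CD274", the planted
#' modulator "MOD1" and decoys); the 0/1 indicators T (arm), P (biomarker)
#' and V (modulator) dichotomize at the generating medians. Survival times
#' are exponential with rate
#' \eqn{h_0 f_i \exp(bT T + bP P + bV V + bPV PV + bTP TP + bTPV TPV)}
#' where \eqn{f_i} is a shared log-normal frailty making OS and PFS
#' correlate (PFS runs at twice the baseline hazard). Censoring is
#' independent uniform administrative censoring with the window solved
#' numerically to hit \code{censor_rate}. Best response is Bernoulli
#' through the logistic analogue, responders drawn CR/PR and
#' non-responders SD/PD/NE. PD-L1 IHC percent derives from CD274
#' expression through a logistic link plus noise, truncated to [0, 100].
#' Cell fractions are generated with lymphocyte content tied to the
#' biomarker and stromal content (Endothelium + Fibroblasts) tied to the
#' modulator.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{cohort} (an \code{"ici_cohort"}) and
#'   \code{truth} (planted coefficients, medians used for dichotomization,
#'   realized censoring fractions).
#' @export
simulate_cohort <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed + 2L)
  n <- config$cohort_n
  ids <- sprintf("pt%05d", seq_len(n))
  arm <- rep(c("ICI", "CHEMO"), length.out = n)
  Tt <- as.integer(arm == "ICI")
  genes <- c("CD274", "MOD1", sprintf("DECOY%03d",
                                      seq_len(config$n_decoy_genes)))
  expr <- base::matrix(rnorm(length(genes) * n, mean = 2, sd = 1),
                       nrow = length(genes),
                       dimnames = list(genes, ids))
  P <- dichotomize(expr["CD274", ])
  V <- dichotomize(expr["MOD1", ])
  b <- config$coef
  lp <- b["bT"] * Tt + b["bP"] * P + b["bV"] * V + b["bPV"] * P * V +
    b["bTP"] * Tt * P + b["bTPV"] * Tt * P * V
  frailty <- rlnorm(n, 0, config$frailty_sd)
  rate_os <- config$baseline_hazard * frailty * exp(lp)
  rate_pfs <- 2 * config$baseline_hazard * frailty * exp(lp)
  t_os <- rexp(n, rate_os)
  t_pfs <- rexp(n, rate_pfs)
  cmax_os <- .censor_window(rate_os, config$censor_rate)
  cmax_pfs <- .censor_window(rate_pfs, config$censor_rate)
  c_os <- if (is.finite(cmax_os)) runif(n, 0, cmax_os) else rep(Inf, n)
  c_pfs <- if (is.finite(cmax_pfs)) runif(n, 0, cmax_pfs) else rep(Inf, n)
  os_time <- pmin(t_os, c_os)
  pfs_time <- pmin(t_pfs, c_pfs)
  os_event <- as.integer(t_os <= c_os)
  pfs_event <- as.integer(t_pfs <= c_pfs)
  rb <- config$response_coef
  eta <- rb["b0"] + rb["bT"] * Tt + rb["bP"] * P + rb["bV"] * V +
    rb["bPV"] * P * V + rb["bTP"] * Tt * P + rb["bTPV"] * Tt * P * V
  responder <- rbinom(n, 1, stats::plogis(eta))
  response <- ifelse(responder == 1,
                     sample(c("CR", "PR"), n, TRUE, prob = c(0.2, 0.8)),
                     sample(c("SD", "PD", "NE"), n, TRUE,
                            prob = c(0.4, 0.5, 0.1)))
  link <- config$pdl1_ihc_link
  ihc <- 100 * stats::plogis(
    (expr["CD274", ] - median(expr["CD274", ]) - link$offset) / link$scale) +
    rnorm(n, 0, link$noise_sd)
  ihc <- pmin(100, pmax(0, ihc))
  lymph_base <- 0.12 + 0.08 * P + rnorm(n, 0, 0.03)
  stroma_base <- 0.10 + 0.10 * V + rnorm(n, 0, 0.03)
  lymph <- pmin(0.6, pmax(0.01, lymph_base))
  stroma <- pmin(0.6, pmax(0.01, stroma_base))
  cf <- cbind(
    B_cells = lymph * 0.2, CD4_T_cells = lymph * 0.35,
    CD8_T_cells = lymph * 0.30, NK_cells = lymph * 0.15,
    Endothelium = stroma * 0.4, Fibroblasts = stroma * 0.6,
    Macrophages = pmin(0.3, pmax(0.01, 0.08 + rnorm(n, 0, 0.02))))
  cf <- cbind(cf, Other = pmax(0, 1 - rowSums(cf)))
  rownames(cf) <- ids
  clinical <- data.frame(
    patient_id = ids, arm = arm, os_time = os_time, os_event = os_event,
    pfs_time = pfs_time, pfs_event = pfs_event, response = response,
    pdl1_ihc = ihc, tmb = pmax(0, rlnorm(n, log(8), 0.9)),
    tnb = pmax(0, rlnorm(n, log(3), 0.8)), stringsAsFactors = FALSE)
  truth <- .manifest(
    config, planted_gene = "MOD1", coef = b, response_coef = rb,
    pdl1_median = median(expr["CD274", ]), mod_median = median(expr["MOD1", ]),
    realized_censor_os = mean(1 - os_event),
    realized_censor_pfs = mean(1 - pfs_event))
  list(cohort = ici_cohort(clinical, expr, cf), truth = truth)
}

#' End-to-end recovery experiment over many seeds
#'
#' Runs the pipeline's recovery checks once per seed: simulate a cohort
#' with the config's coefficients, rank all genes by their Cox interaction
#' with the biomarker in the treated arm, record the planted modulator's
#' rank; simulate an expression panel, fit the predictiveness-score model
#' on its medians against the planted HRDs, record the slope/intercept
#' error; score and split the cohort with the fitted model and record
#' whether the Predictiveness-High group shows HR(biomarker+ vs -) < 1 and
#' the Predictiveness-Low group HR > 1 within the treated arm.
#'
#' @param config A \code{\link{sim_config}} (its seed is replaced per run).
#' @param n_seeds Number of independent seeds (default 200).
#' @param seeds Optional explicit integer seed vector overriding
#'   \code{n_seeds}.
#' @return Data frame of class \code{"recovery_report"} with one row per
#'   seed: \code{seed}, \code{planted_rank}, \code{top1}, \code{slope},
#'   \code{intercept}, \code{slope_err}, \code{hr_ph}, \code{hr_pl},
#'   \code{pattern} (PH HR < 1 and PL HR > 1).
#' @export
recovery_experiment <- function(config, n_seeds = 200, seeds = NULL) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_seeds) * 1000L
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s %% .Machine$integer.max)
    sim <- simulate_cohort(cfg)
    treated <- subset_cohort(
      sim$cohort,
      sim$cohort$clinical$patient_id[sim$cohort$clinical$arm == "ICI"])
    cand <- setdiff(rownames(sim$cohort$expr), "CD274")
    ranks <- rank_interactions(treated, "CD274", cand, endpoint = "OS")
    planted_rank <- match("MOD1", ranks$gene)
    pan <- simulate_expression_panel(cfg)
    med <- median_profile(pan$panel, "MOD1")[, "MOD1"]
    psm <- fit_ps_model(med, pan$truth$hrd, gene = "MOD1")
    scores <- score_and_split(sim$cohort, psm, reference = "TREATED_ARM")
    strat <- stratify_pdl1(sim$cohort, mode = "RNA2")
    grid <- efficacy_grid(sim$cohort, scores, strat,
                          comparison = "POS_vs_NEG_within_ICI",
                          endpoints = "OS", groups = c("PH", "PL"))
    hr_ph <- grid$hr[grid$group == "PH"]
    hr_pl <- grid$hr[grid$group == "PL"]
    data.frame(seed = cfg$seed, planted_rank = planted_rank,
               top1 = identical(planted_rank, 1L),
               slope = psm$slope, intercept = psm$intercept,
               slope_err = psm$slope - config$modulator_slope,
               hr_ph = hr_ph, hr_pl = hr_pl,
               pattern = !is.na(hr_ph) && !is.na(hr_pl) &&
                 hr_ph < 1 && hr_pl > 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery experiment over %d seeds\n", nrow(x)))
  cat(sprintf("  planted modulator top-1: %.1f%%\n", 100 * mean(x$top1)))
  cat(sprintf("  slope error: mean %.3f (sd %.3f)\n",
              mean(x$slope_err), sd(x$slope_err)))
  cat(sprintf("  PH HR<1 & PL HR>1 pattern: %.1f%%\n",
              100 * mean(x$pattern)))
  invisible(x)
}
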