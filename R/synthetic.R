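# Seeded synthetic-data generators. Each generator emulates the statistical
# structure of one input class (single-cell cohort, bulk survival cohort,
# TCR repertoires, spatial lattice) together with a truth table sufficient to
# score every downstream caller without re-simulation.

#' Simulation configuration
#'
#' Collects every generative assumption behind the synthetic cohorts. Marker
#' expression is modelled on the ln(CPM+1) scale as a two-component mixture:
#' a near-zero background component and a high component whose mean sits above
#' the absolute 2.5 calling threshold, because the calling rules operate on
#' that scale. Binary outcomes follow a logistic model with additive planted
#' log-odds effects for true bias, sex and age; survival is exponential with
#' group-specific rates and independent uniform censoring; repertoires plant
#' CMV-associated clones at status-dependent hit rates; spatial lattices carry
#' tumor/benign zones, CD8 marker spots, disjoint NKG2A/NKG2C sub-regions and
#' a configurable ligand-receptor co-expression enrichment.
#'
#' @param seed Mandatory integer seed; every generator is fully reproducible
#'   given the seed.
#' @param n_patients Number of patients in the single-cell cohort.
#' @param cells_per_patient Cells simulated per patient.
#' @param cell_type_mix Named proportions over `CD8T`, `NK`, `other`
#'   (must include `CD8T` and `NK`, and sum to 1).
#' @param p_bias_A Probability a patient is truly NKG2A-biased.
#' @param expr_model List: `high_mean`, `high_sd`, `bg_mean`, `bg_sd` of the
#'   marker mixture on the ln(CPM+1) scale; `marker_pos_frac`, the fraction of
#'   NK/CD8 T cells carrying a marker; `within_bias_prop`, the proportion of
#'   marker-positive cells matching the patient's true bias; `n_bg_genes`.
#' @param outcome_lnOR Planted log-odds effect of a true NKG2A bias on the
#'   binary outcome.
#' @param covariate_lnORs Named vector of planted `female` and `age` log-odds.
#' @param outcome_intercept Logistic intercept; `NULL` centres the marginal
#'   outcome rate near 0.5 given the planted effects.
#' @param n_timepoints Acute timepoints per patient in the single-cell cohort.
#' @param survival List: exponential rates `rate_A`, `rate_C` (> 0, per day),
#'   `censor_max` (upper bound of the uniform censoring time; may be `Inf`),
#'   `n_per_arm`, `n_bg_genes`.
#' @param cmv List: `n_patients`, `prevalence`, `list_size` (>= 1),
#'   `hit_rate_pos`, `hit_rate_neg` (per-list-entry detection probabilities by
#'   serostatus), `rep_size_range` (distinct clones per sample),
#'   `samples_per_patient`.
#' @param spatial List: `n_row`, `n_col` (>= 4), `lattice`, `cd8_frac`,
#'   `n_pairs`, `n_planted`, `enrichment` (co-expression factor for planted
#'   pairs in NKG2A+ CD8 spots; 1 = null), `base_meanlog`, `base_sdlog`.
#' @return Validated configuration list of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       n_patients = 120,
                       cells_per_patient = 60,
                       cell_type_mix = c(CD8T = 0.4, NK = 0.35, other = 0.25),
                       p_bias_A = 0.5,
                       expr_model = list(),
                       outcome_lnOR = 1.0,
                       covariate_lnORs = c(female = 0.3, age = 0.01),
                       outcome_intercept = NULL,
                       n_timepoints = 2,
                       survival = list(),
                       cmv = list(),
                       spatial = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  expr_model <- utils::modifyList(
    list(high_mean = 4.0, high_sd = 0.5, bg_mean = 0.1, bg_sd = 0.1,
         marker_pos_frac = 0.35, within_bias_prop = 0.85, n_bg_genes = 20),
    expr_model)
  survival <- utils::modifyList(
    list(rate_A = 1 / 400, rate_C = 1 / 200, censor_max = 1500,
         n_per_arm = 100, n_bg_genes = 20),
    survival)
  cmv <- utils::modifyList(
    list(n_patients = 120, prevalence = 0.5, list_size = 164,
         hit_rate_pos = 0.05, hit_rate_neg = 0.001,
         rep_size_range = c(500L, 2000L), samples_per_patient = 1),
    cmv)
  spatial <- utils::modifyList(
    list(n_row = 20, n_col = 20, lattice = "square", cd8_frac = 0.5,
         n_pairs = 8, n_planted = 1, enrichment = 4,
         base_meanlog = 0, base_sdlog = 0.4),
    spatial)

  if (!all(c("CD8T", "NK") %in% names(cell_type_mix))) {
    stop("cell_type_mix must include CD8T and NK")
  }
  if (any(cell_type_mix < 0) || abs(sum(cell_type_mix) - 1) > 1e-8) {
    stop("cell_type_mix proportions must be non-negative and sum to 1")
  }
  probs <- c(p_bias_A, cmv$prevalence, cmv$hit_rate_pos, cmv$hit_rate_neg,
             expr_model$marker_pos_frac, expr_model$within_bias_prop,
             spatial$cd8_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (survival$rate_A <= 0 || survival$rate_C <= 0) {
    stop("survival rates must be positive")
  }
  if (cmv$list_size < 1) stop("CMV-associated clone list size must be at least 1")
  if (spatial$n_row < 4 || spatial$n_col < 4) stop("lattice must be at least 4 x 4")

  structure(list(seed = seed, n_patients = n_patients,
                 cells_per_patient = cells_per_patient,
                 cell_type_mix = cell_type_mix, p_bias_A = p_bias_A,
                 expr_model = expr_model, outcome_lnOR = outcome_lnOR,
                 covariate_lnORs = covariate_lnORs,
                 outcome_intercept = outcome_intercept,
                 n_timepoints = n_timepoints, survival = survival,
                 cmv = cmv, spatial = spatial),
            class = "SimConfig")
}

#' Generate a patient-level cohort with planted outcome effects
#'
#' Draws each patient's true bias, sex and age, then the binary outcome from
#' the logistic model `logit(p) = intercept + lnOR_bias * biasA +
#' lnOR_female * female + lnOR_age * age`. This is the patient layer used by
#' [gen_single_cell_cohort()], exposed directly so coefficient-recovery
#' studies can run at large n without simulating cells.
#'
#' @param config A [sim_config()].
#' @return List with a `ClinicalTable` (`clinical`) and a per-patient truth
#'   table (`truth`: `patient_id`, `true_bias`, `female`, `age`, `survived`).
#' @export
gen_patient_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))
  true_bias <- ifelse(stats::runif(n) < config$p_bias_A, "A", "C")
  female <- stats::rbinom(n, 1, 0.5)
  age <- round(stats::runif(n, 20, 90))
  wos <- sample(0:8, n, replace = TRUE)
  b <- config$covariate_lnORs
  icpt <- config$outcome_intercept %||%
    -(config$outcome_lnOR * config$p_bias_A + b[["female"]] * 0.5 +
        b[["age"]] * 55)
  lp <- icpt + config$outcome_lnOR * (true_bias == "A") +
    b[["female"]] * female + b[["age"]] * age
  survived <- stats::rbinom(n, 1, stats::plogis(lp))
  clinical <- as_clinical(data.frame(
    patient_id = pid, sex = ifelse(female == 1, "female", "male"),
    age = age, wos = wos, survived = survived, stringsAsFactors = FALSE))
  truth <- data.frame(patient_id = pid, true_bias = true_bias,
                      female = female, age = age, survived = survived,
                      stringsAsFactors = FALSE)
  list(clinical = clinical, truth = truth)
}

#' Generate a single-cell cohort on the ln(CPM+1) scale
#'
#' Builds on [gen_patient_cohort()]: every patient contributes
#' `cells_per_patient` cells with types drawn from `cell_type_mix` and acute
#' timepoints assigned uniformly. NK and CD8 T cells are marker-positive with
#' probability `marker_pos_frac`; among positives, the NKG2A/NKG2C identity
#' follows the patient's true bias with probability `within_bias_prop`.
#' NKG2A+ cells draw CD94 (KLRD1) and NKG2A (KLRC1) from the high mixture
#' component and NKG2C (KLRC2) from background; NKG2C+ cells symmetrically.
#'
#' @param config A [sim_config()].
#' @return List: `expression` (`ExpressionMatrix`, ln_cpm1), `annotations`
#'   (cell_id, patient_id, cell_type, timepoint, is_acute), `clinical`, and
#'   `truth` (list with `cells` and `patients` tables).
#' @export
gen_single_cell_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  pc <- gen_patient_cohort(config)  # seeds the stream
  em <- config$expr_model
  n_cells <- config$n_patients * config$cells_per_patient
  patient <- rep(pc$truth$patient_id, each = config$cells_per_patient)
  bias <- rep(pc$truth$true_bias, each = config$cells_per_patient)
  cell_type <- sample(names(config$cell_type_mix), n_cells, replace = TRUE,
                      prob = config$cell_type_mix)
  tp <- sample(seq_len(config$n_timepoints), n_cells, replace = TRUE)
  marker_pos <- cell_type %in% c("CD8T", "NK") &
    stats::runif(n_cells) < em$marker_pos_frac
  p_A <- ifelse(bias == "A", em$within_bias_prop, 1 - em$within_bias_prop)
  true_label <- ifelse(marker_pos,
                       ifelse(stats::runif(n_cells) < p_A, "A", "C"),
                       "none")
  genes <- c("KLRD1", "KLRC1", "KLRC2",
             sprintf("BG%02d", seq_len(em$n_bg_genes)))
  vals <- matrix(pmax(0, stats::rnorm(n_cells * length(genes),
                                      em$bg_mean, em$bg_sd)),
                 nrow = n_cells, dimnames = list(
                   sprintf("C%06d", seq_len(n_cells)), genes))
  hi <- function(k) pmax(0, stats::rnorm(k, em$high_mean, em$high_sd))
  iA <- true_label == "A"
  iC <- true_label == "C"
  vals[iA, "KLRD1"] <- hi(sum(iA)); vals[iA, "KLRC1"] <- hi(sum(iA))
  vals[iC, "KLRD1"] <- hi(sum(iC)); vals[iC, "KLRC2"] <- hi(sum(iC))
  annotations <- data.frame(
    cell_id = rownames(vals), patient_id = patient, cell_type = cell_type,
    timepoint = sprintf("T%d", tp), is_acute = TRUE,
    stringsAsFactors = FALSE)
  list(expression = expression_matrix(vals, "ln_cpm1"),
       annotations = annotations, clinical = pc$clinical,
       truth = list(cells = data.frame(cell_id = rownames(vals),
                                       true_label = true_label,
                                       stringsAsFactors = FALSE),
                    patients = pc$truth))
}

#' Generate a bulk cohort with exponential survival
#'
#' Two arms of `n_per_arm` samples with true bias group A or C. Marker
#' expression is drawn so the log2 product-ratio score
#' log2(CD94*NKG2A / CD94*NKG2C) separates the groups; survival times are
#' exponential with the group rate and censored by an independent
#' Uniform(0, `censor_max`) time (exponential medians are ln(2)/rate, giving a
#' closed-form oracle).
#'
#' @param config A [sim_config()].
#' @return List: `expression` (samples x genes, ln_cpm1), `clinical`
#'   (with `survival_time`/`event`), `truth` (sample_id, group, latent time).
#' @export
gen_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  sv <- config$survival
  set.seed(config$seed)
  n <- sv$n_per_arm
  group <- rep(c("A", "C"), each = n)
  ids <- sprintf("S%04d", seq_along(group))
  genes <- c("KLRD1", "KLRC1", "KLRC2",
             sprintf("BG%02d", seq_len(sv$n_bg_genes)))
  vals <- matrix(pmax(0, stats::rnorm(length(ids) * length(genes), 1, 0.3)),
                 nrow = length(ids), dimnames = list(ids, genes))
  vals[, "KLRD1"] <- pmax(0, stats::rnorm(length(ids), 4, 0.8))
  hiA <- group == "A"
  vals[hiA, "KLRC1"] <- pmax(0, stats::rnorm(sum(hiA), 6, 1))
  vals[!hiA, "KLRC2"] <- pmax(0, stats::rnorm(sum(!hiA), 6, 1))
  rate <- ifelse(group == "A", sv$rate_A, sv$rate_C)
  latent <- stats::rexp(length(ids), rate)
  cens <- if (is.infinite(sv$censor_max)) rep(Inf, length(ids)) else
    stats::runif(length(ids), 0, sv$censor_max)
  time <- pmin(latent, cens)
  event <- as.integer(latent <= cens)
  clinical <- as_clinical(data.frame(
    patient_id = ids,
    sex = ifelse(stats::rbinom(length(ids), 1, 0.5) == 1, "female", "male"),
    age = round(stats::runif(length(ids), 30, 85)),
    survival_time = time, event = event, stringsAsFactors = FALSE))
  list(expression = expression_matrix(vals, "ln_cpm1"), clinical = clinical,
       truth = data.frame(sample_id = ids, group = group,
                          latent_time = latent, stringsAsFactors = FALSE))
}

#' Generate TCR repertoires with a planted CMV-associated clone signal
#'
#' Emits a synthetic CMV-associated clone list (CDR3 length 13) alongside the
#' repertoires. Each sample's hit count is Binomial(list size, hit rate) with
#' the rate set by the patient's true serostatus; background clones (CDR3
#' length 12, hence disjoint from the list by construction) fill the sample
#' to its drawn size.
#'
#' @param config A [sim_config()]. A `hit_rate_pos` below `hit_rate_neg`
#'   triggers a warning (signal inverted), not an error.
#' @param cmv_list Optional CMV-associated clone table (`cdr3_aa`, `v_gene`,
#'   `j_gene`) shared with other cohorts, mirroring the real workflow where
#'   the list is a fixed external input; by default a synthetic list of
#'   `list_size` triples is drawn from the seed.
#' @return List: `repertoire` (`RepertoireTable`), `cmv_list` (the planted
#'   CMV-associated triples), `clinical` (with `cmv_positive` truth).
#' @export
gen_repertoires <- function(config, cmv_list = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  cm <- config$cmv
  set.seed(config$seed)
  if (cm$hit_rate_pos < cm$hit_rate_neg) {
    warning("planted CMV signal inverted: hit_rate_pos < hit_rate_neg")
  }
  v_pool <- sprintf("TRBV%02d", 1:30)
  j_pool <- sprintf("TRBJ%02d", 1:14)
  if (is.null(cmv_list)) {
    cmv_list <- unique(data.frame(
      cdr3_aa = random_cdr3(cm$list_size, 13L),
      v_gene = sample(v_pool, cm$list_size, replace = TRUE),
      j_gene = sample(j_pool, cm$list_size, replace = TRUE),
      stringsAsFactors = FALSE))
    while (nrow(cmv_list) < cm$list_size) {  # top up rare collisions
      extra <- data.frame(cdr3_aa = random_cdr3(cm$list_size - nrow(cmv_list), 13L),
                          v_gene = sample(v_pool, cm$list_size - nrow(cmv_list), TRUE),
                          j_gene = sample(j_pool, cm$list_size - nrow(cmv_list), TRUE),
                          stringsAsFactors = FALSE)
      cmv_list <- unique(rbind(cmv_list, extra))
    }
  } else {
    stopifnot(all(c("cdr3_aa", "v_gene", "j_gene") %in% names(cmv_list)))
    if (!nrow(cmv_list)) stop("CMV list size must be at least 1")
  }
  n <- cm$n_patients
  pid <- sprintf("R%04d", seq_len(n))
  cmv_pos <- as.integer(stats::runif(n) < cm$prevalence)
  sample_patient <- rep(pid, each = cm$samples_per_patient)
  sample_id <- paste0(sample_patient, "-S",
                      rep(seq_len(cm$samples_per_patient), times = n))
  rate <- ifelse(rep(cmv_pos, each = cm$samples_per_patient) == 1,
                 cm$hit_rate_pos, cm$hit_rate_neg)
  sizes <- sample(cm$rep_size_range[1]:cm$rep_size_range[2],
                  length(sample_id), replace = TRUE)
  n_hits <- stats::rbinom(length(sample_id), nrow(cmv_list), rate)
  hit_idx <- lapply(n_hits, function(h) sample.int(nrow(cmv_list), h))
  n_bg <- pmax(sizes - n_hits, 0L)
  hits <- cmv_list[unlist(hit_idx), , drop = FALSE]
  total_bg <- sum(n_bg)
  bg <- data.frame(cdr3_aa = random_cdr3(total_bg, 12L),
                   v_gene = sample(v_pool, total_bg, replace = TRUE),
                   j_gene = sample(j_pool, total_bg, replace = TRUE),
                   stringsAsFactors = FALSE)
  rep_tab <- data.frame(
    cdr3_aa = c(hits$cdr3_aa, bg$cdr3_aa),
    v_gene = c(hits$v_gene, bg$v_gene),
    j_gene = c(hits$j_gene, bg$j_gene),
    patient_id = c(rep(sample_patient, n_hits), rep(sample_patient, n_bg)),
    sample_id = c(rep(sample_id, n_hits), rep(sample_id, n_bg)),
    stringsAsFactors = FALSE)
  rep_tab <- suppressMessages(as_repertoire(rep_tab))
  clinical <- as_clinical(data.frame(patient_id = pid, cmv_positive = cmv_pos,
                                     stringsAsFactors = FALSE))
  list(repertoire = rep_tab, cmv_list = cmv_list, clinical = clinical)
}

#' Generate a spatial lattice with planted ligand-receptor enrichment
#'
#' Tumor and benign zones are laid out as contiguous column blocks. A random
#' `cd8_frac` of spots carry CD3/CD8 marker expression; CD8 spots in the top
#' half of the lattice express NKG2A (KLRC1), a random half of the bottom CD8
#' spots express NKG2C (KLRC2) — the two regions are disjoint by construction.
#' All spots express the ligand-receptor subunit genes at a lognormal
#' baseline; for the first `n_planted` pairs, both subunits are multiplied by
#' sqrt(`enrichment`) in NKG2A+ CD8 spots, so the per-spot product score is
#' enriched by `enrichment` (1 = null).
#'
#' @param config A [sim_config()].
#' @return List: `spatial` (`SpatialDataset` with pathology zones), `pairs`
#'   (`LRPairTable`; the last pair has a two-subunit receptor complex), and
#'   `truth` (planted pair ids and the spot classes).
#' @export
gen_spatial <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  sp <- config$spatial
  set.seed(config$seed)
  grid <- expand.grid(row = seq_len(sp$n_row), col = seq_len(sp$n_col))
  n_spots <- nrow(grid)
  ids <- sprintf("SP%04d", seq_len(n_spots))
  zone <- ifelse(grid$col <= sp$n_col / 2, "tumor", "benign")
  cd8 <- stats::runif(n_spots) < sp$cd8_frac
  nkg2a_spot <- cd8 & grid$row <= sp$n_row / 2
  nkg2c_spot <- cd8 & grid$row > sp$n_row / 2 & stats::runif(n_spots) < 0.5

  k <- sp$n_pairs
  lig <- sprintf("LIG%02d", seq_len(k))
  rec <- sprintf("REC%02d", seq_len(k))
  rec_genes <- as.list(rec)
  rec_genes[[k]] <- paste0(rec[k], c("A", "B"))  # one receptor complex
  pair_genes <- c(lig, unlist(rec_genes))
  markers <- c("CD3D", "CD3E", "CD3G", "CD8A", "CD8B",
               "KLRD1", "KLRC1", "KLRC2")
  genes <- c(markers, pair_genes)
  vals <- matrix(0, n_spots, length(genes), dimnames = list(ids, genes))
  vals[, pair_genes] <- stats::rlnorm(n_spots * length(pair_genes),
                                      sp$base_meanlog, sp$base_sdlog)
  pos_expr <- function(k) stats::rlnorm(k, 0.2, 0.3)
  for (g in c("CD3D", "CD3E", "CD3G", "CD8A", "CD8B", "KLRD1")) {
    vals[cd8, g] <- pos_expr(sum(cd8))
  }
  vals[nkg2a_spot, "KLRC1"] <- pos_expr(sum(nkg2a_spot))
  vals[nkg2c_spot, "KLRC2"] <- pos_expr(sum(nkg2c_spot))

  planted <- seq_len(sp$n_planted)
  for (p in planted) {
    pg <- c(lig[p], unlist(rec_genes[[p]]))
    vals[nkg2a_spot, pg] <- vals[nkg2a_spot, pg] * sqrt(sp$enrichment)
  }

  pairs <- as_lr_pairs(data.frame(
    pair_id = sprintf("LR%02d", seq_len(k)), ligand = lig,
    receptor = vapply(rec_genes, paste, character(1), collapse = "+"),
    stringsAsFactors = FALSE))
  coords <- data.frame(spot_id = ids, row = grid$row, col = grid$col,
                       stringsAsFactors = FALSE)
  sd <- spatial_dataset(coords, expression_matrix(vals, "ln_cpm1"),
                        lattice = sp$lattice,
                        pathology = stats::setNames(zone, ids))
  list(spatial = sd, pairs = pairs,
       truth = list(planted_pairs = sprintf("LR%02d", planted),
                    cd8_spots = ids[cd8],
                    nkg2a_cd8_spots = ids[nkg2a_spot],
                    nkg2c_spots = ids[nkg2c_spot]))
}
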