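# NKG2A/NKG2C classification rules at cell, bulk-sample, spot and patient
# level, plus marker-rule phenotype annotation of clusters.

new_bias_calls <- function(entity_id, level, label, score, rule) {
  out <- data.frame(entity_id = entity_id, level = level, label = label,
                    score = as.numeric(score), rule = rule,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- unique(c("BiasCalls", class(out)))
  out
}

#' Absolute-threshold single-cell calling rule
#'
#' On ln(CPM+1) values, a cell is NKG2A+ (`A`) when CD94 and NKG2A are both at
#' or above the threshold and NKG2C is not; NKG2C+ (`C`) symmetrically; `dual`
#' when both marker criteria pass (CD94 plus both NKG2A and NKG2C at
#' threshold); `none` otherwise. CD94 co-expression is required because
#' NKG2A/C function as CD94 heterodimers.
#'
#' @param expr `ExpressionMatrix` tagged `ln_cpm1`.
#' @param cd94_gene,a_gene,c_gene Gene identifiers for CD94 (KLRD1),
#'   NKG2A (KLRC1) and NKG2C (KLRC2).
#' @param threshold Inclusive positivity threshold, default 2.5 ln(CPM+1).
#' @return A `BiasCalls` data frame (entity_id, level, label, score, rule);
#'   the score is the limiting expression value behind the call (the minimum
#'   of CD94 and the relevant marker).
#' @export
call_cells_absolute <- function(expr, cd94_gene = "KLRD1", a_gene = "KLRC1",
                                c_gene = "KLRC2", threshold = 2.5) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$normalization != "ln_cpm1") {
    stop("absolute rule requires ln_cpm1 normalization, got '",
         expr$normalization, "'")
  }
  cd94 <- gene_values(expr, cd94_gene)
  a <- gene_values(expr, a_gene)
  c_ <- gene_values(expr, c_gene)
  a_pass <- cd94 >= threshold & a >= threshold
  c_pass <- cd94 >= threshold & c_ >= threshold
  label <- ifelse(a_pass & c_pass, "dual",
                  ifelse(a_pass, "A", ifelse(c_pass, "C", "none")))
  score <- ifelse(label == "A", pmin(cd94, a),
                  ifelse(label == "C", pmin(cd94, c_),
                         pmin(cd94, pmax(a, c_))))
  new_bias_calls(entity_ids(expr), "cell", label, score, "absolute")
}

#' Z-score margin calling rule
#'
#' For per-gene standardized expression, a cell is NKG2A+ when its NKG2A
#' Z-score exceeds its NKG2C Z-score by at least the margin, and NKG2C+
#' symmetrically; a `dual` label is impossible under this rule.
#'
#' @param expr `ExpressionMatrix` tagged `zscore`.
#' @param a_gene,c_gene NKG2A and NKG2C gene identifiers.
#' @param margin Required Z-score difference, default 1 (must be > 0).
#' @return A `BiasCalls` data frame; the score is z(NKG2A) - z(NKG2C).
#' @export
call_cells_zscore <- function(expr, a_gene = "KLRC1", c_gene = "KLRC2",
                              margin = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"), margin > 0)
  if (expr$normalization != "zscore") {
    stop("Z-score rule requires zscore normalization, got '",
         expr$normalization, "'")
  }
  d <- gene_values(expr, a_gene) - gene_values(expr, c_gene)
  label <- ifelse(d >= margin, "A", ifelse(-d >= margin, "C", "none"))
  new_bias_calls(entity_ids(expr), "cell", label, d, "zscore")
}

#' Bulk log2 product-ratio score
#'
#' Per sample, `log2((CD94 * NKG2A + eps) / (CD94 * NKG2C + eps))` on
#' normalized non-negative expression; the symmetric pseudocount guards
#' zero-expression samples and makes NKG2A = NKG2C score exactly 0.
#'
#' @param expr `ExpressionMatrix` (non-negative normalization).
#' @param cd94_gene,a_gene,c_gene Marker gene identifiers.
#' @param pseudocount Symmetric guard, default 0.01.
#' @return Named numeric vector of per-sample scores.
#' @export
score_bulk_samples <- function(expr, cd94_gene = "KLRD1", a_gene = "KLRC1",
                               c_gene = "KLRC2", pseudocount = 0.01) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$normalization == "zscore") {
    stop("bulk product score requires non-negative expression")
  }
  cd94 <- gene_values(expr, cd94_gene)
  a <- gene_values(expr, a_gene)
  c_ <- gene_values(expr, c_gene)
  log2((cd94 * a + pseudocount) / (cd94 * c_ + pseudocount))
}

#' Pentile assignment of bulk samples
#'
#' The top `floor(pentile * N)` scores are called NKG2A+ and the bottom
#' `floor(pentile * N)` NKG2C+; the remainder is `none`. Ties at either
#' boundary are broken by ascending sample identifier so the assignment is
#' deterministic; the two sets are always disjoint and of equal size.
#'
#' @param scores Named per-sample scores (names = sample identifiers), e.g.
#'   from [score_bulk_samples()].
#' @param pentile Fraction assigned to each extreme, in (0, 0.5\]; default 0.20.
#' @return A `BiasCalls` data frame at level `sample`, rule `bulk_pentile`.
#' @export
call_bulk_cohort <- function(scores, pentile = 0.20) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be uniquely named by sample identifier")
  }
  n <- length(scores)
  if (n < 5) stop("at least 5 samples are required for the pentile rule")
  if (pentile <= 0 || pentile > 0.5) stop("pentile must lie in (0, 0.5]")
  k <- floor(pentile * n)
  ids <- names(scores)
  ord_top <- ids[order(-scores, ids)]
  a_set <- ord_top[seq_len(k)]
  rest <- setdiff(ids, a_set)
  ord_bot <- rest[order(scores[rest], rest)]
  c_set <- ord_bot[seq_len(k)]
  label <- ifelse(ids %in% a_set, "A", ifelse(ids %in% c_set, "C", "none"))
  new_bias_calls(ids, "sample", label, unname(scores), "bulk_pentile")
}

#' Sparse spatial spot calling rule
#'
#' Spatial capture is sparse, so any non-zero expression counts as positive:
#' a spot is NKG2A+ when NKG2A > 0 and NKG2C = 0, NKG2C+ symmetrically,
#' `dual` when both are non-zero, `none` when neither is.
#'
#' @param spatial A `SpatialDataset`.
#' @param a_gene,c_gene NKG2A and NKG2C gene identifiers.
#' @return A `BiasCalls` data frame at level `spot`, rule `spatial_sparse`;
#'   the score is the larger of the two marker values.
#' @export
call_spots_sparse <- function(spatial, a_gene = "KLRC1", c_gene = "KLRC2") {
  stopifnot(inherits(spatial, "SpatialDataset"))
  a <- gene_values(spatial$expression, a_gene)
  c_ <- gene_values(spatial$expression, c_gene)
  label <- ifelse(a > 0 & c_ > 0, "dual",
                  ifelse(a > 0, "A", ifelse(c_ > 0, "C", "none")))
  new_bias_calls(entity_ids(spatial$expression), "spot", label,
                 pmax(a, c_), "spatial_sparse")
}

#' Identify CD8 T cell spots and split them by NKG2A expression
#'
#' Sequential gating on the pooled spatial data: a T cell score (mean of the
#' CD3 genes) must be positive, then a CD8 score (mean of CD8A/CD8B) must be
#' positive; qualifying spots are split into NKG2A+ and NKG2A- CD8 classes by
#' non-zero NKG2A expression.
#'
#' @param spatial A `SpatialDataset`.
#' @param cd3_genes,cd8_genes Marker gene sets for the two gates.
#' @param nkg2a_gene NKG2A gene identifier.
#' @return Data frame: `spot_id`, `t_score`, `cd8_score`, `class` in
#'   `{NKG2A_pos_CD8, NKG2A_neg_CD8, non_CD8}`.
#' @export
identify_spatial_cd8 <- function(spatial,
                                 cd3_genes = c("CD3D", "CD3E", "CD3G"),
                                 cd8_genes = c("CD8A", "CD8B"),
                                 nkg2a_gene = "KLRC1") {
  stopifnot(inherits(spatial, "SpatialDataset"))
  t_score <- rowMeans(gene_values(spatial$expression, cd3_genes))
  cd8_score <- rowMeans(gene_values(spatial$expression, cd8_genes))
  a <- gene_values(spatial$expression, nkg2a_gene)
  cls <- ifelse(t_score > 0 & cd8_score > 0,
                ifelse(a > 0, "NKG2A_pos_CD8", "NKG2A_neg_CD8"),
                "non_CD8")
  data.frame(spot_id = entity_ids(spatial$expression), t_score = t_score,
             cd8_score = cd8_score, class = cls, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Patient-level bias assignment from labelled cells
#'
#' Within one cell compartment, a patient (or a patient-timepoint) is
#' NKG2A-biased when the NKG2A+ cell count strictly exceeds `ratio_threshold`
#' times the NKG2C+ count ("more than" is strict, so ties go to C). The NK
#' compartment uses ratio 3 by default — NK cells are inherently NKG2A-rich —
#' and the CD8 T compartment ratio 1. Under `any_acute`, only acute
#' timepoints are counted and the patient is A-biased if A-biased at any of
#' them; under `single`, counts are pooled over all cells. Dual-positive and
#' unlabelled cells are excluded from the counts; patients with no labelled
#' cells in the compartment are excluded and flagged (attribute
#' `indeterminate`, with a logged count).
#'
#' @param calls `BiasCalls` at cell level.
#' @param annotations Cell annotation table (`cell_id`, `patient_id`,
#'   `cell_type`, `timepoint`, `is_acute`).
#' @param compartment `"NK"` or `"CD8T"`.
#' @param ratio_threshold Override for the compartment ratio rule.
#' @param timepoint_rule `"any_acute"` or `"single"`.
#' @return Data frame classed `PatientBias`: `patient_id`, `compartment`,
#'   `label` (`A`/`C`), `n_A`, `n_C`, `timepoint_rule`.
#' @export
assign_patient_bias <- function(calls, annotations,
                                compartment = c("NK", "CD8T"),
                                ratio_threshold = NULL,
                                timepoint_rule = c("any_acute", "single")) {
  compartment <- match.arg(compartment)
  timepoint_rule <- match.arg(timepoint_rule)
  ratio_threshold <- ratio_threshold %||% if (compartment == "NK") 3 else 1
  d <- merge(calls, annotations, by.x = "entity_id", by.y = "cell_id")
  d <- d[d$cell_type == compartment, , drop = FALSE]
  patients_all <- unique(annotations$patient_id)
  d <- d[d$label %in% c("A", "C"), , drop = FALSE]
  if (timepoint_rule == "any_acute") d <- d[d$is_acute, , drop = FALSE]

  call_one <- function(n_A, n_C) if (n_A > ratio_threshold * n_C) "A" else "C"
  res <- lapply(split(d, d$patient_id), function(dp) {
    if (timepoint_rule == "any_acute") {
      per_tp <- vapply(split(dp, dp$timepoint), function(dt) {
        call_one(sum(dt$label == "A"), sum(dt$label == "C"))
      }, character(1))
      label <- if (any(per_tp == "A")) "A" else "C"
    } else {
      label <- call_one(sum(dp$label == "A"), sum(dp$label == "C"))
    }
    data.frame(patient_id = dp$patient_id[1], compartment = compartment,
               label = label, n_A = sum(dp$label == "A"),
               n_C = sum(dp$label == "C"), timepoint_rule = timepoint_rule,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), compartment = character(0),
                      label = character(0), n_A = integer(0), n_C = integer(0),
                      timepoint_rule = character(0), stringsAsFactors = FALSE)
  }
  indeterminate <- setdiff(patients_all, out$patient_id)
  if (length(indeterminate)) {
    message(sprintf(
      "%d patient(s) with no labelled %s cells excluded as indeterminate",
      length(indeterminate), compartment))
  }
  attr(out, "indeterminate") <- indeterminate
  class(out) <- unique(c("PatientBias", class(out)))
  out
}

#' Default marker-rule phenotype table
#'
#' Literature-marker rules for CD8 T cell cluster annotation, in precedence
#' order: proliferating (MKI67) > MAIT (KLRB1) > SLEC-like (B3GAT1/CD57 and
#' IFNG) > memory (IL7R) > effector (GZMB while not SLEC-like).
#'
#' @return Data frame with list columns `high` and `low` and unique
#'   `precedence` ranks (1 = checked first).
#' @export
phenotype_rules <- function() {
  data.frame(
    phenotype = c("proliferating", "MAIT", "SLEC_like", "memory", "effector"),
    high = I(list("MKI67", "KLRB1", c("B3GAT1", "IFNG"), "IL7R", "GZMB")),
    low = I(list(character(0), character(0), character(0), character(0),
                 c("B3GAT1", "IFNG"))),
    precedence = 1:5,
    stringsAsFactors = FALSE)
}

#' Annotate clusters with marker-rule phenotypes
#'
#' Each cluster receives the highest-precedence rule whose required-high genes
#' all exceed the positivity cut and whose required-low genes all stay at or
#' below it. The default cut per gene is its across-cluster mean. Clusters
#' matching no rule are labelled `unassigned`.
#'
#' @param cluster_means Clusters-by-genes matrix of mean expression on a
#'   common scale (row names = cluster identifiers).
#' @param rules Rule table as from [phenotype_rules()]; precedence ranks must
#'   be unique.
#' @param cutoff Optional named per-gene positivity cut overriding the
#'   across-cluster mean.
#' @return Named character vector of phenotypes per cluster.
#' @export
annotate_cluster_phenotypes <- function(cluster_means,
                                        rules = phenotype_rules(),
                                        cutoff = NULL) {
  cluster_means <- as.matrix(cluster_means)
  if (anyDuplicated(rules$precedence)) stop("duplicate precedence ranks")
  rules <- rules[order(rules$precedence), , drop = FALSE]
  used <- unique(unlist(c(rules$high, rules$low)))
  absent <- setdiff(used, colnames(cluster_means))
  if (length(absent)) {
    stop("marker gene(s) absent from cluster means: ",
         paste(absent, collapse = ", "))
  }
  cut <- cutoff %||% colMeans(cluster_means)
  out <- rep("unassigned", nrow(cluster_means))
  names(out) <- rownames(cluster_means)
  for (cl in seq_len(nrow(cluster_means))) {
    for (r in seq_len(nrow(rules))) {
      hi <- rules$high[[r]]
      lo <- rules$low[[r]]
      if (all(cluster_means[cl, hi] > cut[hi]) &&
          (!length(lo) || all(cluster_means[cl, lo] <= cut[lo]))) {
        out[cl] <- rules$phenotype[r]
        break
      }
    }
  }
  out
}
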