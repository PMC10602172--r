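test_that("absolute rule honours the CD94 co-requirement and inclusive threshold", {
  em <- make_em(
    c1 = c(KLRD1 = 3.0, KLRC1 = 2.6, KLRC2 = 0.0),
    c2 = c(KLRD1 = 2.4, KLRC1 = 9.9, KLRC2 = 9.9),
    c3 = c(KLRD1 = 3.0, KLRC1 = 2.5, KLRC2 = 2.5),
    c4 = c(KLRD1 = 3.0, KLRC1 = 0.0, KLRC2 = 2.5))
  calls <- call_cells_absolute(em)
  expect_identical(calls$label, c("A", "none", "dual", "C"))
  expect_error(call_cells_absolute(make_em(c1 = c(KLRD1 = 1, KLRC1 = 1, KLRC2 = 1),
                                           normalization = "zscore")),
               "ln_cpm1")
  expect_error(call_cells_absolute(make_em(c1 = c(KLRD1 = 1, KLRC1 = 1))),
               "absent")
})

test_that("z-score rule requires the full margin and admits no dual label", {
  em <- make_em(
    c1 = c(KLRC1 = 0.6, KLRC2 = -0.5),
    c2 = c(KLRC1 = 2.0, KLRC2 = 2.0),
    c3 = c(KLRC1 = 0.999, KLRC2 = 0.0),
    c4 = c(KLRC1 = -1.2, KLRC2 = 0.1),
    normalization = "zscore")
  calls <- call_cells_zscore(em)
  expect_identical(calls$label, c("A", "none", "none", "C"))
  expect_false(any(calls$label == "dual"))
  expect_error(call_cells_zscore(make_em(c1 = c(KLRC1 = 1, KLRC2 = 0))),
               "zscore")
})

test_that("bulk product-ratio score matches direct arithmetic", {
  em <- make_em(
    s1 = c(KLRD1 = 4, KLRC1 = 8, KLRC2 = 2),
    s2 = c(KLRD1 = 2, KLRC1 = 3, KLRC2 = 3),
    s3 = c(KLRD1 = 1, KLRC1 = 1, KLRC2 = 0))
  s <- score_bulk_samples(em)
  expect_equal(unname(s["s1"]), log2(32.01 / 8.01), tolerance = 1e-12)
  expect_identical(unname(s["s2"]), 0)  # symmetric pseudocount
  expect_equal(unname(s["s3"]), log2(1.01 / 0.01), tolerance = 1e-12)
  expect_equal(unname(s["s3"]), 6.658, tolerance = 1e-3)
})

test_that("pentile assignment sizes and tie-breaks are deterministic", {
  scores <- stats::setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1),
                            sprintf("s%02d", 1:10))
  calls <- call_bulk_cohort(scores)
  expect_equal(sum(calls$label == "A"), 2L)
  expect_equal(sum(calls$label == "C"), 2L)
  expect_equal(sum(calls$label == "none"), 6L)
  expect_setequal(calls$entity_id[calls$label == "A"], c("s01", "s02"))

  five <- call_bulk_cohort(stats::setNames(1:5, paste0("t", 1:5)))
  expect_equal(sum(five$label == "A"), 1L)
  expect_equal(sum(five$label == "C"), 1L)

  tied <- call_bulk_cohort(stats::setNames(rep(1, 10), sprintf("s%02d", 1:10)))
  expect_setequal(tied$entity_id[tied$label == "A"], c("s01", "s02"))
  expect_setequal(tied$entity_id[tied$label == "C"], c("s03", "s04"))

  expect_error(call_bulk_cohort(stats::setNames(1:4, paste0("u", 1:4))),
               "at least 5")
  expect_error(call_bulk_cohort(stats::setNames(1:10, sprintf("s%02d", 1:10)),
                                pentile = 0.6), "0.5")
})

test_that("pentile set sizes hold for every cohort size and tie structure", {
  set.seed(1)
  for (n in 5:30) {
    scores <- stats::setNames(sample(round(stats::rnorm(n), 1)),
                              sprintf("x%03d", seq_len(n)))
    calls <- call_bulk_cohort(scores)
    k <- floor(0.2 * n)
    expect_equal(sum(calls$label == "A"), k)
    expect_equal(sum(calls$label == "C"), k)
    expect_length(intersect(calls$entity_id[calls$label == "A"],
                            calls$entity_id[calls$label == "C"]), 0)
    expect_equal(nrow(calls), n)
  }
})

test_that("sparse spot rule treats any non-zero expression as positive", {
  sp <- gen_spatial(sim_config(61, spatial = list(n_row = 4, n_col = 4)))
  em <- make_em(
    s1 = c(KLRC1 = 0.3, KLRC2 = 0),
    s2 = c(KLRC1 = 0, KLRC2 = 0),
    s3 = c(KLRC1 = 0.2, KLRC2 = 0.1))
  coords <- data.frame(spot_id = c("s1", "s2", "s3"), row = 1L, col = 1:3)
  sd <- spatial_dataset(coords, em, "square")
  calls <- call_spots_sparse(sd)
  expect_identical(calls$label, c("A", "none", "dual"))
  expect_s3_class(call_spots_sparse(sp$spatial), "BiasCalls")
})

test_that("spatial CD8 identification gates sequentially on CD3 then CD8", {
  em <- make_em(
    s1 = c(CD3D = 1, CD3E = 0, CD3G = 0, CD8A = 0.5, CD8B = 0, KLRC1 = 0),
    s2 = c(CD3D = 0, CD3E = 0, CD3G = 0, CD8A = 0, CD8B = 0, KLRC1 = 0),
    s3 = c(CD3D = 1, CD3E = 1, CD3G = 1, CD8A = 0, CD8B = 0, KLRC1 = 1),
    s4 = c(CD3D = 1, CD3E = 0, CD3G = 0, CD8A = 0, CD8B = 0.4, KLRC1 = 0.2))
  coords <- data.frame(spot_id = paste0("s", 1:4), row = 1L, col = 1:4)
  cls <- identify_spatial_cd8(spatial_dataset(coords, em, "square"))
  expect_identical(cls$class,
                   c("NKG2A_neg_CD8", "non_CD8", "non_CD8", "NKG2A_pos_CD8"))
})

test_that("patient ratio rules are strict and compartment-specific", {
  mk <- function(n_A, n_C, type) {
    n <- n_A + n_C
    calls <- new_calls(sprintf("c%03d", seq_len(n)),
                       c(rep("A", n_A), rep("C", n_C)))
    annot <- data.frame(cell_id = calls$entity_id, patient_id = "P1",
                        cell_type = type, timepoint = "T1", is_acute = TRUE)
    assign_patient_bias(calls, annot, type)
  }
  new_calls <- function(ids, labels) {
    data.frame(entity_id = ids, level = "cell", label = labels, score = 1,
               rule = "absolute", stringsAsFactors = FALSE)
  }
  expect_identical(mk(31, 10, "NK")$label, "A")   # 31 > 3 * 10
  expect_identical(mk(30, 10, "NK")$label, "C")   # boundary is strict
  expect_identical(mk(5, 5, "CD8T")$label, "C")   # a tie is not "more"
  expect_identical(mk(6, 5, "CD8T")$label, "A")
})

test_that("any-acute rule flags a patient biased at any acute timepoint", {
  calls <- data.frame(entity_id = sprintf("c%02d", 1:8), level = "cell",
                      label = c(rep("A", 4), rep("C", 4)), score = 1,
                      rule = "absolute", stringsAsFactors = FALSE)
  annot <- data.frame(cell_id = calls$entity_id, patient_id = "P1",
                      cell_type = "CD8T",
                      timepoint = c(rep("T1", 4), rep("T2", 4)),
                      is_acute = c(rep(TRUE, 4), rep(TRUE, 4)))
  any_acute <- assign_patient_bias(calls, annot, "CD8T",
                                   timepoint_rule = "any_acute")
  expect_identical(any_acute$label, "A")  # A-biased at T1
  pooled <- assign_patient_bias(calls, annot, "CD8T", timepoint_rule = "single")
  expect_identical(pooled$label, "C")     # 4 vs 4 pooled is a tie
  # non-acute cells are ignored under any_acute
  annot$is_acute <- c(rep(FALSE, 4), rep(TRUE, 4))
  post <- assign_patient_bias(calls, annot, "CD8T", timepoint_rule = "any_acute")
  expect_identical(post$label, "C")
})

test_that("patients without labelled compartment cells are flagged indeterminate", {
  calls <- data.frame(entity_id = c("c1", "c2"), level = "cell",
                      label = c("A", "dual"), score = 1, rule = "absolute",
                      stringsAsFactors = FALSE)
  annot <- data.frame(cell_id = c("c1", "c2"), patient_id = c("P1", "P2"),
                      cell_type = "NK", timepoint = "T1", is_acute = TRUE)
  expect_message(pb <- assign_patient_bias(calls, annot, "NK"),
                 "indeterminate")
  expect_identical(pb$patient_id, "P1")
  expect_identical(attr(pb, "indeterminate"), "P2")
})

test_that("dual and none cells never enter the ratio counts", {
  calls <- data.frame(entity_id = sprintf("c%d", 1:6), level = "cell",
                      label = c("A", "A", "C", "dual", "dual", "none"),
                      score = 1, rule = "absolute", stringsAsFactors = FALSE)
  annot <- data.frame(cell_id = calls$entity_id, patient_id = "P1",
                      cell_type = "CD8T", timepoint = "T1", is_acute = TRUE)
  pb <- assign_patient_bias(calls, annot, "CD8T")
  expect_equal(pb$n_A, 2)
  expect_equal(pb$n_C, 1)
})

test_that("raising a required gene never flips a positive call negative", {
  set.seed(5)
  for (i in 1:50) {
    v <- stats::setNames(round(stats::runif(3, 0, 5), 2),
                         c("KLRD1", "KLRC1", "KLRC2"))
    em <- make_em(c1 = v)
    lab <- call_cells_absolute(em)$label
    if (lab %in% c("A", "dual")) {
      bumped <- v + c(1, 1, 0)
      lab2 <- call_cells_absolute(make_em(c1 = bumped))$label
      expect_true(lab2 %in% c("A", "dual"))
    }
    sd0 <- spatial_dataset(data.frame(spot_id = "s", row = 1L, col = 1L),
                           make_em(s = v[c("KLRC1", "KLRC2")]), "square")
    lab_sp <- call_spots_sparse(sd0)$label
    if (lab_sp %in% c("A", "dual")) {
      sd1 <- spatial_dataset(data.frame(spot_id = "s", row = 1L, col = 1L),
                             make_em(s = v[c("KLRC1", "KLRC2")] + c(1, 0)),
                             "square")
      expect_true(call_spots_sparse(sd1)$label %in% c("A", "dual"))
    }
  }
})

test_that("labels partition the input and counts reconcile", {
  sc <- gen_single_cell_cohort(sim_config(71, n_patients = 10,
                                          cells_per_patient = 30))
  calls <- call_cells_absolute(sc$expression)
  expect_equal(nrow(calls), nrow(sc$expression$values))
  expect_true(all(calls$label %in% c("A", "C", "dual", "none")))
  expect_equal(sum(table(calls$label)), nrow(calls))
  expect_true(all(is.finite(calls$score)))
})

test_that("per-cell calls recover the planted truth at high sensitivity and specificity", {
  sc <- gen_single_cell_cohort(sim_config(72, n_patients = 30,
                                          cells_per_patient = 60))
  calls <- call_cells_absolute(sc$expression)
  truth <- sc$truth$cells$true_label
  sens_A <- mean(calls$label[truth == "A"] == "A")
  sens_C <- mean(calls$label[truth == "C"] == "C")
  spec <- mean(calls$label[truth == "none"] == "none")
  expect_gte(sens_A, 0.9)
  expect_gte(sens_C, 0.9)
  expect_gte(spec, 0.9)
})

test_that("absolute and z-score rules agree in direction where both call", {
  sc <- gen_single_cell_cohort(sim_config(73, n_patients = 20,
                                          cells_per_patient = 50))
  abs_calls <- call_cells_absolute(sc$expression)
  z_vals <- scale(sc$expression$values)
  attr(z_vals, "scaled:center") <- NULL
  attr(z_vals, "scaled:scale") <- NULL
  z_em <- expression_matrix(z_vals, "zscore")
  z_calls <- call_cells_zscore(z_em)
  both <- abs_calls$label %in% c("A", "C") & z_calls$label %in% c("A", "C")
  expect_gt(sum(both), 0)
  expect_true(all(abs_calls$label[both] == z_calls$label[both]))
})

test_that("cluster phenotype annotation follows marker precedence", {
  genes <- c("MKI67", "KLRB1", "B3GAT1", "IFNG", "IL7R", "GZMB")
  means <- rbind(
    k1 = c(5, 0, 0, 0, 0, 0),       # proliferating
    k2 = c(0, 0, 0, 0, 0, 4),       # effector: GZMB without SLEC markers
    k3 = c(0, 0, 3, 3, 0, 4),       # SLEC-like beats effector
    k4 = c(0, 0, 0, 0, 0, 0),       # background -> unassigned
    k5 = c(0, 4, 0, 0, 0, 0))       # MAIT
  colnames(means) <- genes
  ph <- annotate_cluster_phenotypes(means)
  expect_identical(unname(ph[c("k1", "k2", "k3", "k4", "k5")]),
                   c("proliferating", "effector", "SLEC_like", "unassigned",
                     "MAIT"))
  rules <- phenotype_rules()
  rules$precedence[2] <- 1
  expect_error(annotate_cluster_phenotypes(means, rules), "precedence")
})
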