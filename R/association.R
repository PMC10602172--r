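# Covariate-adjusted log-odds models, survival curves and log-rank tests,
# hypergeometric overlap, rank tests, correlations, and the selection rules
# for differential proteins and confidently expressed genes.

#' Encode clinical covariates into a model design matrix
#'
#' Applies the published covariate encoding: female sex is 1 and male 0; age
#' stays in years; severity is the indicator of WHO Ordinal Scale at or above
#' the cut (default 5); `bias_A` is the indicator of an NKG2A-biased patient
#' label. Sex and WOS columns are only encoded when present in the clinical
#' table. Records with any missing field are dropped (complete-case analysis)
#' and the drop count is logged and stored in attribute `n_dropped`.
#'
#' @param clinical A `ClinicalTable`.
#' @param patient_bias A `PatientBias` table (or any data frame with
#'   `patient_id` and `label` in `{A, C}`).
#' @param outcome Name of the binary outcome column in `clinical`.
#' @param wos_cut Severity cut on the WHO Ordinal Scale, default 5.
#' @param extra_covariates Further clinical columns to carry through as-is
#'   (e.g. `cmv_positive`).
#' @return Data frame classed `DesignMatrix` with `patient_id`, `outcome`,
#'   and the encoded covariates.
#' @export
encode_covariates <- function(clinical, patient_bias, outcome = "survived",
                              wos_cut = 5, extra_covariates = character(0)) {
  if (!outcome %in% names(clinical)) {
    stop(sprintf("outcome column '%s' not found in the clinical table", outcome))
  }
  m <- merge(as.data.frame(clinical),
             as.data.frame(patient_bias)[, c("patient_id", "label")],
             by = "patient_id")
  design <- data.frame(patient_id = m$patient_id, outcome = m[[outcome]],
                       bias_A = as.integer(m$label == "A"),
                       stringsAsFactors = FALSE)
  if ("sex" %in% names(m)) design$female <- as.integer(m$sex == "female")
  if ("age" %in% names(m)) design$age <- as.numeric(m$age)
  if ("wos" %in% names(m)) design$severe <- as.integer(m$wos >= wos_cut)
  for (v in extra_covariates) {
    if (!v %in% names(m)) stop(sprintf("extra covariate '%s' not found", v))
    design[[v]] <- m[[v]]
  }
  complete <- stats::complete.cases(design)
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message(sprintf("dropped %d record(s) with missing fields", n_dropped))
  }
  design <- design[complete, , drop = FALSE]
  if (!nrow(design)) stop("empty design matrix after dropping incomplete records")
  rownames(design) <- NULL
  attr(design, "n_dropped") <- n_dropped
  class(design) <- unique(c("DesignMatrix", class(design)))
  design
}

#' Fit a covariate-adjusted logistic (log-odds) model
#'
#' Maximum-likelihood logistic regression of the binary outcome on all design
#' covariates, with an intercept. Coefficients are ln(odds ratios); Wald
#' standard errors give symmetric 95% confidence intervals (estimate +/- 1.96
#' SE) and two-sided p-values, the quantities a forest plot displays.
#' Collinear covariates and complete separation (any |coefficient| > 20, a
#' diverging estimate) are rejected with explicit errors.
#'
#' @param design A [encode_covariates()] design matrix.
#' @return Data frame classed `LogitFit` with one row per term (including the
#'   intercept): `term`, `estimate`, `se`, `ci_low`, `ci_high`, `p_value`;
#'   attributes `converged` and `n`.
#' @export
fit_logistic <- function(design) {
  covars <- setdiff(names(design), c("patient_id", "outcome"))
  if (!length(covars)) stop("at least one covariate is required")
  if (length(unique(design$outcome)) < 2) stop("outcome is constant")
  X <- cbind(`(Intercept)` = 1, as.matrix(design[covars]))
  if (qr(X)$rank < ncol(X)) stop("collinear covariates in the design matrix")
  dat <- design[c("outcome", covars)]
  fit <- suppressWarnings(stats::glm(outcome ~ ., data = dat,
                                     family = stats::binomial(),
                                     control = stats::glm.control(maxit = 100)))
  beta <- stats::coef(fit)
  separating <- setdiff(names(beta)[abs(beta) > 20], "(Intercept)")
  if (length(separating) || any(abs(beta) > 20)) {
    stop("complete separation detected for covariate(s): ",
         paste(if (length(separating)) separating else names(beta)[abs(beta) > 20],
               collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se),
                    ci_low = unname(beta - 1.96 * se),
                    ci_high = unname(beta + 1.96 * se),
                    p_value = unname(2 * stats::pnorm(-abs(beta / se))),
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- fit$converged
  attr(out, "n") <- nrow(design)
  class(out) <- unique(c("LogitFit", class(out)))
  out
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Data frame classed `SurvivalCurve` with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`; the median survival time (first time the
#'   curve drops to 0.5 or below, `NA` if never) is stored in attribute
#'   `median`. A fully censored input yields the constant curve 1.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative survival time")
  f <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
                    n_censor = f$n.censor, surv = f$surv)
  med <- unname(summary(f)$table["median"])
  attr(out, "median") <- med
  class(out) <- unique(c("SurvivalCurve", class(out)))
  out
}

#' Log-rank test between survival groups
#'
#' Supports the per-cancer-type two-group runs and the pooled pan-cancer
#' comparison alike: any number of groups >= 2, each non-empty, with at least
#' one event overall.
#'
#' @param times,events As in [kaplan_meier()].
#' @param group Group labels, one per subject.
#' @return A `TestResult` with the chi-square statistic and p-value; per-group
#'   sizes in attribute `n`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2 || any(table(group) == 0)) {
    stop("at least two non-empty groups are required")
  }
  if (sum(events) < 1) stop("at least one event is required")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd_$n) - 1
  p <- stats::pchisq(sd_$chisq, df, lower.tail = FALSE)
  new_test_result("log-rank", unname(sd_$chisq), p, as.vector(table(group)))
}

#' Hypergeometric set-overlap tail probabilities
#'
#' For an observed overlap of `k` elements between a set of size `K` and a
#' set of size `n` drawn from a universe of size `N`, returns the probability
#' of overlapping as much or more (`p_over = P(X >= k)`, the upper tail
#' including the observed value) and of overlapping as little or less
#' (`p_under = P(X <= k)`).
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K,n Sizes of the two sets, each at most `N`.
#' @param N Universe size.
#' @return List with elements `p_over` and `p_under`.
#' @export
hypergeometric_overlap <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("counts must be non-negative integers")
  }
  if (K > N || n > N || k > min(K, n)) stop("inconsistent overlap counts")
  list(p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_under = stats::phyper(k, K, N - K, n))
}

#' Two-sided Mann-Whitney U test
#'
#' The default two-sample test of the pipeline. For small pooled sizes
#' (`n_a + n_b <= exact_limit`) the exact two-sided p-value is computed by
#' enumerating all rank assignments (midranks under ties); larger samples use
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact_limit Pooled-size bound for the exact branch, default 12.
#' @return A `TestResult` holding the U statistic of sample `a`; the branch
#'   used is stored in attribute `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 12L) {
  if (!length(a) || !length(b)) stop("empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_limit) {
    idx <- utils::combn(n, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    t_ <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(t_^3 - t_) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  out <- new_test_result("Mann-Whitney U", U, p, c(na, nb))
  attr(out, "method") <- method
  out
}

corr_test <- function(x, y, method) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 3) stop("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  new_test_result(paste0(method, " correlation"), unname(ct$estimate),
                  min(1, ct$p.value), length(x))
}

#' Correlation tests
#'
#' Pearson is the pipeline's default correlation; Spearman is used for
#' rank-based comparisons (e.g. immunogenicity rankings against bias
#' percentages) because it is invariant under monotone transforms.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return A `TestResult` with the correlation coefficient and two-sided p.
#' @export
spearman_corr <- function(x, y) corr_test(x, y, "spearman")

#' @rdname spearman_corr
#' @export
pearson_corr <- function(x, y) corr_test(x, y, "pearson")

#' Select differentially abundant proteins across timepoints
#'
#' Union over timepoints of proteins passing `p < p_cut` with a positive
#' log-fold change; the last table is treated as the late (2-3 month)
#' timepoint and drives the `late_significant` flag.
#'
#' @param timepoint_stats List of data frames with columns `protein`, `p`,
#'   `lfc`, one per timepoint (late timepoint last).
#' @param p_cut Significance cut, default 0.05.
#' @param lfc_cut Fold-change lower bound (exclusive), default 0.
#' @return Data frame with `protein` and logical `late_significant`.
#' @export
select_de_proteins <- function(timepoint_stats, p_cut = 0.05, lfc_cut = 0) {
  if (!is.list(timepoint_stats) || !length(timepoint_stats)) {
    stop("timepoint_stats must be a non-empty list of tables")
  }
  pick <- function(d) {
    need <- c("protein", "p", "lfc")
    if (!all(need %in% names(d))) stop("malformed differential table")
    d$protein[d$p < p_cut & d$lfc > lfc_cut]
  }
  selected <- sort(unique(unlist(lapply(timepoint_stats, pick))))
  late <- pick(timepoint_stats[[length(timepoint_stats)]])
  data.frame(protein = selected, late_significant = selected %in% late,
             stringsAsFactors = FALSE)
}

#' Filter to confidently expressed genes
#'
#' Two published modes: `top_decile` keeps the `floor(top_frac * G)` genes
#' with the highest mean expression (ties broken by ascending gene id), the
#' mode used for infection cohorts; `abs_threshold` keeps genes with mean
#' expression strictly above the threshold, the mode used for the cancer
#' spatial context.
#'
#' @param expr An `ExpressionMatrix`.
#' @param mode `"top_decile"` or `"abs_threshold"`.
#' @param threshold Mean-expression bound for `abs_threshold`, default 0.01.
#' @param top_frac Kept fraction for `top_decile`, default 0.10.
#' @return A `GeneSet` (possibly flagged empty).
#' @export
confident_gene_filter <- function(expr, mode = c("top_decile", "abs_threshold"),
                                  threshold = 0.01, top_frac = 0.10) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  m <- colMeans(expr$values)
  if (mode == "top_decile") {
    k <- floor(top_frac * length(m))
    keep <- names(m)[order(-m, names(m))][seq_len(k)]
  } else {
    keep <- names(m)[m > threshold]
  }
  gs <- gene_set(paste0("confident_", mode), keep, allow_empty = TRUE)
  if (gs$empty) message("confident gene filter returned an empty set")
  gs
}

#' Immunoglobulin (antibody) gene set from a gene universe
#'
#' Gene symbols starting with IGH, IGK or IGL (heavy chain, kappa and lambda
#' light chain immunoglobulins), minus a stop-list of non-antibody symbols
#' that share those prefixes.
#'
#' @param universe Character vector of gene symbols.
#' @param stop_list Non-antibody prefixed symbols to exclude; default
#'   `c("IGHMBP2")`, user-extendable.
#' @return A `GeneSet` named `antibody` (possibly flagged empty).
#' @export
antibody_gene_set <- function(universe, stop_list = c("IGHMBP2")) {
  g <- universe[grepl("^(IGH|IGK|IGL)", universe)]
  g <- setdiff(g, stop_list)
  gs <- gene_set("antibody", g, allow_empty = TRUE)
  if (gs$empty) message("no immunoglobulin genes found in the universe")
  gs
}
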