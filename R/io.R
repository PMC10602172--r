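# Readers, writers and validators for clinical, repertoire, spatial and
# ligand-receptor tables, plus the declarative rule-parameter configuration.

#' Validate a clinical covariate/outcome table
#'
#' Checks the typed contract of the per-patient table: `patient_id` unique and
#' mandatory; `sex` restricted to female/male; `age >= 0`; WHO Ordinal Scale
#' `wos` an integer in \[0, 8\]; `survival_time` and `event` present together;
#' `survived`, `event`, `cmv_positive` and every unrecognized column (treated
#' as a binary comorbidity/symptom flag) strictly 0/1.
#'
#' @param df A data frame.
#' @return The validated table, classed `ClinicalTable`, with the flag column
#'   names stored in attribute `flag_cols`.
#' @export
as_clinical <- function(df) {
  known <- c("patient_id", "sex", "age", "wos", "survived",
             "survival_time", "event", "cmv_positive")
  if (!"patient_id" %in% names(df)) stop("missing mandatory column 'patient_id'")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  if ("sex" %in% names(df)) {
    bad <- setdiff(unique(stats::na.omit(df$sex)), c("female", "male"))
    if (length(bad)) stop("unknown sex level(s): ", paste(bad, collapse = ", "))
  }
  if ("age" %in% names(df) && any(df$age < 0, na.rm = TRUE)) {
    stop("age must be non-negative")
  }
  if ("wos" %in% names(df)) {
    w <- df$wos[!is.na(df$wos)]
    if (length(w) && (any(w != round(w)) || any(w < 0 | w > 8))) {
      stop("wos must be an integer in [0, 8]")
    }
  }
  if (xor("survival_time" %in% names(df), "event" %in% names(df))) {
    stop("survival_time and event must be provided together")
  }
  binary_cols <- intersect(c("survived", "event", "cmv_positive"), names(df))
  flags <- setdiff(names(df), known)
  for (f in c(binary_cols, flags)) {
    v <- df[[f]][!is.na(df[[f]])]
    if (length(v) && !all(v %in% c(0, 1))) {
      stop(sprintf("column '%s' must be binary 0/1", f))
    }
  }
  attr(df, "flag_cols") <- flags
  class(df) <- unique(c("ClinicalTable", class(df)))
  df
}

#' Read a clinical CSV
#'
#' @param path CSV with a header row.
#' @param schema Optional named list mapping canonical roles
#'   (`patient_id`, `sex`, `age`, `wos`, ...) to the column names used in the
#'   file; matched columns are renamed before validation.
#' @return A validated `ClinicalTable`; see [as_clinical()].
#' @export
read_clinical <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (role in names(schema)) {
      hit <- names(df) == schema[[role]]
      if (!any(hit)) stop(sprintf("schema column '%s' not found", schema[[role]]))
      names(df)[hit] <- role
    }
  }
  as_clinical(df)
}

#' Validate a TCR-beta repertoire table
#'
#' Clones are keyed by the (CDR3 amino-acid sequence, V gene, J gene) triple;
#' duplicate clone rows within a sample are collapsed to one (the collapse
#' count is reported via [message()]). CDR3 sequences must use the 20-letter
#' amino-acid alphabet.
#'
#' @param df Data frame with columns `patient_id`, `sample_id`, `cdr3_aa`,
#'   `v_gene`, `j_gene`.
#' @return The collapsed table, classed `RepertoireTable`.
#' @export
as_repertoire <- function(df) {
  need <- c("patient_id", "sample_id", "cdr3_aa", "v_gene", "j_gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing repertoire column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  ok <- grepl(sprintf("^[%s]+$", paste(AA20, collapse = "")), df$cdr3_aa)
  if (!all(ok)) {
    stop("CDR3 contains non-amino-acid characters, e.g. '",
         df$cdr3_aa[which(!ok)[1]], "'")
  }
  n0 <- nrow(df)
  df <- unique(df)
  if (nrow(df) < n0) {
    message(sprintf("collapsed %d duplicate clone row(s)", n0 - nrow(df)))
  }
  rownames(df) <- NULL
  class(df) <- unique(c("RepertoireTable", class(df)))
  df
}

#' Read an AIRR-like repertoire TSV
#'
#' Accepts either the canonical column names (`cdr3_aa`, `v_gene`, `j_gene`,
#' `sample_id`, `patient_id`) or the common AIRR aliases (`junction_aa`,
#' `v_call`, `j_call`, `repertoire_id`, `subject_id`).
#'
#' @param path TSV path.
#' @return A `RepertoireTable`; see [as_repertoire()].
#' @export
read_repertoire <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  aliases <- c(cdr3_aa = "junction_aa", v_gene = "v_call", j_gene = "j_call",
               sample_id = "repertoire_id", patient_id = "subject_id")
  for (canon in names(aliases)) {
    if (!canon %in% names(df) && aliases[[canon]] %in% names(df)) {
      names(df)[names(df) == aliases[[canon]]] <- canon
    }
  }
  as_repertoire(df)
}

#' Write a repertoire table as TSV
#' @param df A `RepertoireTable`.
#' @param path Output path.
#' @export
write_repertoire <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a ligand-receptor pair table
#'
#' CSV with columns `pair_id`, `ligand`, `receptor`; multi-subunit complexes
#' are `+`-joined gene lists (the CellphoneDB-style convention).
#'
#' @param path CSV path.
#' @return Data frame classed `LRPairTable`.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_lr_pairs(df)
}

#' @rdname read_lr_pairs
#' @param df Data frame to validate in place of a file.
#' @export
as_lr_pairs <- function(df) {
  need <- c("pair_id", "ligand", "receptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing pair column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$pair_id)) stop("duplicate pair_id")
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor))) {
    stop("ligand and receptor subunit lists must be non-empty")
  }
  class(df) <- unique(c("LRPairTable", class(df)))
  df
}

# Split a '+'-joined subunit list into gene identifiers.
lr_subunits <- function(x) strsplit(x, "+", fixed = TRUE)

#' Spatial transcriptomics dataset
#'
#' Spots on a declared square (4-neighbour) or hex (6-neighbour, odd-row
#' offset) lattice with integer row/column coordinates, spot-level expression,
#' and optional pathology zone labels.
#'
#' @param coords Data frame with columns `spot_id`, `row`, `col` (integers;
#'   coordinate pairs unique).
#' @param expression An [expression_matrix()] whose entities equal the spot ids.
#' @param lattice `"square"` or `"hex"`.
#' @param pathology Optional named character vector of zone labels per spot.
#' @return An object of class `SpatialDataset`.
#' @export
spatial_dataset <- function(coords, expression, lattice = c("square", "hex"),
                            pathology = NULL) {
  lattice <- match.arg(lattice)
  need <- c("spot_id", "row", "col")
  miss <- setdiff(need, names(coords))
  if (length(miss)) stop("missing coordinate column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(coords$spot_id)) stop("duplicate spot identifiers")
  if (any(coords$row != round(coords$row)) || any(coords$col != round(coords$col))) {
    stop("lattice coordinates must be integers")
  }
  if (anyDuplicated(paste(coords$row, coords$col))) stop("duplicate coordinates")
  if (!setequal(coords$spot_id, entity_ids(expression))) {
    stop("expression entity identifiers must equal the spot identifiers")
  }
  expression$values <- expression$values[as.character(coords$spot_id), , drop = FALSE]
  if (!is.null(pathology)) {
    if (is.null(names(pathology)) || !setequal(names(pathology), coords$spot_id)) {
      stop("pathology labels must be named by spot_id and cover all spots")
    }
    pathology <- pathology[as.character(coords$spot_id)]
  }
  structure(list(coords = coords, expression = expression,
                 lattice = lattice, pathology = pathology),
            class = "SpatialDataset")
}

#' @export
print.SpatialDataset <- function(x, ...) {
  cat(sprintf("SpatialDataset: %d spots on a %s lattice, %d genes%s\n",
              nrow(x$coords), x$lattice, ncol(x$expression$values),
              if (is.null(x$pathology)) "" else ", with pathology zones"))
  invisible(x)
}

#' Read a spatial dataset from disk
#'
#' @param coords_path TSV with columns `spot_id`, `row`, `col`, `lattice`
#'   (constant) and optionally `zone`.
#' @param matrix_path,genes_path,spots_path Expression files as in
#'   [read_expression()] (entities = spots).
#' @param normalization Normalization tag of the expression values.
#' @return A `SpatialDataset`.
#' @export
read_spatial <- function(coords_path, matrix_path, genes_path, spots_path,
                         normalization = "ln_cpm1") {
  coords <- utils::read.delim(coords_path, stringsAsFactors = FALSE)
  lattice <- unique(coords$lattice)
  if (length(lattice) != 1L) stop("lattice type must be declared once")
  expr <- read_expression(matrix_path, genes_path, spots_path, normalization)
  pathology <- NULL
  if ("zone" %in% names(coords)) {
    pathology <- stats::setNames(coords$zone, coords$spot_id)
  }
  spatial_dataset(coords[c("spot_id", "row", "col")], expr, lattice, pathology)
}

#' Write a spatial dataset to a directory
#' @param x A `SpatialDataset`.
#' @param dir Output directory (created if needed).
#' @export
write_spatial <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coords <- x$coords
  coords$lattice <- x$lattice
  if (!is.null(x$pathology)) coords$zone <- unname(x$pathology)
  utils::write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression(x$expression, file.path(dir, "matrix.mtx"),
                   file.path(dir, "genes.tsv"), file.path(dir, "spots.tsv"))
  invisible(x)
}

#' Named gene set
#'
#' @param name Set name.
#' @param genes Character vector of gene identifiers (deduplicated).
#' @param allow_empty Permit an empty set; it is then flagged via the `empty`
#'   element rather than rejected.
#' @return Object of class `GeneSet`.
#' @export
gene_set <- function(name, genes, allow_empty = FALSE) {
  genes <- unique(as.character(genes))
  if (!length(genes) && !allow_empty) stop(sprintf("gene set '%s' is empty", name))
  structure(list(name = name, genes = genes, empty = length(genes) == 0L),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d gene(s)%s\n", x$name, length(x$genes),
              if (x$empty) " [flagged empty]" else ""))
  invisible(x)
}

#' Default rule-parameter configuration
#'
#' All behavioural rule parameters with their published defaults: the absolute
#' single-cell threshold (2.5 ln(CPM+1)), the Z-score margin (1), the bulk
#' pentile (0.20) and pseudocount, the NK and CD8 T patient ratio rules (3 and
#' 1), the WHO Ordinal Scale severity cut (5), the cross-validation fold count
#' (6), and the spatial diffusion/differential parameters.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(threshold = 2.5, zscore_margin = 1, pentile = 0.20,
       bulk_pseudocount = 0.01, nk_ratio = 3, cd8_ratio = 1, wos_cut = 5,
       cv_folds = 6, diffusion_decay = 0.5, diffusion_radius = 2,
       lr_pseudocount = 1e-3)
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file whose keys must all be known configuration keys.
#' @return Named list as in [default_config()], with file values applied.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(base, cfg)
}
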