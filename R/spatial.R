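# Spatial stages: lattice neighbour graphs, positive-spot density diffusion,
# and differential ligand-receptor product scoring between NKG2A+ and NKG2A-
# CD8 spot groups.

#' Build the spot neighbour graph of a lattice
#'
#' Square lattices use the 4-neighbourhood (orthogonal neighbours); hex
#' lattices the 6-neighbourhood in odd-row offset coordinates. Boundary spots
#' simply have fewer neighbours. Adjacency is symmetric with no self-edges.
#'
#' @param spatial A `SpatialDataset`.
#' @return Object of class `NeighborGraph`: a named list `adj` of neighbour
#'   spot-id vectors plus the lattice type.
#' @export
build_spot_graph <- function(spatial) {
  stopifnot(inherits(spatial, "SpatialDataset"))
  coords <- spatial$coords
  key <- paste(coords$row, coords$col)
  if (anyDuplicated(key)) stop("duplicate coordinates")
  index <- stats::setNames(seq_along(key), key)
  ids <- as.character(coords$spot_id)
  offsets_for <- function(row) {
    if (spatial$lattice == "square") {
      list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    } else if (row %% 2 == 0) {  # odd-row offset hex
      list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0), c(-1, -1), c(1, -1))
    } else {
      list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0), c(-1, 1), c(1, 1))
    }
  }
  adj <- vector("list", nrow(coords))
  names(adj) <- ids
  for (i in seq_len(nrow(coords))) {
    offs <- offsets_for(coords$row[i])
    nb_keys <- vapply(offs, function(o) {
      paste(coords$row[i] + o[1], coords$col[i] + o[2])
    }, character(1))
    j <- index[nb_keys]
    adj[[i]] <- ids[j[!is.na(j)]]
  }
  structure(list(adj = adj, lattice = spatial$lattice),
            class = "NeighborGraph")
}

#' Diffuse positive-spot density over the neighbour graph
#'
#' Each positive spot is diffused outwards to delineate its region of
#' occupancy: the density at a spot is `decay^d` where `d` is the
#' shortest-path graph distance to the nearest positive spot
#' (nearest-source semantics, no summation over sources), clipped to 0
#' beyond `radius` steps. Positive spots themselves have density 1; density
#' never increases with distance.
#'
#' @param positive Character vector of positive spot ids (subset of the
#'   graph's spots). An empty set yields an all-zero field with a warning.
#' @param graph A [build_spot_graph()] result.
#' @param decay Geometric decay per step, in (0, 1); default 0.5.
#' @param radius Maximum diffusion distance in steps (>= 0); default 2.
#'   `radius = 0` gives the indicator of the positive set.
#' @return Data frame classed `DensityField`: `spot_id`, `distance` (`NA`
#'   beyond the radius), `density`.
#' @export
diffuse_density <- function(positive, graph, decay = 0.5, radius = 2) {
  stopifnot(inherits(graph, "NeighborGraph"))
  if (decay <= 0 || decay >= 1) stop("decay must lie in (0, 1)")
  if (radius < 0) stop("radius must be non-negative")
  spots <- names(graph$adj)
  positive <- as.character(positive)
  if (length(setdiff(positive, spots))) {
    stop("positive spot(s) not present in the graph")
  }
  d <- stats::setNames(rep(Inf, length(spots)), spots)
  if (!length(positive)) {
    warning("empty positive set: returning an all-zero density field")
  } else {
    d[positive] <- 0
    frontier <- positive
    depth <- 0
    while (length(frontier) && depth < radius) {
      nb <- unique(unlist(graph$adj[frontier], use.names = FALSE))
      new <- nb[!is.finite(d[nb])]
      d[new] <- depth + 1
      frontier <- new
      depth <- depth + 1
    }
  }
  density <- ifelse(is.finite(d) & d <= radius, decay^d, 0)
  out <- data.frame(spot_id = spots,
                    distance = ifelse(is.finite(d), d, NA_real_),
                    density = density, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- unique(c("DensityField", class(out)))
  out
}

#' Per-spot ligand-receptor product scores
#'
#' For each interaction pair, the per-spot score is the product of the
#' ligand and receptor expression in that spot; multi-subunit complexes are
#' aggregated to their limiting subunit (the minimum across subunits, the
#' convention of the source interaction database; `mean` is available as an
#' option). Pairs with any absent subunit gene are skipped and logged.
#'
#' @param spatial A `SpatialDataset`.
#' @param pairs An `LRPairTable`.
#' @param spots Optional subset of spot ids to score (default: all).
#' @param subunit_aggregate `"min"` (default) or `"mean"`.
#' @return Spots-by-pairs numeric matrix of non-negative scores; skipped
#'   pair ids are recorded in attribute `skipped`.
#' @export
score_lr_products <- function(spatial, pairs, spots = NULL,
                              subunit_aggregate = c("min", "mean")) {
  stopifnot(inherits(spatial, "SpatialDataset"))
  subunit_aggregate <- match.arg(subunit_aggregate)
  v <- spatial$expression$values
  if (!is.null(spots)) {
    absent <- setdiff(spots, rownames(v))
    if (length(absent)) stop("unknown spot id(s) in subset")
    v <- v[as.character(spots), , drop = FALSE]
  }
  agg <- function(genes) {
    sub <- v[, genes, drop = FALSE]
    if (subunit_aggregate == "min") {
      apply(sub, 1, min)
    } else {
      rowMeans(sub)
    }
  }
  skipped <- character(0)
  cols <- list()
  for (i in seq_len(nrow(pairs))) {
    lg <- lr_subunits(pairs$ligand[i])[[1]]
    rg <- lr_subunits(pairs$receptor[i])[[1]]
    if (length(setdiff(c(lg, rg), colnames(v)))) {
      skipped <- c(skipped, pairs$pair_id[i])
      next
    }
    cols[[pairs$pair_id[i]]] <- agg(lg) * agg(rg)
  }
  if (length(skipped)) {
    message("skipped pair(s) with absent subunit gene(s): ",
            paste(skipped, collapse = ", "))
  }
  if (!length(cols)) stop("all ligand-receptor pairs were skipped")
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(v)
  attr(out, "skipped") <- skipped
  out
}

#' Differential ligand-receptor interaction between spot groups
#'
#' Per pair, compares the per-spot product scores of the NKG2A+ CD8 group
#' against the NKG2A- CD8 group: a pseudocounted log2 fold change of group
#' means and a two-sided Mann-Whitney p-value, plus the volcano-style
#' effect-size rank (log2 fold change times -log10 p, the quantity a dot
#' size encodes).
#'
#' @param scores Spots-by-pairs matrix from [score_lr_products()].
#' @param group_a,group_b Non-empty, disjoint spot-id vectors (rows of
#'   `scores`), conventionally the NKG2A+ and NKG2A- CD8 spot classes from
#'   [identify_spatial_cd8()].
#' @param pseudocount Guard on the group means, default 1e-3.
#' @return Data frame classed `InteractionTable`: `pair_id`, `log2fc`,
#'   `p_value`, `n_a`, `n_b`, `neg_log10_p`, `rank_product`.
#' @export
differential_lr <- function(scores, group_a, group_b, pseudocount = 1e-3) {
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (!length(group_a) || !length(group_b)) stop("both spot groups must be non-empty")
  absent <- setdiff(c(group_a, group_b), rownames(scores))
  if (length(absent)) stop("spot id(s) absent from the score matrix")
  rows <- lapply(colnames(scores), function(p) {
    sa <- scores[group_a, p]
    sb <- scores[group_b, p]
    mw <- mann_whitney(sa, sb)
    l2fc <- log2((mean(sa) + pseudocount) / (mean(sb) + pseudocount))
    nlp <- -log10(max(mw$p_value, .Machine$double.xmin))
    data.frame(pair_id = p, log2fc = l2fc, p_value = mw$p_value,
               n_a = length(sa), n_b = length(sb), neg_log10_p = nlp,
               rank_product = l2fc * nlp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- unique(c("InteractionTable", class(out)))
  out
}
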