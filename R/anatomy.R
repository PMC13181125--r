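# Retrograde-tracing quantification: region-hierarchy aggregation, input
# fractions, volume-normalized densities, within-group normalization, the
# log2 anterior/posterior bias index, dorsoventral profiles, and injection
# fluorescence density.

#' Load a brain-region ontology
#'
#' Reads a region hierarchy CSV (`region_id, acronym, parent_id, group,
#' volume_mm3`) and validates that it forms a rooted tree. The package
#' ships a small synthetic ontology (about 40 regions with nominal
#' volumes) standing in for a full atlas-derived table; users may supply
#' their own CSV with the same columns.
#'
#' @param path CSV path; default is the bundled synthetic ontology.
#' @return data frame of class `region_ontology`.
#' @export
load_ontology <- function(path = system.file("extdata",
                                             "synthetic_region_ontology.csv",
                                             package = "navcode")) {
  ont <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "acronym", "parent_id", "group", "volume_mm3")
  if (!all(need %in% names(ont))) stop_invalid("ontology lacks required columns")
  roots <- which(is.na(ont$parent_id))
  if (length(roots) != 1) stop_invalid("ontology must have exactly one root")
  # cycle check: every node must reach the root
  idx <- match(ont$parent_id, ont$region_id)
  for (i in seq_len(nrow(ont))) {
    j <- i; steps <- 0
    while (!is.na(ont$parent_id[j])) {
      j <- idx[j]; steps <- steps + 1
      if (is.na(j) || steps > nrow(ont)) stop_invalid("ontology contains a cycle or dangling parent")
    }
  }
  class(ont) <- c("region_ontology", "data.frame")
  ont
}

# Internal: acronyms of all descendants of `acronym` (inclusive).
subtree_acronyms <- function(ontology, acronym) {
  id <- ontology$region_id[ontology$acronym == acronym]
  if (length(id) != 1) return(character(0))
  out <- id
  frontier <- id
  repeat {
    kids <- ontology$region_id[ontology$parent_id %in% frontier]
    kids <- setdiff(kids, out)
    if (length(kids) == 0) break
    out <- c(out, kids); frontier <- kids
  }
  ontology$acronym[match(out, ontology$region_id)]
}

# Internal: for each acronym, its ancestor (inclusive) within `level`, or NA.
ancestor_at_level <- function(ontology, acronyms, level) {
  idx <- match(ontology$parent_id, ontology$region_id)
  vapply(acronyms, function(a) {
    j <- match(a, ontology$acronym)
    if (is.na(j)) return(NA_character_)
    while (!is.na(j)) {
      if (ontology$acronym[j] %in% level) return(ontology$acronym[j])
      j <- idx[j]
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Aggregate labeled cells up the region hierarchy
#'
#' Assigns each labeled cell (or leaf-level count) to its ancestor among
#' the requested level regions and sums counts per region and injection
#' target. Cells whose acronym cannot be resolved, or that have no
#' ancestor at the level, are reported as rejects and excluded from
#' totals.
#'
#' @param cells data frame with columns `acronym` and `target`
#'   (one row per cell), or `region`/`target`/`count` (pre-counted).
#' @param ontology a [load_ontology()] table.
#' @param level character vector of region acronyms forming the
#'   aggregation level (an antichain covering the labeled leaves).
#' @return list with `counts` (data frame `region, target, count`,
#'   complete over level x target) and `rejects` (excluded rows with
#'   counts).
#' @export
aggregate_counts <- function(cells, ontology, level) {
  if ("count" %in% names(cells)) {
    acr <- cells$region %||% cells$acronym
    w <- cells$count
    tg <- cells$target
  } else {
    acr <- cells$acronym
    w <- rep(1L, nrow(cells))
    tg <- cells$target
  }
  anc <- ancestor_at_level(ontology, acr, level)
  bad <- is.na(anc)
  rejects <- if (any(bad)) {
    stats::aggregate(list(count = w[bad]), by = list(acronym = acr[bad]), sum)
  } else data.frame(acronym = character(), count = integer())
  grid <- expand.grid(region = level, target = sort(unique(tg)),
                      stringsAsFactors = FALSE)
  kept <- !bad & w > 0
  agg <- if (any(kept)) {
    stats::aggregate(list(count = w[kept]),
                     by = list(region = anc[kept], target = tg[kept]), sum)
  } else data.frame(region = character(), target = character(),
                    count = integer())
  counts <- merge(grid, agg, all.x = TRUE)
  counts$count[is.na(counts$count)] <- if (is.integer(w)) 0L else 0
  counts <- counts[order(counts$target, match(counts$region, level)), ]
  rownames(counts) <- NULL
  list(counts = counts, rejects = rejects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Input fractions per injection target
#'
#' Fraction of labeled neurons in each region relative to the total input
#' population of that target; sums to 1 per target.
#'
#' @param counts data frame `region, target, count`.
#' @return the same frame with a `fraction` column.
#' @export
input_fractions <- function(counts) {
  totals <- tapply(counts$count, counts$target, sum)
  if (any(totals == 0)) stop_invalid("zero total count for a target")
  counts$fraction <- as.numeric(counts$count / totals[counts$target])
  counts
}

#' Volume-normalized cell density
#'
#' Cells per cubic millimeter, with each aggregated region's volume taken
#' as the sum of its leaf-region volumes. Regions without any leaf volume
#' are flagged with `NA` density.
#'
#' @param counts data frame `region, target, count`.
#' @param ontology a [load_ontology()] table.
#' @return the frame with `volume_mm3` and `density_per_mm3` columns.
#' @export
volume_density <- function(counts, ontology) {
  has_child <- ontology$region_id %in% ontology$parent_id
  vol_of <- function(acr) {
    subs <- subtree_acronyms(ontology, acr)
    leaves <- subs[!has_child[match(subs, ontology$acronym)]]
    v <- ontology$volume_mm3[match(leaves, ontology$acronym)]
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }
  counts$volume_mm3 <- vapply(unique(counts$region), vol_of,
                              numeric(1))[match(counts$region,
                                                unique(counts$region))]
  counts$density_per_mm3 <- counts$count / counts$volume_mm3
  counts
}

#' Within-group input fractions
#'
#' Normalizes counts of a group's subregions (e.g. all VIS areas) by the
#' group total for each target; sums to 1 per target within the group.
#' Targets without labeled cells in the group get `NA`.
#'
#' @param counts data frame `region, target, count` at subregion level.
#' @param ontology a [load_ontology()] table.
#' @param group group label from the ontology `group` column.
#' @return subset frame with a `group_fraction` column.
#' @export
group_fractions <- function(counts, ontology, group = "VIS") {
  grp <- ontology$acronym[ontology$group == group]
  sub <- counts[counts$region %in% grp, , drop = FALSE]
  if (nrow(sub) == 0) stop_invalid("no counts in group '%s'", group)
  totals <- tapply(sub$count, sub$target, sum)
  sub$group_fraction <- as.numeric(sub$count / totals[sub$target])
  sub$group_fraction[totals[sub$target] == 0] <- NA_real_
  rownames(sub) <- NULL
  sub
}

#' Anterior/posterior input bias index
#'
#' `log2(f_posterior / f_anterior)` of a region's fractional input to the
#' posterior versus anterior injection target. Positive values indicate a
#' posterior bias; the index negates exactly under target swap.
#'
#' @param f_posterior,f_anterior input fractions.
#' @return log2 ratio (`NA` where both fractions are zero).
#' @export
bias_index <- function(f_posterior, f_anterior) {
  out <- log2(f_posterior / f_anterior)
  out[f_posterior == 0 & f_anterior == 0] <- NA_real_
  out
}

#' Per-region bias-index table
#'
#' Computes input fractions per target and the log2 posterior/anterior
#' bias index per region. When any region x target count is zero, a
#' pseudocount of 1 cell is added to every region x target cell before
#' fractions are computed, keeping the log ratio finite; raw counts are
#' always reported alongside.
#'
#' @param counts data frame `region, target, count` with targets
#'   `anterior` and `posterior`.
#' @return data frame `region, count_anterior, count_posterior,
#'   f_anterior, f_posterior, bias_index`.
#' @export
bias_index_table <- function(counts) {
  stopifnot(all(c("anterior", "posterior") %in% counts$target))
  regions <- unique(counts$region)
  ca <- counts$count[match(paste(regions, "anterior"),
                           paste(counts$region, counts$target))]
  cp <- counts$count[match(paste(regions, "posterior"),
                           paste(counts$region, counts$target))]
  ca[is.na(ca)] <- 0; cp[is.na(cp)] <- 0
  pa <- ca; pp <- cp
  if (any(c(ca, cp) == 0)) { pa <- ca + 1; pp <- cp + 1 }
  fa <- pa / sum(pa); fp <- pp / sum(pp)
  data.frame(region = regions, count_anterior = ca, count_posterior = cp,
             f_anterior = fa, f_posterior = fp,
             bias_index = bias_index(fp, fa))
}

#' Dorsoventral profile of labeled cells
#'
#' Empirical CDFs of the DV coordinate per injection target within a
#' region (subtree), compared by a two-sample Kolmogorov-Smirnov test.
#' Cells with missing coordinates are excluded and counted.
#'
#' @param cells data frame `acronym, target, dv_mm` (one row per cell).
#' @param region region acronym whose subtree to analyze; `NULL` uses all
#'   cells.
#' @param ontology required when `region` is given.
#' @return list with per-target `ecdf` functions, `ks` (`D`, `p`),
#'   per-target `n`, and `n_missing`.
#' @export
dv_profile <- function(cells, region = NULL, ontology = NULL) {
  if (!is.null(region)) {
    if (is.null(ontology)) stop_invalid("ontology required for region subsetting")
    cells <- cells[cells$acronym %in% subtree_acronyms(ontology, region), ]
  }
  n_missing <- sum(is.na(cells$dv_mm))
  cells <- cells[!is.na(cells$dv_mm), ]
  targets <- sort(unique(cells$target))
  if (length(targets) != 2) stop_invalid("need exactly 2 targets")
  xs <- split(cells$dv_mm, cells$target)
  if (any(vapply(xs, length, 1L) < 2))
    stop_invalid("need at least 2 cells per target")
  ks <- ks_two_sample(xs[[1]], xs[[2]])
  list(ecdf = lapply(xs, stats::ecdf), ks = ks,
       n = vapply(xs, length, 1L), n_missing = n_missing)
}

#' Injection-site fluorescence density
#'
#' Standardized preprocessing of an injection-site image: Gaussian
#' smoothing, percentile normalization (99th percentile), background
#' subtraction (mean over an annotated background region, or the lowest
#' intensity decile), rescaling to `[0, 1]`, and the 90th-percentile
#' density level used for contour visualization. Invariant to positive
#' intensity scaling.
#'
#' @param image 2-D numeric matrix.
#' @param percentile contour percentile (default 90).
#' @param smooth_sigma Gaussian SD in pixels.
#' @param bg_mask optional logical matrix marking background pixels.
#' @return list with `image_norm`, `level` (the contour level; `NA` for a
#'   degenerate constant image), `contour_mask`, `degenerate`.
#' @export
injection_density <- function(image, percentile = 90, smooth_sigma = 2,
                              bg_mask = NULL) {
  stopifnot(is.matrix(image))
  if (max(image) == min(image))
    return(list(image_norm = image * 0, level = NA_real_,
                contour_mask = image > Inf, degenerate = TRUE))
  sm <- smooth_rows_gaussian(image, smooth_sigma)
  sm <- t(smooth_rows_gaussian(t(sm), smooth_sigma))
  sm <- sm / quantile(sm, 0.99, names = FALSE)
  bg <- if (is.null(bg_mask)) mean(sm[sm <= quantile(sm, 0.1)])
        else mean(sm[bg_mask])
  sm <- pmax(sm - bg, 0)
  if (max(sm) > 0) sm <- sm / max(sm)
  level <- quantile(sm, percentile / 100, names = FALSE)
  list(image_norm = sm, level = level, contour_mask = sm >= level,
       degenerate = FALSE)
}
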