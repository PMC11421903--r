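#' Simple-ratio association matrix from a sighting table
#'
#' `index(A, B) = x / (x + yA + yB)` where `x` counts sightings containing
#' both individuals and `yA`/`yB` sightings containing exactly one of them.
#' Individuals seen fewer than `min_sightings` times are dropped before the
#' indices are computed. The diagonal is 1 by convention.
#'
#' @param sightings a `sighting_table` (tibble with list-column `ids`), or
#'   any data frame with an `ids` list-column.
#' @param min_sightings minimum sighting count to retain an individual.
#' @return list of class `association_matrix`: `index` (symmetric matrix in
#'   `[0, 1]`), `ids`, `n_sightings` (per retained individual).
#' @export
association_matrix <- function(sightings, min_sightings = 20) {
  if (nrow(sightings) == 0) stop("empty sighting table")
  all_ids <- sort(unique(unlist(sightings$ids)))
  counts <- table(factor(unlist(sightings$ids), levels = all_ids))
  keep <- names(counts)[counts >= min_sightings]
  if (length(keep) < 2)
    stop("fewer than 2 individuals meet the min-sightings threshold (",
         min_sightings, ")")
  n <- length(keep)
  ## incidence matrix: sightings x individuals
  inc <- vapply(keep, function(id)
    vapply(sightings$ids, function(s) id %in% s, logical(1)), logical(nrow(sightings)))
  inc <- matrix(as.numeric(inc), ncol = n, dimnames = list(NULL, keep))
  x <- crossprod(inc)                        # joint sightings
  seen <- colSums(inc)
  denom <- outer(seen, seen, "+") - x        # x + yA + yB
  idx <- ifelse(denom > 0, x / denom, 0)
  diag(idx) <- 1
  structure(list(index = idx, ids = keep,
                 n_sightings = as.numeric(counts[keep])),
            class = "association_matrix")
}

#' Ward hierarchical clustering of an association matrix
#'
#' Standard Ward linkage (`hclust`, method `ward.D2`) on the dissimilarity
#' `1 - index`.
#'
#' @param assoc an [association_matrix()].
#' @return an `hclust` object (merge heights nondecreasing).
#' @export
ward_dendrogram <- function(assoc) {
  if (length(assoc$ids) < 2) stop("need at least 2 individuals")
  d <- as.dist(1 - assoc$index)
  hclust(d, method = "ward.D2")
}

#' Locate the most significant knot of a dendrogram
#'
#' Builds the cumulative-bifurcation curve (number of merges at or below each
#' height, as a function of height) and returns the merge height at maximum
#' perpendicular distance from the chord joining the curve's endpoints --
#' an automated stand-in for identifying the knot by visual inspection. Both
#' axes are normalised to `[0, 1]` before distances are measured. Distances
#' within a relative `tie_tol` of the maximum are treated as tied and the
#' tie is broken toward the *largest* height: the knot is the last point
#' before the curve flattens, so a straggling intermediate merge is kept
#' below the cut rather than promoted to its own cluster.
#'
#' @param dend an `hclust` from [ward_dendrogram()].
#' @param tol minimum normalised chord distance to accept a knot.
#' @param tie_tol relative tolerance within which chord distances count as
#'   tied.
#' @return the knot height.
#' @export
find_knot <- function(dend, tol = 1e-9, tie_tol = 0.02) {
  h <- sort(dend$height)
  if (length(h) < 3) stop("need at least 3 merges to locate a knot")
  cum <- seq_along(h)
  hx <- (h - h[1]) / max(h[length(h)] - h[1], .Machine$double.eps)
  cy <- (cum - cum[1]) / (cum[length(cum)] - cum[1])
  ## perpendicular distance from chord (0,0)-(1,1): |y - x| / sqrt(2)
  dist <- abs(cy - hx) / sqrt(2)
  if (max(dist) < tol)
    stop("no knot: cumulative-bifurcation curve is indistinguishable from its chord")
  max(h[dist >= max(dist) * (1 - tie_tol)])
}

#' Cut a dendrogram strictly below a height
#'
#' Clusters are the connected components of all merges with height strictly
#' below `h`; merges at or above `h` are not performed.
#'
#' @param dend an `hclust`.
#' @param h cut height.
#' @return named integer vector: cluster id per leaf label.
#' @export
cut_partition <- function(dend, h) {
  n <- length(dend$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ## union-find over the merge list below h
  cl_of_merge <- integer(nrow(dend$merge))
  leaf_grp <- function(m) if (m < 0) -m else cl_of_merge[m]
  for (k in seq_len(nrow(dend$merge))) {
    a <- leaf_grp(dend$merge[k, 1]); b <- leaf_grp(dend$merge[k, 2])
    if (dend$height[k] < h) {
      ra <- find(a); rb <- find(b)
      parent[rb] <- ra
      cl_of_merge[k] <- ra
    } else {
      cl_of_merge[k] <- find(a)  # bookkeeping only; no union performed
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  setNames(as.integer(factor(roots)), dend$labels)
}

#' Cut a dendrogram just above its knot
#'
#' [find_knot()] returns the height of the last merge before the
#' cumulative-bifurcation curve flattens; the clusters "below the knot" must
#' include that merge, so the cut is placed halfway between the knot height
#' and the next-larger merge height (or just above the knot if it is the
#' final merge).
#'
#' @param dend an `hclust`.
#' @return list: `clusters` (from [cut_partition()]), `knot`, `cut_height`.
#' @export
cut_at_knot <- function(dend) {
  knot <- find_knot(dend)
  hs <- sort(dend$height)
  above <- hs[hs > knot]
  h_cut <- if (length(above)) (knot + above[1]) / 2 else
    knot + max(abs(knot), 1) * 1e-6
  list(clusters = cut_partition(dend, h_cut), knot = knot,
       cut_height = h_cut)
}

#' Infer core and bond groups from sightings
#'
#' Core groups: simple-ratio association indices (individuals under the
#' sighting threshold excluded), Ward clustering, knot-height cut. Bond
#' groups: the procedure repeated on the matriarchs only (oldest female per
#' core group, lexicographic tie-break), each bond group being the union of
#' its matriarchs' core groups. With a single core group, bond inference
#' degenerates to one bond group containing it. When a clustering stage has
#' no knot (the cumulative-bifurcation curve is indistinguishable from its
#' chord, i.e. no detectable substructure), that stage yields a single
#' cluster rather than an error.
#'
#' @param sightings a `sighting_table`.
#' @param ages named numeric vector: age per individual id.
#' @param min_sightings sighting threshold, applied to core-level clustering
#'   only.
#' @return list of class `social_partition`: `members` (tibble: id, core,
#'   bond, matriarch), `core_to_bond`, `core_cut_height`, `bond_cut_height`.
#' @export
infer_tiers <- function(sightings, ages, min_sightings = 20) {
  assoc <- association_matrix(sightings, min_sightings)
  dend <- ward_dendrogram(assoc)
  core_cut <- tryCatch(cut_at_knot(dend), error = function(e) NULL)
  if (is.null(core_cut)) {  # no substructure: everyone one core group
    core_h <- NA_real_
    core_cl <- setNames(rep(1L, length(assoc$ids)), assoc$ids)
  } else {
    core_h <- core_cut$cut_height
    core_cl <- core_cut$clusters
  }
  cores <- sprintf("core%02d", core_cl)
  names(cores) <- names(core_cl)

  ## matriarch = oldest member of each core group
  mats <- vapply(split(names(cores), cores), function(ids) {
    a <- ages[ids]
    ids[order(-a, ids)][1]
  }, character(1))

  bond_h <- NA_real_
  if (length(mats) == 1) {
    core_to_bond <- setNames("bond01", names(mats))
  } else {
    mat_sight <- sightings
    mat_sight$ids <- lapply(sightings$ids, intersect, unname(mats))
    mat_sight <- mat_sight[lengths(mat_sight$ids) > 0, , drop = FALSE]
    mat_assoc <- association_matrix(mat_sight, min_sightings = 0)
    if (length(mats) == 2) {
      ## two matriarchs: a single merge, no knot is definable; they form one
      ## bond group only if strongly associated, else separate bonds
      together <- mat_assoc$index[mats[1], mats[2]] > 0.5
      bond_cl <- if (together) c(1L, 1L) else c(1L, 2L)
      names(bond_cl) <- mats
    } else {
      mat_dend <- ward_dendrogram(mat_assoc)
      bond_cut <- tryCatch(cut_at_knot(mat_dend), error = function(e) NULL)
      bond_cl <- if (is.null(bond_cut)) {  # no substructure: one bond group
        setNames(rep(1L, length(mats)), unname(mats))
      } else {
        bond_h <- bond_cut$cut_height
        bond_cut$clusters
      }
    }
    mat_bond <- sprintf("bond%02d", bond_cl)
    names(mat_bond) <- names(bond_cl)
    core_to_bond <- setNames(mat_bond[mats], names(mats))
  }

  members <- tibble::tibble(
    id = names(cores),
    core = unname(cores),
    bond = unname(core_to_bond[cores]),
    matriarch = names(cores) %in% unname(mats))
  structure(list(members = members, core_to_bond = core_to_bond,
                 core_cut_height = core_h, bond_cut_height = bond_h),
            class = "social_partition")
}
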