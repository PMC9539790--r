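# Voronoi-tessellation cluster analysis.
#
# Each localization owns the Voronoi polygon of points closer to it than to
# any other localization; the Delaunay triangulation is the dual adjacency.
# Two per-point statistics drive the analysis: d_i, the mean distance to
# the Delaunay (natural) neighbours, whose distribution is trimodal when
# nanoclustered, microclustered and diffuse populations coexist; and the
# first-rank density delta_i = 1 / cell area, used SR-Tesseler-style to
# threshold cluster members. Localization uncertainty is deliberately not
# weighted into any of these computations.

# Accept a 2-column matrix, a data.frame with x/y, or a localization table.
as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_nm", "y_nm") %in% names(points)))
      return(cbind(points$x_nm, points$y_nm))
    return(as.matrix(points[, 1:2]))
  }
  as.matrix(points)[, 1:2, drop = FALSE]
}

#' Voronoi tessellation and Delaunay neighbourhood statistics
#'
#' @param points localization coordinates: a 2-column matrix/data.frame or
#'   a localization table with `x_nm`/`y_nm` (nm). At least 3 non-collinear
#'   points; exact duplicates must have been merged upstream
#'   ([merge_duplicates()]).
#' @param window optional `c(xmin, xmax, ymin, ymax)` clipping rectangle;
#'   default is the bounding box padded by 5%. Cells clipped by the window
#'   (convex-hull region cells, which are unbounded in the open plane) are
#'   flagged and excluded from area/density statistics.
#' @return a `voronoi_tessellation`: list with `points` (n x 2), per-point
#'   `neighbors` (Delaunay adjacency lists), `mean_neighbor_distance_nm`
#'   (d_i, defined for every point), `cell_area_nm2` (NA for clipped
#'   cells), `first_rank_density` (1/area), `unbounded` (logical),
#'   `edges` (Delaunay edge list), `voronoi_segments` (Voronoi edge table
#'   with the indices of the two points each edge separates), `window`.
#' @export
tessellate <- function(points, window = NULL) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (n < 3L) stop("tessellation needs at least 3 points")
  if (anyDuplicated(xy))
    stop("duplicate coordinates; run merge_duplicates() first")
  # collinearity: rank of centred coordinates
  cc <- sweep(xy, 2L, colMeans(xy))
  if (min(svd(cc)$d) < 1e-9 * max(svd(cc)$d))
    stop("points are collinear; tessellation undefined")
  if (is.null(window)) {
    rx <- range(xy[, 1L]); ry <- range(xy[, 2L])
    pad <- 0.05 * max(diff(rx), diff(ry))
    window <- c(rx[1L] - pad, rx[2L] + pad, ry[1L] - pad, ry[2L] + pad)
  }
  dd <- deldir::deldir(xy[, 1L], xy[, 2L], rw = window)
  edges <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
  elen <- sqrt((dd$delsgs$x1 - dd$delsgs$x2)^2 +
                 (dd$delsgs$y1 - dd$delsgs$y2)^2)
  neighbors <- vector("list", n)
  acc_sum <- numeric(n); acc_n <- integer(n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    neighbors[[i]] <- c(neighbors[[i]], j)
    neighbors[[j]] <- c(neighbors[[j]], i)
    acc_sum[i] <- acc_sum[i] + elen[k]; acc_n[i] <- acc_n[i] + 1L
    acc_sum[j] <- acc_sum[j] + elen[k]; acc_n[j] <- acc_n[j] + 1L
  }
  d_i <- ifelse(acc_n > 0L, acc_sum / pmax(acc_n, 1L), NA_real_)
  unbounded <- dd$summary$nbpt > 0L
  area <- dd$summary$dir.area
  area[unbounded] <- NA_real_
  vs <- dd$dirsgs
  structure(list(points = xy, neighbors = neighbors,
                 mean_neighbor_distance_nm = d_i,
                 cell_area_nm2 = area,
                 first_rank_density = 1 / area,
                 unbounded = unbounded,
                 edges = edges,
                 voronoi_segments = data.frame(
                   x1 = vs$x1, y1 = vs$y1, x2 = vs$x2, y2 = vs$y2,
                   ind1 = vs$ind1, ind2 = vs$ind2,
                   clipped = vs$bp1 | vs$bp2),
                 window = window),
            class = "voronoi_tessellation")
}

#' @export
print.voronoi_tessellation <- function(x, ...) {
  cat(sprintf("<voronoi_tessellation> %d points, %d Delaunay edges, %d clipped cell(s)\n",
              nrow(x$points), nrow(x$edges), sum(x$unbounded)))
  cat(sprintf("  mean neighbour distance: median %.2f nm\n",
              median(x$mean_neighbor_distance_nm, na.rm = TRUE)))
  invisible(x)
}

#' Histogram of mean Delaunay-neighbour distances
#'
#' The per-cell mean distance distribution; with coexisting nanocluster,
#' microcluster and diffuse populations it is trimodal.
#'
#' @param tess a [tessellate()] result.
#' @param bin_width_nm histogram bin width.
#' @return `data.frame(bin_lo, bin_hi, count)`; counts sum to the point
#'   count. Empty bins are retained.
#' @export
mean_distance_distribution <- function(tess, bin_width_nm = 2) {
  d <- tess$mean_neighbor_distance_nm
  edges <- seq(0, (floor(max(d) / bin_width_nm) + 1L) * bin_width_nm,
               by = bin_width_nm)
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
             count = tabulate(idx, nbins = length(edges) - 1L))
}

#' Classify point sets by mean neighbour distance
#'
#' Band edges default to 6 and 30 nm: mean d <= 6 nm is a nanocluster,
#' (6, 30] nm a microcluster, > 30 nm diffuse. The bands are contiguous
#' half-open intervals so every value receives exactly one label.
#'
#' @param mean_d_nm numeric vector of mean neighbour distances.
#' @param edges_nm two increasing band edges `c(nano_max, micro_max)`.
#' @return character vector: `"nanocluster"`, `"microcluster"` or
#'   `"diffuse"`.
#' @export
classify_by_mean_distance <- function(mean_d_nm, edges_nm = c(6, 30)) {
  if (!length(mean_d_nm)) stop("empty input")
  if (edges_nm[1L] >= edges_nm[2L]) stop("edges must be increasing")
  ifelse(mean_d_nm <= edges_nm[1L], "nanocluster",
         ifelse(mean_d_nm <= edges_nm[2L], "microcluster", "diffuse"))
}

#' Morphometrics of one cluster
#'
#' Area is the sum of the member points' finite Voronoi cell areas;
#' the perimeter is the boundary length of the union of member cells
#' (the total length of Voronoi edges separating a member from a
#' non-member); circularity is `4 pi A / P^2` (1 for a disc); diameter is
#' the equivalent-circle diameter `2 sqrt(A / pi)`; density is members per
#' area.
#'
#' @param tess a [tessellate()] result.
#' @param members integer indices of the member points.
#' @return list `(n, area_nm2, perimeter_nm, circularity, diameter_nm,
#'   density_per_um2, mean_d_nm)`; `NULL` if no member has a finite cell.
#' @export
cluster_metrics <- function(tess, members) {
  area <- sum(tess$cell_area_nm2[members], na.rm = TRUE)
  if (!is.finite(area) || area <= 0) return(NULL)
  vs <- tess$voronoi_segments
  m1 <- vs$ind1 %in% members
  m2 <- vs$ind2 %in% members
  on_boundary <- xor(m1, m2)
  per <- sum(sqrt((vs$x1[on_boundary] - vs$x2[on_boundary])^2 +
                    (vs$y1[on_boundary] - vs$y2[on_boundary])^2))
  circ <- if (per > 0) min(1, 4 * pi * area / per^2) else NA_real_
  list(n = length(members), area_nm2 = area, perimeter_nm = per,
       circularity = circ, diameter_nm = 2 * sqrt(area / pi),
       density_per_um2 = length(members) / area * 1e6,
       mean_d_nm = mean(tess$mean_neighbor_distance_nm[members]))
}

#' Segment clusters by first-rank density thresholding
#'
#' SR-Tesseler-style segmentation: points whose first-rank density
#' `delta_i = 1 / cell area` exceeds `density_factor` times the mean
#' density over finite cells are retained; clusters are the connected
#' components of the retained points under the Delaunay adjacency
#' restricted to retained points. Components violating the
#' localization-count or area bounds are discarded. Retained singletons
#' and all discarded points form the diffuse pool. Each surviving cluster
#' is classified by its members' mean neighbour distance
#' ([classify_by_mean_distance()]).
#'
#' @param tess a [tessellate()] result.
#' @param density_factor threshold factor alpha (default 2).
#' @param min_locs,max_locs bounds on member count.
#' @param min_area_nm2,max_area_nm2 bounds on cluster area.
#' @param class_edges_nm passed to [classify_by_mean_distance()].
#' @return list with `clusters` (one row per cluster: `cluster`, `class`,
#'   `n`, `area_nm2`, `perimeter_nm`, `circularity`, `diameter_nm`,
#'   `density_per_um2`, `mean_d_nm`), `members` (list of index vectors),
#'   `assignment` (per-point cluster id, 0 = diffuse pool) and `retained`
#'   (logical, the thresholding result).
#' @export
segment_clusters <- function(tess, density_factor = 2, min_locs = 10L,
                             max_locs = Inf, min_area_nm2 = 0,
                             max_area_nm2 = Inf, class_edges_nm = c(6, 30)) {
  dens <- tess$first_rank_density
  finite <- !tess$unbounded & is.finite(dens)
  if (!any(finite)) stop("no finite Voronoi cells")
  thr <- density_factor * mean(dens[finite])
  retained <- finite & dens > thr
  n <- nrow(tess$points)
  keep_edge <- retained[tess$edges[, 1L]] & retained[tess$edges[, 2L]]
  comp <- edge_components(n, tess$edges[keep_edge, , drop = FALSE])
  comp[!retained] <- NA_integer_
  assignment <- integer(n)
  members <- list(); rows <- list()
  next_id <- 0L
  for (cid in unique(comp[!is.na(comp)])) {
    idx <- which(!is.na(comp) & comp == cid)
    if (length(idx) < 2L) next                     # retained singleton
    if (length(idx) < min_locs || length(idx) > max_locs) next
    met <- cluster_metrics(tess, idx)
    if (is.null(met)) {
      message("dropping cluster with no finite cell area")
      next
    }
    if (met$area_nm2 < min_area_nm2 || met$area_nm2 > max_area_nm2) next
    next_id <- next_id + 1L
    assignment[idx] <- next_id
    members[[next_id]] <- idx
    rows[[next_id]] <- data.frame(
      cluster = next_id,
      class = classify_by_mean_distance(met$mean_d_nm, class_edges_nm),
      n = met$n, area_nm2 = met$area_nm2, perimeter_nm = met$perimeter_nm,
      circularity = met$circularity, diameter_nm = met$diameter_nm,
      density_per_um2 = met$density_per_um2, mean_d_nm = met$mean_d_nm)
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), class = character(), n = integer(),
               area_nm2 = numeric(), perimeter_nm = numeric(),
               circularity = numeric(), diameter_nm = numeric(),
               density_per_um2 = numeric(), mean_d_nm = numeric())
  list(clusters = clusters, members = members, assignment = assignment,
       retained = retained, density_threshold = thr)
}

#' Per-point nearest-neighbour distances
#'
#' Each localization is assigned the distance to the closest other
#' localization in the dataset (uncertainties are not weighted in).
#'
#' @param points coordinates as in [tessellate()] (>= 2 points).
#' @return numeric vector of nearest-neighbour distances, one per point.
#' @export
nearest_neighbor_distances <- function(points) {
  xy <- as_xy(points)
  if (nrow(xy) < 2L) stop("need at least 2 points")
  RANN::nn2(xy, xy, k = 2L)$nn.dists[, 2L]
}

#' Compare two separation-distance samples
#'
#' Welch two-sample t test plus means and standard errors, the comparison
#' used to contrast per-frame PSF separations between labelling
#' strategies.
#'
#' @param a,b numeric distance samples.
#' @return list `(mean_a, sem_a, mean_b, sem_b, t, p_value)`. When both
#'   samples are constant the p-value degenerates to 1 for equal means and
#'   0 otherwise.
#' @export
compare_separation <- function(a, b) {
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  out <- list(mean_a = mean(a), sem_a = sem(a),
              mean_b = mean(b), sem_b = sem(b))
  if ((length(a) < 2L || var(a) == 0) && (length(b) < 2L || var(b) == 0)) {
    out$t <- NA_real_
    out$p_value <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(out)
  }
  tt <- t.test(a, b)
  out$t <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out
}
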