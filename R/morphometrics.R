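#' Threshold the differentiation field into a tissue region
#'
#' The tissue is the set of voxels whose differentiation marker meets the
#' threshold (`Y >= Ya`). Shape metrics are computed on the largest
#' 26-connected component: the principal-axis ratio (longest over shortest
#' second-moment axis) separates elongated stalks from isotropic blobs, and
#' sphericity compares the component's surface area against that of an
#' equal-volume sphere (surface area is estimated from exposed voxel faces
#' with the standard 2/3 stereological correction, so a digitized ball
#' scores close to 1).
#'
#' @param Y a 3D numeric array (the differentiation-marker field) or an
#'   `rd_state`/`rd_run`, whose `Y` is used.
#' @param Ya threshold concentration in `(0, 1]` (default 0.5).
#' @return An object of class `tissue_region`: list with `mask` (logical
#'   array), `labels`, `largest` (logical array, largest component), `Ya`,
#'   `volume_fraction`, `n_components`, `n_voxels_largest`,
#'   `principal_axis_ratio`, `sphericity`. An empty mask is valid and has
#'   `n_components = 0`.
#' @examples
#' vol <- make_fixture(fixture_spec("sphere", radius = 6, dim = c(24, 24, 24)))
#' extract_tissue(vol)$n_components
#' @export
extract_tissue <- function(Y, Ya = 0.5) {
  if (inherits(Y, "rd_run")) Y <- Y$final
  if (inherits(Y, "rd_state")) Y <- Y$Y
  if (is.logical(Y)) Y <- Y + 0
  if (is.null(dim(Y)) || length(dim(Y)) != 3L)
    stop("Y must be a 3D array", call. = FALSE)
  if (Ya <= 0 || Ya > 1) stop("Ya must be in (0, 1]", call. = FALSE)
  mask <- Y >= Ya
  dm <- dim(mask)
  labels <- label_components_cpp(mask, as.integer(dm))
  ncomp <- attr(labels, "n_components")
  out <- list(mask = mask, labels = labels, Ya = Ya,
              volume_fraction = mean(mask), n_components = ncomp,
              largest = array(FALSE, dm), n_voxels_largest = 0L,
              principal_axis_ratio = NA_real_, sphericity = NA_real_)
  if (ncomp > 0L) {
    counts <- tabulate(labels[labels > 0L], nbins = ncomp)
    big <- which.max(counts)
    largest <- array(labels == big, dm)
    out$largest <- largest
    out$n_voxels_largest <- counts[big]
    out$principal_axis_ratio <- principal_axis_ratio(largest)
    out$sphericity <- voxel_sphericity(largest)
  }
  structure(out, class = "tissue_region")
}

#' @export
print.tissue_region <- function(x, ...) {
  cat(sprintf("<tissue_region> Ya = %g\n", x$Ya))
  cat(sprintf("  volume fraction %.4g, %d component(s), largest %d voxels\n",
              x$volume_fraction, x$n_components, x$n_voxels_largest))
  if (x$n_components > 0)
    cat(sprintf("  principal-axis ratio %.3g, sphericity %.3g\n",
                x$principal_axis_ratio, x$sphericity))
  invisible(x)
}

#' @export
tidy.tissue_region <- function(x, ...) {
  tibble::tibble(Ya = x$Ya, volume_fraction = x$volume_fraction,
                 n_components = x$n_components,
                 n_voxels_largest = x$n_voxels_largest,
                 principal_axis_ratio = x$principal_axis_ratio,
                 sphericity = x$sphericity)
}

principal_axis_ratio <- function(mask) {
  co <- which(mask, arr.ind = TRUE)
  if (nrow(co) < 2L) return(1)
  ev <- eigen(stats::cov(co), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1 / 12)  # single-voxel-thin directions get the voxel's own
                          # second moment, avoiding a zero denominator
  sqrt(max(ev) / min(ev))
}

voxel_sphericity <- function(mask) {
  V <- sum(mask)
  if (V == 0L) return(NA_real_)
  area <- (2 / 3) * exposed_faces(mask)
  if (area <= 0) return(NA_real_)
  (pi^(1 / 3) * (6 * V)^(2 / 3)) / area
}

# Count foreground voxel faces adjacent to background (domain border counts
# as background).
exposed_faces <- function(mask) {
  dm <- dim(mask)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  n <- 0L
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[2:(dm[1] + 1) + sh[1], 2:(dm[2] + 1) + sh[2],
              2:(dm[3] + 1) + sh[3], drop = FALSE]
    dim(nb) <- dm
    n <- n + sum(mask & !nb)
  }
  n
}

#' Skeletonize a tissue region into a branch graph
#'
#' Thins the largest connected component to a one-voxel-wide, topology
#' preserving curve skeleton, then traces it into a graph: endpoint voxels
#' (one skeleton neighbor) become tips, voxels with three or more neighbors
#' become junctions, and touching junction voxels are fused into a single
#' branch-point node. Edge arc lengths are measured along the voxel chain
#' with the 26-connected step metric (1, sqrt 2, sqrt 3). The root is the
#' node nearest `root_hint` (default: the domain center), and each edge gets
#' a generation: the number of branch points between the root and that edge.
#'
#' @param region a `tissue_region` from [extract_tissue()], or a logical 3D
#'   array.
#' @param root_hint length-3 voxel coordinate used to pick the root node;
#'   `NULL` means the domain center.
#' @return An object of class `branch_structure`: list with `skeleton`
#'   (logical array), `coords` (matrix of skeleton voxel coordinates),
#'   `nodes` (tibble: `node`, `x`, `y`, `z`, `kind`, `degree`,
#'   `dist_from_root`), `edges` (tibble: `from`, `to`, `arc_length`,
#'   `generation`), `graph` (igraph, weighted by arc length), `root`,
#'   `n_branch_points`, `n_tips`, `max_generation`, `voxel_graph` and
#'   `voxel_coords` (for profile placement).
#' @examples
#' vol <- make_fixture(fixture_spec("y_tube", dim = c(40, 40, 48)))
#' sk <- skeletonize_region(extract_tissue(vol))
#' c(sk$n_branch_points, sk$n_tips)
#' @export
skeletonize_region <- function(region, root_hint = NULL) {
  mask <- if (inherits(region, "tissue_region")) region$largest else region
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("region must be a tissue_region or a logical 3D array", call. = FALSE)
  dm <- dim(mask)
  empty <- empty_branch_structure(dm)
  if (!any(mask)) return(empty)

  skel <- thin3d_cpp(mask, as.integer(dm))
  co <- which(skel, arr.ind = TRUE)
  nv <- nrow(co)
  if (nv == 0L) return(empty)

  lin <- as.integer(which(skel))
  # adjacency among skeleton voxels (26-neighborhood)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nlin <- (nb[, 3] - 1L) * dm[1] * dm[2] + (nb[, 2] - 1L) * dm[1] + nb[, 1]
    j <- match(nlin, lin)
    hit <- ok & !is.na(j)
    i <- which(hit)
    keep <- i < j[hit]  # each undirected pair once
    ef <- c(ef, i[keep]); et <- c(et, j[hit][keep])
    ew <- c(ew, rep(sqrt(sum(offs[r, ]^2)), sum(keep)))
  }
  vg <- igraph::make_empty_graph(nv, directed = FALSE)
  if (length(ef))
    vg <- igraph::add_edges(vg, rbind(ef, et), weight = ew)

  deg <- igraph::degree(vg)
  node_vox <- which(deg != 2L)  # endpoints, junctions, isolated voxels
  if (length(node_vox) == 0L) {
    # pure cycle: no natural endpoints; use the first voxel as a node
    node_vox <- 1L
  }

  # fuse touching junction voxels into branch-point clusters (radius-1)
  junction <- deg >= 3L
  cluster_id <- integer(nv)
  if (any(junction)) {
    sub <- igraph::induced_subgraph(vg, which(junction))
    comp <- igraph::components(sub)$membership
    cluster_id[which(junction)] <- comp
  }
  # node ids: one per junction cluster, one per non-junction node voxel
  n_clusters <- if (any(junction)) max(cluster_id) else 0L
  vox_node <- integer(nv)  # 0 = chain voxel
  vox_node[junction] <- cluster_id[junction]
  nonj <- setdiff(node_vox, which(junction))
  vox_node[nonj] <- n_clusters + seq_along(nonj)
  n_nodes <- n_clusters + length(nonj)

  # representative coordinate per node (junction cluster: voxel nearest the
  # cluster centroid)
  node_xyz <- matrix(NA_real_, n_nodes, 3)
  for (id in seq_len(n_nodes)) {
    vox <- which(vox_node == id)
    if (length(vox) == 1L) node_xyz[id, ] <- co[vox, ]
    else {
      ctr <- colMeans(co[vox, , drop = FALSE])
      d2 <- rowSums(sweep(co[vox, , drop = FALSE], 2, ctr)^2)
      node_xyz[id, ] <- co[vox[which.min(d2)], ]
    }
  }

  # trace edges: from every node voxel, walk through degree-2 chain voxels
  adj <- igraph::as_adj_list(vg)
  wmat <- NULL
  edge_w <- function(a, b) sqrt(sum((co[a, ] - co[b, ])^2))
  e_from <- integer(0); e_to <- integer(0); e_len <- numeric(0)
  e_chain <- list()
  seen <- character(0)
  for (v in which(vox_node > 0L)) {
    for (w in as.integer(adj[[v]])) {
      if (vox_node[w] > 0L) {
        # direct node-node contact (skip intra-cluster contacts)
        if (vox_node[w] == vox_node[v]) next
        key <- paste(min(v, w), max(v, w), sep = "-")
        if (key %in% seen) next
        seen <- c(seen, key)
        e_from <- c(e_from, vox_node[v]); e_to <- c(e_to, vox_node[w])
        e_len <- c(e_len, edge_w(v, w))
        e_chain[[length(e_chain) + 1L]] <- c(v, w)
        next
      }
      prev <- v; cur <- w; len <- edge_w(v, w); chain <- c(v, w)
      repeat {
        nxt <- setdiff(as.integer(adj[[cur]]), prev)
        if (length(nxt) == 0L) { nxt <- cur; break }  # dangling (shouldn't happen)
        nxt <- nxt[1]
        len <- len + edge_w(cur, nxt)
        chain <- c(chain, nxt)
        if (vox_node[nxt] > 0L) break
        prev <- cur; cur <- nxt
      }
      endv <- chain[length(chain)]
      if (vox_node[endv] == 0L) next  # open chain into nothing
      key <- paste(min(v, endv), max(v, endv), paste(range(chain), collapse = ":"),
                   sep = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      e_from <- c(e_from, vox_node[v]); e_to <- c(e_to, vox_node[endv])
      e_len <- c(e_len, len)
      e_chain[[length(e_chain) + 1L]] <- chain
    }
  }
  # duplicate suppression for chains traced from both ends
  if (length(e_from)) {
    sig <- vapply(seq_along(e_from), function(i) {
      ch <- e_chain[[i]]
      if (ch[1] > ch[length(ch)]) ch <- rev(ch)
      paste(ch, collapse = ",")
    }, character(1))
    keep <- !duplicated(sig)
    e_from <- e_from[keep]; e_to <- e_to[keep]; e_len <- e_len[keep]
    e_chain <- e_chain[keep]
  }

  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  if (length(e_from))
    g <- igraph::add_edges(g, rbind(e_from, e_to), weight = e_len)

  node_is_bp <- vapply(seq_len(n_nodes), function(id)
    any(junction[vox_node == id]), logical(1))
  node_deg <- igraph::degree(g)

  root_hint <- root_hint %||% (dm / 2)
  d2root <- rowSums(sweep(node_xyz, 2, root_hint)^2)
  root <- which.min(d2root)

  dist_root <- suppressWarnings(
    igraph::distances(g, v = root, weights = igraph::E(g)$weight))[1, ]

  kind <- ifelse(node_is_bp, "branch_point",
                 ifelse(node_deg <= 1L, "tip", "node"))
  kind[root] <- paste0(kind[root], "+root")

  nodes <- tibble::tibble(node = seq_len(n_nodes),
                          x = node_xyz[, 1], y = node_xyz[, 2],
                          z = node_xyz[, 3], kind = kind,
                          degree = node_deg,
                          dist_from_root = dist_root)

  # per-edge generation: branch points on the root-side path before the edge
  gen <- integer(length(e_from))
  if (length(e_from)) {
    for (i in seq_along(e_from)) {
      ends <- c(e_from[i], e_to[i])
      prox <- ends[which.min(dist_root[ends])]
      if (is.finite(dist_root[prox])) {
        pth <- igraph::shortest_paths(g, from = root, to = prox,
                                      weights = igraph::E(g)$weight)$vpath[[1]]
        on_path <- setdiff(as.integer(pth), integer(0))
        gen[i] <- sum(node_is_bp[on_path])
      } else gen[i] <- NA_integer_
    }
  }
  edges <- tibble::tibble(from = e_from, to = e_to, arc_length = e_len,
                          generation = gen)

  structure(list(skeleton = skel, coords = co, nodes = nodes, edges = edges,
                 graph = g, root = root,
                 n_branch_points = sum(node_is_bp),
                 n_tips = sum(node_deg <= 1L & !node_is_bp),
                 max_generation = if (length(gen)) max(gen, na.rm = TRUE) else 0L,
                 voxel_graph = vg, voxel_coords = co,
                 voxel_node = vox_node, edge_chains = e_chain,
                 dim = dm),
            class = "branch_structure")
}

empty_branch_structure <- function(dm) {
  structure(list(skeleton = array(FALSE, dm),
                 coords = matrix(numeric(0), 0, 3),
                 nodes = tibble::tibble(node = integer(), x = numeric(),
                                        y = numeric(), z = numeric(),
                                        kind = character(), degree = integer(),
                                        dist_from_root = numeric()),
                 edges = tibble::tibble(from = integer(), to = integer(),
                                        arc_length = numeric(),
                                        generation = integer()),
                 graph = igraph::make_empty_graph(0, directed = FALSE),
                 root = NA_integer_, n_branch_points = 0L, n_tips = 0L,
                 max_generation = 0L,
                 voxel_graph = igraph::make_empty_graph(0, directed = FALSE),
                 voxel_coords = matrix(numeric(0), 0, 3),
                 voxel_node = integer(0), edge_chains = list(), dim = dm),
            class = "branch_structure")
}

#' @export
print.branch_structure <- function(x, ...) {
  cat(sprintf("<branch_structure> %d skeleton voxels, %d node(s), %d edge(s)\n",
              nrow(x$coords), nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  branch points: %d, tips: %d, max generation: %d\n",
              x$n_branch_points, x$n_tips, x$max_generation))
  invisible(x)
}

#' @export
tidy.branch_structure <- function(x, ...) x$edges

#' @export
glance.branch_structure <- function(x, ...) {
  tibble::tibble(n_skeleton_voxels = nrow(x$coords),
                 n_branch_points = x$n_branch_points, n_tips = x$n_tips,
                 max_generation = x$max_generation,
                 total_arc_length = sum(x$edges$arc_length))
}

#' Arc-length separations between consecutive bifurcation points
#'
#' The spatial separation of bifurcation events is the centerline arc
#' distance between a branch point and the next branch point along the
#' growing structure. For each branch point that has a parent branch point
#' on its path to the root, one separation is reported. The distance from
#' the root to the first branch point is returned separately as the
#' `root_to_first` attribute.
#'
#' @param structure a `branch_structure` from [skeletonize_region()].
#' @return A tibble with columns `from`, `to` (node ids) and `separation`
#'   (voxel units), one row per consecutive branch-point pair; attribute
#'   `root_to_first` holds the root-to-first-branch-point arc distance (or
#'   `NA` when there is no branch point).
#' @export
bifurcation_separations <- function(structure) {
  stopifnot(inherits(structure, "branch_structure"))
  empty <- tibble::tibble(from = integer(), to = integer(),
                          separation = numeric())
  bp <- which(grepl("branch_point", structure$nodes$kind))
  if (length(bp) == 0L) {
    attr(empty, "root_to_first") <- NA_real_
    return(empty)
  }
  g <- structure$graph
  w <- igraph::E(g)$weight
  droot <- structure$nodes$dist_from_root
  # nearest branch point to the root (along arc length)
  first_bp <- bp[which.min(droot[bp])]
  rtf <- droot[first_bp]

  from <- integer(0); to <- integer(0); sep <- numeric(0)
  for (b in bp) {
    pth <- igraph::shortest_paths(g, from = structure$root, to = b,
                                  weights = w)$vpath[[1]]
    pth <- as.integer(pth)
    if (length(pth) < 2L) next
    anc <- intersect(rev(pth[-length(pth)]), bp)  # nearest ancestor bp first
    if (length(anc) == 0L) next
    parent <- anc[1]
    d <- igraph::distances(g, v = parent, to = b, weights = w)[1, 1]
    from <- c(from, parent); to <- c(to, b); sep <- c(sep, d)
  }
  out <- tibble::tibble(from = from, to = to, separation = sep)
  attr(out, "root_to_first") <- rtf
  out
}

#' Classify a branch pattern into one of five regimes
#'
#' Operationalizes the visual five-regime reading of simulated structures as
#' a deterministic metric cascade:
#'
#' 1. `volume_fraction > spillover_frac` -> `SPATIAL_SPILLOVER` (tissue
#'    floods the box);
#' 2. near-spherical largest component (`sphericity > sphere_min` and
#'    principal-axis ratio < 1.5) -> `NO_BRANCH` (isotropic expansion);
#' 3. no branch points -> `PARENT_ONLY` (a single elongated stalk);
#' 4. branch points predominantly in the distal `tip_zone` fraction of the
#'    skeleton's arc-length extent, with near-symmetric daughter arms ->
#'    `TIP_SPLITTING`;
#' 5. otherwise -> `SIDE_BRANCHING`.
#'
#' An empty tissue region is `UNDETERMINED`.
#'
#' @param region a `tissue_region`.
#' @param structure the matching `branch_structure`; computed from `region`
#'   when omitted.
#' @param spillover_frac volume-fraction bound for spillover (default 0.5).
#' @param sphere_min sphericity bound for the no-branch ball (default 0.85).
#' @param tip_zone distal fraction of the root-to-tip arc extent in which
#'   tip-splitting branch points live (default 0.25).
#' @param arm_symmetry minimum length ratio (short/long) of the two daughter
#'   arms at the distal-most branch point for a split to count as
#'   symmetric tip bifurcation (default 0.25).
#' @return An object of class `pattern_class`: list with `label` (one of
#'   `SPATIAL_SPILLOVER`, `NO_BRANCH`, `PARENT_ONLY`, `SIDE_BRANCHING`,
#'   `TIP_SPLITTING`, `UNDETERMINED`) and `evidence` (one-row tibble of the
#'   metrics that produced it).
#' @export
classify_pattern <- function(region, structure = NULL, spillover_frac = 0.5,
                             sphere_min = 0.85, tip_zone = 0.25,
                             arm_symmetry = 0.25) {
  stopifnot(inherits(region, "tissue_region"))
  if (is.null(structure)) structure <- skeletonize_region(region)
  ev <- tidy(region)
  ev$n_branch_points <- structure$n_branch_points
  ev$n_tips <- structure$n_tips
  ev$max_generation <- structure$max_generation
  ev$distal_bp_fraction <- NA_real_
  ev$arm_ratio <- NA_real_

  lab <- "UNDETERMINED"
  if (region$n_components == 0L) {
    lab <- "UNDETERMINED"
  } else if (region$volume_fraction > spillover_frac) {
    lab <- "SPATIAL_SPILLOVER"
  } else if (!is.na(region$sphericity) && region$sphericity > sphere_min &&
             region$principal_axis_ratio < 1.5) {
    lab <- "NO_BRANCH"
  } else if (structure$n_branch_points == 0L) {
    lab <- "PARENT_ONLY"
  } else {
    droot <- structure$nodes$dist_from_root
    bp <- which(grepl("branch_point", structure$nodes$kind))
    reach <- max(droot[is.finite(droot)], 0)
    distal_frac <- if (reach > 0)
      mean(droot[bp] >= (1 - tip_zone) * reach) else 0
    ev$distal_bp_fraction <- distal_frac
    ev$arm_ratio <- distal_arm_ratio(structure)
    if (distal_frac > 0.5 && !is.na(ev$arm_ratio) &&
        ev$arm_ratio >= arm_symmetry) {
      lab <- "TIP_SPLITTING"
    } else {
      lab <- "SIDE_BRANCHING"
    }
  }
  structure(list(label = lab, evidence = ev), class = "pattern_class")
}

# Length ratio (short/long) of the two longest arms leaving the distal-most
# branch point away from the root.
distal_arm_ratio <- function(structure) {
  bp <- which(grepl("branch_point", structure$nodes$kind))
  if (length(bp) == 0L) return(NA_real_)
  droot <- structure$nodes$dist_from_root
  b <- bp[which.max(droot[bp])]
  g <- structure$graph
  w <- igraph::E(g)$weight
  nbs <- as.integer(igraph::neighbors(g, b))
  out <- setdiff(nbs[droot[nbs] > droot[b] - 1e-9], structure$root)
  if (length(out) < 2L) return(NA_real_)
  # arm length: farthest reachable distance beyond b through each daughter
  d_from_b <- igraph::distances(g, v = b, weights = w)[1, ]
  pths <- igraph::shortest_paths(g, from = b, weights = w)$vpath
  arms <- vapply(out, function(nb) {
    # nodes whose path from b starts through this daughter
    through <- vapply(pths, function(p) length(p) >= 2 && p[2] == nb,
                      logical(1))
    if (!any(through)) return(d_from_b[nb])
    max(d_from_b[which(through)])
  }, numeric(1))
  arms <- sort(arms, decreasing = TRUE)
  if (length(arms) < 2L || arms[1] <= 0) return(NA_real_)
  arms[2] / arms[1]
}

#' @export
print.pattern_class <- function(x, ...) {
  cat(sprintf("<pattern_class> %s\n", x$label))
  print(as.data.frame(x$evidence))
  invisible(x)
}

#' @export
tidy.pattern_class <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(label = x$label), x$evidence)
}
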