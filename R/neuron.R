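# Morphometry of reconstructed projection neurons: critical points
# (branching- and endpoints), density-based tuft clustering (more than 5
# points within < 15 um spatial proximity), convex-hull tuft volumes, path
# and Euclidean distances, branch classification and population comparison.

.child_counts <- function(nodes) {
  cnt <- table(factor(nodes$parent, levels = nodes$id))
  as.integer(cnt)
}

# cumulative edge length from the soma to every node, in node-table order
.path_distances <- function(tree) {
  nd <- treeNodes(tree)
  idx <- match(nd$parent, nd$id)
  n <- nrow(nd)
  edge <- numeric(n)
  has <- !is.na(idx)
  edge[has] <- sqrt((nd$x[has] - nd$x[idx[has]])^2 +
                    (nd$y[has] - nd$y[idx[has]])^2 +
                    (nd$z[has] - nd$z[idx[has]])^2)
  depthDist <- rep(NA_real_, n)
  depthDist[nd$parent == -1L] <- 0
  repeat {
    todo <- which(is.na(depthDist))
    if (!length(todo)) break
    ready <- todo[!is.na(depthDist[idx[todo]])]
    depthDist[ready] <- depthDist[idx[ready]] + edge[ready]
  }
  setNames(depthDist, nd$id)
}

#' Branching- and endpoints of a neuron tree
#'
#' Nodes with two or more children are branching points; leaves are
#' endpoints. The soma (root) is excluded even when it is leaf- or
#' branching-like.
#'
#' @param tree a [NeuronTree-class].
#' @return data.frame with \code{id}, \code{kind} ("branching"/"endpoint"),
#'   \code{x}, \code{y}, \code{z} (micrometers).
#' @export
criticalPoints <- function(tree) {
  nd <- treeNodes(tree)
  nch <- .child_counts(nd)
  soma <- somaId(tree)
  keepB <- nch >= 2L & nd$id != soma
  keepE <- nch == 0L & nd$id != soma
  out <- rbind(
    data.frame(id = nd$id[keepB], kind = rep("branching", sum(keepB)),
               x = nd$x[keepB], y = nd$y[keepB], z = nd$z[keepB]),
    data.frame(id = nd$id[keepE], kind = rep("endpoint", sum(keepE)),
               x = nd$x[keepE], y = nd$y[keepE], z = nd$z[keepE]))
  out[order(out$id), , drop = FALSE]
}

#' Density-based tuft detection
#'
#' Clusters critical points with DBSCAN semantics: a point is a core point if
#' at least \code{minCount - 1} other points lie strictly within \code{eps}
#' of it; clusters are the connected components of core points plus their
#' border points. An accumulation of more than 5 points within < 15 um
#' (defaults) forms a tuft-cluster; sparse points are blunt endings (noise).
#' Border points are assigned to the cluster of their first core neighbor in
#' node-id order (a deterministic resolution of the DBSCAN tie).
#'
#' @param points data.frame from [criticalPoints()] (needs id, x, y, z).
#' @param eps neighborhood radius in micrometers (default 15, strict "<").
#' @param minCount minimum cluster size (default 6, i.e. more than 5 points).
#' @return list with \code{clusters} (list; each has \code{member_ids},
#'   \code{centroid}, \code{n}) and \code{noise_ids} (blunt endings).
#' @export
detectTufts <- function(points, eps = 15, minCount = 6L) {
  pts <- as.data.frame(points)[order(points$id), , drop = FALSE]
  n <- nrow(pts)
  if (n == 0L) return(list(clusters = list(), noise_ids = integer(0)))
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  D <- as.matrix(dist(xyz))
  adj <- D < eps
  diag(adj) <- FALSE
  nbCount <- rowSums(adj)
  core <- nbCount >= (minCount - 1L)
  labels <- rep(0L, n)
  nextLab <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    nextLab <- nextLab + 1L
    queue <- i
    labels[i] <- nextLab
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      nbs <- which(adj[cur, ] & core & labels == 0L)
      labels[nbs] <- nextLab
      queue <- c(queue, nbs)
    }
  }
  # border points: first-claiming core neighbor in id order
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    coreNb <- which(adj[i, ] & core)
    if (length(coreNb)) labels[i] <- labels[coreNb[1L]]
  }
  clusters <- lapply(seq_len(max(labels, 0L)), function(k) {
    m <- which(labels == k)
    list(member_ids = pts$id[m],
         centroid = colMeans(xyz[m, , drop = FALSE]),
         n = length(m))
  })
  list(clusters = clusters, noise_ids = pts$id[labels == 0L])
}

#' Tuft volume (convex hull)
#'
#' Volume of the convex hull of a cluster's critical points. Degenerate
#' clusters (fewer than 4 points, or collinear/coplanar) get volume 0 and a
#' flag rather than failing the cell.
#'
#' @param points critical-point table of the cell.
#' @param memberIds ids of the cluster members.
#' @return list with \code{volume} (um^3) and \code{degenerate}.
#' @export
tuftVolume <- function(points, memberIds) {
  m <- points[points$id %in% memberIds, c("x", "y", "z"), drop = FALSE]
  convexHullVolume(as.matrix(m))
}

#' Soma-to-tuft path distance
#'
#' Cumulative dendritic edge length from the soma to the cluster's attachment
#' node, defined as the cluster member with the smallest path distance to the
#' soma. Always at least the straight-line (Euclidean) soma-attachment
#' distance.
#'
#' @param tree a [NeuronTree-class].
#' @param memberIds ids of the cluster members (must be tree nodes).
#' @return list with \code{path_um}, \code{attachment_id},
#'   \code{euclidean_um}.
#' @export
tuftSomaDistance <- function(tree, memberIds) {
  nd <- treeNodes(tree)
  if (!all(memberIds %in% nd$id))
    stop("cluster member not found in tree: ",
         memberIds[!(memberIds %in% nd$id)][1L])
  pd <- .path_distances(tree)
  dm <- pd[as.character(memberIds)]
  att <- memberIds[which.min(dm)]
  soma <- nd[nd$id == somaId(tree), c("x", "y", "z")]
  an <- nd[nd$id == att, c("x", "y", "z")]
  list(path_um = unname(min(dm)), attachment_id = att,
       euclidean_um = sqrt(sum((soma - an)^2)))
}

#' Mean inter-tuft distance
#'
#' Mean pairwise Euclidean distance between tuft centroids; absent (NA) for
#' cells with fewer than two tufts.
#'
#' @param clusters cluster list from [detectTufts()].
#' @return mean distance in micrometers, or NA.
#' @export
interTuftDistance <- function(clusters) {
  if (length(clusters) < 2L) return(NA_real_)
  cen <- do.call(rbind, lapply(clusters, `[[`, "centroid"))
  mean(dist(cen))
}

#' Classify neurite branches
#'
#' Branches (maximal unbranched segments between the soma, branching points
#' and endpoints) are classified along two axes: primary (originating at the
#' soma) versus secondary, and tufted (on the soma-to-tuft path of at least
#' one tuft, or distal to a tuft attachment) versus basal.
#'
#' @param tree a [NeuronTree-class].
#' @param clusters cluster list from [detectTufts()].
#' @return list with the four counts (\code{primary_tufted},
#'   \code{primary_basal}, \code{secondary_tufted}, \code{secondary_basal})
#'   and the per-branch table (\code{proximal}, \code{distal},
#'   \code{primary}, \code{tufted}).
#' @export
classifyBranches <- function(tree, clusters) {
  nd <- treeNodes(tree)
  soma <- somaId(tree)
  idx <- match(nd$parent, nd$id)
  children <- split(nd$id, factor(nd$parent, levels = nd$id))
  nch <- lengths(children)
  names(nch) <- nd$id
  isCritical <- setNames(nch >= 2L | nch == 0L, nd$id)
  isCritical[as.character(soma)] <- TRUE

  # tufted node set: attachments, their ancestors (to soma, exclusive) and
  # their descendants
  tufted <- character(0)
  if (length(clusters)) {
    pd <- .path_distances(tree)
    atts <- vapply(clusters, function(cl) {
      m <- cl$member_ids
      m[which.min(pd[as.character(m)])]
    }, numeric(1))
    anc <- character(0)
    for (a in atts) {
      cur <- a
      while (cur != soma) {
        anc <- c(anc, as.character(cur))
        cur <- nd$parent[match(cur, nd$id)]
      }
    }
    # descendants: walk in depth order, inherit the flag from the parent
    desc <- setNames(rep(FALSE, nrow(nd)), nd$id)
    desc[as.character(atts)] <- TRUE
    ord <- order(pd)
    for (i in ord) {
      p <- idx[i]
      if (!is.na(p) && desc[p]) desc[i] <- TRUE
    }
    tufted <- unique(c(anc, names(desc)[desc]))
  }

  branches <- list()
  for (c0 in nd$id[isCritical[as.character(nd$id)]]) {
    for (ch in children[[as.character(c0)]]) {
      cur <- ch
      while (!isCritical[as.character(cur)])
        cur <- children[[as.character(cur)]][1L]
      branches[[length(branches) + 1L]] <- data.frame(
        proximal = c0, distal = cur,
        primary = c0 == soma,
        tufted = as.character(cur) %in% tufted)
    }
  }
  tab <- if (length(branches)) do.call(rbind, branches)
         else data.frame(proximal = integer(0), distal = integer(0),
                         primary = logical(0), tufted = logical(0))
  list(primary_tufted = sum(tab$primary & tab$tufted),
       primary_basal = sum(tab$primary & !tab$tufted),
       secondary_tufted = sum(!tab$primary & tab$tufted),
       secondary_basal = sum(!tab$primary & !tab$tufted),
       branches = tab)
}

#' Morphometric profile of one projection neuron
#'
#' Runs critical-point extraction, tuft detection, hull volumes, path and
#' inter-tuft distances and branch classification, returning one row of
#' descriptors.
#'
#' @param tree a [NeuronTree-class].
#' @param eps,minCount tuft-clustering parameters (defaults 15 um / 6).
#' @return one-row data.frame: \code{n_tufts}, \code{mean_tuft_volume_um3},
#'   \code{mean_tuft_soma_distance_um}, \code{mean_inter_tuft_distance_um}
#'   (NA for uni-tufted cells), the four branch-class counts,
#'   \code{multi_tufted}, and \code{degenerate_hulls}.
#' @export
morphometricProfile <- function(tree, eps = 15, minCount = 6L) {
  cp <- criticalPoints(tree)
  tufts <- detectTufts(cp, eps = eps, minCount = minCount)
  cl <- tufts$clusters
  k <- length(cl)
  vols <- if (k) vapply(cl, function(x) tuftVolume(cp, x$member_ids)$volume,
                        numeric(1)) else numeric(0)
  degen <- if (k) vapply(cl, function(x)
    tuftVolume(cp, x$member_ids)$degenerate, logical(1)) else logical(0)
  dists <- if (k) vapply(cl, function(x)
    tuftSomaDistance(tree, x$member_ids)$path_um, numeric(1)) else numeric(0)
  br <- classifyBranches(tree, cl)
  data.frame(
    n_tufts = k,
    mean_tuft_volume_um3 = if (k) mean(vols) else NA_real_,
    mean_tuft_soma_distance_um = if (k) mean(dists) else NA_real_,
    mean_inter_tuft_distance_um = interTuftDistance(cl),
    primary_tufted = br$primary_tufted,
    primary_basal = br$primary_basal,
    secondary_tufted = br$secondary_tufted,
    secondary_basal = br$secondary_basal,
    multi_tufted = k >= 2L,
    degenerate_hulls = sum(degen))
}

#' Compare two projection-neuron populations
#'
#' Descriptor-wise two-sided Mann-Whitney U tests between two populations of
#' [morphometricProfile()] rows, plus the uni/bi/tri+ tuft-class share table.
#' Descriptors absent (all NA) in a population are omitted with a note.
#'
#' @param profilesA,profilesB data.frames of profiles (rows = cells).
#' @param labels group labels for the report.
#' @return list with \code{tests} (data.frame: descriptor, medians, means,
#'   sds, U, p), \code{tuft_shares} (percent uni/bi/tri+ per group), and
#'   \code{omitted} descriptors.
#' @export
populationCompare <- function(profilesA, profilesB,
                              labels = c("A", "B")) {
  stopifnot(nrow(profilesA) > 0L, nrow(profilesB) > 0L)
  descriptors <- c("n_tufts", "mean_tuft_volume_um3",
                   "mean_tuft_soma_distance_um",
                   "mean_inter_tuft_distance_um",
                   "primary_tufted", "primary_basal",
                   "secondary_tufted", "secondary_basal")
  rows <- list()
  omitted <- character(0)
  for (d in descriptors) {
    a <- profilesA[[d]][!is.na(profilesA[[d]])]
    b <- profilesB[[d]][!is.na(profilesB[[d]])]
    if (!length(a) || !length(b)) {
      omitted <- c(omitted, d)
      next
    }
    mw <- mannWhitneyU(a, b)
    rows[[d]] <- data.frame(
      descriptor = d,
      median_a = median(a), median_b = median(b),
      mean_a = mean(a), mean_b = mean(b),
      sd_a = sd(a), sd_b = sd(b),
      U = mw$U, p_value = mw$p_value)
  }
  shares <- function(p) {
    cls <- cut(p$n_tufts, c(-Inf, 1, 2, Inf),
               labels = c("uni", "bi", "tri+"))
    100 * as.numeric(table(cls)) / nrow(p)
  }
  tuftShares <- data.frame(group = labels,
                           rbind(shares(profilesA), shares(profilesB)))
  names(tuftShares)[2:4] <- c("uni_percent", "bi_percent", "tri_plus_percent")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  list(tests = res, tuft_shares = tuftShares, omitted = omitted)
}
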