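#' Topology-preserving thinning of a binary mask
#'
#' Iterative two-subcycle thinning (Zhang-Suen scheme, 8-connectivity)
#' reducing the foreground to a one-pixel-wide skeleton, as done by the
#' ImageJ-style skeletonisation that microglia morphometry workflows rely
#' on. The skeleton is a subset of the foreground and preserves its
#' connectivity.
#'
#' @param mask logical/numeric matrix, foreground = TRUE/positive.
#' @return logical matrix of the same dimensions.
#' @export
thin_mask <- function(mask) {
  m <- as_binary_matrix(mask)
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- lapply(seq_len(8), function(i) {
        shift_mat(m, -NB8[i, 1], -NB8[i, 2]) # value of neighbour i at each pixel
      })
      # p[[1]]=N, 2=NE, 3=E, 4=SE, 5=S, 6=SW, 7=W, 8=NW
      B <- Reduce(`+`, p)
      seqp <- p[c(1:8, 1)]
      A <- Reduce(`+`, lapply(1:8, function(i) (!seqp[[i]]) & seqp[[i + 1]]))
      if (phase == 1) {
        c1 <- !(p[[1]] & p[[3]] & p[[5]])
        c2 <- !(p[[3]] & p[[5]] & p[[7]])
      } else {
        c1 <- !(p[[1]] & p[[3]] & p[[7]])
        c2 <- !(p[[1]] & p[[5]] & p[[7]])
      }
      del <- m & (B >= 2) & (B <= 6) & (A == 1) & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Adjacency with triangle reduction: a diagonal edge is dropped when the
# two pixels also connect through an orthogonal common neighbour on the
# skeleton (the diagonal merely short-circuits a right-angle corner and
# would spuriously raise neighbour counts there). Returns the per-pixel
# neighbour count under this reduced adjacency.
skeleton_neighbour_counts <- function(skel) {
  counts <- matrix(0L, nrow(skel), ncol(skel))
  for (i in seq_len(8)) {
    dr <- NB8[i, 1]; dc <- NB8[i, 2]
    nb <- shift_mat(skel, -dr, -dc)
    if (abs(dr) + abs(dc) == 2L) {
      corner1 <- shift_mat(skel, -dr, 0L) # (r+dr, c)
      corner2 <- shift_mat(skel, 0L, -dc) # (r, c+dc)
      nb <- nb & !(corner1 | corner2)
    }
    counts <- counts + nb
  }
  counts
}

# TRUE if pixels i and j (rows of `pixels`) are adjacent under the
# reduced adjacency used for classification
reduced_adjacent <- function(skel, r1, c1, r2, c2) {
  dr <- r2 - r1; dc <- c2 - c1
  if (max(abs(dr), abs(dc)) != 1L || (dr == 0L && dc == 0L)) return(FALSE)
  if (abs(dr) + abs(dc) == 1L) return(TRUE)
  !(skel[r1 + dr, c1] || skel[r1, c1 + dc])
}

#' Skeletonise a single-cell mask and decompose it into branches
#'
#' Thins the mask, classifies every skeleton pixel by its number of
#' skeleton neighbours (1 or 0 = endpoint, 2 = slab, >= 3 = junction,
#' the AnalyzeSkeleton convention), groups adjacent junction pixels into
#' junction clusters, and walks the slab paths between terminals to
#' extract branches with their path lengths (orthogonal steps count
#' 1 x calibration, diagonal steps sqrt(2) x calibration) and
#' endpoint-to-endpoint Euclidean chords.
#'
#' @param mask a [cell_mask()] or binary matrix.
#' @param calibration micrometres per pixel; defaults to the mask
#'   calibration (0.31 if a bare matrix is given).
#' @return An object of class `skeleton_graph`: list with `skeleton`
#'   (logical matrix), `pixels` (data.frame row/col/class/cluster),
#'   `branches` (list of n x 2 pixel-path matrices), `branch_lengths_um`,
#'   `branch_chords_um`, `junction_cluster_arity` and `calibration`.
#' @export
skeletonize <- function(mask, calibration = NULL) {
  calib <- calibration %||% attr(mask, "calibration") %||% 0.31
  m <- as_binary_matrix(mask)
  gp_assert(any(m), "cannot skeletonize an empty mask", "gp_empty_mask_error")
  nc <- n_components(m)
  if (nc != 1L) {
    gp_stop(
      sprintf("skeletonize() requires a single-component mask; found %d components", nc),
      "gp_multi_component_error"
    )
  }
  skel <- thin_mask(m)
  graph_from_skeleton(skel, calib)
}

# build the branch graph from an already-thinned skeleton
graph_from_skeleton <- function(skel, calibration) {
  nbr <- skeleton_neighbour_counts(skel)
  idx <- which(skel, arr.ind = TRUE)
  counts <- nbr[skel]
  cls <- ifelse(counts <= 1L, "endpoint", ifelse(counts == 2L, "slab", "junction"))

  # junction clusters: 8-connected components of junction pixels
  jmask <- skel & (nbr >= 3L)
  jlab <- label_components(jmask)
  cluster <- rep(NA_integer_, length(cls))
  cluster[cls == "junction"] <- jlab[cbind(idx[cls == "junction", 1], idx[cls == "junction", 2])]

  pixels <- data.frame(
    row = idx[, 1], col = idx[, 2],
    class = cls, cluster = cluster, stringsAsFactors = FALSE
  )

  nr <- nrow(skel)
  key <- function(r, c) (c - 1L) * nr + r
  pix_key <- key(pixels$row, pixels$col)
  lookup <- setNames(seq_len(nrow(pixels)), pix_key)

  neighbours_of <- function(i) {
    r <- pixels$row[i] + NB8[, 1]
    c <- pixels$col[i] + NB8[, 2]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= ncol(skel)
    j <- lookup[as.character(key(r[ok], c[ok]))]
    j <- j[!is.na(j)]
    keep <- vapply(j, function(jj) {
      reduced_adjacent(skel, pixels$row[i], pixels$col[i],
                       pixels$row[jj], pixels$col[jj])
    }, logical(1))
    j[keep]
  }

  is_terminal <- pixels$class != "slab"
  visited_slab <- rep(FALSE, nrow(pixels))
  branches <- list()

  walk <- function(from, first) {
    path <- c(from, first)
    prev <- from; cur <- first
    while (pixels$class[cur] == "slab") {
      visited_slab[cur] <<- TRUE
      nb <- neighbours_of(cur)
      nxt <- setdiff(nb, path)
      if (length(nxt) == 0L) break # closed loop back onto path
      # prefer terminals, then unvisited slabs; a clean slab has one exit
      nxt <- nxt[order(!is_terminal[nxt])][1]
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }

  terminals <- which(is_terminal)
  for (t in terminals) {
    for (nb in neighbours_of(t)) {
      if (pixels$class[nb] == "slab") {
        if (!visited_slab[nb]) {
          branches[[length(branches) + 1L]] <- walk(t, nb)
        }
      } else {
        # direct terminal-terminal adjacency: register once; skip pairs
        # inside the same junction cluster
        same_cluster <- pixels$class[t] == "junction" &&
          pixels$class[nb] == "junction" &&
          identical(pixels$cluster[t], pixels$cluster[nb])
        if (!same_cluster && t < nb) {
          branches[[length(branches) + 1L]] <- c(t, nb)
        }
      }
    }
  }
  # pure cycles with no terminal pixel (rare ring skeletons)
  remaining <- which(pixels$class == "slab" & !visited_slab)
  while (length(remaining) > 0L) {
    start <- remaining[1]
    visited_slab[start] <- TRUE
    nb <- neighbours_of(start)
    if (length(nb) == 0L) {
      remaining <- which(pixels$class == "slab" & !visited_slab)
      next
    }
    path <- walk(start, nb[1])
    visited_slab[path[pixels$class[path] == "slab"]] <- TRUE
    branches[[length(branches) + 1L]] <- path
    remaining <- which(pixels$class == "slab" & !visited_slab)
  }

  path_mats <- lapply(branches, function(p) cbind(row = pixels$row[p], col = pixels$col[p]))
  step_len <- function(pm) {
    if (nrow(pm) < 2L) return(0)
    d <- abs(diff(pm))
    sum(ifelse(rowSums(d) == 2L, sqrt(2), 1)) * calibration
  }
  lens <- vapply(path_mats, step_len, numeric(1))
  chords <- vapply(path_mats, function(pm) {
    sqrt(sum((pm[nrow(pm), ] - pm[1, ])^2)) * calibration
  }, numeric(1))

  # incident branch count per junction cluster
  n_clusters <- max(c(0L, pixels$cluster), na.rm = TRUE)
  arity <- integer(n_clusters)
  for (p in branches) {
    for (endp in c(p[1], p[length(p)])) {
      cl <- pixels$cluster[endp]
      if (!is.na(cl)) arity[cl] <- arity[cl] + 1L
    }
  }

  structure(
    list(
      skeleton = skel, pixels = pixels, branches = path_mats,
      branch_lengths_um = lens, branch_chords_um = chords,
      junction_cluster_arity = arity, calibration = calibration
    ),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d pixels (%d endpoint / %d slab / %d junction), %d branches, calib %.3g um/px\n",
    nrow(x$pixels), sum(x$pixels$class == "endpoint"), sum(x$pixels$class == "slab"),
    sum(x$pixels$class == "junction"), length(x$branches), x$calibration
  ))
  invisible(x)
}

#' Ten skeleton-derived morphometric features
#'
#' Summarises a [skeletonize()] result into the ramification feature
#' block: branch and voxel-class counts, branch-length statistics (in
#' micrometres), the Euclidean chord of the longest branch (a tortuosity
#' indicator: chord equals path length only for straight processes), and
#' the numbers of triple and quadruple points (junction clusters with
#' exactly 3 or 4 incident branches).
#'
#' @param sk a `skeleton_graph`.
#' @param calibration optional override of the graph's calibration.
#' @return named numeric vector of length 10 (see
#'   [skeleton_feature_names()]). An empty skeleton yields zeros.
#' @export
skeleton_feature_vector <- function(sk, calibration = NULL) {
  gp_assert(inherits(sk, "skeleton_graph"), "sk must be a skeleton_graph")
  scale <- 1
  if (!is.null(calibration)) {
    gp_assert(is_scalar_num(calibration) && calibration > 0, "calibration must be > 0")
    scale <- calibration / sk$calibration
  }
  lens <- sk$branch_lengths_um * scale
  chords <- sk$branch_chords_um * scale
  nb <- length(lens)
  longest <- if (nb > 0) which.max(lens) else NA_integer_
  out <- c(
    n_branches = nb,
    n_junction_voxels = sum(sk$pixels$class == "junction"),
    n_endpoint_voxels = sum(sk$pixels$class == "endpoint"),
    n_slab_voxels = sum(sk$pixels$class == "slab"),
    avg_branch_length = if (nb > 0) mean(lens) else 0,
    max_branch_length = if (nb > 0) max(lens) else 0,
    total_branch_length = sum(lens),
    euclidean_distance = if (nb > 0) chords[longest] else 0,
    n_triple_points = sum(sk$junction_cluster_arity == 3L),
    n_quadruple_points = sum(sk$junction_cluster_arity == 4L)
  )
  out[skeleton_feature_names()]
}
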