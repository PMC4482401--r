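#' @title Neuron morphologies from SWC reconstructions
#' @description Read, validate, write and dissect SWC neuron reconstructions
#'   (the 7-column neuromorpho.org dialect), compute the length/volume
#'   statistics the spine-allocation law consumes, generate synthetic binary
#'   dendritic trees, and export NEURON-compatible input bundles.
#' @name morphology
NULL

# SWC structure codes excluded from dendritic accounting: 1 = soma, 2 = axon.
.non_dendritic_codes <- c(1L, 2L)

new_morphology <- function(nodes) {
  structure(list(nodes = nodes), class = "morphology")
}

#' Construct and validate a morphology from a node table
#'
#' @param nodes data.frame with columns `id`, `structure`, `x`, `y`, `z`,
#'   `radius`, `parent` (parent `-1` marks the root). Coordinates and radii
#'   are micrometres, per SWC convention; no unit auto-detection is done.
#' @return An object of class `morphology`.
#' @export
morphology <- function(nodes) {
  required <- c("id", "structure", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    stop("node table must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$structure <- as.integer(nodes$structure)
  nodes$parent <- as.integer(nodes$parent)
  validate_morphology(new_morphology(nodes))
}

validate_morphology <- function(m) {
  nodes <- m$nodes
  if (nrow(nodes) == 0) stop("morphology has no nodes")
  if (anyDuplicated(nodes$id)) {
    stop("structural error: duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (any(!is.finite(nodes$radius)) || any(nodes$radius <= 0)) {
    stop("structural error: radii must be positive and finite")
  }
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0) stop("structural error: no root node (parent -1)")
  if (length(roots) > 1) {
    stop("structural error: multiple roots (nodes ",
         paste(nodes$id[roots], collapse = ", "),
         "); multi-tree SWC files are not supported")
  }
  idx <- match(nodes$parent, nodes$id)
  dangling <- nodes$parent != -1L & is.na(idx)
  if (any(dangling)) {
    stop("structural error: node ", nodes$id[which(dangling)[1]],
         " references absent parent ", nodes$parent[which(dangling)[1]])
  }
  # cycle check: walking to the root must terminate for every node
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    steps <- 0L
    j <- i
    while (!is.na(idx[j])) {
      j <- idx[j]
      steps <- steps + 1L
      if (steps > n) stop("structural error: cycle detected at node ", nodes$id[i])
    }
  }
  m
}

#' @export
print.morphology <- function(x, ...) {
  st <- morpho_stats(x)
  cat(sprintf(
    "<morphology> %d nodes, %d dendritic branches, L = %.1f um, V = %.1f um^3\n",
    nrow(x$nodes), st$n_branches, st$total_length, st$total_volume))
  invisible(x)
}

#' Read an SWC reconstruction
#'
#' Parses a 7-column SWC file (comment lines beginning with `#` allowed) and
#' returns a validated [morphology]. Soma (structure code 1) and axon (code 2)
#' nodes are retained but excluded from dendritic length/volume/branch
#' accounting downstream.
#'
#' @param path path to an SWC file.
#' @return A `morphology` object.
#' @export
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("# toy", "1 1 0 0 0 5 -1", "2 3 0 0 10 1 1"), f)
#' read_swc(f)
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("parse error: no data lines in ", path)
  parsed <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    fields <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1]]
    if (length(fields) != 7) {
      stop("parse error at line ", rows[k], ": expected 7 columns, got ",
           length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop("parse error at line ", rows[k], ": non-numeric field")
    }
    parsed[[k]] <- vals
  }
  tab <- do.call(rbind, parsed)
  nodes <- data.frame(
    id = as.integer(tab[, 1]), structure = as.integer(tab[, 2]),
    x = tab[, 3], y = tab[, 4], z = tab[, 5],
    radius = tab[, 6], parent = as.integer(tab[, 7])
  )
  morphology(nodes)
}

#' Write a morphology as SWC
#'
#' Coordinates and radii are printed with 6 decimals, so a read/write
#' round-trip is lossless at printed precision.
#'
#' @param m a `morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  n <- m$nodes
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   n$id, n$structure, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# SWC written by dendrim", lines), path)
  invisible(path)
}

.is_dendritic <- function(structure) !(structure %in% .non_dendritic_codes)

# Internal edge table: one row per node with a parent, with Euclidean length
# and conical-frustum volume. An edge is dendritic iff its child node is.
.edge_table <- function(m) {
  n <- m$nodes
  has_parent <- n$parent != -1L
  child <- which(has_parent)
  pidx <- match(n$parent[child], n$id)
  dx <- n$x[child] - n$x[pidx]
  dy <- n$y[child] - n$y[pidx]
  dz <- n$z[child] - n$z[pidx]
  h <- sqrt(dx^2 + dy^2 + dz^2)
  r1 <- n$radius[pidx]
  r2 <- n$radius[child]
  vol <- pi * h * (r1^2 + r1 * r2 + r2^2) / 3
  data.frame(
    child = n$id[child], parent = n$parent[child],
    length = h, volume = vol,
    dendritic = .is_dendritic(n$structure[child])
  )
}

#' Dissect a morphology into dendritic branches
#'
#' A branch is a maximal unbranched path whose endpoints are the tree root
#' (or the attachment point on the soma/axon), a dendritic branch point, or a
#' terminal tip. Every dendritic edge belongs to exactly one branch; the
#' root-to-first-branch-point stem counts as a branch.
#'
#' @param m a `morphology`.
#' @return List of `branch` objects, each with `node_path` (ordered node
#'   ids), `length` (um), `volume` (um^3) and `branch_index`. Empty
#'   morphologies (no dendritic nodes) give an empty list.
#' @export
dissect_branches <- function(m) {
  stopifnot(inherits(m, "morphology"))
  n <- m$nodes
  dend <- .is_dendritic(n$structure)
  if (!any(dend)) return(list())
  idx_of <- function(ids) match(ids, n$id)
  pidx <- idx_of(n$parent)            # NA for root
  # dendritic children per node index
  kids <- vector("list", nrow(n))
  for (i in which(dend & !is.na(pidx))) {
    p <- pidx[i]
    kids[[p]] <- c(kids[[p]], i)
  }
  # a dendritic root node has dendritic children too, handled via seeds below
  n_dkids <- vapply(kids, length, integer(1))
  parent_dendritic <- !is.na(pidx) & dend[ifelse(is.na(pidx), 1L, pidx)]
  is_start <- dend & (is.na(pidx) | !parent_dendritic)
  is_junction <- dend & n_dkids >= 2L
  seeds <- which(is_start | (dend & parent_dendritic &
                               is_junction[ifelse(is.na(pidx), 1L, pidx)]))
  seeds <- seeds[order(n$id[seeds])]
  et <- .edge_table(m)
  edge_len <- stats::setNames(et$length, et$child)
  edge_vol <- stats::setNames(et$volume, et$child)
  branches <- vector("list", length(seeds))
  for (b in seq_along(seeds)) {
    v <- seeds[b]
    path <- if (is.na(pidx[v])) integer(0) else pidx[v]
    path <- c(path, v)
    cur <- v
    while (!is_junction[cur] && n_dkids[cur] == 1L) {
      cur <- kids[[cur]][1]
      path <- c(path, cur)
    }
    ids <- n$id[path]
    # edges of the path are those whose child is a path member after the first
    child_ids <- ids[-1]
    l_b <- sum(edge_len[as.character(child_ids)])
    v_b <- sum(edge_vol[as.character(child_ids)])
    branches[[b]] <- structure(
      list(node_path = ids, length = unname(l_b), volume = unname(v_b),
           branch_index = b),
      class = "branch")
  }
  branches
}

#' Morphometric summary of the dendritic tree
#'
#' @param m a `morphology`.
#' @return List with `total_length` L (um, sum of Euclidean parent-child
#'   distances over dendritic edges), `total_volume` V (um^3, sum of conical
#'   frustum volumes \eqn{\pi h (r_1^2 + r_1 r_2 + r_2^2)/3}), `n_branches`
#'   and `n_branch_points`.
#' @export
morpho_stats <- function(m) {
  stopifnot(inherits(m, "morphology"))
  et <- .edge_table(m)
  de <- et[et$dendritic, , drop = FALSE]
  br <- dissect_branches(m)
  # dendritic branch points: dendritic nodes with >= 2 dendritic children
  kid_counts <- table(de$parent)
  dend_ids <- m$nodes$id[.is_dendritic(m$nodes$structure)]
  bp <- sum(kid_counts >= 2 & as.integer(names(kid_counts)) %in% dend_ids)
  list(
    total_length = sum(de$length),
    total_volume = sum(de$volume),
    n_branches = length(br),
    n_branch_points = as.integer(bp)
  )
}

#' Generate a random synthetic binary dendritic tree
#'
#' Grows a soma-rooted random binary tree with exactly `n_branch_points`
#' bifurcations (hence `2 * n_branch_points + 1` dendritic branches). Branch
#' lengths are gamma-distributed around `mean_branch_length` (CV 0.3), radii
#' taper linearly within `radius_range` from branch start to tip. The result
#' is a valid single-root SWC morphology and is byte-reproducible for a fixed
#' seed.
#'
#' @param n_branch_points number of bifurcations (>= 0).
#' @param mean_branch_length mean branch length, um (> 0).
#' @param radius_range length-2 numeric, um; branch start/end radii are drawn
#'   inside this range.
#' @param seed integer seed.
#' @param nodes_per_branch segments per branch (>= 2).
#' @return A `morphology`.
#' @export
#' @examples
#' m <- gen_synthetic_morphology(5, 40, c(0.3, 0.8), seed = 1)
#' length(dissect_branches(m))  # 11 branches
gen_synthetic_morphology <- function(n_branch_points,
                                     mean_branch_length = 40,
                                     radius_range = c(0.3, 0.8),
                                     seed = 1L,
                                     nodes_per_branch = 5L) {
  if (n_branch_points < 0) stop("n_branch_points must be >= 0")
  if (mean_branch_length <= 0) stop("mean_branch_length must be positive")
  if (length(radius_range) != 2 || any(radius_range <= 0)) {
    stop("radius_range must be two positive radii")
  }
  radius_range <- sort(radius_range)
  nodes_per_branch <- max(2L, as.integer(nodes_per_branch))
  with_seed(seed, {
    soma_r <- 6
    nodes <- data.frame(id = 1L, structure = 1L, x = 0, y = 0, z = 0,
                        radius = soma_r, parent = -1L)
    next_id <- 2L
    shape <- 1 / 0.3^2  # gamma with CV 0.3
    grow_branch <- function(parent_id, origin, direction) {
      len <- stats::rgamma(1, shape = shape, rate = shape / mean_branch_length)
      r0 <- stats::runif(1, radius_range[1], radius_range[2])
      r1 <- stats::runif(1, radius_range[1], r0)
      k <- nodes_per_branch
      # random wobble around the nominal direction, renormalized per segment
      seg <- len / k
      pos <- origin
      dirv <- direction / sqrt(sum(direction^2))
      ids <- integer(k)
      for (i in seq_len(k)) {
        wob <- dirv + stats::rnorm(3, sd = 0.25)
        wob <- wob / sqrt(sum(wob^2))
        pos <- pos + wob * seg
        rad <- r0 + (r1 - r0) * i / k
        nodes[nrow(nodes) + 1L, ] <<- list(
          next_id, 3L, pos[1], pos[2], pos[3], rad,
          if (i == 1) parent_id else ids[i - 1])
        ids[i] <- next_id
        next_id <<- next_id + 1L
      }
      list(tip_id = ids[k], tip_pos = pos, tip_dir = wobble_dir(dirv))
    }
    wobble_dir <- function(d) {
      w <- d + stats::rnorm(3, sd = 0.4)
      w / sqrt(sum(w^2))
    }
    stem <- grow_branch(1L, c(0, 0, 0), c(0, 0, 1))
    tips <- list(stem)
    if (n_branch_points > 0) {
      for (b in seq_len(n_branch_points)) {
        pick <- sample.int(length(tips), 1)
        t0 <- tips[[pick]]
        tips[[pick]] <- NULL
        for (d in 1:2) {
          dir_d <- t0$tip_dir + stats::rnorm(3, sd = 0.6)
          tips[[length(tips) + 1L]] <- grow_branch(t0$tip_id, t0$tip_pos, dir_d)
        }
      }
    }
    morphology(nodes)
  })
}

#' Synthetic mouse-cortical-like fixture suite
#'
#' A reproducible set of synthetic morphologies whose branch counts, branch
#' lengths and calibre spread emulate small mouse cortical dendritic trees.
#' The suite is the reference against which the default Cuntz proportionality
#' constant is calibrated (see [cuntz_params()]).
#'
#' @param n_cells number of morphologies.
#' @param seed integer seed.
#' @return List of `morphology` objects.
#' @export
synthetic_cortical_suite <- function(n_cells = 12L, seed = 20150623L) {
  seeds <- derive_seeds(seed, paste0("cell", seq_len(n_cells)))
  res <- vector("list", n_cells)
  with_seed(seed, {
    bp <- sample(10:40, n_cells, replace = TRUE)
    mbl <- stats::runif(n_cells, 25, 60)
    rlo <- stats::runif(n_cells, 0.3, 0.45)
    rhi <- rlo + stats::runif(n_cells, 0.25, 0.5)
    for (i in seq_len(n_cells)) {
      res[[i]] <- gen_synthetic_morphology(bp[i], mbl[i], c(rlo[i], rhi[i]),
                                           seed = seeds[i])
    }
  })
  res
}
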