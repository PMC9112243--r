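#' Neuronal morphology container
#'
#' A rooted tree of 3-D points with SWC semantics: one soma root, each
#' further node attached to a parent that appears earlier in the table.
#'
#' @param nodes data.frame with columns `id`, `parent_id` (-1 for the
#'   root), `type` (1 soma, 3 dendrite, 2 axon), `x`, `y`, `z` (micron),
#'   `radius` (micron).
#' @return `morphology` object.
#' @export
morphology <- function(nodes) {
  req <- c("id", "parent_id", "type", "x", "y", "z", "radius")
  stopifnot(is.data.frame(nodes), all(req %in% names(nodes)))
  m <- structure(list(nodes = nodes[req]), class = "morphology")
  validate_morphology(m)
  m
}

validate_morphology <- function(m) {
  nd <- m$nodes
  roots <- which(nd$parent_id == -1)
  if (length(roots) != 1L)
    stop("morphology must have exactly one root (parent_id -1)")
  if (nd$type[roots] != 1L)
    stop("root node must be of soma type (1)")
  if (anyDuplicated(nd$id)) stop("duplicate node ids")
  pos <- match(nd$parent_id, nd$id)
  bad <- which(nd$parent_id != -1 & is.na(pos))
  if (length(bad))
    stop("orphan node at row ", bad[1], ": parent ",
         nd$parent_id[bad[1]], " not found")
  if (any(nd$parent_id != -1 & pos >= seq_len(nrow(nd))))
    stop("parent must precede child (acyclic, topologic order)")
  if (!all(is.finite(as.matrix(nd[c("x", "y", "z")]))))
    stop("coordinates must be finite")
  invisible(m)
}

#' @export
print.morphology <- function(x, ...) {
  met <- dendrite_metrics(x)
  cat("morphology: ", nrow(x$nodes), " nodes, ",
      round(met$cumulative_length, 1), " um dendrite, ",
      met$n_nodes, " branch points\n", sep = "")
  invisible(x)
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments
#' allowed.  Structural errors (orphan nodes, missing or duplicate root,
#' malformed lines) are reported with the offending line number.
#'
#' @param path file path.
#' @return `morphology`.
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", lineno[bad[1]], " in ", path)
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop("non-numeric field in SWC file ", path)
  nodes <- data.frame(id = as.integer(m[, 1]),
                      parent_id = as.integer(m[, 7]),
                      type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6])
  orphan <- which(nodes$parent_id != -1 &
                    !(nodes$parent_id %in% nodes$id))
  if (length(orphan))
    stop("orphan node at SWC line ", lineno[orphan[1]], ": parent ",
         nodes$parent_id[orphan[1]], " not found in ", path)
  root <- which(nodes$parent_id == -1)
  if (length(root) != 1L)
    stop("SWC file must have exactly one root node: ", path)
  pos <- match(nodes$parent_id, nodes$id)
  if (!any(nodes$parent_id != -1 & pos >= seq_len(nrow(nodes))))
    return(morphology(nodes))   # already parents-first: keep file order
  # otherwise reorder topologically (parents first) via BFS from the root
  ord <- root
  frontier <- nodes$id[root]
  seen <- 1L
  while (length(frontier)) {
    kids <- which(nodes$parent_id %in% frontier)
    kids <- setdiff(kids, ord)
    if (!length(kids)) break
    ord <- c(ord, kids)
    frontier <- nodes$id[kids]
    seen <- seen + length(kids)
  }
  if (seen != nrow(nodes)) {
    left <- setdiff(seq_len(nrow(nodes)), ord)[1]
    stop("cyclic or disconnected SWC node id ", nodes$id[left],
         " in ", path)
  }
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  morphology(nodes)
}

#' Write a morphology to an SWC file
#'
#' Node ids are renumbered contiguously from 1 in topological order;
#' coordinates round-trip losslessly through [read_swc()].
#'
#' @param m `morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  validate_morphology(m)
  nd <- m$nodes
  newid <- seq_len(nrow(nd))
  parent <- ifelse(nd$parent_id == -1, -1L,
                   newid[match(nd$parent_id, nd$id)])
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   newid, nd$type, nd$x, nd$y, nd$z, nd$radius, parent)
  writeLines(c("# SWC exported by matcare", lines), path)
  invisible(path)
}

# Euclidean distance of each node from the soma root
node_soma_dist <- function(m) {
  nd <- m$nodes
  root <- which(nd$parent_id == -1)
  sqrt((nd$x - nd$x[root])^2 + (nd$y - nd$y[root])^2 +
         (nd$z - nd$z[root])^2)
}

# edge table: child row index, parent row index, length, child type
edge_table <- function(m) {
  nd <- m$nodes
  child <- which(nd$parent_id != -1)
  parent <- match(nd$parent_id[child], nd$id)
  len <- sqrt((nd$x[child] - nd$x[parent])^2 +
                (nd$y[child] - nd$y[parent])^2 +
                (nd$z[child] - nd$z[parent])^2)
  data.frame(child = child, parent = parent, length = len,
             type = nd$type[child])
}

#' Sholl profile of a morphology
#'
#' Counts, for each shell radius `r0, r0 + step, ...` (defaults 20-micron
#' shells), the number of dendritic edges whose two endpoint distances from
#' the soma straddle the radius.  An endpoint lying exactly on a shell
#' counts as crossing it.  Radii extend to the maximal node distance.
#'
#' @param m `morphology`.
#' @param r0 first shell radius (micron), default 20.
#' @param step shell spacing (micron), default 20.
#' @return list with `radii` and `intersections` (integer counts).
#' @export
sholl <- function(m, r0 = 20, step = 20) {
  validate_morphology(m)
  d <- node_soma_dist(m)
  ed <- edge_table(m)
  ed <- ed[ed$type == 3L, , drop = FALSE]
  rmax <- max(d)
  if (rmax < r0)
    return(list(radii = numeric(0), intersections = integer(0)))
  radii <- seq(r0, rmax, by = step)
  lo <- pmin(d[ed$child], d[ed$parent])
  hi <- pmax(d[ed$child], d[ed$parent])
  counts <- vapply(radii, function(r) sum(lo <= r & hi >= r), integer(1))
  list(radii = radii, intersections = counts)
}

#' Cumulative length, branch points and soma area
#'
#' Cumulative length sums Euclidean inter-node distances over dendritic
#' edges; `n_nodes` counts branch points (nodes with two or more children);
#' soma area is the circle area `pi * radius^2` of the soma node, or the
#' shoelace polygon area when a soma outline (several soma-type points) is
#' present.
#'
#' @param m `morphology`.
#' @return list `cumulative_length` (micron), `n_nodes`, `soma_area`
#'   (micron^2).
#' @export
dendrite_metrics <- function(m) {
  validate_morphology(m)
  nd <- m$nodes
  ed <- edge_table(m)
  dl <- sum(ed$length[ed$type == 3L])
  kids <- table(factor(ed$parent, levels = seq_len(nrow(nd))))
  n_branch <- sum(kids >= 2)
  soma_rows <- which(nd$type == 1L)
  soma_area <- if (length(soma_rows) >= 3L) {
    x <- nd$x[soma_rows]; y <- nd$y[soma_rows]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  } else {
    pi * nd$radius[which(nd$parent_id == -1)]^2
  }
  list(cumulative_length = dl, n_nodes = as.integer(n_branch),
       soma_area = soma_area)
}

#' Generate a synthetic dendritic tree with ground truth
#'
#' Two modes.  `"binary"`: a deterministic full binary tree of `tree_depth`
#' segment generations, each of exactly `branch_len` micron (depth 0 is a
#' bare soma; depth 2 is a trunk plus two daughters).  `"random"`: a
#' randomized tree in which every segment grows strictly outward from the
#' soma (each child is farther from the soma than its parent, and distance
#' to the soma increases monotonically along every segment), with segment
#' lengths jittered around `branch_len`.  Ground truth records total
#' dendritic length and branch-point count.
#'
#' @param cfg [sim_config()].
#' @param mode `"random"` (default) or `"binary"`.
#' @return `morphology` with a `truth` attribute:
#'   list(total_length, n_branch_points).
#' @export
gen_morphology <- function(cfg, mode = c("random", "binary")) {
  validate_sim_config(cfg)
  mode <- match.arg(mode)
  set.seed(substream_seed(cfg$seed, "morphology"))
  depth <- cfg$tree_depth
  L <- cfg$branch_len
  nodes <- data.frame(id = 1L, parent_id = -1L, type = 1L,
                      x = 0, y = 0, z = 0, radius = cfg$soma_radius)
  total_len <- 0
  n_branch <- 0L
  nid <- 1L

  rand_dir <- function(radial) {
    # outward direction: positive projection on the radial unit vector
    repeat {
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2))
      u <- radial + 0.9 * v
      u <- u / sqrt(sum(u^2))
      if (sum(u * radial) > 0.35) return(u)
    }
  }

  grow <- function(parent_id, pos, dir, lev) {
    if (lev > depth) return(invisible(NULL))
    len <- if (mode == "binary") L else L * stats::runif(1, 0.7, 1.3)
    newpos <- pos + len * dir
    nid <<- nid + 1L
    nodes[nrow(nodes) + 1L, ] <<- list(nid, parent_id, 3L, newpos[1],
                                       newpos[2], newpos[3], 0.5)
    total_len <<- total_len + len
    me <- nid
    if (lev < depth) {
      n_branch <<- n_branch + 1L
      radial <- newpos / sqrt(sum(newpos^2))
      if (mode == "binary") {
        # rotate +-30 degrees in the plane spanned by dir and a normal
        nrm <- if (abs(dir[3]) < 0.9) {
          v <- c(-dir[2], dir[1], 0)
          v / sqrt(sum(v^2))
        } else c(1, 0, 0)
        for (s in c(-1, 1)) {
          ang <- s * pi / 6
          d2 <- cos(ang) * dir + sin(ang) * nrm
          grow(me, newpos, d2, lev + 1L)
        }
      } else {
        for (s in 1:2) grow(me, newpos, rand_dir(radial), lev + 1L)
      }
    }
    invisible(NULL)
  }

  if (depth >= 1L) {
    dir0 <- if (mode == "binary") c(1, 0, 0) else {
      v <- stats::rnorm(3); v / sqrt(sum(v^2))
    }
    grow(1L, c(0, 0, 0), dir0, 1L)
  }
  m <- morphology(nodes)
  attr(m, "truth") <- list(total_length = total_len,
                           n_branch_points = n_branch)
  m
}

#' Classify a dendritic spine from its measurements
#'
#' Ordered decision tree on spine length `L`, head width `HW` and neck
#' width `NW` (all micron): `L > len_filo` filopodia; else `HW > hw_mushroom`
#' mushroom; else `L / max(HW, NW) < ratio_stubby` stubby; else
#' `L > len_long` long_thin; else thin.  Any positive input receives
#' exactly one class at any threshold setting.
#'
#' @param L,HW,NW spine length, head width, neck width (micron), > 0.
#' @param len_filo,hw_mushroom,ratio_stubby,len_long thresholds.
#' @return character class, one of `stubby`, `mushroom`, `thin`,
#'   `long_thin`, `filopodia`.
#' @export
classify_spine <- function(L, HW, NW, len_filo = 2, hw_mushroom = 0.6,
                           ratio_stubby = 1, len_long = 1) {
  stopifnot(L > 0, HW > 0, NW > 0)
  if (L > len_filo) return("filopodia")
  if (HW > hw_mushroom) return("mushroom")
  if (L / max(HW, NW) < ratio_stubby) return("stubby")
  if (L > len_long) return("long_thin")
  "thin"
}

#' Spine density per 10 micron of dendrite
#'
#' @param counts spines counted per segment.
#' @param segment_lengths matching segment lengths (micron).
#' @return list with `pooled` (spines per 10 micron over all segments) and
#'   `per_segment`.
#' @export
spine_density <- function(counts, segment_lengths) {
  stopifnot(length(counts) == length(segment_lengths))
  if (sum(segment_lengths) <= 0) stop("zero total segment length")
  list(pooled = 10 * sum(counts) / sum(segment_lengths),
       per_segment = 10 * counts / segment_lengths)
}
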