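# 2D topology-preserving thinning (Zhang-Suen) and branch-point counting.
# Hand-rolled because the installed R stack has no 2D skeletonization;
# vectorized over the whole image per sub-iteration.

shift2d <- function(m, di, dj) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  if (abs(di) >= d[1] || abs(dj) >= d[2]) return(out)
  si <- max(1, 1 + di):min(d[1], d[1] + di)
  sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

# 8-neighborhood in Zhang-Suen order p2..p9 (N, NE, E, SE, S, SW, W, NW),
# with "north" = decreasing row index
zs_neighbors <- function(m) {
  list(p2 = shift2d(m, -1, 0), p3 = shift2d(m, -1, 1), p4 = shift2d(m, 0, 1),
       p5 = shift2d(m, 1, 1), p6 = shift2d(m, 1, 0), p7 = shift2d(m, 1, -1),
       p8 = shift2d(m, 0, -1), p9 = shift2d(m, -1, -1))
}

# number of 0->1 transitions in the cyclic sequence p2..p9,p2
zs_transitions <- function(nb) {
  seqs <- nb[c("p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9", "p2")]
  a <- matrix(0, nrow(nb$p2), ncol(nb$p2))
  for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
  a
}

#' Skeletonize a 2D binary map
#'
#' Topology-preserving Zhang-Suen thinning to a one-pixel-wide,
#' 8-connected skeleton (the medial axis of each foreground component),
#' followed by removal of residual fully occupied 2x2 blocks so that no
#' skeleton pixel has a complete 2x2 neighborhood.
#'
#' @param map Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
thin_skeleton <- function(map) {
  m <- map > 0
  # the thinning neighborhood needs a border; pad by one and crop after
  d <- dim(m)
  p <- matrix(FALSE, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- m
  m <- p
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- zs_neighbors(m)
      B <- Reduce(`+`, lapply(nb, function(x) x + 0))
      A <- zs_transitions(nb)
      if (step == 1) {
        cond <- !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m <- clean_thick_blocks(m)
  m <- prune_staircases(m)
  m[2:(d[1] + 1), 2:(d[2] + 1), drop = FALSE]
}

# cyclic ring offsets N, NE, E, SE, S, SW, W, NW and their mutual
# 8-adjacency (Chebyshev distance 1 between ring cells)
ring_offsets <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                      c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
ring_adjacency <- local({
  adj <- matrix(FALSE, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    adj[a, b] <- a != b && max(abs(ring_offsets[a, ] - ring_offsets[b, ])) <= 1
  }
  adj
})

# number of 8-connected components among the present ring cells
ring_components <- function(present) {
  idx <- which(present)
  if (length(idx) == 0) return(0L)
  comp <- seq_along(idx)
  repeat {
    changed <- FALSE
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (ring_adjacency[idx[a], idx[b]] && comp[b] != comp[a]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# Remove staircase corner pixels the Zhang-Suen pass leaves behind: a
# degree-2/3 pixel whose foreground neighbors form a single 8-connected
# component, with at most 2 cardinal neighbors, is redundant (its
# neighbors remain mutually connected without it), whereas true
# junctions (e.g. a plus-sign center, 4 cardinal neighbors) are kept.
# Without this pass, corner pixels inflate the branch-point count.
prune_staircases <- function(m) {
  repeat {
    changed <- FALSE
    cand <- which(m)
    for (idx in cand) {
      i <- ((idx - 1) %% nrow(m)) + 1
      j <- ((idx - 1) %/% nrow(m)) + 1
      if (i == 1 || j == 1 || i == nrow(m) || j == ncol(m)) next
      present <- m[cbind(i + ring_offsets[, 1], j + ring_offsets[, 2])]
      deg <- sum(present)
      cardinal <- sum(present[c(1, 3, 5, 7)])
      if (deg >= 2 && deg <= 3 && cardinal <= 2 &&
          ring_components(present) == 1) {
        m[i, j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) return(m)
  }
}

# Remove one simple pixel from any fully occupied 2x2 block left by the
# thinning (rare staircase residue), deterministically.
clean_thick_blocks <- function(m) {
  repeat {
    blocks <- m & shift2d(m, 1, 0) & shift2d(m, 0, 1) & shift2d(m, 1, 1)
    if (!any(blocks)) return(m)
    idx <- which(blocks)[1]
    # blocks marks the bottom-right corner of each fully occupied 2x2
    i <- ((idx - 1) %% nrow(m)) + 1
    j <- ((idx - 1) %/% nrow(m)) + 1
    cand <- rbind(c(i, j), c(i - 1, j), c(i, j - 1), c(i - 1, j - 1))
    nb <- zs_neighbors(m)
    A <- zs_transitions(nb)
    B <- Reduce(`+`, lapply(nb, function(x) x + 0))
    removed <- FALSE
    for (r in seq_len(nrow(cand))) {
      ci <- cand[r, 1]; cj <- cand[r, 2]
      if (A[ci, cj] == 1 && B[ci, cj] > 1) { # simple, not an endpoint
        m[ci, cj] <- FALSE
        removed <- TRUE
        break
      }
    }
    if (!removed) { # fallback: drop the most-connected corner
      r <- which.max(B[cand])
      m[cand[r, 1], cand[r, 2]] <- FALSE
    }
  }
}

#' Count 8-connected skeleton neighbors per pixel
#'
#' @param skel Logical matrix.
#' @return Integer matrix of foreground-neighbor counts.
#' @export
skeleton_neighbor_count <- function(skel) {
  nb <- zs_neighbors(skel > 0)
  Reduce(`+`, lapply(nb, function(x) x + 0L))
}

#' Branch points of a skeleton
#'
#' A branch point is a skeleton pixel where three or more skeleton
#' segments converge. The default `"segments"` rule requires a Rutovitz
#' crossing number of at least 3 (number of background-to-foreground
#' transitions walking the 8-neighborhood ring): on a plus-sign only the
#' center qualifies. The `"neighbors"` rule is the raw count of
#' foreground 8-neighbors, which also fires on pixels in diagonal
#' contact with a perpendicular arm.
#'
#' @param skel Logical skeleton matrix.
#' @param rule `"segments"` (default) or `"neighbors"`.
#' @return Logical matrix marking branch points.
#' @export
branch_points <- function(skel, rule = c("segments", "neighbors")) {
  rule <- match.arg(rule)
  skel <- skel > 0
  if (rule == "neighbors") return(skel & skeleton_neighbor_count(skel) >= 3)
  skel & zs_transitions(zs_neighbors(skel)) >= 3
}

#' Skeleton length and branch-point densities
#'
#' Thins the suprathreshold map to its skeleton, then reports skeleton
#' length density (skeleton pixels / region pixels, a normalized total
#' filament length per unit area) and branch-point density (fraction of
#' skeleton pixels that are branch points, see [branch_points()],
#' quantifying branching/fragmentation of the instability network).
#'
#' @param map Logical matrix (suprathreshold region on the analysis slice).
#' @param branch_rule Passed to [branch_points()].
#' @return A list: `skel_length_density`, `branch_point_density`,
#'   `n_region_px`, `n_skeleton_px`, `n_branch_px`, `skeleton` (matrix).
#' @export
skeleton_metrics <- function(map, branch_rule = "segments") {
  m <- map > 0
  n_region <- sum(m)
  if (n_region == 0) {
    return(list(skel_length_density = NaN, branch_point_density = NaN,
                n_region_px = 0L, n_skeleton_px = 0L, n_branch_px = 0L,
                skeleton = m))
  }
  skel <- thin_skeleton(m)
  n_skel <- sum(skel)
  n_branch <- sum(branch_points(skel, rule = branch_rule))
  list(skel_length_density = n_skel / n_region,
       branch_point_density = if (n_skel > 0) n_branch / n_skel else NaN,
       n_region_px = as.integer(n_region), n_skeleton_px = as.integer(n_skel),
       n_branch_px = as.integer(n_branch), skeleton = skel)
}

# 2D binary opening with a disc structuring element (radius in pixels)
disc_offsets <- function(r_px) {
  g <- expand.grid(di = -r_px:r_px, dj = -r_px:r_px)
  g[g$di^2 + g$dj^2 <= r_px^2, , drop = FALSE]
}

binary_open_2d <- function(map, r_px) {
  offs <- disc_offsets(r_px)
  m <- map > 0
  er <- m
  for (r in seq_len(nrow(offs))) er <- er & shift2d(m, offs$di[r], offs$dj[r])
  di <- er
  for (r in seq_len(nrow(offs))) di <- di | shift2d(er, offs$di[r], offs$dj[r])
  di
}
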