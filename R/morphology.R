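# 3D morphology under 6-connectivity (face neighbours), vectorised with array
# shifts. Used by the body contour, candidate segmentation, Round-Robin growth
# and VOI extraction.

# The six face-neighbour offsets.
face_offsets <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

# out[i,j,k] = a[i+d1, j+d2, k+d3], `fill` outside the grid.
shift3 <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (d[k] >= 0) {
      n <- dm[k] - d[k]
      if (n <= 0) return(out)
      src[[k]] <- seq_len(n) + d[k]
      dst[[k]] <- seq_len(n)
    } else {
      n <- dm[k] + d[k]
      if (n <= 0) return(out)
      src[[k]] <- seq_len(n)
      dst[[k]] <- seq_len(n) - d[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Erosion by the 6-connectivity structuring element: a voxel survives iff it and
# all six face neighbours are in the mask (outside the grid counts as FALSE).
erode6 <- function(mask) {
  out <- mask
  off <- face_offsets()
  for (i in seq_len(nrow(off))) {
    out <- out & shift3(mask, off[i, ], fill = FALSE)
  }
  out
}

#' Connected components under 6-connectivity
#'
#' Labels the face-connected components of a 3D logical mask by vectorised
#' breadth-first frontier expansion (each voxel is visited once). Component
#' ids are 1..K in first-encounter order; background is 0.
#'
#' @param mask 3D logical array.
#' @return Integer array of the same shape with component ids.
#' @export
connected_components <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  d <- dim(mask)
  n <- prod(d)
  lab <- integer(n)
  mv <- as.logical(mask)
  seeds <- which(mv)
  if (length(seeds) == 0L) return(array(lab, d))
  i0 <- seq_len(n) - 1L
  row <- i0 %% d[1]
  col <- (i0 %/% d[1]) %% d[2]
  sli <- i0 %/% (d[1] * d[2])
  step <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
  id <- 0L
  for (s in seeds) {
    if (lab[s] > 0L) next
    id <- id + 1L
    lab[s] <- id
    frontier <- s
    while (length(frontier) > 0L) {
      nb <- c(
        frontier[row[frontier] < d[1] - 1L] + step[1],
        frontier[row[frontier] > 0L] + step[2],
        frontier[col[frontier] < d[2] - 1L] + step[3],
        frontier[col[frontier] > 0L] + step[4],
        frontier[sli[frontier] < d[3] - 1L] + step[5],
        frontier[sli[frontier] > 0L] + step[6]
      )
      nb <- unique(nb[mv[nb] & lab[nb] == 0L])
      lab[nb] <- id
      frontier <- nb
    }
  }
  array(lab, d)
}

# Fill interior holes of a mask: any background component that does not touch
# the grid boundary is set TRUE.
fill_holes <- function(mask) {
  bg <- connected_components(!mask)
  if (max(bg) == 0L) return(mask)
  d <- dim(mask)
  touching <- unique(c(
    bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]
  ))
  touching <- setdiff(touching, 0L)
  mask | (bg != 0L & !(bg %in% touching))
}

# Integer voxel offsets whose physical displacement is within radius_mm.
ball_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(dr = -r[1]:r[1], dc = -r[2]:r[2], ds = -r[3]:r[3])
  d2 <- (g$dr * spacing[1])^2 + (g$dc * spacing[2])^2 + (g$ds * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2, , drop = FALSE])
}
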