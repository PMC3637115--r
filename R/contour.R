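# Marching-squares contour extraction on binary masks.
#
# Pixel (i, j) of the mask (1-based R indexing) sits at 0-based continuous
# coordinates (row = i - 1, col = j - 1); the iso-contour is traced at level
# 0.5, so vertices fall on midpoints of edges between a foreground and a
# background pixel centre. Saddle cells (two diagonal foreground corners)
# are resolved as connected foreground, consistent with the 8-connectivity
# used for object labeling.

# Build the 14-entry case table once. Each case maps to one or two directed
# segments; direction is chosen so that foreground lies on the left of
# travel, which makes segment chaining orientation-consistent.
.ms_case_table <- local({
  corners <- list(TL = c(0, 0), TR = c(0, 1), BL = c(1, 0), BR = c(1, 1))
  mids <- list(top = c(0, 0.5), bottom = c(1, 0.5),
               left = c(0.5, 0), right = c(0.5, 1))
  edges <- list(top = c("TL", "TR"), bottom = c("BL", "BR"),
                left = c("TL", "BL"), right = c("TR", "BR"))
  # Orientation convention: walking from -> to keeps foreground on the
  # left, where "left" of direction d = (dr, dc) is the (-dc, dr) side.
  left_of <- function(d) c(-d[2], d[1])
  orient_towards <- function(m1, m2, target) {
    # direction chosen so that `target` lies on the left of travel
    d <- m2 - m1
    mm <- (m1 + m2) / 2
    if (sum(left_of(d) * (target - mm)) > 0) list(m1, m2) else list(m2, m1)
  }
  tab <- vector("list", 14L)
  for (code in 1:14) {
    fg <- names(corners)[bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L]
    bg <- setdiff(names(corners), fg)
    segs <- list()
    if (!code %in% c(6L, 9L)) {
      mixed <- names(edges)[vapply(edges, function(e)
        sum(e %in% fg) == 1L, logical(1))]
      fgc <- colMeans(do.call(rbind, corners[fg]))
      bgc <- colMeans(do.call(rbind, corners[bg]))
      # fg centroid minus bg centroid points into the foreground half
      m1 <- mids[[mixed[1]]]; m2 <- mids[[mixed[2]]]
      segs[[1]] <- orient_towards(m1, m2, (m1 + m2) / 2 + (fgc - bgc))
    } else {
      # saddle: two diagonal fg corners, resolved as connected foreground;
      # pair the edge midpoints flanking each bg corner, bg corner on the
      # right of travel
      for (b in bg) {
        adj <- names(edges)[vapply(edges, function(e) b %in% e, logical(1))]
        m1 <- mids[[adj[1]]]; m2 <- mids[[adj[2]]]
        sgm <- orient_towards(m1, m2, corners[[b]])
        segs[[length(segs) + 1L]] <- list(sgm[[2]], sgm[[1]])  # bg on right
      }
    }
    tab[[code]] <- lapply(segs, function(s) c(s[[1]], s[[2]]))
  }
  tab
})

# Trace all closed iso-contours of a binary matrix. Returns a list of closed
# loops, each an n x 2 matrix of (row, col) coordinates in the 0-based pixel
# frame of `mask` (vertices are not repeated; the loop closes implicitly).
ms_contours <- function(mask) {
  storage.mode(mask) <- "integer"
  nr0 <- nrow(mask); nc0 <- ncol(mask)
  p <- matrix(0L, nr0 + 2L, nc0 + 2L)
  p[2:(nr0 + 1L), 2:(nc0 + 1L)] <- mask
  nr <- nrow(p); nc <- ncol(p)
  a <- p[-nr, -nc]; b <- p[-nr, -1]; cc <- p[-1, -nc]; d <- p[-1, -1]
  code <- a + 2L * b + 4L * cc + 8L * d
  hit <- which(code > 0L & code < 15L)
  if (length(hit) == 0L) return(list())
  ci <- ((hit - 1L) %% (nr - 1L)) + 1L
  cj <- ((hit - 1L) %/% (nr - 1L)) + 1L
  # each segment: from (r, c) -> to (r, c) in padded coordinates, doubled to
  # give exact integer endpoint keys
  n_seg_per <- ifelse(code[hit] %in% c(6L, 9L), 2L, 1L)
  total <- sum(n_seg_per)
  fr <- numeric(total); fc <- numeric(total)
  tr <- numeric(total); tc <- numeric(total)
  k <- 0L
  for (s in seq_along(hit)) {
    base <- c(ci[s], cj[s])  # cell corner TL = padded pixel (ci, cj) at coord (ci, cj)
    for (seg in .ms_case_table[[code[hit[s]]]]) {
      k <- k + 1L
      fr[k] <- base[1] + seg[1]; fc[k] <- base[2] + seg[2]
      tr[k] <- base[1] + seg[3]; tc[k] <- base[2] + seg[4]
    }
  }
  fkey <- paste(2 * fr, 2 * fc)
  tkey <- paste(2 * tr, 2 * tc)
  nxt <- match(tkey, fkey)
  used <- logical(total)
  loops <- list()
  for (s0 in seq_len(total)) {
    if (used[s0]) next
    cur <- s0
    rows <- numeric(0); cols <- numeric(0)
    repeat {
      used[cur] <- TRUE
      rows <- c(rows, fr[cur]); cols <- c(cols, fc[cur])
      cur <- nxt[cur]
      if (is.na(cur) || used[cur]) break
    }
    # shift from padded to 0-based original pixel coordinates
    loops[[length(loops) + 1L]] <- cbind(row = rows - 2, col = cols - 2)
  }
  loops
}

# Signed area (shoelace) of a closed loop; magnitude used to pick the outer
# contour of an object when holes are present.
poly_area_signed <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  sum(P[, 2] * P[j, 1] - P[j, 2] * P[, 1]) / 2
}

poly_length <- function(P) {
  Q <- rbind(P, P[1L, , drop = FALSE])
  sum(sqrt(rowSums(diff(Q)^2)))
}

# Circular moving-average smoothing of a closed polygon. Applied before
# length measurement to remove the staircase bias of the raw iso-contour
# (which overestimates a digitized disk's perimeter by 6-9%).
poly_smooth <- function(P, window = 5L) {
  n <- nrow(P)
  if (n < 2L * window) return(P)
  h <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, o) ((i + o - 1L) %% n) + 1L)
  cbind(row = rowMeans(matrix(P[idx, 1], n)),
        col = rowMeans(matrix(P[idx, 2], n)))
}
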