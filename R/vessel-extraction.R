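# Vessel masking, centerline extraction and scan-line SV averaging.
#
# Coordinate convention (fixed so ROI files are portable): 0-based, x to the
# right (matrix column - 1), y down (matrix row - 1), pixel centers at
# integer coordinates.

# ---- small binary morphology toolbox (3x3 structuring element) --------------

shift_mat <- function(m, dy, dx, fill = FALSE) {
  ny <- nrow(m)
  nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  ok_y <- ys >= 1 & ys <= ny
  ok_x <- xs >= 1 & xs <= nx
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

dilate3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy != 0 || dx != 0) out <- out | shift_mat(m, dy, dx)
  }
  out
}

erode3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy != 0 || dx != 0) out <- out & shift_mat(m, dy, dx, fill = TRUE)
  }
  out
}

close3 <- function(m) erode3(dilate3(m))

# label 8-connected components; returns integer matrix (0 = background)
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  todo <- which(m & lab == 0L)
  while (length(todo) > 0) {
    cur <- cur + 1L
    frontier <- matrix(FALSE, nrow(m), ncol(m))
    frontier[todo[1]] <- TRUE
    comp <- frontier
    repeat {
      grown <- dilate3(comp) & m
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- cur
    todo <- which(m & lab == 0L)
  }
  lab
}

largest_component <- function(m) {
  lab <- label_components(m)
  if (max(lab) == 0L) return(m & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# ---- ROI polygons ------------------------------------------------------------

#' Read / write a region-of-interest polygon as JSON
#'
#' Polygons are stored as a JSON list of `[x, y]` vertices in the package's
#' pixel convention (0-based, x right, y down, pixel centers at integers).
#'
#' @param roi Numeric matrix or data frame with columns `x`, `y` (>= 3
#'   vertices).
#' @param path JSON file path.
#' @return `read_roi()` returns an n x 2 matrix with columns `x`, `y`.
#' @export
write_roi <- function(roi, path) {
  roi <- check_roi(roi)
  jsonlite::write_json(lapply(seq_len(nrow(roi)), function(i) unname(roi[i, ])),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (is.matrix(v)) v else do.call(rbind, v)
  colnames(m) <- c("x", "y")
  check_roi(m)
}

check_roi <- function(roi) {
  roi <- as.matrix(as.data.frame(roi))
  if (ncol(roi) != 2) abort("`roi` must have two columns (x, y).")
  colnames(roi) <- c("x", "y")
  if (nrow(roi) < 3) abort("`roi` must have at least 3 vertices.")
  roi
}

# logical matrix of pixels whose centers fall inside the polygon
roi_mask <- function(roi, ny, nx) {
  roi <- check_roi(roi)
  px <- rep(0:(nx - 1), each = ny)
  py <- rep(0:(ny - 1), times = nx)
  bnd <- list(x = c(roi[, "x"], roi[1, "x"]), y = c(roi[, "y"], roi[1, "y"]))
  inside <- mgcv::in.out(cbind(bnd$x, bnd$y), cbind(px, py))
  matrix(inside, ny, nx)
}

# ---- operations --------------------------------------------------------------

#' Mask a vessel inside a region of interest
#'
#' Segments the vessel from a mean SV frame: pixels inside the ROI whose SV
#' exceeds the `threshold_quantile` of in-ROI SV values are kept, the
#' largest 8-connected component is selected, and the mask is morphologically
#' closed (3x3).  Works because perfused vessels carry distinctly higher SV
#' than the surrounding tissue.
#'
#' @param mean_sv An `sv_map` (typically from [mean_sv_map()]).
#' @param roi Polygon (matrix/data frame with columns `x`, `y`).
#' @param threshold_quantile Quantile of in-ROI SV values used as the
#'   threshold; `0` keeps every in-ROI pixel (degenerate but allowed).
#' @return A `vessel_mask`: logical matrix with attribute `roi`.
#' @export
mask_vessel <- function(mean_sv, roi, threshold_quantile = 0.5) {
  stopifnot(inherits(mean_sv, "sv_map"))
  if (!is_scalar_number(threshold_quantile) ||
      threshold_quantile < 0 || threshold_quantile > 1) {
    abort("`threshold_quantile` must be in [0, 1].")
  }
  ny <- nrow(mean_sv$values)
  nx <- ncol(mean_sv$values)
  roi <- check_roi(roi)
  if (any(roi[, "x"] < 0 | roi[, "x"] > nx - 1 | roi[, "y"] < 0 | roi[, "y"] > ny - 1)) {
    abort("`roi` vertices fall outside the image bounds.")
  }
  in_roi <- roi_mask(roi, ny, nx)
  sel <- in_roi & mean_sv$valid
  if (!any(sel)) abort("ROI contains no valid SV pixels.")
  thr <- quantile(mean_sv$values[sel], threshold_quantile, names = FALSE)
  above <- sel & !is.na(mean_sv$values) & mean_sv$values > thr
  if (threshold_quantile == 0) {
    mask <- sel
  } else {
    mask <- largest_component(above)
    mask <- close3(mask) & in_roi
  }
  if (!any(mask)) {
    abort("Empty vessel mask for the given ROI; no pixels exceed the SV threshold.")
  }
  structure(mask, class = c("vessel_mask", "matrix", "array"), roi = roi)
}

# ---- centerline --------------------------------------------------------------

# Zhang-Suen thinning to a 1-px-wide skeleton
zhang_suen <- function(m) {
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  p <- function(img, dy, dx) shift_mat(img, dy, dx)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      img <- pad
      # neighbours P2..P9 clockwise from north
      n2 <- p(img, 1, 0);  n3 <- p(img, 1, -1); n4 <- p(img, 0, -1)
      n5 <- p(img, -1, -1); n6 <- p(img, -1, 0); n7 <- p(img, -1, 1)
      n8 <- p(img, 0, 1);  n9 <- p(img, 1, 1)
      nb <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      seqs <- list(n2, n3, n4, n5, n6, n7, n8, n9, n2)
      a <- matrix(0L, nrow(img), ncol(img))
      for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
      if (step == 1) {
        cond <- img & nb >= 2 & nb <= 6 & a == 1 &
          !(n2 & n4 & n6) & !(n4 & n6 & n8)
      } else {
        cond <- img & nb >= 2 & nb <= 6 & a == 1 &
          !(n2 & n4 & n8) & !(n2 & n6 & n8)
      }
      if (any(cond)) {
        pad[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
}

# BFS over the 8-connected skeleton graph from a linear index; returns
# distances (-1 = unreachable) and parents
skel_bfs <- function(idx_set, ny, start) {
  dist <- setNames(rep(-1L, length(idx_set)), idx_set)
  parent <- setNames(rep(NA_integer_, length(idx_set)), idx_set)
  dist[as.character(start)] <- 0L
  queue <- start
  offsets <- c(-1, 1, -ny, ny, -ny - 1, -ny + 1, ny - 1, ny + 1)
  rows <- ((idx_set - 1) %% ny) + 1
  row_of <- setNames(rows, idx_set)
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    for (off in offsets) {
      nb <- cur + off
      key <- as.character(nb)
      if (!is.na(match(key, names(dist))) && dist[key] < 0) {
        # guard against wrap-around between first/last rows
        if (abs(row_of[key] - row_of[as.character(cur)]) <= 1) {
          dist[key] <- dist[as.character(cur)] + 1L
          parent[key] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Extract an ordered vessel centerline from a mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning) and returns the longest
#' geodesic path through the skeleton (double-sweep breadth-first search),
#' as an ordered single-pixel-wide path. Every path pixel lies inside the
#' mask.
#'
#' @param mask A `vessel_mask` (or logical matrix).
#' @return A `centerline`: integer matrix with columns `x`, `y` (0-based
#'   pixel coordinates), ordered along the vessel.
#' @export
extract_centerline <- function(mask) {
  m <- unclass(mask)
  if (!is.matrix(m) || !is.logical(m)) abort("`mask` must be a logical matrix.")
  if (!any(m)) abort("`mask` is empty.")
  if (sum(m) == 1L) {
    idx <- which(m)
    out <- cbind(x = (idx - 1) %/% nrow(m), y = (idx - 1) %% nrow(m))
    return(structure(out, class = c("centerline", "matrix", "array")))
  }
  if (max(label_components(m)) > 1L) {
    abort("`mask` must be a single connected component.")
  }
  skel <- zhang_suen(m)
  if (!any(skel)) skel <- m & FALSE
  if (sum(skel) == 0L) {
    # degenerate: thinning erased everything (tiny blob); use the single
    # most central pixel
    idx <- which(m)[1]
    out <- cbind(x = (idx - 1) %/% nrow(m), y = (idx - 1) %% nrow(m))
    return(structure(out, class = c("centerline", "matrix", "array")))
  }
  ny <- nrow(m)
  idx_set <- which(skel)
  b1 <- skel_bfs(idx_set, ny, idx_set[1])
  far1 <- idx_set[which.max(b1$dist)]
  b2 <- skel_bfs(idx_set, ny, far1)
  far2 <- idx_set[which.max(b2$dist)]
  # walk back along parents
  path <- integer(0)
  cur <- far2
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- b2$parent[as.character(cur)]
  }
  if (length(path) < 0.5 * length(idx_set)) {
    abort("Skeleton is strongly branched with no dominant path; use a tighter ROI around a single vessel.")
  }
  out <- cbind(x = (path - 1) %/% ny, y = (path - 1) %% ny)
  structure(out, class = c("centerline", "matrix", "array"))
}

# ---- per-vessel time series --------------------------------------------------

# per-centerline-point scan-line pixel indices (linear, into a ny x nx image)
scanline_indices <- function(centerline, mask) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  pts <- unclass(centerline)
  n <- nrow(pts)
  lapply(seq_len(n), function(i) {
    i0 <- max(1, i - 2)
    i1 <- min(n, i + 2)
    tangent <- pts[i1, ] - pts[i0, ]
    len <- sqrt(sum(tangent^2))
    if (len == 0) tangent <- c(1, 0) else tangent <- tangent / len
    normal <- c(-tangent[2], tangent[1])
    out <- integer(0)
    for (dir in c(-1, 1)) {
      s <- if (dir == 1) 0 else 1  # include the center point once
      repeat {
        xx <- round(pts[i, 1] + dir * s * normal[1])
        yy <- round(pts[i, 2] + dir * s * normal[2])
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) break
        if (!mask[yy + 1, xx + 1]) break
        out <- c(out, yy + 1 + ny * xx)
        s <- s + 1
      }
    }
    unique(out)
  })
}

#' Per-vessel SV time series by perpendicular scan-line averaging
#'
#' For each frame, SV is sampled along scan lines perpendicular to the local
#' vessel axis (tangent from a +/-2-point central difference along the
#' centerline), restricted to the vessel mask, using nearest-pixel lookup;
#' each scan line is averaged, then the scan-line means are averaged along
#' the centerline, yielding one scalar per frame.  Invalid SV pixels are
#' excluded from the averages; a frame with no valid sample anywhere is
#' returned as `NA`.
#'
#' @param sv_maps An `sv_map_stack`.
#' @param mask A `vessel_mask`.
#' @param centerline A `centerline` (from [extract_centerline()]); every
#'   point must lie inside the mask.
#' @param vessel_id Identifier stored on the series.
#' @return An `sv_series` tibble (`time`, `sv`; `sv` is `NA` for frames with
#'   no valid sample).
#' @export
vessel_sv_timeseries <- function(sv_maps, mask, centerline, vessel_id = "v1") {
  stopifnot(inherits(sv_maps, "sv_map_stack"))
  m <- unclass(mask)
  pts <- unclass(centerline)
  ny <- nrow(m)
  inside <- m[pts[, "y"] + 1 + ny * pts[, "x"]]
  if (!all(inside)) abort("`centerline` has points outside the mask.")
  lines <- scanline_indices(centerline, m)
  keep <- lengths(lines) > 0
  lines <- lines[keep]
  group <- rep(seq_along(lines), lengths(lines))
  allidx <- unlist(lines)
  nt <- dim(sv_maps$values)[3]
  plane <- prod(dim(sv_maps$values)[1:2])
  sv <- vapply(seq_len(nt), function(j) {
    vals <- sv_maps$values[allidx + (j - 1) * plane]
    ok <- sv_maps$valid[allidx + (j - 1) * plane]
    line_means <- tapply(ifelse(ok, vals, NA_real_), group,
                         function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    if (all(is.na(line_means))) NA_real_ else mean(line_means, na.rm = TRUE)
  }, numeric(1))
  new_sv_series(time = (seq_len(nt) - 1) / sv_maps$fps, sv = sv,
                fps = sv_maps$fps, vessel_id = vessel_id)
}
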