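# Graded tensor-product triangulations of the axisymmetric domain.
# Grid lines are placed on every planar tissue interface and on the
# electrode surfaces, with cell size h_fine at the electrode, h_lesion in
# the region swept by the lethal isoline, and h_coarse far away. Each grid
# rectangle is split into two triangles (alternating diagonals); element
# labels come from the tissue map at the element centroid, so planar
# interfaces are conforming while curved fat blobs are voxelized at the
# local resolution.

# Fill (a, b) with points whose spacing follows hfun, marching from the
# finer end so grading is monotone away from the electrode.
fill_interval <- function(a, b, hfun) {
  if (b - a <= 1.01 * min(hfun(a), hfun(b))) return(c(a, b))
  if (hfun(b) < hfun(a)) {
    neg <- fill_interval(-b, -a, function(x) hfun(-x))
    return(rev(-neg))
  }
  xs <- x <- a
  repeat {
    x <- x + hfun(x)
    if (x >= b) break
    xs <- c(xs, x)
  }
  # contract the marched points onto [a, b]; cells only ever shrink, so no
  # spacing exceeds its local target
  t <- (c(xs, x) - a) / (x - a)
  a + t * (b - a)
}

graded_axis <- function(breaks, hfun) {
  breaks <- sort(unique(breaks))
  out <- breaks[1]
  for (k in seq_len(length(breaks) - 1)) {
    seg <- fill_interval(breaks[k], breaks[k + 1], hfun)
    out <- c(out, seg[-1])
  }
  out
}

# Build a labeled triangulation from tensor-product grid lines (mm).
# Elements labeled ELECTRODE / INSULATED_SHAFT are excluded from the
# conductive domain; electrode_fun / ground_fun mark Dirichlet nodes.
tensor_mesh <- function(rl, zl, label_fun, electrode_fun, ground_fun) {
  nr <- length(rl)
  nz <- length(zl)
  nid <- matrix(seq_len(nr * nz), nr, nz)
  rg <- rep(rl, times = nz)
  zg <- rep(zl, each = nr)

  i <- rep(seq_len(nr - 1), times = nz - 1)
  j <- rep(seq_len(nz - 1), each = nr - 1)
  n00 <- nid[cbind(i, j)]
  n10 <- nid[cbind(i + 1, j)]
  n01 <- nid[cbind(i, j + 1)]
  n11 <- nid[cbind(i + 1, j + 1)]
  even <- (i + j) %% 2L == 0L
  t1 <- cbind(n00, n10, ifelse(even, n11, n01))
  t2 <- cbind(ifelse(even, n00, n10), n11, n01)
  tri <- rbind(t1, t2)

  cr <- (rg[tri[, 1]] + rg[tri[, 2]] + rg[tri[, 3]]) / 3
  cz <- (zg[tri[, 1]] + zg[tri[, 2]] + zg[tri[, 3]]) / 3
  lab <- label_fun(cr, cz)
  if (anyNA(lab)) stop("mesh elements outside all labeled regions")
  keep <- !(lab %in% c("ELECTRODE", "INSULATED_SHAFT"))
  tri <- tri[keep, , drop = FALSE]
  lab <- lab[keep]

  used <- sort(unique(as.vector(tri)))
  renum <- integer(nr * nz)
  renum[used] <- seq_along(used)
  tri <- matrix(renum[tri], ncol = 3)
  r_mm <- rg[used]
  z_mm <- zg[used]

  # SI coordinates for assembly
  x <- r_mm * 1e-3
  y <- z_mm * 1e-3
  x1 <- x[tri[, 1]]; x2 <- x[tri[, 2]]; x3 <- x[tri[, 3]]
  y1 <- y[tri[, 1]]; y2 <- y[tri[, 2]]; y3 <- y[tri[, 3]]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(area2 <= 0)) stop("degenerate or inverted mesh element")
  area <- area2 / 2
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / area2
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / area2
  rbar <- (x1 + x2 + x3) / 3

  # 3x3 element geometric stiffness, row-major flattening
  w <- 2 * pi * rbar * area
  geo <- matrix(0, nrow(tri), 9)
  for (a_ in 1:3) for (b_ in 1:3)
    geo[, (a_ - 1) * 3 + b_] <- w * (b[, a_] * b[, b_] + cc[, a_] * cc[, b_])
  ii <- as.vector(t(tri[, rep(1:3, each = 3)]))
  jj <- as.vector(t(tri[, rep(1:3, times = 3)]))

  el <- which(electrode_fun(r_mm, z_mm))
  gr <- setdiff(which(ground_fun(r_mm, z_mm)), el)
  if (!length(el)) stop("no electrode nodes found")
  if (!length(gr)) stop("no ground boundary found; system would be singular")

  grid_node <- matrix(NA_integer_, nr, nz)
  grid_node[used] <- seq_along(used)

  structure(list(rl = rl, zl = zl, r_mm = r_mm, z_mm = z_mm,
                 node_grid_id = used, grid_node = grid_node,
                 nr = nr, nz = nz,
                 tri = tri, label = lab, area = area, rbar = rbar,
                 grad_b = b, grad_c = cc, geo = geo,
                 asm_i = ii, asm_j = jj,
                 idx_electrode = el, idx_ground = gr,
                 n_nodes = length(r_mm), n_elements = nrow(tri)),
            class = "fem_mesh")
}

#' Generate a graded finite-element mesh for a tissue map
#'
#' @param map a [build_model()] tissue map
#' @param h_fine target edge length at the electrode surface (mm)
#' @param h_coarse cell size at the domain boundary (mm)
#' @param h_lesion cell size in the region swept by the lethal isoline (mm)
#' @param lesion_box c(rmax, zmax) extent (mm) of the h_lesion region
#' @return object of class `fem_mesh`
#' @export
generate_mesh <- function(map, h_fine = 0.05, h_coarse = 1.5,
                          h_lesion = 0.15, lesion_box = c(10, 7)) {
  stopifnot(h_fine < h_coarse, h_fine <= h_lesion)
  spec <- map$spec
  rel <- spec$electrode_diameter / 2
  ztip <- spec$insertion_depth
  zetop <- ztip - spec$electrode_length
  grow <- 0.45  # spacing increase per mm of distance from the electrode

  hr <- function(r) {
    cap <- ifelse(r <= lesion_box[1] + 1e-9, h_lesion, h_coarse)
    pmin(cap, pmax(h_fine, h_fine + grow * pmax(0, r - rel)))
  }
  hz <- function(z) {
    d <- pmax(0, pmax(zetop - z, z - ztip))
    cap <- ifelse(z >= -1e-9 & z <= lesion_box[2] + 1e-9, h_lesion, h_coarse)
    pmin(cap, pmax(h_fine, h_fine + grow * d))
  }

  br <- c(0, rel, lesion_box[1], map$rmax)
  bz <- c(map$zmin, zetop, 0, ztip, lesion_box[2],
          spec$wall_thickness,
          spec$wall_thickness + spec$epicardial_fat_thickness, map$zmax)
  if (!is.null(map$scar)) {
    sc <- map$scar
    br <- c(br, sc$channel_width / 2, sc$main_fat_slab_radius,
            sc$scar_width / 2)
    bz <- c(bz, sc$rim_thickness, sc$main_fat_slab_top,
            sc$main_fat_slab_bottom, sc$scar_depth_extent)
  }
  br <- sort(unique(pmin(pmax(br, 0), map$rmax)))
  bz <- sort(unique(pmin(pmax(bz, map$zmin), map$zmax)))
  br <- br[c(TRUE, diff(br) > 1e-9)]
  bz <- bz[c(TRUE, diff(bz) > 1e-9)]

  rl <- graded_axis(br, hr)
  zl <- graded_axis(bz, hz)

  tol <- 1e-6
  electrode_fun <- function(r, z)
    (abs(r - rel) < tol & z >= zetop - tol & z <= ztip + tol) |
    (abs(z - ztip) < tol & r <= rel + tol)
  ground_fun <- function(r, z)
    r > map$rmax - tol | z < map$zmin + tol | z > map$zmax - tol

  m <- tensor_mesh(rl, zl, function(r, z) label_points(map, r, z),
                   electrode_fun, ground_fun)
  m$map <- map
  m$h_fine <- h_fine
  m$h_lesion <- h_lesion
  m$h_coarse <- h_coarse
  m
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat("Axisymmetric FEM mesh:", x$n_nodes, "nodes,",
      x$n_elements, "triangles\n")
  cat("  labels:", paste(names(table(x$label)), table(x$label),
                         collapse = ", "), "\n")
  cat("  electrode nodes:", length(x$idx_electrode),
      " ground nodes:", length(x$idx_ground), "\n")
  invisible(x)
}
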