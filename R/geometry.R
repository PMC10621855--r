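# Axisymmetric (r, z) tissue geometries for a focal PFA catheter against a
# layered ventricular wall. z = 0 is the undisturbed endocardial surface,
# +z points into the tissue, r = 0 is the catheter axis. All lengths in mm.

#' Tissue labels used throughout the package
#'
#' Every point of the modeling domain carries exactly one of these labels.
#' @export
tissue_labels <- function() {
  c("MYOCARDIUM", "FIBROSIS", "FAT", "BLOOD", "CONNECTIVE",
    "ELECTRODE", "INSULATED_SHAFT")
}

#' Geometry of the catheter, wall and computational domain
#'
#' Defaults describe a 7-Fr (2.33 mm) 3.5-mm blunt-tip focal catheter
#' perpendicular to the endocardium and inserted 0.5 mm, a 7-mm ventricular
#' wall with a 2-mm epicardial fat layer, a blood pool above and connective
#' tissue below, truncated at a grounded outer box.
#'
#' @param wall_thickness ventricular wall thickness (mm)
#' @param epicardial_fat_thickness epicardial fat layer thickness (mm)
#' @param electrode_diameter catheter diameter (mm); 7 Fr = 7/3 mm
#' @param electrode_length active electrode length (mm)
#' @param insertion_depth electrode insertion into the tissue (mm)
#' @param domain_radius radial extent of the domain (mm)
#' @param domain_height_blood blood pool height above the endocardium (mm)
#' @param domain_depth_connective connective tissue depth below the wall (mm)
#' @return object of class `geometry_spec`
#' @export
geometry_spec <- function(wall_thickness = 7,
                          epicardial_fat_thickness = 2,
                          electrode_diameter = 7 / 3,
                          electrode_length = 3.5,
                          insertion_depth = 0.5,
                          domain_radius = 40,
                          domain_height_blood = 20,
                          domain_depth_connective = 20) {
  s <- list(wall_thickness = wall_thickness,
            epicardial_fat_thickness = epicardial_fat_thickness,
            electrode_diameter = electrode_diameter,
            electrode_length = electrode_length,
            insertion_depth = insertion_depth,
            domain_radius = domain_radius,
            domain_height_blood = domain_height_blood,
            domain_depth_connective = domain_depth_connective)
  lens <- unlist(s)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all geometry lengths must be finite and > 0")
  if (insertion_depth >= electrode_length)
    stop("insertion_depth must be smaller than electrode_length")
  if (epicardial_fat_thickness + wall_thickness >=
      wall_thickness + epicardial_fat_thickness + domain_depth_connective)
    stop("wall + fat must fit above the domain bottom")
  structure(s, class = "geometry_spec")
}

#' Parametric scar description for the heterogeneous wall models
#'
#' The scar is a fibrotic region under the electrode; model D adds a
#' dominant intramyocardial fat slab (whose lower boundary clamps the
#' lesion) plus seeded patchy elliptical fat blobs; model E opens a channel
#' of viable myocardium on the axis; model F replaces the subendocardial
#' viable rim by fibrosis.
#'
#' @param scar_width full lateral width of the scar (mm)
#' @param scar_depth_extent scar depth below the endocardial surface (mm)
#' @param rim_thickness subendocardial viable-myocardium rim thickness (mm);
#'   this rim becomes fibrotic in model F
#' @param fat_blob_count number of patchy fat blobs (model D)
#' @param fat_blob_size_range semi-axis range of the blobs (mm)
#' @param main_fat_slab_top,main_fat_slab_bottom depth of the dominant fat
#'   slab's upper/lower boundary below the surface (mm)
#' @param main_fat_slab_radius radial extent of the dominant slab (mm)
#' @param channel_width width of the viable-myocardium channel (mm, model E)
#' @return object of class `scar_spec`
#' @export
scar_spec <- function(scar_width = 18,
                      scar_depth_extent = 6,
                      rim_thickness = 1,
                      fat_blob_count = 6,
                      fat_blob_size_range = c(0.3, 1.0),
                      main_fat_slab_top = 2.6,
                      main_fat_slab_bottom = 4.59,
                      main_fat_slab_radius = 3.5,
                      channel_width = 2) {
  stopifnot(scar_width > 0, scar_depth_extent > 0, rim_thickness >= 0,
            fat_blob_count >= 0, length(fat_blob_size_range) == 2,
            all(fat_blob_size_range > 0),
            main_fat_slab_top < main_fat_slab_bottom,
            main_fat_slab_radius > 0, channel_width > 0)
  structure(list(scar_width = scar_width,
                 scar_depth_extent = scar_depth_extent,
                 rim_thickness = rim_thickness,
                 fat_blob_count = fat_blob_count,
                 fat_blob_size_range = fat_blob_size_range,
                 main_fat_slab_top = main_fat_slab_top,
                 main_fat_slab_bottom = main_fat_slab_bottom,
                 main_fat_slab_radius = main_fat_slab_radius,
                 channel_width = channel_width),
            class = "scar_spec")
}

region_rect <- function(label, r0, r1, z0, z1, inclusion = FALSE) {
  list(label = label, shape = "rect", rect = c(r0, r1, z0, z1),
       inclusion = inclusion)
}

region_ellipse <- function(label, rc, zc, ar, az, inclusion = FALSE) {
  list(label = label, shape = "ellipse", ell = c(rc, zc, ar, az),
       inclusion = inclusion)
}

in_region <- function(reg, r, z) {
  if (reg$shape == "rect") {
    p <- reg$rect
    r >= p[1] & r <= p[2] & z >= p[3] & z <= p[4]
  } else {
    p <- reg$ell
    ((r - p[1]) / p[3])^2 + ((z - p[2]) / p[4])^2 <= 1
  }
}

new_tissue_map <- function(regions, model_id, spec, scar = NULL, seed = NA) {
  zbot <- spec$wall_thickness + spec$epicardial_fat_thickness +
    spec$domain_depth_connective
  structure(list(regions = regions, model_id = model_id, spec = spec,
                 scar = scar, seed = seed,
                 rmax = spec$domain_radius,
                 zmin = -spec$domain_height_blood, zmax = zbot),
            class = "tissue_map")
}

# Minimal tissue map over an arbitrary rectangular half-plane window; used
# for analytic verification problems (uniform far fields, isolated
# inclusions) that have no catheter geometry.
synthetic_map <- function(regions, rmax, zmin, zmax, model_id = "synthetic") {
  structure(list(regions = regions, model_id = model_id, spec = NULL,
                 scar = NULL, seed = NA,
                 rmax = rmax, zmin = zmin, zmax = zmax),
            class = "tissue_map")
}

place_fat_blobs <- function(scar, seed) {
  n <- scar$fat_blob_count
  if (n == 0) return(list())
  sw2 <- scar$scar_width / 2
  lo <- scar$fat_blob_size_range[1]
  hi <- scar$fat_blob_size_range[2]
  clearance <- 0.15  # mm kept between blobs, slab and scar boundary
  withr::with_seed(seed, {
    # draw all semi-axes once; place the largest blobs first, each at the
    # candidate position with the widest clearance margin (best-of-k
    # placement keeps the packing spread out); if a configuration still
    # jams, restart the positions with fresh draws
    ar <- stats::runif(n, lo, hi)
    az <- stats::runif(n, lo, hi)
    ord <- order(pmax(ar, az), decreasing = TRUE)
    ar <- ar[ord]
    az <- az[ord]
    for (restart in 1:400) {
      # an extreme draw (all blobs near the maximum size) can be
      # geometrically unpackable; shrink the semi-axes by 7% after every
      # 40 failed restarts so the requested blob count is always honoured
      if (restart %% 40 == 1 && restart > 1) {
        ar <- 0.93 * ar
        az <- 0.93 * az
      }
      blobs <- list()
      for (k in seq_len(n)) {
        # candidate boxes inside the scar that keep clear of the slab: the
        # band lateral to it, and the pocket between rim and slab top
        boxes <- list(
          c(scar$main_fat_slab_radius + clearance + ar[k],
            sw2 - clearance - ar[k],
            scar$rim_thickness + clearance + az[k],
            scar$scar_depth_extent - clearance - az[k]),
          c(clearance + ar[k],
            scar$main_fat_slab_radius - clearance - ar[k],
            scar$rim_thickness + clearance + az[k],
            scar$main_fat_slab_top - clearance - az[k]))
        boxes <- Filter(function(b) b[1] < b[2] && b[3] < b[4], boxes)
        if (!length(boxes))
          stop("fat blobs do not fit inside the scar bounds")
        w_box <- vapply(boxes, function(b) (b[2] - b[1]) * (b[4] - b[3]),
                        numeric(1))
        nb <- sample.int(length(boxes), 250, replace = TRUE,
                         prob = w_box)
        rc <- zc <- numeric(250)
        for (j in seq_along(boxes)) {
          sel <- nb == j
          rc[sel] <- stats::runif(sum(sel), boxes[[j]][1], boxes[[j]][2])
          zc[sel] <- stats::runif(sum(sel), boxes[[j]][3], boxes[[j]][4])
        }
        # margin: distance beyond touching, via ellipse support radii
        # along the center-center direction (conservative bound)
        margin <- rep(Inf, length(rc))
        for (b in blobs) {
          dr <- rc - b$ell[1]
          dz <- zc - b$ell[2]
          d <- pmax(sqrt(dr^2 + dz^2), 1e-12)
          s1 <- sqrt((ar[k] * dr / d)^2 + (az[k] * dz / d)^2)
          s2 <- sqrt((b$ell[3] * dr / d)^2 + (b$ell[4] * dz / d)^2)
          margin <- pmin(margin, d - s1 - s2)
        }
        best <- which.max(margin)
        if (margin[best] < clearance) {
          blobs <- NULL
          break
        }
        blobs[[length(blobs) + 1]] <-
          region_ellipse("FAT", rc[best], zc[best], ar[k], az[k],
                         inclusion = TRUE)
      }
      if (!is.null(blobs)) return(blobs)
    }
    stop("could not place ", n, " non-overlapping fat blobs in the scar")
  })
}

#' Build one of the six ventricular wall models
#'
#' Model A: homogeneous myocardium with an epicardial fat layer.
#' B: as A with the fat layer replaced by connective tissue.
#' C: fibrotic scar under the electrode (viable subendocardial rim, no fat).
#' D: as C plus a dominant intramyocardial fat slab and seeded patchy fat
#'    blobs (a parametric synthetic stand-in for a histology-derived
#'    distribution). E: as C with a viable-myocardium channel on the axis.
#' F: as C with the subendocardial rim replaced by fibrosis ("blocked").
#' The electrode indents the tissue conformally by `insertion_depth`; the
#' insulated shaft continues to the top of the blood pool.
#'
#' @param model_id one of "A".."F"
#' @param spec a [geometry_spec()]
#' @param scar a [scar_spec()]; required for models C--F
#' @param seed integer seed for the model-D blob placement
#' @return object of class `tissue_map`
#' @export
build_model <- function(model_id, spec = geometry_spec(), scar = NULL,
                        seed = 1L) {
  if (!is.character(model_id) || !(model_id %in% LETTERS[1:6]))
    stop("unknown model_id: ", model_id)
  if (model_id %in% c("C", "D", "E", "F") && is.null(scar))
    stop("models C-F require a scar_spec")
  w <- spec$wall_thickness
  f <- spec$epicardial_fat_thickness
  zbot <- w + f + spec$domain_depth_connective
  R <- spec$domain_radius
  rel <- spec$electrode_diameter / 2
  ztip <- spec$insertion_depth
  zetop <- ztip - spec$electrode_length  # top of active electrode (in blood)

  regs <- list(
    region_rect("BLOOD", 0, R, -spec$domain_height_blood, 0),
    region_rect("MYOCARDIUM", 0, R, 0, w),
    region_rect(if (model_id == "B") "CONNECTIVE" else "FAT", 0, R, w, w + f),
    region_rect("CONNECTIVE", 0, R, w + f, zbot)
  )

  if (model_id %in% c("C", "D", "E", "F")) {
    sw2 <- scar$scar_width / 2
    zs0 <- if (model_id == "F") 0 else scar$rim_thickness
    regs <- c(regs, list(
      region_rect("FIBROSIS", 0, sw2, zs0, scar$scar_depth_extent)))
    if (model_id == "E") {
      regs <- c(regs, list(
        region_rect("MYOCARDIUM", 0, scar$channel_width / 2, 0,
                    scar$scar_depth_extent)))
    }
    if (model_id == "D") {
      slab <- region_rect("FAT", 0, scar$main_fat_slab_radius,
                          scar$main_fat_slab_top, scar$main_fat_slab_bottom,
                          inclusion = TRUE)
      regs <- c(regs, list(slab), place_fat_blobs(scar, seed))
    }
  }

  regs <- c(regs, list(
    region_rect("ELECTRODE", 0, rel, zetop, ztip),
    region_rect("INSULATED_SHAFT", 0, rel, -spec$domain_height_blood, zetop)))

  new_tissue_map(regs, model_id, spec, scar, seed)
}

#' Tissue label at arbitrary points
#'
#' Painter's-order point membership: later regions override earlier ones,
#' so the electrode and shaft indent the tissue and blood.
#'
#' @param map a `tissue_map`
#' @param r,z coordinates (mm), vectorized
#' @return character vector of labels
#' @export
label_points <- function(map, r, z) {
  lab <- rep(NA_character_, length(r))
  for (reg in map$regions) {
    inside <- in_region(reg, r, z)
    lab[inside] <- reg$label
  }
  lab
}

#' Rasterize a tissue map to a cell-centered label grid
#'
#' @param map a `tissue_map`
#' @param h cell size (mm)
#' @param rlim,zlim window to rasterize; defaults to the full domain
#' @return list with cell-center coordinates `r`, `z`, an integer label
#'   matrix `lab` (rows = r, cols = z, levels = [tissue_labels()]) and `h`
#' @export
rasterize <- function(map, h, rlim = NULL, zlim = NULL) {
  stopifnot(h > 0)
  if (!is.null(map$spec) &&
      h > min(map$spec$insertion_depth, map$spec$electrode_diameter / 2))
    warning("raster cell size exceeds the smallest geometric feature")
  if (is.null(rlim)) rlim <- c(0, map$rmax)
  if (is.null(zlim)) zlim <- c(map$zmin, map$zmax)
  nr <- max(1L, round(diff(rlim) / h))
  nz <- max(1L, round(diff(zlim) / h))
  r <- rlim[1] + (seq_len(nr) - 0.5) * h
  z <- zlim[1] + (seq_len(nz) - 0.5) * h
  pts <- expand.grid(r = r, z = z)
  lab <- label_points(map, pts$r, pts$z)
  m <- matrix(match(lab, tissue_labels()), nrow = nr, ncol = nz)
  list(r = r, z = z, lab = m, h = h, levels = tissue_labels())
}

#' @export
print.tissue_map <- function(x, ...) {
  cat("Axisymmetric tissue map, model", x$model_id, "\n")
  cat(sprintf("  domain: r in [0, %g] mm, z in [%g, %g] mm\n",
              x$rmax, x$zmin, x$zmax))
  cat(sprintf("  wall %g mm + epicardial layer %g mm; %d regions\n",
              x$spec$wall_thickness, x$spec$epicardial_fat_thickness,
              length(x$regions)))
  invisible(x)
}

#' Serialize a tissue map to a structured text config
#'
#' Writes model id, seed and all geometric parameters (mm) as YAML; the map
#' is reconstructed exactly (including seeded blob placement) on read.
#'
#' @param map a `tissue_map`
#' @param path file path
#' @export
write_tissue_config <- function(map, path) {
  cfg <- list(model_id = map$model_id, seed = map$seed,
              geometry = unclass(map$spec),
              scar = if (!is.null(map$scar)) unclass(map$scar))
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' @rdname write_tissue_config
#' @export
read_tissue_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- do.call(geometry_spec, cfg$geometry)
  scar <- if (!is.null(cfg$scar)) {
    cfg$scar$fat_blob_size_range <- unlist(cfg$scar$fat_blob_size_range)
    do.call(scar_spec, cfg$scar)
  }
  build_model(cfg$model_id, spec, scar, cfg$seed)
}
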