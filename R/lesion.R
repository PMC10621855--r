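# Lethal-isoline lesion metrics. The |E| >= threshold superlevel set is
# evaluated on a fine structured resampling grid of the tissue half-plane;
# only the connected component in contact with the electrode counts as the
# ablation lesion (distant superlevel pockets inside fat are reported as
# satellites). Depth is the maximum z of that component below the
# undisturbed endocardial surface; surface width is twice its maximum
# radius in the first tissue row at z = 0+. The lesion extent is measured
# on every tissue the isoline reaches, not only myocardium.

CONDUCTIVE_TISSUES <- c("MYOCARDIUM", "FIBROSIS", "FAT", "CONNECTIVE")

# Core metric computation from a sampled field matrix; exposed internally
# so analytic fields can be pushed through the identical code path.
lesion_metrics_core <- function(E_mat, lab_mat, r, z, h, threshold_Vm,
                                seed_mask = NULL, levels = tissue_labels()) {
  lab_chr <- matrix(levels[lab_mat], nrow = nrow(lab_mat))
  tissue <- matrix(lab_chr %in% CONDUCTIVE_TISSUES, nrow = nrow(lab_mat))
  lesion <- tissue & !is.na(E_mat) & E_mat >= threshold_Vm

  empty <- list(depth = 0, surface_width = 0, volume = 0,
                clamped_to_fat = FALSE, clamp_z = NA_real_,
                n_satellites = 0L)
  if (!any(lesion)) return(empty)

  comp <- EBImage::bwlabel(lesion)
  if (is.null(seed_mask)) {
    el <- matrix(lab_chr == "ELECTRODE", nrow = nrow(lab_mat))
    seed_mask <- dilate_once(el)
    if (!any(seed_mask)) {
      # no electrode in the window: seed at the surface cell on the axis
      seed_mask <- matrix(FALSE, nrow(lab_mat), ncol(lab_mat))
      seed_mask[1, 1] <- TRUE
      seed_mask <- dilate_once(seed_mask)
    }
  }
  ids <- setdiff(unique(comp[seed_mask & lesion]), 0)
  all_ids <- setdiff(unique(as.vector(comp)), 0)
  if (!length(ids)) {
    empty$n_satellites <- length(all_ids)
    return(empty)
  }
  main <- matrix(comp %in% ids, nrow = nrow(comp))

  cells <- which(main, arr.ind = TRUE)
  rc <- r[cells[, 1]]
  zc <- z[cells[, 2]]
  depth <- max(zc) + h / 2
  surf <- main[, 1]
  surface_width <- if (any(surf)) 2 * (max(r[surf]) + h / 2) else 0
  volume <- sum(2 * pi * rc * h^2)

  # fat clamping: deepest cell sits in fat with non-fat right below
  kdeep <- which.max(zc)
  id <- cells[kdeep, 1]
  jd <- cells[kdeep, 2]
  lab_deep <- lab_chr[id, jd]
  lab_below <- if (jd < ncol(lab_chr)) lab_chr[id, jd + 1] else NA
  clamped <- identical(lab_deep, "FAT") && !identical(lab_below, "FAT")

  list(depth = depth, surface_width = surface_width, volume = volume,
       clamped_to_fat = clamped,
       clamp_z = if (clamped) depth else NA_real_,
       n_satellites = length(setdiff(all_ids, ids)))
}

dilate_once <- function(m) {
  out <- m
  out[-1, ] <- out[-1, ] | m[-nrow(m), ]
  out[-nrow(m), ] <- out[-nrow(m), ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -ncol(m)]
  out[, -ncol(m)] <- out[, -ncol(m)] | m[, -1]
  out
}

sample_field_window <- function(sol, h, rmax, zmax) {
  map <- sol$mesh$map
  stopifnot(!is.null(map))
  rmax <- min(rmax, map$rmax)
  zmax <- min(zmax, map$zmax)
  ras <- rasterize(map, h, rlim = c(0, rmax), zlim = c(0, zmax))
  pts <- expand.grid(r = ras$r, z = ras$z)
  lab_chr <- ras$levels[as.vector(ras$lab)]
  f <- field_at_points(sol, pts$r, pts$z, label = lab_chr)
  E_mat <- matrix(f$E_mag, nrow = length(ras$r))
  list(ras = ras, E_mat = E_mat)
}

#' Extract lethal-field isolines
#'
#' Marching-squares interpolation (via [grDevices::contourLines]) of the
#' resampled |E| field over the tissue half-plane.
#'
#' @param sol a `field_solution`
#' @param threshold lethal field threshold (V/cm)
#' @param h resampling cell size (mm)
#' @param rmax,zmax resampling window (mm)
#' @return list of polylines, each a data.frame with `r`, `z` (mm); empty
#'   when the threshold exceeds the global field maximum
#' @export
extract_isoline <- function(sol, threshold = 1000, h = 0.025,
                            rmax = 12, zmax = 9) {
  sw <- sample_field_window(sol, h, rmax, zmax)
  lab_chr <- sw$ras$levels[as.vector(sw$ras$lab)]
  E <- sw$E_mat
  E[!(lab_chr %in% CONDUCTIVE_TISSUES)] <- 0
  E[is.na(E)] <- 0
  cl <- grDevices::contourLines(sw$ras$r, sw$ras$z, E,
                                levels = threshold * 100)
  lapply(cl, function(s) data.frame(r = s$x, z = s$y))
}

#' Lesion size metrics from the lethal isoline
#'
#' @param sol a `field_solution` (converged, with a tissue map)
#' @param threshold lethal field threshold (V/cm, default 1000)
#' @param h resampling cell size (mm)
#' @param rmax,zmax resampling window (mm); enlarge for very wide lesions
#' @param with_isoline also attach the isoline polylines
#' @return object of class `lesion_metrics`: depth (mm), surface_width
#'   (mm), revolved volume (mm^3), fat-clamping diagnostic and satellite
#'   superlevel-pocket count
#' @export
lesion_size <- function(sol, threshold = 1000, h = 0.025,
                        rmax = 12, zmax = 9, with_isoline = FALSE) {
  sw <- sample_field_window(sol, h, rmax, zmax)
  m <- lesion_metrics_core(sw$E_mat, sw$ras$lab, sw$ras$r, sw$ras$z,
                           h, threshold * 100, levels = sw$ras$levels)
  m$threshold <- threshold
  m$V_applied <- sol$V_applied
  m$I_delivered <- sol$I_delivered
  m$model_id <- sol$mesh$map$model_id
  m$isoline <- if (with_isoline)
    extract_isoline(sol, threshold, h, rmax, zmax)
  class(m) <- "lesion_metrics"
  m
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf(
    "Lesion (>= %g V/cm): depth %.2f mm, surface width %.2f mm\n",
    x$threshold, x$depth, x$surface_width))
  cat(sprintf("  volume %.1f mm^3; clamped to fat: %s; satellites: %d\n",
              x$volume, x$clamped_to_fat, x$n_satellites))
  invisible(x)
}

#' Classify field hot and cold points around fat inclusions
#'
#' Current avoids poorly conducting fat: boundary zones where the local
#' current direction is near the inclusion normal (entry/exit points) see a
#' depressed exterior field (cold points), while laterally oriented
#' boundary zones see an enhanced field (hot points).
#'
#' @param sol a `field_solution` whose tissue map contains fat inclusions
#'   (dominant slab and/or blobs); returns an empty frame otherwise
#' @param E_ref reference field magnitude (V/m); when NULL, the median |E|
#'   on a ring at 1.6x the inclusion size is used per inclusion
#' @param offset sampling distance outside the inclusion boundary (mm)
#' @param n_boundary boundary samples per inclusion
#' @param cold_frac,hot_frac classification thresholds relative to E_ref
#' @return data.frame with inclusion id, location, type (HOT/COLD), |E|
#'   (V/cm), alignment cosine and the reference field (V/cm)
#' @export
hotcold_points <- function(sol, E_ref = NULL, offset = 0.15,
                           n_boundary = 64, cold_frac = 0.5,
                           hot_frac = 1.25) {
  map <- sol$mesh$map
  empty <- data.frame(inclusion = integer(), r = numeric(), z = numeric(),
                      type = character(), E_Vcm = numeric(),
                      align = numeric(), E_ref_Vcm = numeric())
  if (is.null(map)) return(empty)
  inc <- Filter(function(rg) isTRUE(rg$inclusion), map$regions)
  if (!length(inc)) return(empty)

  out <- list()
  for (k in seq_along(inc)) {
    reg <- inc[[k]]
    bd <- inclusion_boundary(reg, n_boundary)
    ps <- data.frame(r = bd$r + offset * bd$nr,
                     z = bd$z + offset * bd$nz,
                     nr = bd$nr, nz = bd$nz)
    ps <- ps[ps$r >= 0 & ps$r <= map$rmax &
               ps$z > map$zmin & ps$z < map$zmax, ]
    lab <- label_points(map, ps$r, ps$z)
    ps <- ps[!(lab %in% c("FAT", "ELECTRODE", "INSULATED_SHAFT")), ]
    if (!nrow(ps)) next
    f <- field_at_points(sol, ps$r, ps$z)
    Em <- f$E_mag
    u <- cbind(f$Er, f$Ez) / pmax(Em, 1e-12)
    align <- abs(u[, 1] * ps$nr + u[, 2] * ps$nz)

    ref <- if (!is.null(E_ref)) E_ref else
      inclusion_reference(sol, map, reg)
    type <- rep(NA_character_, nrow(ps))
    type[align >= cos(30 * pi / 180) & Em < cold_frac * ref] <- "COLD"
    type[align <= cos(60 * pi / 180) & Em > hot_frac * ref] <- "HOT"
    keep <- !is.na(type)
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(
        inclusion = k, r = ps$r[keep], z = ps$z[keep], type = type[keep],
        E_Vcm = Em[keep] / 100, align = align[keep],
        E_ref_Vcm = ref / 100)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

inclusion_boundary <- function(reg, n) {
  if (reg$shape == "ellipse") {
    p <- reg$ell
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    r <- p[1] + p[3] * cos(th)
    z <- p[2] + p[4] * sin(th)
    nr <- cos(th) / p[3]
    nz <- sin(th) / p[4]
    nn <- sqrt(nr^2 + nz^2)
    list(r = r, z = z, nr = nr / nn, nz = nz / nn)
  } else {
    p <- reg$rect  # r0, r1, z0, z1; skip the r0 face if on the axis
    m <- max(8L, n %/% 4)
    faces <- list(
      list(r = seq(p[1], p[2], length.out = m), z = rep(p[3], m),
           nr = 0, nz = -1),
      list(r = seq(p[1], p[2], length.out = m), z = rep(p[4], m),
           nr = 0, nz = 1),
      list(r = rep(p[2], m), z = seq(p[3], p[4], length.out = m),
           nr = 1, nz = 0))
    if (p[1] > 1e-9)
      faces <- c(faces, list(list(r = rep(p[1], m),
                                  z = seq(p[3], p[4], length.out = m),
                                  nr = -1, nz = 0)))
    list(r = unlist(lapply(faces, `[[`, "r")),
         z = unlist(lapply(faces, `[[`, "z")),
         nr = unlist(lapply(faces, function(f) rep(f$nr, m))),
         nz = unlist(lapply(faces, function(f) rep(f$nz, m))))
  }
}

inclusion_reference <- function(sol, map, reg, n = 48) {
  if (reg$shape == "ellipse") {
    ctr <- reg$ell[1:2]
    rad <- 1.6 * max(reg$ell[3:4])
  } else {
    p <- reg$rect
    ctr <- c((p[1] + p[2]) / 2, (p[3] + p[4]) / 2)
    rad <- 1.6 * sqrt(((p[2] - p[1]) / 2)^2 + ((p[4] - p[3]) / 2)^2)
  }
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- ctr[1] + rad * cos(th)
  z <- ctr[2] + rad * sin(th)
  ok <- r >= 0 & r <= map$rmax & z > map$zmin & z < map$zmax
  lab <- label_points(map, r[ok], z[ok])
  good <- !(lab %in% c("FAT", "ELECTRODE", "INSULATED_SHAFT"))
  f <- field_at_points(sol, r[ok][good], z[ok][good])
  stats::median(f$E_mag, na.rm = TRUE)
}
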