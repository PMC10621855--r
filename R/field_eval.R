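# Pointwise evaluation of a field solution. The FEM field is constant per
# element; for resampling it is first recovered to the nodes by
# volume-weighted averaging done separately per tissue label, so the
# physical |E| jump across conductivity interfaces is preserved exactly
# instead of being smeared by the averaging. A query point is evaluated
# bilinearly from the nodal values of its own tissue's recovery.

recover_nodal <- function(sol) {
  if (!is.null(sol$nodal_recovery)) return(sol$nodal_recovery)
  mesh <- sol$mesh
  n <- mesh$n_nodes
  w <- mesh$area * mesh$rbar
  labs <- c(unique(mesh$label), ".ALL")

  one_label <- function(els) {
    num_r <- num_z <- num_m <- den <- numeric(n)
    for (k in 1:3) {
      idx <- mesh$tri[els, k]
      s <- rowsum(cbind(w[els] * sol$Er[els], w[els] * sol$Ez[els],
                        w[els] * sol$E_mag[els], w[els]), group = idx)
      at <- as.integer(rownames(s))
      num_r[at] <- num_r[at] + s[, 1]
      num_z[at] <- num_z[at] + s[, 2]
      num_m[at] <- num_m[at] + s[, 3]
      den[at] <- den[at] + s[, 4]
    }
    has <- den > 0
    list(Er = ifelse(has, num_r / den, NA_real_),
         Ez = ifelse(has, num_z / den, NA_real_),
         E_mag = ifelse(has, num_m / den, NA_real_))
  }

  rec <- lapply(labs, function(L) {
    els <- if (L == ".ALL") seq_len(mesh$n_elements) else
      which(mesh$label == L)
    one_label(els)
  })
  names(rec) <- labs
  rec
}

locate_cells <- function(mesh, r, z) {
  i <- pmin(pmax(findInterval(r, mesh$rl), 1L), mesh$nr - 1L)
  j <- pmin(pmax(findInterval(z, mesh$zl), 1L), mesh$nz - 1L)
  tr <- (r - mesh$rl[i]) / (mesh$rl[i + 1] - mesh$rl[i])
  tz <- (z - mesh$zl[j]) / (mesh$zl[j + 1] - mesh$zl[j])
  list(i = i, j = j,
       tr = pmin(pmax(tr, 0), 1), tz = pmin(pmax(tz, 0), 1),
       n00 = mesh$grid_node[cbind(i, j)],
       n10 = mesh$grid_node[cbind(i + 1L, j)],
       n01 = mesh$grid_node[cbind(i, j + 1L)],
       n11 = mesh$grid_node[cbind(i + 1L, j + 1L)])
}

bilinear <- function(v00, v10, v01, v11, tr, tz) {
  v00 * (1 - tr) * (1 - tz) + v10 * tr * (1 - tz) +
    v01 * (1 - tr) * tz + v11 * tr * tz
}

corner_vals <- function(rec, lab, corner, all_rec, what) {
  v <- rep(NA_real_, length(corner))
  ok <- !is.na(corner)
  allv <- all_rec[[what]]
  v[ok] <- allv[corner[ok]]
  for (L in unique(lab[ok])) {
    arr <- rec[[L]]
    if (is.null(arr)) next
    sel <- which(ok & lab == L)
    lv <- arr[[what]][corner[sel]]
    miss <- is.na(lv)
    lv[miss] <- allv[corner[sel][miss]]
    v[sel] <- lv
  }
  v
}

#' Sample a field solution at arbitrary points
#'
#' @param sol a `field_solution`
#' @param r,z query coordinates (mm)
#' @param label optional tissue labels of the query points (computed from
#'   the solution's tissue map when omitted); points labeled ELECTRODE get
#'   phi = V_applied and E = 0
#' @return data.frame with `phi` (V), `Er`, `Ez`, `E_mag` (V/m), `label`
#' @export
field_at_points <- function(sol, r, z, label = NULL) {
  mesh <- sol$mesh
  if (is.null(label)) {
    label <- if (!is.null(mesh$map)) label_points(mesh$map, r, z)
    else rep(".ALL", length(r))
  }
  rec <- recover_nodal(sol)
  loc <- locate_cells(mesh, r, z)

  phi_node <- sol$phi
  getn <- function(corner) ifelse(is.na(corner), NA_real_, phi_node[corner])
  phi <- bilinear(getn(loc$n00), getn(loc$n10), getn(loc$n01),
                  getn(loc$n11), loc$tr, loc$tz)

  out <- data.frame(phi = phi, Er = NA_real_, Ez = NA_real_,
                    E_mag = NA_real_,
                    label = label, stringsAsFactors = FALSE)
  for (what in c("Er", "Ez", "E_mag")) {
    v00 <- corner_vals(rec, label, loc$n00, rec$.ALL, what)
    v10 <- corner_vals(rec, label, loc$n10, rec$.ALL, what)
    v01 <- corner_vals(rec, label, loc$n01, rec$.ALL, what)
    v11 <- corner_vals(rec, label, loc$n11, rec$.ALL, what)
    out[[what]] <- bilinear(v00, v10, v01, v11, loc$tr, loc$tz)
  }
  inside <- which(label %in% c("ELECTRODE", "INSULATED_SHAFT"))
  if (length(inside)) {
    out$phi[inside] <- ifelse(label[inside] == "ELECTRODE",
                              sol$V_applied, NA_real_)
    out$Er[inside] <- out$Ez[inside] <- out$E_mag[inside] <- 0
  }
  out
}

#' Potential and field along the catheter axis
#'
#' Samples phi and |E| along r = 0 from the undisturbed tissue surface
#' down into the wall: the
#' potential decays monotonically while |E| jumps upward wherever the
#' conductivity drops (fat, connective tissue).
#'
#' @param sol a `field_solution`
#' @param z_max profile depth (mm)
#' @param dz sample spacing (mm)
#' @return data.frame with `z_mm`, `phi_V`, `E_Vcm`, `label`
#' @export
axis_profile <- function(sol, z_max = 15, dz = 0.05) {
  z <- seq(0, z_max, by = dz)
  f <- field_at_points(sol, rep(0, length(z)), z)
  data.frame(z_mm = z, phi_V = f$phi, E_Vcm = f$E_mag / 100,
             label = f$label, stringsAsFactors = FALSE)
}
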