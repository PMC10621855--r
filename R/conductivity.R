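# Field-dependent tissue conductivity. Electroporation opens cell
# membranes, raising bulk conductivity from its low-frequency value sigma0
# to the post-electroporation value sigma1; the transition with local field
# magnitude |E| is a sigmoid centered at E_center with width E_slope.
# Tissues without viable cell membranes (scar, fat, blood, connective) have
# sigma0 = sigma1 and stay field-independent.

#' Electrical properties of the modeled tissues
#'
#' Conductivities in S/m: myocardium 0.4 (pre) to 0.6 (post
#' electroporation); fibrotic scar 0.85; fat 0.08 (an alternative published
#' tabulation gives 0.015 -- selectable for sensitivity runs); blood 0.6;
#' connective tissue (50/50 skeletal muscle and fat mix) 0.115. The sigmoid
#' transition is centered at 58 kV/m with a 3 kV/m slope and prefactor 10.
#'
#' @param fat_sigma fat conductivity (S/m)
#' @param myo_sigma0,myo_sigma1 myocardium pre/post conductivities (S/m)
#' @param scar_sigma,blood_sigma,connective_sigma field-independent values (S/m)
#' @param E_center sigmoid center field (V/m)
#' @param E_slope sigmoid slope (V/m)
#' @param prefactor dimensionless sigmoid prefactor
#' @return object of class `tissue_properties`
#' @export
tissue_properties <- function(fat_sigma = 0.08,
                              myo_sigma0 = 0.4, myo_sigma1 = 0.6,
                              scar_sigma = 0.85, blood_sigma = 0.6,
                              connective_sigma = 0.115,
                              E_center = 58000, E_slope = 3000,
                              prefactor = 10) {
  tab <- data.frame(
    label  = c("MYOCARDIUM", "FIBROSIS", "FAT", "BLOOD", "CONNECTIVE"),
    sigma0 = c(myo_sigma0, scar_sigma, fat_sigma, blood_sigma,
               connective_sigma),
    sigma1 = c(myo_sigma1, scar_sigma, fat_sigma, blood_sigma,
               connective_sigma),
    stringsAsFactors = FALSE)
  if (any(tab$sigma0 < 0) || any(tab$sigma1 < tab$sigma0))
    stop("need sigma1 >= sigma0 >= 0 for every tissue")
  structure(list(table = tab, E_center = E_center, E_slope = E_slope,
                 prefactor = prefactor),
            class = "tissue_properties")
}

#' Conductivity at a given field magnitude
#'
#' sigma(E) = sigma0 + (sigma1 - sigma0) /
#'            (1 + prefactor * exp(-(|E| - E_center) / E_slope)).
#' Tissues with sigma0 == sigma1 return that constant for all E.
#'
#' @param label tissue label(s); recycled against `E_mag`
#' @param E_mag field magnitude (V/m), >= 0
#' @param props a [tissue_properties()]
#' @return conductivity in S/m
#' @export
sigma_of_E <- function(label, E_mag, props = tissue_properties()) {
  if (any(E_mag < 0)) stop("E_mag must be non-negative")
  n <- max(length(label), length(E_mag))
  label <- rep_len(label, n)
  E_mag <- rep_len(E_mag, n)
  i <- match(label, props$table$label)
  if (anyNA(i)) stop("no conductivity defined for label(s): ",
                     paste(unique(label[is.na(i)]), collapse = ", "))
  s0 <- props$table$sigma0[i]
  s1 <- props$table$sigma1[i]
  out <- s0
  nl <- which(s1 > s0)
  if (length(nl)) {
    sig <- 1 / (1 + props$prefactor *
                  exp(-(E_mag[nl] - props$E_center) / props$E_slope))
    out[nl] <- s0[nl] + (s1[nl] - s0[nl]) * sig
  }
  out
}

#' Write / read a tissue property table as a structured text config
#'
#' @param props a [tissue_properties()]
#' @param path file path
#' @export
write_tissue_properties <- function(props, path) {
  yaml::write_yaml(list(
    sigma0 = stats::setNames(as.list(props$table$sigma0), props$table$label),
    sigma1 = stats::setNames(as.list(props$table$sigma1), props$table$label),
    E_center = props$E_center, E_slope = props$E_slope,
    prefactor = props$prefactor), path, precision = 17)
  invisible(path)
}

#' @rdname write_tissue_properties
#' @export
read_tissue_properties <- function(path) {
  cfg <- yaml::read_yaml(path)
  s0 <- unlist(cfg$sigma0)
  s1 <- unlist(cfg$sigma1)
  tissue_properties(
    fat_sigma = s0[["FAT"]],
    myo_sigma0 = s0[["MYOCARDIUM"]], myo_sigma1 = s1[["MYOCARDIUM"]],
    scar_sigma = s0[["FIBROSIS"]], blood_sigma = s0[["BLOOD"]],
    connective_sigma = s0[["CONNECTIVE"]],
    E_center = cfg$E_center, E_slope = cfg$E_slope,
    prefactor = cfg$prefactor)
}
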