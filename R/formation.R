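#' Formation-analysis context constants
#'
#' Physical constants and experiment geometry entering the vesicle
#' concentration and lipid-yield calculations. Defaults correspond to a
#' 3 x 3 tile acquisition of a 332.8 um square field (total imaged area
#' 0.9968 mm^2) in an 8-well chambered slide (bottom 80.91 mm^2), a 5 nm
#' bilayer, a 0.71 nm^2 lipid headgroup, a 790 g/mol mean lipid molar mass
#' and 20 ug of deposited lipid.
#'
#' @param A_Img Total imaged area, mm^2.
#' @param A_Well Well bottom area, mm^2.
#' @param V_Well Volume of GUV suspension loaded into the well, uL.
#' @param V_Form Formation volume, uL.
#' @param d_bilayer Bilayer thickness, nm.
#' @param A_hg Lipid headgroup area, nm^2.
#' @param M_l Mean lipid molar mass, g/mol.
#' @param m Deposited lipid mass, ug.
#' @param N_A Avogadro constant, 1/mol.
#' @return List of class `FormationContext`.
#' @export
formation_context <- function(A_Img = 0.9968, A_Well = 80.91, V_Well = 10,
                              V_Form = 500, d_bilayer = 5, A_hg = 0.71,
                              M_l = 790, m = 20, N_A = 6.02214076e23) {
  ctx <- list(A_Img = A_Img, A_Well = A_Well, V_Well = V_Well,
              V_Form = V_Form, d_bilayer = d_bilayer, A_hg = A_hg,
              M_l = M_l, m = m, N_A = N_A)
  bad <- names(ctx)[!vapply(ctx, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("formation context field not a positive number: ",
         paste(bad, collapse = ", "))
  structure(ctx, class = "FormationContext")
}

.check_ctx <- function(ctx, fields) {
  for (f in fields)
    if (is.null(ctx[[f]]) || !is.finite(ctx[[f]]))
      stop("missing formation context field: ", f)
}

#' Total bilayer surface area of a vesicle
#'
#' Both leaflets of the bilayer contribute: the outer leaflet is a sphere of
#' the measured (Feret) diameter, the inner leaflet a concentric sphere
#' smaller by twice the bilayer thickness, so
#' `A = 4*pi*(d/2)^2 + 4*pi*(d/2 - d_bilayer)^2`.
#'
#' @param d_guv Vesicle diameter, um (vectorized).
#' @param d_bilayer Bilayer thickness, nm.
#' @return Surface area, um^2.
#' @export
guv_surface_area <- function(d_guv, d_bilayer = 5) {
  db_um <- d_bilayer / 1000
  if (any(d_guv <= 2 * db_um))
    stop("vesicle diameter must exceed twice the bilayer thickness")
  4 * pi * (d_guv / 2)^2 + 4 * pi * (d_guv / 2 - db_um)^2
}

.feret_of <- function(rois) {
  if (is.numeric(rois)) rois else rois$feret_um
}

#' Vesicle concentration in the loaded suspension
#'
#' Counts detected vesicles with Feret diameter inside `size_range`, converts
#' to a surface density over the imaged area, scales to the whole well bottom
#' and divides by the loaded suspension volume:
#' `N / A_Img * A_Well / V_Well`, reported per mL.
#'
#' @param rois A `guv_rois` table (or a numeric vector of Feret diameters,
#'   um).
#' @param ctx A [formation_context()].
#' @param size_range Diameter acceptance band, um.
#' @return Concentration, GUVs per mL.
#' @export
concentration <- function(rois, ctx = formation_context(),
                          size_range = c(5, 20)) {
  .check_ctx(ctx, c("A_Img", "A_Well", "V_Well"))
  d <- .feret_of(rois)
  n <- sum(d >= size_range[1] & d <= size_range[2])
  n / ctx$A_Img * ctx$A_Well / ctx$V_Well * 1000  # uL -> mL
}

#' Fraction of vesicles inside a size band
#'
#' @inheritParams concentration
#' @return Fraction in `[0, 1]`; an empty input gives 0 with a warning.
#' @export
size_fraction <- function(rois, size_range = c(5, 20)) {
  d <- .feret_of(rois)
  if (length(d) == 0) {
    warning("no vesicles: size fraction of an empty set reported as 0")
    return(0)
  }
  mean(d >= size_range[1] & d <= size_range[2])
}

#' Lipid yield of a GUV formation
#'
#' Converts detected vesicle surface areas into a lipid count (both leaflets,
#' via [guv_surface_area()] divided by the headgroup area), extrapolates from
#' the imaged area to the whole formation
#' (`* A_Well * V_Form / (A_Img * V_Well)`), converts to mass through the
#' Avogadro constant and mean lipid molar mass, and reports the percentage of
#' the deposited lipid mass recovered as GUVs.
#'
#' @inheritParams concentration
#' @return Yield, percent.
#' @export
lipid_yield <- function(rois, ctx = formation_context()) {
  .check_ctx(ctx, c("A_Img", "A_Well", "V_Well", "V_Form", "d_bilayer",
                    "A_hg", "M_l", "m", "N_A"))
  d <- .feret_of(rois)
  if (length(d) == 0) return(0)
  n_lipids_imaged <- sum(guv_surface_area(d, ctx$d_bilayer)) * 1e6 / ctx$A_hg
  n_lipids_total <- n_lipids_imaged *
    (ctx$A_Well * ctx$V_Form) / (ctx$A_Img * ctx$V_Well)
  mass_g <- n_lipids_total / ctx$N_A * ctx$M_l
  100 * mass_g / (ctx$m * 1e-6)
}

#' Slide-well geometry for coated-surface calculations
#'
#' Describes the wetted geometry of a microscopy well so the coated surface
#' (bottom + walls, minus channel openings) can be computed. The
#' `rounding` policy replicates how intermediate values are conventionally
#' reported: the rectangular-well chain rounds the derived wall height to
#' `digits` decimals; the circular-well chain truncates intermediate areas to
#' `digits` decimals when `mode = "truncate"`.
#'
#' @param kind `"rect_well"` or `"circular_well"`.
#' @param width,length Bottom edge lengths (rectangular), mm.
#' @param diameter Bottom diameter (circular), mm.
#' @param wall_height Coated wall height, mm; for rectangular wells it is
#'   derived from `coating_volume / bottom area` when `NULL`.
#' @param coating_volume Coating solution volume, uL.
#' @param channel_correction Wall area removed by channel openings, mm^2.
#' @param rounding `list(digits =, mode = "round"|"truncate")` for
#'   intermediate values.
#' @return List of class `SlideGeometry`.
#' @export
slide_geometry <- function(kind = c("rect_well", "circular_well"),
                           width = NULL, length = NULL, diameter = NULL,
                           wall_height = NULL, coating_volume,
                           channel_correction = 0,
                           rounding = list(digits = 2, mode = "round")) {
  kind <- match.arg(kind)
  stopifnot(channel_correction >= 0, coating_volume > 0)
  structure(list(kind = kind, width = width, length = length,
                 diameter = diameter, wall_height = wall_height,
                 coating_volume = coating_volume,
                 channel_correction = channel_correction,
                 rounding = rounding),
            class = "SlideGeometry")
}

#' @rdname slide_geometry
#' @export
slide_geometry_8well <- function(coating_volume = 200)
  slide_geometry("rect_well", width = 8.7, length = 9.3,
                 coating_volume = coating_volume)

#' @rdname slide_geometry
#' @export
slide_geometry_ibidi <- function(coating_volume = 30)
  slide_geometry("circular_well", diameter = 5.5, wall_height = 1.7,
                 coating_volume = coating_volume, channel_correction = 1,
                 rounding = list(digits = 2, mode = "truncate"))

.apply_rounding <- function(x, rounding) {
  if (is.null(rounding)) return(x)
  if (identical(rounding$mode, "truncate"))
    trunc(x * 10^rounding$digits) / 10^rounding$digits
  else round(x, rounding$digits)
}

#' Coated surface area of a slide well
#'
#' Rectangular wells: bottom `w*l`; the wall height is the coating volume
#' divided by the bottom area (rounded per policy); wall area = perimeter *
#' height; total = bottom + wall. Circular wells: bottom `pi*(d/2)^2` and
#' wall `pi*d*h` (each reported at the rounding policy), total = bottom +
#' wall - channel correction.
#'
#' @param geom A [slide_geometry()].
#' @return Total coated area, mm^2, with the component breakdown (`bottom`,
#'   `wall`, `wall_height`) as attribute `components`.
#' @export
coated_surface <- function(geom) {
  if (geom$kind == "rect_well") {
    bottom <- geom$width * geom$length
    h <- geom$wall_height
    if (is.null(h))
      h <- .apply_rounding(geom$coating_volume / bottom, geom$rounding)
    wall <- 2 * (geom$width + geom$length) * h
    total <- bottom + wall - geom$channel_correction
  } else {
    bottom <- .apply_rounding(pi * (geom$diameter / 2)^2, geom$rounding)
    h <- geom$wall_height
    if (is.null(h)) stop("circular wells need an explicit wall_height")
    wall <- .apply_rounding(pi * geom$diameter * h, geom$rounding)
    total <- bottom + wall - geom$channel_correction
  }
  structure(total, components = list(bottom = bottom, wall = wall,
                                     wall_height = h))
}

#' Coating volume to coated surface ratio
#'
#' @param geom A [slide_geometry()].
#' @return uL per mm^2 of coated surface.
#' @export
volume_surface_ratio <- function(geom) {
  geom$coating_volume / as.numeric(coated_surface(geom))
}

#' Streptavidin coating density
#'
#' Mass of streptavidin applied per coated surface area:
#' `concentration * volume / coated_surface`, in ng/mm^2
#' (ug/mL times uL gives ng).
#'
#' @param conc_ug_ml Streptavidin concentration of the coating solution,
#'   ug/mL.
#' @param volume_ul Coating volume, uL.
#' @param geom A [slide_geometry()].
#' @return Density, ng/mm^2.
#' @export
streptavidin_density <- function(conc_ug_ml, volume_ul, geom) {
  stopifnot(conc_ug_ml >= 0, volume_ul > 0)
  conc_ug_ml * volume_ul / as.numeric(coated_surface(geom))
}

#' Imaged area of a multi-tile acquisition
#'
#' @param n_tiles Number of tiles (e.g. 9 for a 3 x 3 scan).
#' @param field_edge_um Edge length of one square field, um.
#' @return Area in mm^2 (9 tiles of 332.8 um give 0.9968 mm^2).
#' @export
imaged_area_mm2 <- function(n_tiles = 9, field_edge_um = 332.8) {
  n_tiles * (field_edge_um / 1000)^2
}

#' Area of a circle of given diameter
#'
#' Convenience for size-filter bounds: a 5 um circle has area 19.6 um^2 and
#' a 20 um circle 314.1 um^2.
#'
#' @param d Diameter (any length unit).
#' @return Area in the squared unit.
#' @export
circle_area <- function(d) pi * (d / 2)^2
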