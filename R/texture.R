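#' Normalize a USDA texture-class label
#'
#' Field texture-by-feel labels vary in case, hyphenation and spacing
#' ("Silty Clay-Loam", "silty_clay loam"). Normalization lower-cases,
#' collapses separators to single spaces, and resolves common abbreviations
#' ("s", "ls", "sl", "l", "sil", "si", "scl", "cl", "sicl", "sc", "sic", "c").
#'
#' @param texture_class Character vector of class labels.
#' @return Character vector of canonical labels as in
#'   [usda_texture_centroids()].
#' @export
#' @examples
#' normalize_texture_class(c("Silty Clay-Loam", "SIL"))
normalize_texture_class <- function(texture_class) {
  x <- tolower(trimws(as.character(texture_class)))
  x <- gsub("[-_]+", " ", x)
  x <- gsub("\\s+", " ", x)
  abbrev <- c(s = "sand", ls = "loamy sand", sl = "sandy loam", l = "loam",
              sil = "silt loam", si = "silt", scl = "sandy clay loam",
              cl = "clay loam", sicl = "silty clay loam", sc = "sandy clay",
              sic = "silty clay", c = "clay")
  hit <- x %in% names(abbrev)
  x[hit] <- abbrev[x[hit]]
  x
}

#' Centroid composition of a USDA texture class
#'
#' Looks up the sand/silt/clay percentages at the area centroid of the class
#' polygon on the USDA texture triangle. Labels are normalized with
#' [normalize_texture_class()] before lookup.
#'
#' @param texture_class Character vector of USDA class labels.
#' @return A tibble with columns `texture_class` (canonical label),
#'   `sand_pct`, `silt_pct`, `clay_pct`, one row per input element.
#' @export
#' @examples
#' centroid_of_class("silt loam")
centroid_of_class <- function(texture_class) {
  canon <- normalize_texture_class(texture_class)
  tab <- usda_texture_centroids()
  idx <- match(canon, tab$texture_class)
  if (anyNA(idx)) {
    bad <- unique(texture_class[is.na(idx)])
    stop("unknown texture class(es): ", paste(sQuote(bad), collapse = ", "),
         "; accepted labels: ", paste(tab$texture_class, collapse = ", "))
  }
  tab[idx, ]
}

#' Representative particle diameters of the texture separates
#'
#' Arithmetic midpoints of the USDA size limits (clay < 0.002 mm,
#' silt 0.002-0.05 mm, sand 0.05-2.0 mm), the convention used when collapsing
#' a sand/silt/clay composition to a geometric mean diameter.
#'
#' @param clay_mm,silt_mm,sand_mm Representative diameter of each separate, mm.
#' @return A named list with elements `clay_mm`, `silt_mm`, `sand_mm`.
#' @export
#' @examples
#' separate_midpoints()
separate_midpoints <- function(clay_mm = 0.001, silt_mm = 0.026,
                               sand_mm = 1.025) {
  stopifnot(clay_mm > 0, silt_mm > clay_mm, sand_mm > silt_mm)
  list(clay_mm = clay_mm, silt_mm = silt_mm, sand_mm = sand_mm)
}

#' Geometric mean particle diameter of a composition
#'
#' Collapses a sand/silt/clay composition to a single particle size:
#' `exp(0.01 * (clay_pct * log(clay_mm) + silt_pct * log(silt_mm) +
#' sand_pct * log(sand_mm)))`, i.e. the composition-weighted geometric mean
#' of the separates' representative diameters.
#'
#' @param composition A data frame with columns `sand_pct`, `silt_pct`,
#'   `clay_pct` (rows summing to 100), e.g. from [centroid_of_class()].
#' @param midpoints Representative separate diameters, see
#'   [separate_midpoints()].
#' @return Numeric vector of diameters in mm, one per composition row;
#'   always within `[clay_mm, sand_mm]`.
#' @export
#' @examples
#' geometric_mean_diameter(centroid_of_class("loam"))
geometric_mean_diameter <- function(composition,
                                    midpoints = separate_midpoints()) {
  stopifnot(all(c("sand_pct", "silt_pct", "clay_pct") %in% names(composition)))
  tot <- composition$sand_pct + composition$silt_pct + composition$clay_pct
  if (any(abs(tot - 100) > 1e-6)) {
    stop("composition rows ", paste(which(abs(tot - 100) > 1e-6), collapse = ", "),
         " do not sum to 100")
  }
  if (any(composition$sand_pct < 0 | composition$silt_pct < 0 |
          composition$clay_pct < 0)) {
    stop("composition percentages must be non-negative")
  }
  exp(0.01 * (composition$clay_pct * log(midpoints$clay_mm) +
              composition$silt_pct * log(midpoints$silt_mm) +
              composition$sand_pct * log(midpoints$sand_mm)))
}

#' Particle size of a USDA texture class
#'
#' Convenience composition of [centroid_of_class()] and
#' [geometric_mean_diameter()].
#'
#' @inheritParams centroid_of_class
#' @inheritParams geometric_mean_diameter
#' @return Numeric vector of geometric mean diameters, mm.
#' @export
#' @examples
#' class_particle_size(c("sand", "silty clay"))
class_particle_size <- function(texture_class,
                                midpoints = separate_midpoints()) {
  geometric_mean_diameter(centroid_of_class(texture_class), midpoints)
}
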