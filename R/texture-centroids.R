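# Area centroids of the 12 USDA texture-class regions of the sand/silt/clay
# triangle. Frozen output of data-raw/texture_centroids.R (dense-grid
# integration over the standard USDA class inequalities); also shipped as
# inst/extdata/usda_texture_centroids.csv.
.usda_centroids <- data.frame(
  texture_class = c("sand", "loamy sand", "sandy loam", "loam", "silt loam",
                    "silt", "sandy clay loam", "clay loam", "silty clay loam",
                    "sandy clay", "silty clay", "clay"),
  sand = c(91.661, 81.662, 64.597, 41.069, 21.477, 7.434, 59.825, 32.5, 10,
           51.663, 6.666, 19.522),
  silt = c(5.008, 12.505, 24.991, 40.586, 65.309, 87.422, 13.075, 34, 56.5,
           6.674, 46.668, 17.557),
  clay = c(3.331, 5.833, 10.412, 18.345, 13.214, 5.144, 27.1, 33.5, 33.5,
           41.663, 46.666, 62.921),
  stringsAsFactors = FALSE
)

#' USDA texture-class centroid table
#'
#' Sand/silt/clay mass percentages at the area centroid of each of the 12
#' USDA texture-class regions of the texture triangle. These are geometric
#' centroids of the class polygons, precomputed by integrating over the
#' standard USDA class-boundary inequalities.
#'
#' @return A tibble with columns `texture_class`, `sand_pct`, `silt_pct`,
#'   `clay_pct`; one row per USDA class, rows summing to 100.
#' @export
#' @examples
#' usda_texture_centroids()
usda_texture_centroids <- function() {
  tibble::tibble(
    texture_class = .usda_centroids$texture_class,
    sand_pct = .usda_centroids$sand,
    silt_pct = .usda_centroids$silt,
    clay_pct = .usda_centroids$clay
  )
}

#' Classify a sand/silt/clay composition into a USDA texture class
#'
#' Applies the standard USDA class-boundary inequalities (the logic of the
#' NRCS texture calculator). Vectorized; inputs are percentages summing
#' to 100.
#'
#' @param sand_pct,silt_pct,clay_pct Percent by mass of the mineral fraction.
#' @return Character vector of USDA class labels.
#' @export
#' @examples
#' classify_texture(40, 40, 20)
classify_texture <- function(sand_pct, silt_pct, clay_pct) {
  n <- max(length(sand_pct), length(silt_pct), length(clay_pct))
  sand <- rep_len(sand_pct, n); silt <- rep_len(silt_pct, n)
  clay <- rep_len(clay_pct, n)
  bad <- abs(sand + silt + clay - 100) > 1e-6
  if (any(bad)) {
    stop("composition rows ", paste(which(bad), collapse = ", "),
         " do not sum to 100")
  }
  rules <- list(
    sand = silt + 1.5 * clay < 15,
    `loamy sand` = silt + 1.5 * clay >= 15 & silt + 2 * clay < 30,
    `sandy loam` = (clay >= 7 & clay < 20 & sand > 52 & silt + 2 * clay >= 30) |
      (clay < 7 & silt < 50 & silt + 2 * clay >= 30),
    loam = clay >= 7 & clay < 27 & silt >= 28 & silt < 50 & sand <= 52,
    `silt loam` = (silt >= 50 & clay >= 12 & clay < 27) |
      (silt >= 50 & silt < 80 & clay < 12),
    silt = silt >= 80 & clay < 12,
    `sandy clay loam` = clay >= 20 & clay < 35 & silt < 28 & sand > 45,
    `clay loam` = clay >= 27 & clay < 40 & sand > 20 & sand <= 45,
    `silty clay loam` = clay >= 27 & clay < 40 & sand <= 20,
    `sandy clay` = clay >= 35 & sand > 45,
    `silty clay` = clay >= 40 & silt >= 40,
    clay = clay >= 40 & sand <= 45 & silt < 40
  )
  cls <- rep(NA_character_, n)
  for (nm in names(rules)) {
    hit <- is.na(cls) & rules[[nm]]
    cls[hit] <- nm
  }
  cls
}
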