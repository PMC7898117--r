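# Regenerates the packaged USDA texture-class centroid table.
#
# Area centroids of the 12 USDA texture-class regions of the sand/silt/clay
# triangle, computed by dense-grid integration over the standard USDA class
# inequalities (Soil Survey Manual / NRCS texture calculator logic).
# Output is pasted into R/texture-centroids.R; run from the package root:
#   Rscript data-raw/texture_centroids.R

usda_rules <- list(
  sand            = function(sand, silt, clay) silt + 1.5 * clay < 15,
  `loamy sand`    = function(sand, silt, clay) silt + 1.5 * clay >= 15 & silt + 2 * clay < 30,
  `sandy loam`    = function(sand, silt, clay)
    (clay >= 7 & clay < 20 & sand > 52 & silt + 2 * clay >= 30) |
    (clay < 7 & silt < 50 & silt + 2 * clay >= 30),
  loam            = function(sand, silt, clay) clay >= 7 & clay < 27 & silt >= 28 & silt < 50 & sand <= 52,
  `silt loam`     = function(sand, silt, clay)
    (silt >= 50 & clay >= 12 & clay < 27) | (silt >= 50 & silt < 80 & clay < 12),
  silt            = function(sand, silt, clay) silt >= 80 & clay < 12,
  `sandy clay loam` = function(sand, silt, clay) clay >= 20 & clay < 35 & silt < 28 & sand > 45,
  `clay loam`     = function(sand, silt, clay) clay >= 27 & clay < 40 & sand > 20 & sand <= 45,
  `silty clay loam` = function(sand, silt, clay) clay >= 27 & clay < 40 & sand <= 20,
  `sandy clay`    = function(sand, silt, clay) clay >= 35 & sand > 45,
  `silty clay`    = function(sand, silt, clay) clay >= 40 & silt >= 40,
  clay            = function(sand, silt, clay) clay >= 40 & sand <= 45 & silt < 40
)

step <- 0.025
cc <- seq(step / 2, 100 - step / 2, by = step)
grid <- do.call(rbind, lapply(cc, function(cl) {
  hi <- 100 - cl - step / 2
  if (hi < step / 2) return(NULL)
  sa <- seq(step / 2, hi, by = step)
  cbind(sand = sa, clay = cl)
}))
sand <- grid[, "sand"]; clay <- grid[, "clay"]; silt <- 100 - sand - clay

cls <- rep(NA_character_, length(sand))
for (nm in names(usda_rules)) {
  hit <- is.na(cls) & usda_rules[[nm]](sand, silt, clay)
  cls[hit] <- nm
}
stopifnot(!anyNA(cls))

cent <- aggregate(cbind(sand, silt, clay), by = list(texture_class = cls), FUN = mean)
# renormalize so each row sums to exactly 100
tot <- cent$sand + cent$silt + cent$clay
cent$sand <- round(cent$sand / tot * 100, 3)
cent$clay <- round(cent$clay / tot * 100, 3)
cent$silt <- round(100 - cent$sand - cent$clay, 3)

ord <- names(usda_rules)
cent <- cent[match(ord, cent$texture_class), c("texture_class", "sand", "silt", "clay")]

# cross-check: silt polygon (sand,clay) = (20,0),(8,12),(0,12),(0,0), exact
# shoelace centroid sand 7.4286, clay 5.1429
stopifnot(abs(cent$sand[cent$texture_class == "silt"] - 7.4286) < 0.05,
          abs(cent$clay[cent$texture_class == "silt"] - 5.1429) < 0.05)
# cross-check: sand class is the triangle (0,0,100),(10,0,90),(0,15,85);
# triangle centroid = vertex mean = (91.667, 5, 3.333)
stopifnot(abs(cent$sand[cent$texture_class == "sand"] - 91.667) < 0.05)
# every centroid classifies into its own class
for (i in seq_len(nrow(cent))) {
  own <- vapply(names(usda_rules), function(nm)
    usda_rules[[nm]](cent$sand[i], cent$silt[i], cent$clay[i]), logical(1))
  stopifnot(names(usda_rules)[which(own)[1]] == cent$texture_class[i])
}

write.csv(cent, "inst/extdata/usda_texture_centroids.csv", row.names = FALSE, quote = TRUE)
cat("Constant for R/texture-centroids.R:\n\n")
dput(cent)
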