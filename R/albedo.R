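#' Narrowband-to-broadband albedo conversion
#'
#' Broadband shortwave albedo from visible-band reflectances using the
#' Landsat-7 narrowband-to-broadband weights:
#' `albedo = 0.443 * blue + 0.317 * green + 0.240 * red`.
#' The weights sum to 1, so the result is a convex combination of the band
#' reflectances and a spectrally flat surface maps to itself.
#'
#' @param blue,green,red band reflectances in \[0, 1\], vectorised.
#' @return broadband albedo in \[0, 1\].
#' @examples
#' broadband_albedo(0.1, 0.2, 0.3)  # 0.1797
#' @export
broadband_albedo <- function(blue, green, red) {
  n <- max(length(blue), length(green), length(red))
  blue <- rep_len(blue, n); green <- rep_len(green, n); red <- rep_len(red, n)
  if (any(c(blue, green, red) < 0 | c(blue, green, red) > 1))
    stop("band reflectances must lie in [0, 1]")
  0.443 * blue + 0.317 * green + 0.240 * red
}

#' Mean broadband albedo by surface class
#'
#' Aggregates per-pixel broadband albedo over a class mask (e.g. roof pixels
#' identified from building footprints), giving the mean albedo used to
#' characterise each surface class in the control experiment.
#'
#' @param pixels data.frame with columns `blue`, `green`, `red` and a class
#'   column (default `class`); a logical `mask` column, if present, drops
#'   masked-out pixels first.
#' @param class_col name of the class column.
#' @return data.frame with columns `class`, `n`, `mean_albedo`.
#' @export
albedo_by_class <- function(pixels, class_col = "class") {
  stopifnot(is.data.frame(pixels),
            all(c("blue", "green", "red", class_col) %in% names(pixels)))
  if ("mask" %in% names(pixels)) pixels <- pixels[as.logical(pixels$mask), ]
  if (nrow(pixels) == 0L) stop("no pixels after masking")
  a <- broadband_albedo(pixels$blue, pixels$green, pixels$red)
  agg <- aggregate(a, by = list(class = pixels[[class_col]]),
                   FUN = function(x) c(n = length(x), mean = mean(x)))
  data.frame(class = agg$class, n = agg$x[, "n"],
             mean_albedo = agg$x[, "mean"])
}
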