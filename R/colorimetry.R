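# CIELCh / CIELAB / CIE XYZ colorimetry for the stimulus palette.
#
# All conversions use the CIE 1976 L*a*b* definition with the two-branch
# companding function (cube root above (6/29)^3, linear below) and a D65
# reference white. Luminances are in cd/m^2 throughout.

#' Reference white point
#'
#' Constructs a reference white from its CIE 1931 chromaticity and luminance.
#' The default is D65 for the 2 degree observer with `Yn = 100` cd/m^2, the
#' white under which the stimulus palette is defined.
#'
#' @param x,y Chromaticity coordinates of the white, both in (0, 1).
#' @param Yn Luminance of the reference white in cd/m^2.
#' @param name Label for the white point.
#' @return An object of class `white_point`: a list with `name`, `x`, `y`,
#'   `Yn` and the derived tristimulus values `Xn`, `Zn`.
#' @examples
#' w <- white_point()
#' w$Xn / w$Yn  # X/Y ratio of D65
#' @export
white_point <- function(x = 0.31272, y = 0.32903, Yn = 100, name = "D65") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L,
            x > 0, x < 1, y > 0, y < 1, Yn > 0)
  w <- list(name = name, x = x, y = y, Yn = Yn,
            Xn = x / y * Yn, Zn = (1 - x - y) / y * Yn)
  class(w) <- "white_point"
  w
}

#' @export
print.white_point <- function(x, ...) {
  cat(sprintf("White point %s: x = %.5f, y = %.5f, Yn = %.2f cd/m^2\n",
              x$name, x$x, x$y, x$Yn))
  invisible(x)
}

# CIE companding function and its inverse (delta = 6/29)
.cie_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.cie_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert CIELCh to CIELAB
#'
#' Cylindrical-to-Cartesian conversion: `a* = C cos(h)`, `b* = C sin(h)` with
#' the hue angle `h` in degrees.
#'
#' @param L Lightness L* in \[0, 100\] (vectorised).
#' @param C Chroma C*ab, non-negative.
#' @param h Hue angle in degrees.
#' @return A data frame with columns `L`, `a`, `b`.
#' @examples
#' lch_to_lab(60, 34, 0)    # pure +a* (red direction)
#' lch_to_lab(60, 34, 90)   # pure +b* (yellow direction)
#' @export
lch_to_lab <- function(L, C, h) {
  if (is.data.frame(L)) { C <- L$C; h <- L$h; L <- L$L }
  stopifnot(all(C >= 0), all(L >= 0 & L <= 100))
  rad <- h * pi / 180
  data.frame(L = L, a = C * cos(rad), b = C * sin(rad))
}

#' Convert CIELAB to CIE XYZ (and chromaticity)
#'
#' Standard CIELAB inverse under a reference white, using the two-branch
#' inverse companding function.
#'
#' @param L,a,b CIELAB coordinates (vectorised). `L` may also be a data frame
#'   with columns `L`, `a`, `b`.
#' @param white A [white_point()].
#' @return A data frame with tristimulus `X`, `Y`, `Z` (cd/m^2) and
#'   chromaticity `x`, `y`.
#' @examples
#' lab_to_xyz(60, 34, 0)  # the red stimulus: x = 0.380, y = 0.297, Y = 28.12
#' @export
lab_to_xyz <- function(L, a, b, white = white_point()) {
  if (is.data.frame(L)) { a <- L$a; b <- L$b; L <- L$L }
  stopifnot(inherits(white, "white_point"), all(L >= 0 & L <= 100))
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  X <- white$Xn * .cie_finv(fx)
  Y <- white$Yn * .cie_finv(fy)
  Z <- white$Zn * .cie_finv(fz)
  chrom <- xyz_to_chromaticity(X, Y, Z)
  data.frame(X = X, Y = Y, Z = Z, x = chrom$x, y = chrom$y)
}

#' Convert CIE XYZ to CIELAB
#'
#' Forward CIELAB transform; the inverse of [lab_to_xyz()].
#'
#' @param X,Y,Z Tristimulus values (vectorised); `X` may be a data frame with
#'   columns `X`, `Y`, `Z`.
#' @param white A [white_point()].
#' @return A data frame with columns `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(X, Y, Z, white = white_point()) {
  if (is.data.frame(X)) { Y <- X$Y; Z <- X$Z; X <- X$X }
  stopifnot(inherits(white, "white_point"))
  fx <- .cie_f(X / white$Xn)
  fy <- .cie_f(Y / white$Yn)
  fz <- .cie_f(Z / white$Zn)
  data.frame(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' CIE 1931 chromaticity from tristimulus values
#'
#' @param X,Y,Z Tristimulus values (vectorised).
#' @return A data frame with columns `x`, `y`.
#' @examples
#' xyz_to_chromaticity(10, 10, 10)  # equal energy: (1/3, 1/3)
#' @export
xyz_to_chromaticity <- function(X, Y, Z) {
  if (is.data.frame(X)) { Y <- X$Y; Z <- X$Z; X <- X$X }
  s <- X + Y + Z
  if (any(s <= 0)) {
    stop("degenerate color: X + Y + Z must be > 0 to define chromaticity")
  }
  data.frame(x = X / s, y = Y / s)
}

#' Euclidean color difference in CIELAB
#'
#' `delta E*ab = sqrt(dL^2 + da^2 + db^2)`; approximately one just-noticeable
#' difference equals a delta E of 2.3.
#'
#' @param lab1,lab2 Data frames (or single rows) with columns `L`, `a`, `b`.
#' @return Numeric vector of color differences.
#' @examples
#' delta_e_ab(lch_to_lab(60, 34, 0), lch_to_lab(60, 34, 180))  # 68
#' @export
delta_e_ab <- function(lab1, lab2) {
  sqrt((lab1$L - lab2$L)^2 + (lab1$a - lab2$a)^2 + (lab1$b - lab2$b)^2)
}

#' Build the stimulus palette
#'
#' The six stimulus hues (red, green, yellow, blue, orange, lime) share
#' `L* = 60`, `C* = 34` and sit at hue angles 0, 180, 90, 270, 45 and 135
#' degrees; the background is achromatic at `L* = 55`. All CIELAB and XYZ
#' coordinates are computed under the given white.
#'
#' The column `Y_nominal` carries the luminance each color is specified to
#' have on the display (28.12 cd/m^2 for the stimuli and 23.00 cd/m^2 for the
#' background). For the background the printed nominal luminance and the
#' luminance computed from its rounded `L*` differ in the second decimal
#' (22.93 vs 23.00); the nominal value is retained as the defining one.
#'
#' @param white A [white_point()].
#' @return A data frame with one row per color and columns `name`, `L`, `C`,
#'   `h`, `a`, `b`, `X`, `Y`, `Z`, `x`, `y`, `Y_nominal`.
#' @examples
#' pal <- build_palette()
#' pal[pal$name == "yellow", c("x", "y")]
#' @export
build_palette <- function(white = white_point()) {
  spec <- data.frame(
    name = c("red", "green", "yellow", "blue", "orange", "lime", "background"),
    L = c(rep(60, 6), 55),
    C = c(rep(34, 6), 0),
    h = c(0, 180, 90, 270, 45, 135, 0),
    Y_nominal = c(rep(28.12, 6), 23.00),
    stringsAsFactors = FALSE
  )
  lab <- lch_to_lab(spec$L, spec$C, spec$h)
  xyz <- lab_to_xyz(lab, white = white)
  cbind(spec[c("name", "L", "C", "h")], lab[c("a", "b")], xyz,
        spec["Y_nominal"])
}

#' Write / read a palette as CSV
#'
#' @param palette A data frame as returned by [build_palette()].
#' @param path File path.
#' @return `read_palette()` returns the palette data frame.
#' @export
write_palette <- function(palette, path) {
  utils::write.csv(palette, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_palette
#' @export
read_palette <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
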