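#' Whisker geometry
#'
#' Physical description of a (possibly trimmed) conical whisker. A whisker is
#' modeled as a linearly tapered circular beam: the untrimmed cone has total
#' arc length `S_tot`, base radius `R_b` and tip radius `r_t`; trimming cuts
#' it at arc length `l` measured from the base, so the radius at the cut is
#' `R_b - slope_R * l` with `slope_R = (R_b - r_t) / S_tot`.
#'
#' All fields are SI: meters, pascals, kg/m^3. Helper constructors accept
#' `unit = "mm"` or `"um"` for the lengths because whisker dimensions are
#' conventionally reported in millimeters (arc length) and micrometers
#' (radii); mixing scales silently is a classic source of error in this
#' domain, so units must be explicit.
#'
#' @param S_tot total untrimmed arc length \[m\]
#' @param R_b radius at the base \[m\]
#' @param r_t radius at the (untrimmed) tip \[m\]; `0` for an ideal cone
#' @param l arc length after distal truncation \[m\]; defaults to `S_tot`
#'   (untrimmed)
#' @param E Young's modulus \[Pa\]
#' @param rho material density \[kg/m^3\]
#' @param A_curv intrinsic-curvature parabolic coefficient \[1/m\]: the
#'   undeformed whisker shape is `A_curv * x^2` in its own frame
#' @param unit unit of the three length arguments: `"m"` (default), `"mm"`
#'   or `"um"`
#'
#' @return An object of class `whisker_geometry`: a list with fields
#'   `S_tot`, `l`, `R_b`, `r_t`, `slope_R`, `A_curv`, `E`, `rho` (all SI).
#' @examples
#' geom <- whisker_geometry(S_tot = 40, l = 29, R_b = 60e-3, r_t = 0,
#'                          E = 2e9, rho = 1000, unit = "mm")
#' geom$slope_R
#' @export
whisker_geometry <- function(S_tot, R_b, r_t = 0, l = S_tot, E = 3e9,
                             rho = 1100, A_curv = 0, unit = c("m", "mm", "um")) {
  unit <- match.arg(unit)
  k <- switch(unit, m = 1, mm = 1e-3, um = 1e-6)
  force(l)   # the default l = S_tot must bind before S_tot is rescaled
  S_tot <- S_tot * k; R_b <- R_b * k; r_t <- r_t * k; l <- l * k
  A_curv <- A_curv / k
  stopifnot(is.finite(S_tot), S_tot > 0, is.finite(l), l > 0, l <= S_tot,
            is.finite(R_b), R_b > 0, is.finite(r_t), r_t >= 0,
            is.finite(E), E > 0, is.finite(rho), rho > 0)
  if (r_t > R_b) stop("tip radius must not exceed base radius")
  g <- list(S_tot = S_tot, l = l, R_b = R_b, r_t = r_t,
            slope_R = (R_b - r_t) / S_tot, A_curv = A_curv, E = E, rho = rho)
  class(g) <- "whisker_geometry"
  g
}

#' @export
print.whisker_geometry <- function(x, ...) {
  cat(sprintf(
    "whisker_geometry: S_tot = %.3g mm, l = %.3g mm, R_b = %.3g um, r_t = %.3g um\n",
    x$S_tot * 1e3, x$l * 1e3, x$R_b * 1e6, x$r_t * 1e6))
  cat(sprintf("  E = %.4g GPa, rho = %.4g kg/m^3, slope_R = %.3g, A_curv = %.3g 1/m\n",
              x$E / 1e9, x$rho, x$slope_R, x$A_curv))
  invisible(x)
}

#' Local radius, cross-section area and second moment along the whisker
#'
#' @param geom a [whisker_geometry()]
#' @param s arc-length positions from the base \[m\]
#' @return numeric vector: radius \[m\], area \[m^2\], or area moment of
#'   inertia \[m^4\] at `s`.
#' @keywords internal
whisker_radius <- function(geom, s) {
  stopifnot(all(s >= 0), all(s <= geom$l + 1e-12))
  pmax(geom$R_b - geom$slope_R * s, 0)
}

#' @rdname whisker_radius
#' @keywords internal
whisker_area <- function(geom, s) pi * whisker_radius(geom, s)^2

#' @rdname whisker_radius
#' @keywords internal
whisker_moment <- function(geom, s) pi * whisker_radius(geom, s)^4 / 4

#' Read / write whisker geometry as key-value text
#'
#' Plain `key: value` text with explicit `unit_length` field (`m`, `mm` or
#' `um`) applying to `S_tot`, `l`, `R_b`, `r_t` (and reciprocal for
#' `A_curv`); `E` is always Pa and `rho` always kg/m^3.
#'
#' @param geom a [whisker_geometry()]
#' @param path file path
#' @param unit length unit to write
#' @return `read_geometry` returns a [whisker_geometry()];
#'   `write_geometry` returns `path` invisibly.
#' @export
write_geometry <- function(geom, path, unit = c("m", "mm", "um")) {
  unit <- match.arg(unit)
  k <- switch(unit, m = 1, mm = 1e-3, um = 1e-6)
  lines <- c(
    sprintf("unit_length: %s", unit),
    sprintf("S_tot: %.12g", geom$S_tot / k),
    sprintf("l: %.12g", geom$l / k),
    sprintf("R_b: %.12g", geom$R_b / k),
    sprintf("r_t: %.12g", geom$r_t / k),
    sprintf("A_curv: %.12g", geom$A_curv * k),
    sprintf("E: %.12g", geom$E),
    sprintf("rho: %.12g", geom$rho))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), "")
  names(vals) <- keys
  unit <- if ("unit_length" %in% keys) vals[["unit_length"]] else
    stop("geometry file must declare 'unit_length' (m, mm or um)")
  num <- function(k, default = NULL) {
    if (k %in% keys) as.numeric(vals[[k]])
    else if (!is.null(default)) default
    else stop(sprintf("geometry file missing field '%s'", k))
  }
  whisker_geometry(S_tot = num("S_tot"), R_b = num("R_b"),
                   r_t = num("r_t", 0), l = num("l", num("S_tot")),
                   E = num("E"), rho = num("rho"),
                   A_curv = num("A_curv", 0) , unit = unit)
}
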