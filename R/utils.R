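# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "annulipid_error")))
}

warn2 <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "annulipid_warning")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Coordinates of an atom table as an n x 3 matrix
#' @param atoms atom table with `x`, `y`, `z` columns.
#' @return Numeric matrix with one row per atom.
#' @export
atom_xyz <- function(atoms) {
  stopifnot(all(c("x", "y", "z") %in% names(atoms)))
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' Heavy (non-hydrogen) subset of an atom table
#' @param atoms atom table with a `hydrogen` flag column.
#' @return The atom table without hydrogen atoms.
#' @export
heavy_atoms <- function(atoms) {
  atoms[!atoms$hydrogen, , drop = FALSE]
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Render count / n_protomers as an exact rational string ("2/3", "10/3", "9").
format_rational <- function(numerator, denominator) {
  stopifnot(denominator >= 1)
  if (numerator == 0) return("0")
  g <- gcd2(numerator, denominator)
  n <- numerator / g
  d <- denominator / g
  if (d == 1) as.character(n) else paste0(n, "/", d)
}

# Squared distances from a single point q (length-3) to rows of an n x 3
# matrix. Both the brute-force and grid nearest-neighbour paths call this
# helper so that the winning pair is evaluated with identical arithmetic.
point_dist2 <- function(q, xyz) {
  dx <- xyz[, 1L] - q[1L]
  dy <- xyz[, 2L] - q[2L]
  dz <- xyz[, 3L] - q[3L]
  dx * dx + dy * dy + dz * dz
}
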