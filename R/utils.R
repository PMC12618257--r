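# Classed conditions so callers can distinguish failure modes
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "arpgeom_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean helpers on plain numeric 3-vectors / n x 3 matrices
vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a (near-)zero vector", "degenerate_geometry")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) abort("coordinate matrix must have 3 columns", "degenerate_geometry")
    return(x)
  }
  matrix(as.numeric(x), ncol = 3, byrow = TRUE)
}

# wrap degrees into (-180, 180]
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}
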