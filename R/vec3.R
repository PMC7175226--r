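# Minimal 3-vector helpers. Coordinates are plain numeric(3) in Angstrom;
# no class wrapper -- everything downstream works on numeric vectors and
# n x 3 matrices.

v_dot <- function(a, b) sum(a * b)

v_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

v_norm <- function(a) sqrt(sum(a * a))

v_unit <- function(a) {
  n <- v_norm(a)
  if (n == 0) stop("cannot normalize a zero vector")
  a / n
}

stopifnot_finite3 <- function(v, what = "vector") {
  if (length(v) != 3L || !all(is.finite(v)))
    stop(what, " must be a finite numeric vector of length 3")
  invisible(v)
}
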