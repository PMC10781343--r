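# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 100) {
    stop("romval: cannot normalize a (near-)zero vector", call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

is_finite_vec3 <- function(v) {
  is.numeric(v) && length(v) == 3L && all(is.finite(v))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_romval <- function(msg, class) {
  stop(structure(
    class = c(class, "romval_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
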