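# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap phase angles into (-pi, pi]
#'
#' Principal-value wrapping with the convention that -pi maps to +pi, so the
#' wrapped interval is half-open on the left. This convention is used
#' everywhere a phase map is stored or compared.
#'
#' @param x numeric vector/array of angles, radians.
#' @return angles wrapped into (-pi, pi], same shape as `x`.
#' @export
#' @examples
#' wrap_phase(c(0.3, pi, -pi, 3 * pi))
wrap_phase <- function(x) {
  y <- pi - ((pi - x) %% (2 * pi))
  # guard against floating slop at the boundary: values that should be +pi
  y[y <= -pi] <- pi
  dim(y) <- dim(x)
  y
}

# sinc(x) = sin(x)/x with sinc(0) = 1 (unnormalized)
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  dim(out) <- dim(x)
  out
}

# Stop with a formatted message.
abort <- function(...) stop(sprintf(...), call. = FALSE)

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort("`%s` must be a positive finite scalar", name)
  }
  invisible(x)
}

# Convert an index matrix (rows = points, cols = axes) into linear indices
# of an array with dimensions `dims`.
linear_index <- function(idx, dims) {
  idx <- as.matrix(idx)
  if (ncol(idx) != length(dims)) {
    abort("index matrix has %d columns but the grid has %d axes",
          ncol(idx), length(dims))
  }
  if (any(idx < 1) || any(idx > rep(dims, each = nrow(idx)))) {
    abort("voxel index outside the grid")
  }
  lin <- idx[, 1L]
  stride <- 1
  for (a in seq_along(dims)[-1L]) {
    stride <- stride * dims[a - 1L]
    lin <- lin + (idx[, a] - 1L) * stride
  }
  as.integer(lin)
}

# dB MHz^-gamma cm^-1  ->  Np (rad/s)^-gamma m^-1
db_to_neper <- function(alpha_db, gamma) {
  100 * alpha_db * (1e-6 / (2 * pi))^gamma * log(10) / 20
}

# Simple JSON writer wrapper with unboxing and full precision.
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
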