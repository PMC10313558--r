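#' Diffusion-weighting protocol (b-value table with NEX)
#'
#' A `bvalue_protocol` records the ordered diffusion weightings of an
#' acquisition and the number of excitations (NEX) averaged at each b.
#' Noise in a magnitude image scales as 1/sqrt(NEX), which the phantom
#' simulator honours.
#'
#' @param b_values Numeric vector of b-values in s/mm^2, strictly
#'   increasing, starting at 0.
#' @param nex Integer vector of the same length, signal averages per b
#'   (all >= 1).
#' @return An object of class `bvalue_protocol`.
#' @seealso [default_protocol()] for the 12-b head-and-neck scheme.
#' @export
bvalue_protocol <- function(b_values, nex = rep(1L, length(b_values))) {
  b_values <- as.numeric(b_values)
  nex <- as.integer(nex)
  if (length(b_values) < 2L)
    stop_ivim("a protocol needs at least two b-values", "ivimprog_invalid_protocol")
  if (b_values[1L] != 0)
    stop_ivim("the first b-value must be 0", "ivimprog_invalid_protocol")
  if (any(diff(b_values) <= 0))
    stop_ivim("b-values must be strictly increasing", "ivimprog_invalid_protocol")
  if (length(nex) != length(b_values) || any(is.na(nex)) || any(nex < 1L))
    stop_ivim("nex must be positive integers, one per b-value",
              "ivimprog_invalid_protocol")
  structure(list(b_values = b_values, nex = nex), class = "bvalue_protocol")
}

#' Default 12-b-value acquisition protocol
#'
#' b = 0, 10, 20, 30, 50, 70, 100, 150, 200, 400, 800, 1000 s/mm^2 with
#' NEX = 2 for b <= 200 and NEX = 3 for b >= 400.
#'
#' @return A [bvalue_protocol()].
#' @export
default_protocol <- function() {
  b <- c(0, 10, 20, 30, 50, 70, 100, 150, 200, 400, 800, 1000)
  bvalue_protocol(b, ifelse(b <= 200, 2L, 3L))
}

#' @export
print.bvalue_protocol <- function(x, ...) {
  cat("DWI protocol:", length(x$b_values), "b-values (s/mm^2)\n")
  print(data.frame(b_value = x$b_values, nex = x$nex), row.names = FALSE)
  invisible(x)
}

#' Read or write a protocol sidecar file
#'
#' The sidecar is a two-column whitespace-delimited text file with header
#' `b_value nex`.
#'
#' @param path File path.
#' @rdname protocol_io
#' @return `read_protocol` returns a [bvalue_protocol()]; `write_protocol`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  if (!all(c("b_value", "nex") %in% names(tab)))
    stop_ivim("protocol sidecar must have columns b_value and nex",
              "ivimprog_invalid_protocol")
  bvalue_protocol(tab$b_value, tab$nex)
}

#' @param protocol A [bvalue_protocol()].
#' @rdname protocol_io
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "bvalue_protocol"))
  utils::write.table(
    data.frame(b_value = protocol$b_values, nex = protocol$nex),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
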