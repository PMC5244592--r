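# Gauss-Legendre rules on (0,1), cached per order.

.quad_cache <- new.env(parent = emptyenv())

gauss_legendre_01 <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 2 ||
      order != round(order)) {
    stop_input("quad_order must be a single integer >= 2 (got %s)",
               paste(order, collapse = ","))
  }
  key <- as.character(order)
  rule <- .quad_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(as.integer(order), 0, 1)
    .quad_cache[[key]] <- rule
  }
  rule
}
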