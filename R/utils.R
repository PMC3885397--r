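#' @keywords internal
"_PACKAGE"

# Delimiter-sniffing reader for the plain-text tables the pipeline exchanges
# (tab or comma separated, header row required).
read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_delim_table <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
}

logistic <- function(x) stats::plogis(x)

#' Gauss--Hermite nodes and weights
#'
#' Nodes and weights for integration against the weight function
#' \eqn{e^{-x^2}}, computed by the Golub--Welsch eigen decomposition of the
#' Jacobi matrix. Used by the adaptive-quadrature likelihood oracle.
#'
#' @param n Number of nodes.
#' @return List with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}
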