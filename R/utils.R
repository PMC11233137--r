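`%||%` <- function(a, b) if (is.null(a)) b else a

pop_name <- function(x) {
  if (inherits(x, "popscape_population")) x$name
  else if (is.character(x) && length(x) == 1) x
  else stop("expected a population object or name", call. = FALSE)
}

KERNELS <- c("normal", "uniform", "cauchy", "exponential", "brownian")

#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib popscape, .registration = TRUE
NULL
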