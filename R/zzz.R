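#' @importFrom Matrix Matrix sparseMatrix
#' @importFrom stats setNames median quantile cor sd pt rnorm runif na.omit
#' @importFrom utils read.delim write.table packageVersion
NULL

.onUnload <- function(libpath) {
  pf_worker_reset()
}
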