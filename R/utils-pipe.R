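#' Pipe operator
#'
#' Re-exported from the tidyverse so `lincte` results chain naturally.
#'
#' @name %>%
#' @rdname pipe
#' @keywords internal
#' @importFrom dplyr %>%
#' @export
#' @usage lhs \%>\% rhs
#' @param lhs,rhs A value and a function to apply to it.
#' @return The result of `rhs(lhs)`.
NULL
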