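#' @importFrom methods new is slot slot<- validObject setValidity
#' @importFrom stats coef lm poly sd rnorm setNames
#' @importFrom utils read.csv write.csv modifyList
#' @keywords internal
"_PACKAGE"
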