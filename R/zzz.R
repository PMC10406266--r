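.onLoad <- function(libname, pkgname) {
  # the glm module's conjugate block samplers are what make the hierarchical
  # normal models mix well under Gibbs sampling
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  invisible(NULL)
}
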