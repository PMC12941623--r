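.onLoad <- function(libname, pkgname) {
  ## keep the allocator heap-resident (see src/ops.cpp) and avoid BLAS
  ## thread thrash on the small matrix products this package issues
  .c_tune_malloc()
  if (Sys.getenv("OPENBLAS_NUM_THREADS") == "")
    Sys.setenv(OPENBLAS_NUM_THREADS = "1")
  invisible()
}
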