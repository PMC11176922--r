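PKG_CXXFLAGS = -O2 -ffast-math
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
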