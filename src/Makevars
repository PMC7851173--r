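PKG_CPPFLAGS = -DTMB_LIB_INIT=R_init_ctcrwrisk -DTMB_EIGEN_DISABLE_WARNINGS
PKG_LIBS = $(SHLIB_OPENMP_CXXFLAGS)
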