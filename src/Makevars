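# libzstd ships with the R toolchain's prefix (R_HOME = <prefix>/lib/R)
PKG_CPPFLAGS = -I$(R_HOME)/../../include
PKG_LIBS = -L$(R_HOME)/../../lib -Wl,-rpath,$(R_HOME)/../../lib -lzstd
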