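# The scan kernel's row update is reformulated into dependence-free passes
# whose float max-reductions vectorize only when the compiler may assume
# finite scores (true by construction).  The hot loops are additionally
# multi-versioned (target_clones) so wider SIMD units are used when present.
PKG_CXXFLAGS = -funroll-loops -ffinite-math-only -fno-signed-zeros
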