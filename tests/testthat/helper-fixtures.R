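# Small shared fixtures, regenerated in code at test time.

fixture_genome <- function(length_bp = 20000, cg_density = 1, meth_frac = 1,
                           seed = 42L) {
  generate_genome(length_bp, gc_frac = 0.41, cg_density = cg_density,
                  meth_frac = meth_frac, seed = seed)
}

# A methylome with every CG methylated, handy for binding/footprint tests.
fixture_methylated <- function(...) fixture_genome(meth_frac = 1, ...)
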