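# Bitwise-reproducible trajectories: keep the integrator's floating point
# independent of memory alignment (no FMA contraction, no auto-vectorized
# loop peeling), so identical seeds give identical results regardless of
# allocation history.
PKG_CXXFLAGS = -ffp-contract=off -fno-tree-vectorize
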