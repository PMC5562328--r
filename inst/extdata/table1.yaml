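# Reference parameterisation: six canonical activator/inhibitor parameter
# columns (diffusion D um^2/s, decay k 1/s, constant input c uM/s, efficacy
# alpha 1/s). The two panel-2 columns carry their printed stimulus
# (L um, G_star uM, g uM/um); the four panel-3 columns are stimulus-free
# response-curve presets evaluated at the same cone length.
presets:
  fig2C:
    A: {D: 1.0, k: 5.0, c: 0.0, alpha: 0.5}
    I: {D: 100.0, k: 2.0, c: 0.0, alpha: 0.35}
    L: 10.0
    G_star: 10.0
    g: 0.75
  fig2D:
    A: {D: 100.0, k: 2.0, c: 0.0, alpha: 0.35}
    I: {D: 1.0, k: 5.0, c: 0.0, alpha: 0.5}
    L: 10.0
    G_star: 10.0
    g: 0.75
  fig3B:
    A: {D: 1.0, k: 20.0, c: 150.0, alpha: 10.0}
    I: {D: 20.0, k: 1.0, c: 0.05, alpha: 5.0}
    L: 10.0
  fig3C:
    A: {D: 20.0, k: 1.0, c: 0.05, alpha: 2.5}
    I: {D: 1.0, k: 20.0, c: 150.0, alpha: 10.0}
    L: 10.0
  fig3D:
    A: {D: 1.0, k: 20.0, c: 150.0, alpha: 5.0}
    I: {D: 20.0, k: 1.0, c: 0.05, alpha: 5.0}
    L: 10.0
  fig3E:
    A: {D: 20.0, k: 1.0, c: 0.05, alpha: 5.0}
    I: {D: 1.0, k: 20.0, c: 150.0, alpha: 10.0}
    L: 10.0
stated_patterns:
  fig3B: BI_REPEL_TO_ATTRACT
  fig3C: UNI_REPEL
  fig3D: UNI_ATTRACT
  fig3E: BAR
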