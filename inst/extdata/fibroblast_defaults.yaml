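version: 1.0
note: Normalized Boltzmann I-V fitted (tail-referenced) from the synthetic clamp generator's
  default myofibroblast current; phenotypes share the curve, differing in capacitance.
proliferating:
  iv:
    A: 1.0447667
    V_half: -20.0164221
    k: 12.1049533
    C: -0.0377479
  g_scale: 0.25
  E_rev: -50.0
  Cm_CF: 18.0
senescent:
  iv:
    A: 1.0447667
    V_half: -20.0164221
    k: 12.1049533
    C: -0.0377479
  g_scale: 0.25
  E_rev: -50.0
  Cm_CF: 35.0
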