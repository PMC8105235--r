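# EXAMPLE flow-capacity thresholds -- placeholder values for testing and
# demonstration only.  The numeric cutoffs separating flow-capacity classes
# are a clinical choice taken from the flow-capacity literature; review and
# replace them before any real use.
#
# Classes are ordered severe -> normal; each gives the lower bound on CFR
# and on stress perfusion (mL/min/g) at which the class begins.  A point is
# classified by the worse of its two axis classes (lower-left-dominant
# staircase).
classes:
  - name: scar
    cfr_min: 0.0
    stress_min: 0.0
  - name: definite ischemia
    cfr_min: 0.6
    stress_min: 0.4
  - name: moderately reduced
    cfr_min: 1.1
    stress_min: 0.8
  - name: mildly reduced
    cfr_min: 1.6
    stress_min: 1.1
  - name: minimally reduced
    cfr_min: 2.0
    stress_min: 1.4
  - name: normal
    cfr_min: 2.4
    stress_min: 1.8
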