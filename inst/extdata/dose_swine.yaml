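# Dose configuration for the swine low-dose protocol: one volume scan at
# 100 kVp / 200 mA measures 4.6 mGy CTDIvol (32-cm phantom); currents scale
# linearly.  Effective diameter 23 cm, 16 cm cranio-caudal coverage, chest
# DLP coefficient 0.014 mSv per mGy.cm.
ref_ctdi_mgy: 4.6
ref_ma: 200
ref_kvp: 100
low_ma: 50
high_ma: 200
scan_length_cm: 16
effective_diameter_cm: 23
k_msv_per_mgy_cm: 0.014
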