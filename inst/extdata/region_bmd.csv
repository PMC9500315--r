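"region","bmd_mg_cc"
"C2_central_body",200.4
"C2_exterior_body",135.2
"C3_central_body",242.1
"C3_exterior_body",99.7
"C4_central_body",319.2
"C4_exterior_body",185.9
"C5_central_body",301.3
"C5_exterior_body",251.5
"C6_central_body",262.6
"C6_exterior_body",141.8
"C7_central_body",229.1
"C7_exterior_body",124.7
"T1_central_body",165.7
"T1_exterior_body",55.1
"T2_central_body",187.4
"T2_exterior_body",140.4
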